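test_that("the scanner applies the counting and pairing conventions", {
  tx <- tx_tbl("t1", "ATGAAATAG")
  orfs <- scan_orfs(tx)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$codon_length, 2L)  # ATG + AAA, stop excluded

  # nested starts share the downstream stop
  nested <- scan_orfs(tx_tbl("t1", "ATGATGTAA"))
  expect_equal(sort(nested$start), c(0L, 3L))
  expect_equal(unique(nested$end), 9L)

  # no in-frame stop: no candidate
  expect_equal(nrow(scan_orfs(tx_tbl("t1", "ATGAAAAAA"))), 0)

  # codons containing N never match starts or stops
  expect_equal(nrow(scan_orfs(tx_tbl("t1", "ATNAAATAG"))), 0)
  expect_equal(nrow(scan_orfs(tx_tbl("t1", "ATGAAATNA"))), 0)

  # alternative start codons are opt-in
  gug <- tx_tbl("t1", "GTGAAATAG")
  expect_equal(nrow(scan_orfs(gug)), 0)
  expect_equal(scan_orfs(gug, start_codons = c("ATG", "GTG"))$start_codon,
               "GTG")
})

test_that("scanned candidates satisfy their structural invariants", {
  truth <- make_transcriptome(n_transcripts = 10, seed = 31)
  orfs <- scan_orfs(truth$transcripts)
  expect_true(all((orfs$end - orfs$start) %% 3L == 0L))
  expect_true(all(orfs$end - orfs$start >= 6L))
  expect_true(all(orfs$frame == orfs$start %% 3L))
  seqs <- truth$transcripts$sequence[match(orfs$transcript_id,
                                           truth$transcripts$transcript_id)]
  last_codon <- substr(seqs, orfs$end - 2L, orfs$end)
  expect_true(all(last_codon %in% c("TAG", "TAA", "TGA")))
  first_codon <- substr(seqs, orfs$start + 1L, orfs$start + 3L)
  expect_true(all(first_codon == "ATG"))
})

test_that("the scanner agrees with a brute-force oracle on random sequences", {
  set.seed(17)
  mismatches <- 0L
  for (i in 1:1000) {
    len <- sample(1:60, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    got <- scan_orfs(tx_tbl("t1", seq))[, c("start", "end")]
    want <- brute_force_orfs(seq)
    key <- function(d) sort(paste(d$start, d$end))
    if (!identical(key(got), key(want))) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("annotation matching distinguishes recovered from exact", {
  ann <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                        start = c(10L, 20L, 30L), end = c(40L, 50L, 60L))
  # identical sets: full recovery, full exactness
  m1 <- match_annotation(ann, ann)
  expect_equal(m1$recovered_fraction, 1)
  expect_equal(m1$exact_fraction, 1)
  # a 5'-extended start sharing the stop: recovered but not exact
  dn <- ann
  dn$start[2] <- 14L
  m2 <- match_annotation(dn, ann)
  expect_equal(m2$recovered_fraction, 1)
  expect_equal(m2$exact_fraction, 2 / 3)
  # pass fraction relative to the full annotation
  all_ann <- dplyr::bind_rows(ann,
                              tibble::tibble(transcript_id = "t4",
                                             start = 0L, end = 30L))
  expect_equal(match_annotation(dn, ann, all_ann)$annotated_pass_fraction,
               3 / 4)
})

test_that("perturbed annotations reduce the exact fraction by construction", {
  n <- 40L
  ann <- tibble::tibble(transcript_id = sprintf("t%02d", 1:n),
                        start = 30L, end = 120L)
  dn <- ann
  off <- 1:3
  dn$start[off] <- dn$start[off] + 9L  # same stop, shifted start
  m <- match_annotation(dn, ann)
  expect_equal(m$recovered_fraction, 1)
  expect_equal(m$exact_fraction, 37 / 40)
})

test_that("candidates classify into each relation exactly once", {
  main <- tibble::tibble(transcript_id = "t1", start = 30L, end = 90L)
  cands <- tibble::tibble(
    transcript_id = "t1",
    start = c(30L, 0L, 22L, 40L, 96L, 87L, 40L),
    end = c(90L, 9L, 37L, 76L, 105L, 96L, 91L)
  )
  cl <- classify_relative(cands, main)
  expect_equal(cl$relation,
               c("main", "uORF", "overlapping_uORF", "internal_overlapping",
                 "dORF", "readthrough_extension", "other"))
  expect_equal(cl$codon_length[2], 2L)
  expect_error(classify_relative(tibble::tibble(transcript_id = "tX",
                                                start = 0L, end = 9L),
                                 main), "no main CDS")
})

test_that("classification boundaries respect frame and containment", {
  main <- tibble::tibble(transcript_id = "t1", start = 30L, end = 90L)
  # in-frame candidate contained in main is not internal_overlapping
  nested_in_frame <- tibble::tibble(transcript_id = "t1",
                                    start = 42L, end = 90L)
  expect_equal(classify_relative(nested_in_frame, main)$relation, "other")
  # ends exactly at the main start: still a uORF
  touching <- tibble::tibble(transcript_id = "t1", start = 9L, end = 30L)
  expect_equal(classify_relative(touching, main)$relation, "uORF")
  # begins exactly at the main stop, out of frame: dORF only if fully 3'
  at_stop_out_of_frame <- tibble::tibble(transcript_id = "t1",
                                         start = 88L, end = 94L)
  expect_equal(classify_relative(at_stop_out_of_frame, main)$relation,
               "other")
})

test_that("planted 5'-leader uORFs report stop-excluded codon lengths", {
  # ATF4-like leader: a 3-codon uORF and a 59-codon uORF (synthetic
  # sequence, not the RefSeq record)
  leader1 <- paste0(strrep("C", 20), orf_seq(3), strrep("C", 7),
                    orf_seq(59), strrep("C", 11))
  main1 <- orf_seq(100)
  tx1 <- tx_tbl("atf4_like", paste0(leader1, main1, strrep("C", 30)))
  main_cds <- tibble::tibble(transcript_id = "atf4_like",
                             start = nchar(leader1),
                             end = nchar(leader1) + nchar(main1))
  orfs <- scan_orfs(tx1)
  cl <- classify_relative(orfs, main_cds)
  uorfs <- cl[cl$relation == "uORF" & cl$start_codon == "ATG", ]
  expect_true(all(c(3L, 59L) %in% uorfs$codon_length))

  # eIF4G2-like leader with 16- and 7-codon uORFs
  leader2 <- paste0(strrep("C", 25), orf_seq(16), strrep("C", 8),
                    orf_seq(7), strrep("C", 12))
  main2 <- orf_seq(80)
  tx2 <- tx_tbl("eif4g2_like", paste0(leader2, main2, strrep("C", 30)))
  cl2 <- classify_relative(
    scan_orfs(tx2),
    tibble::tibble(transcript_id = "eif4g2_like", start = nchar(leader2),
                   end = nchar(leader2) + nchar(main2))
  )
  u2 <- cl2[cl2$relation == "uORF", ]
  expect_true(all(c(16L, 7L) %in% u2$codon_length))
})

test_that("ORF tables round-trip through the annotation TSV and export to BED", {
  truth <- make_transcriptome(n_transcripts = 4, seed = 12)
  orfs <- scan_orfs(truth$transcripts)
  tsv <- tempfile(fileext = ".tsv")
  write_orfs(orfs, tsv)
  back <- read_cds_annotation(tsv)
  expect_equal(back$start, orfs$start)
  expect_equal(back$end, orfs$end)
  bed <- tempfile(fileext = ".bed")
  write_orfs(orfs, bed, format = "bed")
  bed_back <- read_cds_bed(bed)
  expect_equal(bed_back$start, orfs$start)
})
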