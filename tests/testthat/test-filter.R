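# One candidate spanning codons 0..29 of a 120-nt transcript.
cand <- tibble::tibble(cds_id = "c1", transcript_id = "tx1",
                       start = 0L, end = 90L)

# Reads of the focal class in a given phase at chosen locations.
phased_reads <- function(positions, phase, len = 27L, weight = 1) {
  rd("tx1", as.integer(positions * 3L + phase), len, weight = weight)
}

test_that("support counting reports in-frame reads, locations and phases", {
  reads <- dplyr::bind_rows(
    phased_reads(0:9, phase = 1, weight = 5),  # 50 in expected phase, 10 locs
    phased_reads(0:4, phase = 0, weight = 2)   # 10 out of phase
  )
  sup <- support_counts(cand, reads, focal_length = 27L, expected_phase = 1L)
  expect_equal(sup$reads_in_frame, 50)
  expect_equal(sup$distinct_locations, 10L)
  expect_equal(sup$phase1, 50)
  expect_equal(sup$phase0, 10)
  expect_equal(sup$maximal_phase, 1L)
})

test_that("distinct locations agree with the occupancy oracle", {
  L <- 20L
  k <- 50L
  set.seed(13)
  occ <- replicate(200, {
    pos <- sample(0:(L - 1), k, replace = TRUE)
    reads <- phased_reads(pos, phase = 1)
    sup <- support_counts(cand, reads, 27L, 1L)
    # dual check: the package count equals direct enumeration
    stopifnot(sup$distinct_locations == length(unique(pos)))
    sup$distinct_locations
  })
  expected <- L * (1 - (1 - 1 / L)^k)
  expect_lt(abs(mean(occ) - expected), 3 * stats::sd(occ) / sqrt(length(occ)))
})

test_that("filter thresholds are sharp at (50 reads, 10 locations)", {
  cfg <- filter_config(focal_length = 27L, expected_phase = 1L)
  pass_reads <- phased_reads(0:9, phase = 1, weight = 5)
  rep1 <- filter_cds(cand, pass_reads, cfg)
  expect_true(rep1$pass)
  expect_true(is.na(rep1$failure_reason))

  few <- pass_reads
  few$weight[1] <- 4  # 49 reads, still 10 locations
  rep2 <- filter_cds(cand, few, cfg)
  expect_false(rep2$pass)
  expect_equal(rep2$failure_reason, "min_reads")

  clustered <- dplyr::bind_rows(phased_reads(0:8, phase = 1, weight = 5),
                                phased_reads(8, phase = 1, weight = 5))
  rep3 <- filter_cds(cand, clustered, cfg)  # 50 reads, 9 locations
  expect_false(rep3$pass)
  expect_equal(rep3$failure_reason, "min_locations")
})

test_that("reads piled on a single location fail the location rule", {
  reads <- phased_reads(rep(3, 1), phase = 1, weight = 50)
  cfg <- filter_config(focal_length = 27L, expected_phase = 1L)
  rep <- filter_cds(cand, reads, cfg)
  expect_equal(rep$distinct_locations, 1L)
  expect_equal(rep$failure_reason, "min_locations")
})

test_that("the chi-square statistic matches a brute-force Pearson computation", {
  res <- phase_consistency_test(c(90, 10), c(50, 50), alpha = 0.05)
  tab <- rbind(c(90, 10), c(50, 50))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  brute <- sum((tab - expected)^2 / expected)
  expect_lt(abs(res$chi2 - brute), 1e-9)
  expect_lt(res$p, 1e-6)
  expect_true(res$pass)
})

test_that("the phase test requires enrichment in the right direction", {
  # candidate matching the global proportions: no enrichment, fail
  expect_false(phase_consistency_test(c(50, 50), c(500, 500))$pass)
  # all reads in the maximal phase: fail regardless of significance
  expect_false(phase_consistency_test(c(0, 100), c(500, 500))$pass)
  # strong enrichment over the global ratio: pass
  expect_true(phase_consistency_test(c(90, 10), c(100, 300))$pass)
  expect_error(phase_consistency_test(c(10, 10), c(0, 0)), "global")
})

test_that("out-of-phase shadows of a hot region are excluded by the phase test", {
  cands <- tibble::tibble(
    cds_id = c("real", "shadow", "genuine"),
    transcript_id = c("t1", "t2", "t3"),
    start = 0L, end = 90L
  )
  reads <- dplyr::bind_rows(
    # the real region: concordant, deep
    rd("t1", 0:19 * 3L + 1L, 27L, weight = 45),
    # shadow: jitter reads in the expected phase, bulk in another phase
    rd("t2", 0:11 * 3L + 1L, 27L, weight = 5),
    rd("t2", 0:11 * 3L + 0L, 27L, weight = 50),
    # genuine discordant region: nearly balanced, strongly enriched
    # in the expected phase relative to the global ratio
    rd("t3", 0:19 * 3L + 1L, 27L, weight = 30),
    rd("t3", 0:19 * 3L + 0L, 27L, weight = 33)
  )
  cfg <- filter_config(focal_length = 27L, expected_phase = 1L)
  rep <- filter_cds(cands, reads, cfg)
  expect_true(rep$pass[rep$cds_id == "real"])
  expect_false(rep$pass[rep$cds_id == "shadow"])
  expect_equal(rep$failure_reason[rep$cds_id == "shadow"], "phase_test")
  expect_true(rep$pass[rep$cds_id == "genuine"])
})

test_that("a constructed candidate set passes in the constructed numbers", {
  n <- 20L
  good <- 7L
  cands <- tibble::tibble(cds_id = sprintf("c%02d", 1:n),
                          transcript_id = sprintf("t%02d", 1:n),
                          start = 0L, end = 90L)
  reads <- purrr::map(seq_len(n), function(i) {
    w <- if (i <= good) 6 else 2  # 60 vs 20 in-frame reads over 10 locations
    rd(sprintf("t%02d", i), 0:9 * 3L + 1L, 27L, weight = w)
  }) |> dplyr::bind_rows()
  cfg <- filter_config(focal_length = 27L, expected_phase = 1L)
  rep <- filter_cds(cands, reads, cfg)
  expect_equal(sum(rep$pass), good)
})

test_that("raising thresholds never enlarges the pass set, and added in-frame
           reads never flip a candidate to fail", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12L
    cands <- tibble::tibble(cds_id = sprintf("c%02d", 1:n),
                            transcript_id = sprintf("t%02d", 1:n),
                            start = 0L, end = 90L)
    reads <- purrr::map(seq_len(n), function(i) {
      k <- sample(20:90, 1)
      pos <- sample(0:29, k, replace = TRUE)
      ph <- sample(0:2, k, replace = TRUE, prob = c(0.2, 0.6, 0.2))
      rd(sprintf("t%02d", i), pos * 3L + ph, 27L)
    }) |> dplyr::bind_rows()
    cfg <- filter_config(min_reads = 30, min_locations = 8,
                         focal_length = 27L, expected_phase = 1L)
    base <- filter_cds(cands, reads, cfg)
    stricter <- filter_cds(cands, reads,
                           filter_config(min_reads = 45, min_locations = 12,
                                         focal_length = 27L,
                                         expected_phase = 1L))
    expect_true(all(passing_cds(stricter)$cds_id %in%
                      passing_cds(base)$cds_id))
    # add in-frame focal reads to one passing candidate: it must keep passing
    if (any(base$pass)) {
      lucky <- passing_cds(base)$transcript_id[1]
      more <- rd(lucky, 0:9 * 3L + 1L, 27L, weight = 10)
      again <- filter_cds(cands, dplyr::bind_rows(reads, more), cfg)
      expect_true(again$pass[again$transcript_id == lucky])
    }
  }
})
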