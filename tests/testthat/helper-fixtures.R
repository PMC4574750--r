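# In-code fixture builders shared across the suite.

# Quick read-table constructor.
rd <- function(transcript_id, five_prime, length = 27L, sample = "s1",
               weight = 1) {
  tibble::tibble(transcript_id = transcript_id,
                 five_prime = as.integer(five_prime),
                 length = as.integer(length), sample = sample,
                 weight = weight)
}

# A transcript tibble from raw sequences (optionally with a CDS).
tx_tbl <- function(ids, seqs, cds_start = NA_integer_, cds_end = NA_integer_,
                   category = "mRNA") {
  tibble::tibble(transcript_id = ids, sequence = seqs, length = nchar(seqs),
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end), category = category)
}

# An ORF of k sense codons with a stop-free body.
orf_seq <- function(k, body = "GCT", stop = "TAA") {
  paste0("ATG", strrep(body, k - 1L), stop)
}

# Hand-built SAM file from records; returns the path.
write_test_sam <- function(sq, records) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)),
               records), path)
  path
}

# A SAM record with given qname/flag/ref/1-based pos and read length.
sam_rec <- function(qname, rname, pos, len, flag = 0L) {
  sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, len, strrep("A", len))
}

# Brute-force ORF scanner used as the independent oracle: walks every
# position, reads codons one at a time.
brute_force_orfs <- function(seq, start_codons = "ATG") {
  stops <- c("TAG", "TAA", "TGA")
  n <- nchar(seq)
  out <- list()
  for (s in seq_len(n)) {
    if (s + 2 > n) break
    if (!(substr(seq, s, s + 2) %in% start_codons)) next
    p <- s + 3
    while (p + 2 <= n) {
      cod <- substr(seq, p, p + 2)
      if (cod %in% stops) {
        out[[length(out) + 1]] <- c(start = s - 1L, end = p + 2L)
        break
      }
      p <- p + 3
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]))
}
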