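#' Read transcriptome alignments into a read table
#'
#' Parses a SAM or BAM file of footprint (or RNA-seq) reads aligned to
#' transcript references and normalises each aligned record into one row
#' of the internal read model: the 0-based transcript offset of the
#' read's leftmost aligned base (`five_prime`, SAM `POS - 1`), the
#' aligned read length after soft-clipping, and a sample label.
#'
#' Reads on a transcriptome are sense by definition, so unmapped and
#' reverse-strand records are dropped (and counted in the attached
#' summary). Reads whose query name carries several alignments are
#' resolved according to `multimap_policy`: `"random"` assigns each such
#' read to exactly one of its alignments uniformly at random under
#' `seed` (conserving the total read count), `"all"` keeps every
#' alignment (diagnostics only).
#'
#' @param path SAM (`.sam`) or BAM file aligned to transcript references.
#' @param transcripts Transcript tibble from [read_transcriptome()];
#'   every reference name in the alignment must resolve against it.
#' @param sample Sample label stored with each read.
#' @param seed Integer seed for the multimap assignment (mandatory so
#'   runs are reproducible).
#' @param multimap_policy `"random"` (default) or `"all"`.
#' @param length_window Two integers; reads whose aligned length falls
#'   outside are dropped and logged. Default `c(20, 40)`.
#'
#' @return A tibble of reads (`transcript_id`, `five_prime`, `length`,
#'   `sample`, `weight`, `read_seq`) with a `"drop_summary"` attribute
#'   counting unmapped/reverse/out-of-window records.
#' @export
read_alignments <- function(path, transcripts, sample = "sample1",
                            seed = 1L, multimap_policy = c("random", "all"),
                            length_window = c(20L, 40L)) {
  multimap_policy <- match.arg(multimap_policy)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")
  ))[[1]]
  n_total <- length(res$qname)
  mapped <- !bitwAnd(res$flag, 4L)
  reverse <- bitwAnd(res$flag, 16L) > 0L & mapped
  keep <- mapped & !reverse
  qlen <- rep(NA_integer_, n_total)
  qlen[keep] <- GenomicAlignments::cigarWidthAlongQuerySpace(
    res$cigar[keep], after.soft.clipping = TRUE
  )
  in_window <- keep & qlen >= length_window[1] & qlen <= length_window[2]
  reads <- tibble(
    qname = res$qname[in_window],
    transcript_id = as.character(res$rname[in_window]),
    five_prime = res$pos[in_window] - 1L,
    length = qlen[in_window],
    read_seq = as.character(res$seq[in_window])
  )
  unknown <- setdiff(reads$transcript_id, transcripts$transcript_id)
  if (length(unknown)) {
    abort(paste0("alignment references absent from the transcriptome: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (multimap_policy == "random") {
    reads <- withr::with_seed(seed, {
      reads %>%
        group_by(.data$qname) %>%
        slice(sample.int(n(), 1L)) %>%
        ungroup()
    })
  }
  out <- reads %>%
    mutate(sample = sample, weight = 1) %>%
    select("transcript_id", "five_prime", "length", "sample", "weight",
           "read_seq") %>%
    arrange(.data$transcript_id, .data$five_prime, .data$length)
  attr(out, "drop_summary") <- c(
    records = n_total,
    unmapped = sum(!mapped),
    reverse_strand = sum(reverse),
    outside_length_window = sum(keep & !in_window)
  )
  attr(out, "multimap") <- list(policy = multimap_policy, seed = seed)
  out
}

#' Write a read table as SAM
#'
#' Emits a minimal valid SAM file (header `@SQ` lines from the
#' transcript table, one record per read, CIGAR all-match) so that
#' simulated reads round-trip through [read_alignments()]. Read
#' sequences are taken from `read_seq` when present, otherwise extracted
#' from the transcript sequence.
#'
#' @param reads Read tibble (`transcript_id`, `five_prime`, `length`, ...).
#' @param transcripts Transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, transcripts, path) {
  idx <- match(reads$transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) abort("reads reference transcripts absent from the transcriptome")
  seqs <- reads[["read_seq"]]
  if (is.null(seqs) || anyNA(seqs)) {
    seqs <- substr(transcripts$sequence[idx], reads$five_prime + 1L,
                   reads$five_prime + reads$length)
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", transcripts$transcript_id, transcripts$length)
  )
  qname <- sprintf("r%07d", seq_len(nrow(reads)))
  records <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     qname, reads$transcript_id, reads$five_prime + 1L,
                     reads$length, seqs)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Per-sample read totals
#'
#' @param reads Read tibble.
#' @return Tibble `sample`, `total` (sum of weights).
#' @export
read_totals <- function(reads) {
  reads %>%
    group_by(.data$sample) %>%
    summarise(total = sum(.data$weight), .groups = "drop")
}
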