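#' Per-transcript frame-coloured profile
#'
#' Builds the data behind the per-transcript view: footprint 5'-end
#' counts split by frame relative to transcript nt 1 (`position mod 3`),
#' RNA-seq coverage as an underlay, and the ORF track of candidate
#' coding regions with their filter status. By default the ORF track is
#' restricted to candidates with at least 50 footprints mapping to at
#' least 10 locations (`show_all = TRUE` keeps every candidate).
#'
#' @param ribo_reads Footprint read tibble.
#' @param rna_reads RNA-seq read tibble (may be empty or `NULL`).
#' @param transcripts Transcript tibble.
#' @param transcript_id Transcript to profile.
#' @param orf_track Optional candidate tibble; when it is a
#'   [filter_cds()] report the `pass` column is used, otherwise all
#'   rows are treated as passing.
#' @param lengths Optional length classes kept for the footprint series
#'   (default all).
#' @param rna_mode `"coverage"` (full-read coverage, default) or
#'   `"five_prime"` (5'-end counts) for the RNA underlay.
#' @param show_all Keep unsupported ORF candidates in the track.
#' @return List of class `ribo_transcript_profile`: `transcript_id`,
#'   `length` (nt), `ribo` (tibble `position`, `frame`, `count`; one
#'   row per position and frame), `rna` (tibble `position`, `coverage`),
#'   `orfs` (candidate tibble with `pass`).
#' @export
transcript_profile <- function(ribo_reads, rna_reads, transcripts,
                               transcript_id, orf_track = NULL,
                               lengths = NULL,
                               rna_mode = c("coverage", "five_prime"),
                               show_all = FALSE) {
  rna_mode <- match.arg(rna_mode)
  tx <- transcripts[transcripts$transcript_id == transcript_id, ]
  if (!nrow(tx)) abort(paste0("unknown transcript: ", transcript_id))
  tlen <- tx$length[1]
  rr <- ribo_reads[ribo_reads$transcript_id == transcript_id, ]
  if (!is.null(lengths)) rr <- rr[rr$length %in% lengths, ]
  ribo <- tidyr::expand_grid(position = 0:(tlen - 1L), frame = 0:2) %>%
    mutate(count = 0)
  if (nrow(rr)) {
    tallied <- rr %>%
      mutate(position = .data$five_prime, frame = .data$five_prime %% 3L) %>%
      group_by(.data$position, .data$frame) %>%
      summarise(count = sum(.data$weight), .groups = "drop")
    ribo <- ribo %>%
      rows_update_counts(tallied)
  }
  rna <- tibble(position = 0:(tlen - 1L), coverage = 0)
  if (!is.null(rna_reads)) {
    nr <- rna_reads[rna_reads$transcript_id == transcript_id, ]
    if (nrow(nr)) {
      if (rna_mode == "five_prime") {
        cov <- tapply(nr$weight, factor(nr$five_prime, levels = 0:(tlen - 1L)),
                      sum, default = 0)
      } else {
        cov <- numeric(tlen)
        for (i in seq_len(nrow(nr))) {
          span <- (nr$five_prime[i] + 1L):min(nr$five_prime[i] + nr$length[i],
                                              tlen)
          cov[span] <- cov[span] + nr$weight[i]
        }
      }
      rna$coverage <- as.numeric(cov)
    }
  }
  orfs <- NULL
  if (!is.null(orf_track)) {
    orfs <- as_tibble(unclass(orf_track)) %>%
      filter(.data$transcript_id == !!transcript_id)
    if (is.null(orfs[["pass"]])) {
      sup <- support_counts_any_length(orfs, ribo_reads)
      orfs$pass <- sup$n_reads >= 50 & sup$n_locations >= 10
    }
    if (!show_all) orfs <- filter(orfs, .data$pass)
  }
  structure(
    list(transcript_id = transcript_id, length = tlen,
         ribo = ribo, rna = rna, orfs = orfs),
    class = "ribo_transcript_profile"
  )
}

# Interior footprint support of candidates, all lengths and phases
# pooled (the display-track criterion: ">= 50 reads at >= 10 locations").
support_counts_any_length <- function(candidates, reads) {
  base <- tibble(cds_id = candidates$cds_id, n_reads = 0, n_locations = 0L)
  if (!nrow(candidates) || !nrow(reads)) return(base)
  sup <- interior_reads(reads, candidates) %>%
    group_by(.data$cds_id) %>%
    summarise(n_reads = sum(.data$weight),
              n_locations = n_distinct(.data$five_prime), .groups = "drop")
  idx <- match(base$cds_id, sup$cds_id)
  base$n_reads <- dplyr::coalesce(sup$n_reads[idx], 0)
  base$n_locations <- dplyr::coalesce(sup$n_locations[idx], 0L)
  base
}

rows_update_counts <- function(grid, tallied) {
  key <- paste(grid$position, grid$frame)
  idx <- match(paste(tallied$position, tallied$frame), key)
  grid$count[idx] <- tallied$count
  grid
}

#' Centred sliding-window mean over codon counts
#'
#' @param counts Numeric series indexed per codon.
#' @param window_codons Odd window size (default 15). Edges use
#'   truncated windows (the mean over the codons available); a window
#'   larger than the series yields the global mean everywhere.
#' @return Numeric series of the same length.
#' @export
sliding_window_mean <- function(counts, window_codons = 15L) {
  n <- length(counts)
  if (!n) return(numeric())
  if (window_codons %% 2L == 0L) abort("window_codons must be odd")
  if (window_codons >= n) return(rep(mean(counts), n))
  half <- window_codons %/% 2L
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Codon-indexed filtered counts for the sliding-window track
#'
#' Counts footprint 5' ends of the predominant size class in its called
#' frame, per codon of that frame across the whole transcript — the
#' "filtered" series smoothed under the per-transcript plot.
#'
#' @param profile A [transcript_profile()].
#' @param calls A [frame_call()] result (sets size class and frame), or
#'   `NULL` to pool all lengths/frames.
#' @param ribo_reads The footprint read tibble the profile was built
#'   from (needed to restrict by length when `calls` is given).
#' @return Tibble `codon` (0-based), `position` (first nt), `count`.
#' @export
codon_counts <- function(profile, calls = NULL, ribo_reads = NULL) {
  tlen <- profile$length
  if (is.null(calls)) {
    per_pos <- profile$ribo %>%
      group_by(.data$position) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    frame0 <- 0L
  } else {
    cls <- predominant_class(calls)
    if (is.null(ribo_reads)) abort("ribo_reads needed when calls is given")
    rr <- ribo_reads %>%
      filter(.data$transcript_id == profile$transcript_id,
             .data$length == cls$length)
    per_pos <- rr %>%
      group_by(position = .data$five_prime) %>%
      summarise(count = sum(.data$weight), .groups = "drop")
    frame0 <- 0L
  }
  codon <- 0:((tlen - 1L) %/% 3L)
  pos0 <- codon * 3L + frame0
  cnt <- numeric(length(codon))
  if (nrow(per_pos)) {
    idx <- per_pos$position %/% 3L + 1L
    keep <- idx >= 1 & idx <= length(cnt)
    agg <- tapply(per_pos$count[keep], idx[keep], sum)
    cnt[as.integer(names(agg))] <- agg
  }
  tibble(codon = codon, position = pos0, count = cnt)
}
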