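#' Restrict reads to the interior of coding regions
#'
#' A read is interior to a CDS when the entire read is contained within
#' the coding interval (`start <= five_prime` and
#' `five_prime + length <= end`), which in general excludes footprints of
#' initiating and terminating ribosomes. Each retained read is annotated
#' with the CDS it falls in and its phase relative to that CDS's own
#' start (`(five_prime - start) mod 3`): the codon position its 5' end
#' maps to, 0-based (displayed as codon positions 1..3).
#'
#' @param reads Read tibble.
#' @param cds Tibble `cds_id`, `transcript_id`, `start`, `end` (e.g.
#'   [cds_table()] output or ORF candidates).
#' @return Read tibble with added `cds_id`, `cds_start`, `cds_end`,
#'   `phase` columns. A read interior to several overlapping CDSs
#'   appears once per CDS.
#' @export
interior_reads <- function(reads, cds) {
  if (!nrow(cds)) abort("empty CDS set")
  reads %>%
    inner_join(
      select(cds, "cds_id", "transcript_id", cds_start = "start", cds_end = "end"),
      by = "transcript_id", relationship = "many-to-many"
    ) %>%
    filter(.data$cds_start <= .data$five_prime,
           .data$five_prime + .data$length <= .data$cds_end) %>%
    mutate(phase = (.data$five_prime - .data$cds_start) %% 3L)
}

#' Phase histogram of 5' ends by read-length class
#'
#' Tallies interior-read 5' ends by (length, phase): the triplet
#' periodicity fingerprint used for frame calling.
#'
#' @param interior Output of [interior_reads()].
#' @param length_window Two integers bounding the length classes kept.
#' @return Tibble `sample`, `length`, `phase`, `count`, class
#'   `ribo_phase_hist`; all (length, phase) cells in the window present
#'   (zero-filled).
#' @export
phase_by_length <- function(interior, length_window = c(20L, 40L)) {
  if (is.null(interior[["phase"]])) {
    abort("reads carry no phase; run interior_reads() first")
  }
  kept <- interior %>%
    filter(.data$length >= length_window[1], .data$length <= length_window[2])
  hist <- kept %>%
    group_by(.data$sample, .data$length, .data$phase) %>%
    summarise(count = sum(.data$weight), .groups = "drop") %>%
    tidyr::complete(
      !!rlang::sym("sample"),
      length = seq.int(length_window[1], length_window[2]),
      phase = 0:2,
      fill = list(count = 0)
    ) %>%
    arrange(.data$sample, .data$length, .data$phase)
  class(hist) <- c("ribo_phase_hist", class(hist))
  hist
}

#' Normalised read-length distribution per transcript group
#'
#' @param interior Output of [interior_reads()].
#' @param groups Optional tibble `transcript_id`, `group` partitioning
#'   the transcripts (e.g. by genomic compartment); unlisted transcripts
#'   are dropped. Default: one group `"all"`.
#' @param length_window Length classes kept.
#' @return Tibble `sample`, `group`, `length`, `count`, `fraction`;
#'   fractions sum to 1 within each non-empty (sample, group).
#' @export
length_distribution <- function(interior, groups = NULL,
                                length_window = c(20L, 40L)) {
  kept <- interior %>%
    filter(.data$length >= length_window[1], .data$length <= length_window[2])
  if (is.null(groups)) {
    kept$group <- "all"
  } else {
    kept <- inner_join(kept, groups, by = "transcript_id")
  }
  kept %>%
    group_by(.data$sample, .data$group, .data$length) %>%
    summarise(count = sum(.data$weight), .groups = "drop_last") %>%
    mutate(fraction = .data$count / sum(.data$count)) %>%
    ungroup() %>%
    arrange(.data$sample, .data$group, .data$length)
}

#' Call the predominant frame per read-length class
#'
#' For each length class the phase with the most 5' ends is the frame
#' call; its fraction of the class total measures framing fidelity. Ties
#' are broken toward the smallest phase index with a warning.
#'
#' @param hist A [phase_by_length()] histogram.
#' @return Tibble `sample`, `length`, `phase`, `fraction`, `total`,
#'   `tied`, class `ribo_frame_call`; empty length classes are dropped.
#' @export
frame_call <- function(hist) {
  if (!nrow(hist)) abort("empty phase histogram")
  calls <- hist %>%
    group_by(.data$sample, .data$length) %>%
    summarise(
      total = sum(.data$count),
      phase = .data$phase[which.max(.data$count)],
      top = max(.data$count),
      tied = sum(.data$count == max(.data$count)) > 1L,
      .groups = "drop"
    ) %>%
    filter(.data$total > 0) %>%
    mutate(fraction = .data$top / .data$total) %>%
    select("sample", "length", "phase", "fraction", "total", "tied")
  if (any(calls$tied)) {
    warn(paste0("tied phase counts for length class(es) ",
                paste(calls$length[calls$tied], collapse = ", "),
                "; smallest phase index reported"))
  }
  class(calls) <- c("ribo_frame_call", class(calls))
  calls
}

#' @export
tidy.ribo_frame_call <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.ribo_frame_call <- function(x, ...) {
  x <- as_tibble(unclass(x))
  x %>%
    group_by(.data$sample) %>%
    summarise(
      predominant_length = .data$length[which.max(.data$total)],
      predominant_phase = .data$phase[which.max(.data$total)],
      framing_fidelity = .data$fraction[which.max(.data$total)],
      total_reads = sum(.data$total),
      .groups = "drop"
    )
}

#' Most abundant read-length class of a frame call
#'
#' @param calls A [frame_call()] result (single sample, or the first
#'   sample is used with a message).
#' @return Named list `length`, `phase` for the most abundant class.
#' @export
predominant_class <- function(calls) {
  if (n_distinct(calls$sample) > 1L) {
    inform("multiple samples in frame call; using the first")
    calls <- calls[calls$sample == calls$sample[1], ]
  }
  i <- which.max(calls$total)
  list(length = calls$length[i], phase = calls$phase[i])
}
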