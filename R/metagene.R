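#' Select coding regions for metagene averaging
#'
#' Keeps coding regions with at least `min_reads` reads of the most
#' abundant read-length size class mapping in frame at `min_locations`
#' or more separate locations — the same support gate as the main
#' filter, without the phase-consistency step.
#'
#' @param reads Read tibble.
#' @param cds CDS tibble (`cds_id`, `transcript_id`, `start`, `end`).
#' @param calls [frame_call()] result giving the most abundant size
#'   class and its expected phase.
#' @param min_reads,min_locations Support thresholds (defaults 50, 10).
#' @return Subset of `cds`; warns (does not error) when empty.
#' @export
select_metagene_transcripts <- function(reads, cds, calls,
                                        min_reads = 50L, min_locations = 10L) {
  cls <- predominant_class(calls)
  sup <- support_counts(cds, reads, cls$length, cls$phase)
  keep <- sup$cds_id[sup$reads_in_frame >= min_reads &
                       sup$distinct_locations >= min_locations]
  out <- cds[cds$cds_id %in% keep, ]
  if (!nrow(out)) warn("no coding regions meet the metagene support criteria")
  out
}

#' Weighted metagene profile of footprint 5' ends
#'
#' Averages, over the selected coding regions, the positional abundance
#' of n-nt read 5' ends around the start and stop codons (offset 0 =
#' first nucleotide of the start/stop codon). Each coding region's
#' positional counts are down-weighted by its mean per-nucleotide
#' density of n-nt reads (total n-nt reads within the CDS divided by
#' CDS length), so highly translated regions do not dominate; the
#' profile is the simple mean of these normalised counts over
#' contributing regions. Regions with zero n-nt reads contribute
#' nothing for that size class.
#'
#' @param reads Read tibble.
#' @param selected CDS tibble, e.g. from
#'   [select_metagene_transcripts()].
#' @param lengths Integer vector of read-length classes to profile.
#' @param start_window,stop_window Offset windows (defaults `-30..60`
#'   around the start, `-60..30` around the stop).
#' @return Tibble of class `ribo_metagene`: `sample`, `length`,
#'   `anchor` (`"start"`/`"stop"`), `offset`, `density`,
#'   `n_transcripts`.
#' @export
metagene_profile <- function(reads, selected, lengths,
                             start_window = c(-30L, 60L),
                             stop_window = c(-60L, 30L)) {
  if (!nrow(selected)) abort("empty selection for metagene profile")
  joined <- reads %>%
    filter(.data$length %in% lengths) %>%
    inner_join(select(selected, "cds_id", "transcript_id",
                      cds_start = "start", cds_end = "end"),
               by = "transcript_id", relationship = "many-to-many")
  dens <- joined %>%
    filter(.data$five_prime >= .data$cds_start,
           .data$five_prime < .data$cds_end) %>%
    group_by(.data$sample, .data$cds_id, .data$length) %>%
    summarise(total = sum(.data$weight),
              cds_len = .data$cds_end[1] - .data$cds_start[1],
              .groups = "drop") %>%
    mutate(density = .data$total / .data$cds_len)
  n_contrib <- dens %>%
    count(.data$sample, .data$length, name = "n_transcripts")
  one_anchor <- function(anchor, window) {
    anchored <- joined %>%
      mutate(offset = .data$five_prime -
               if (anchor == "start") .data$cds_start else .data$cds_end - 3L) %>%
      filter(.data$offset >= window[1], .data$offset <= window[2]) %>%
      group_by(.data$sample, .data$cds_id, .data$length, .data$offset) %>%
      summarise(count = sum(.data$weight), .groups = "drop") %>%
      inner_join(select(dens, "sample", "cds_id", "length", "density"),
                 by = c("sample", "cds_id", "length")) %>%
      mutate(norm = .data$count / .data$density) %>%
      group_by(.data$sample, .data$length, .data$offset) %>%
      summarise(wsum = sum(.data$norm), .groups = "drop")
    grid <- tidyr::expand_grid(
      dplyr::distinct(n_contrib, .data$sample, .data$length),
      offset = seq.int(window[1], window[2])
    )
    grid %>%
      left_join(anchored, by = c("sample", "length", "offset")) %>%
      inner_join(n_contrib, by = c("sample", "length")) %>%
      mutate(anchor = anchor,
             density = dplyr::coalesce(.data$wsum, 0) / .data$n_transcripts) %>%
      select("sample", "length", "anchor", "offset", "density",
             "n_transcripts")
  }
  out <- bind_rows(one_anchor("start", start_window),
                   one_anchor("stop", stop_window)) %>%
    arrange(.data$sample, .data$length, .data$anchor, .data$offset)
  class(out) <- c("ribo_metagene", class(out))
  out
}

#' Infer footprint geometry from metagene profiles
#'
#' Reads the protected-fragment geometry off the positions of the
#' profile maxima. The initiating ribosome holds the start codon in its
#' P-site, so the start-window maximum sits at offset `-L5` and gives
#' the elongation-state geometry: `L5 = -offset`, `L3 = n - L5 - 6`
#' (two-codon P/A core). The terminating (paused) ribosome holds the
#' stop codon in its empty A-site, so the stop-window maximum sits at
#' offset `-(L5 + 3)` and gives the termination-state geometry:
#' `L5 = -offset - 3`, `L3 = n - L5 - 6`.
#'
#' Maxima are searched within `+/-(n + margin)` nt of the anchor; exact
#' ties are resolved toward the offset nearest the canonical
#' expectation and flagged `ambiguous`.
#'
#' @param profile A [metagene_profile()].
#' @param margin Search-window slack beyond the read length (default 5).
#' @return Tibble of class `ribo_geometry`: `sample`, `length`, `state`
#'   (`"elongation"`/`"termination"`), `peak_offset`, `L5`, `L3`,
#'   `ambiguous`.
#' @export
infer_offsets <- function(profile, margin = 5L) {
  locate <- function(d, key) {
    n <- key$length[1]
    win <- d[abs(d$offset) <= n + margin, ]
    if (!nrow(win) || all(win$density == 0)) {
      return(tibble(peak_offset = NA_integer_, ambiguous = NA))
    }
    peaks <- win$offset[win$density == max(win$density)]
    expect <- if (key$anchor[1] == "start") -(n %/% 2) else -(n %/% 2) - 3L
    tibble(peak_offset = peaks[which.min(abs(peaks - expect))],
           ambiguous = length(peaks) > 1L)
  }
  peaks <- as_tibble(unclass(profile)) %>%
    group_by(.data$sample, .data$length, .data$anchor) %>%
    dplyr::group_modify(locate) %>%
    ungroup()
  out <- peaks %>%
    mutate(
      state = ifelse(.data$anchor == "start", "elongation", "termination"),
      L5 = ifelse(.data$anchor == "start",
                  -.data$peak_offset, -.data$peak_offset - 3L),
      L3 = .data$length - .data$L5 - 6L
    ) %>%
    select("sample", "length", "state", "peak_offset", "L5", "L3",
           "ambiguous")
  class(out) <- c("ribo_geometry", class(out))
  out
}

#' @export
tidy.ribo_geometry <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.ribo_geometry <- function(x, ...) {
  x <- as_tibble(unclass(x))
  tibble(
    n_classes = nrow(x),
    n_ambiguous = sum(x$ambiguous, na.rm = TRUE),
    geometry_consistent = all(x$L5 + 6L + x$L3 == x$length, na.rm = TRUE)
  )
}

#' End extensions relative to a reference elongation class
#'
#' Expresses each (length, state) footprint geometry as nucleotides
#' added at the 5' and 3' ends relative to a reference elongation-state
#' class — e.g. a termination footprint one class longer with unchanged
#' `L5` reports `(delta5, delta3) = (0, +1)`.
#'
#' @param geometry A [infer_offsets()] result (or any tibble with
#'   `length`, `state`, `L5`, `L3`).
#' @param reference_length Length of the reference elongation class;
#'   default the shortest elongation class present.
#' @return Tibble `sample`, `length`, `state`, `delta5`, `delta3`.
#' @export
termination_extension <- function(geometry, reference_length = NULL) {
  geo <- as_tibble(unclass(geometry))
  if (is.null(geo[["sample"]])) geo$sample <- "sample1"
  elong <- geo %>% filter(.data$state == "elongation", !is.na(.data$L5))
  if (is.null(reference_length)) {
    if (!nrow(elong)) abort("no elongation class available as reference")
    reference_length <- min(elong$length)
  }
  refs <- elong %>%
    filter(.data$length == reference_length) %>%
    select("sample", ref_L5 = "L5", ref_L3 = "L3")
  if (!nrow(refs)) {
    abort(sprintf("reference elongation class %d missing from geometry",
                  reference_length))
  }
  geo %>%
    inner_join(refs, by = "sample") %>%
    mutate(delta5 = .data$L5 - .data$ref_L5,
           delta3 = .data$L3 - .data$ref_L3) %>%
    select("sample", "length", "state", "delta5", "delta3")
}
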