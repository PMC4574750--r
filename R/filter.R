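#' Filtering thresholds for translated coding regions
#'
#' Defaults follow the package's standard gate: a coding region is
#' considered credibly translated when it contains at least 50 reads of
#' the focal length class in the expected phase, mapping to at least 10
#' distinct locations, and (when its maximal phase disagrees with the
#' expected phase) survives a chi-square phase-consistency test at
#' alpha = 0.05.
#'
#' @param min_reads Minimum in-frame focal-length reads (default 50).
#' @param min_locations Minimum distinct 5'-end locations among those
#'   reads (default 10).
#' @param focal_length Read-length class used for support counting;
#'   `NULL` means take the predominant class from a frame call.
#' @param expected_phase Phase (0..2, relative to each CDS's own start)
#'   expected for focal-length reads; `NULL` means take it from the
#'   frame call.
#' @param alpha Significance threshold of the phase test.
#' @param phase_test_all Apply the chi-square test to every candidate
#'   (`TRUE`) or only when maximal phase != expected phase (default).
#' @param correct Continuity correction for the chi-square test
#'   (default off).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_reads = 50L, min_locations = 10L,
                          focal_length = NULL, expected_phase = NULL,
                          alpha = 0.05, phase_test_all = FALSE,
                          correct = FALSE) {
  stopifnot(min_reads >= 1, min_locations >= 1, alpha > 0, alpha < 1)
  structure(
    list(min_reads = as.integer(min_reads),
         min_locations = as.integer(min_locations),
         focal_length = focal_length, expected_phase = expected_phase,
         alpha = alpha, phase_test_all = phase_test_all, correct = correct),
    class = "filter_config"
  )
}

#' In-frame support of candidate coding regions
#'
#' For each candidate, counts interior reads of the focal length class
#' whose phase (relative to the candidate's own start) equals the
#' expected phase, the number of distinct 5'-end locations among them,
#' and the full per-phase counts used by the phase-consistency test.
#'
#' @param candidates Tibble `cds_id`, `transcript_id`, `start`, `end`.
#' @param reads Read tibble.
#' @param focal_length Length class counted.
#' @param expected_phase Expected phase (0..2).
#' @return Tibble per candidate: `reads_in_frame`, `distinct_locations`,
#'   `phase0`, `phase1`, `phase2`, `maximal_phase`, `expected_phase`.
#' @export
support_counts <- function(candidates, reads, focal_length, expected_phase) {
  focal <- interior_reads(reads, candidates) %>%
    filter(.data$length == focal_length)
  per_phase <- focal %>%
    group_by(.data$cds_id, .data$phase) %>%
    summarise(count = sum(.data$weight), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "count",
                       names_prefix = "phase", values_fill = 0)
  for (col in paste0("phase", 0:2)) {
    if (is.null(per_phase[[col]])) per_phase[[col]] <- 0
  }
  locs <- focal %>%
    filter(.data$phase == expected_phase) %>%
    group_by(.data$cds_id) %>%
    summarise(reads_in_frame = sum(.data$weight),
              distinct_locations = n_distinct(.data$five_prime),
              .groups = "drop")
  out <- candidates %>%
    select("cds_id", "transcript_id", "start", "end") %>%
    left_join(per_phase, by = "cds_id") %>%
    left_join(locs, by = "cds_id") %>%
    mutate(across(all_of(c("phase0", "phase1", "phase2",
                           "reads_in_frame", "distinct_locations")),
                  ~ dplyr::coalesce(.x, 0)))
  pc <- as.matrix(out[, paste0("phase", 0:2)])
  out$maximal_phase <- max.col(pc, ties.method = "first") - 1L
  out$expected_phase <- as.integer(expected_phase)
  out
}

#' Chi-square phase-consistency test for a discordant candidate
#'
#' A highly translated region sheds a small proportion of out-of-phase
#' reads onto overlapping, out-of-phase candidate regions, which can
#' carry enough raw support to pass the count filters. For a candidate
#' whose maximal phase is not its expected phase, this test compares the
#' candidate's expected:maximal read ratio with the ratio aggregated
#' over all supported coding regions using a 2x2 Pearson chi-square test
#' (df = 1). The candidate is kept only if its ratio exceeds the global
#' ratio *and* the difference is significant at `alpha`.
#'
#' @param candidate_counts Numeric length-2: candidate reads in
#'   (expected phase, maximal phase).
#' @param global_counts Numeric length-2: the same two counts aggregated
#'   over all supported coding regions.
#' @param alpha Significance threshold.
#' @param correct Continuity correction (default off).
#' @return List `chi2`, `p`, `pass`.
#' @export
phase_consistency_test <- function(candidate_counts, global_counts,
                                   alpha = 0.05, correct = FALSE) {
  if (sum(global_counts) <= 0) abort("zero global phase counts")
  tab <- rbind(as.numeric(candidate_counts), as.numeric(global_counts))
  direction <- candidate_counts[1] * global_counts[2] >
    candidate_counts[2] * global_counts[1]
  if (sum(candidate_counts) == 0) {
    return(list(chi2 = NA_real_, p = NA_real_, pass = FALSE))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value),
       pass = direction && unname(ht$p.value) < alpha)
}

#' Filter candidate coding regions by footprint support
#'
#' Applies the full gate: focal-length in-frame read count, distinct
#' locations, then the phase-consistency test for candidates whose
#' maximal phase disagrees with the expected phase. The global reference
#' counts for the phase test are aggregated over the candidates passing
#' the count/location filters (before the phase test), avoiding
#' circularity.
#'
#' @param candidates Tibble `cds_id`, `transcript_id`, `start`, `end`.
#' @param reads Read tibble.
#' @param config A [filter_config()].
#' @param calls Optional [frame_call()] result used to default
#'   `focal_length` and `expected_phase`.
#' @return A tibble of class `ribo_filter`: one row per candidate with
#'   support counts, `chi2`, `p_value`, `pass` and `failure_reason`
#'   (`"min_reads"`, `"min_locations"`, `"phase_test"` or `NA`). The
#'   applied configuration is attached as attribute `"config"`.
#' @export
filter_cds <- function(candidates, reads, config = filter_config(),
                       calls = NULL) {
  if (!nrow(candidates)) abort("empty candidate set")
  focal_length <- config$focal_length
  expected_phase <- config$expected_phase
  if (is.null(focal_length) || is.null(expected_phase)) {
    if (is.null(calls)) {
      abort("focal_length/expected_phase unset and no frame call supplied")
    }
    cls <- predominant_class(calls)
    focal_length <- focal_length %||% cls$length
    expected_phase <- expected_phase %||% cls$phase
  }
  rep <- support_counts(candidates, reads, focal_length, expected_phase)
  rep$count_pass <- rep$reads_in_frame >= config$min_reads &
    rep$distinct_locations >= config$min_locations
  pc <- as.matrix(rep[, paste0("phase", 0:2)])
  expected_n <- pc[cbind(seq_len(nrow(rep)), rep$expected_phase + 1L)]
  maximal_n <- pc[cbind(seq_len(nrow(rep)), rep$maximal_phase + 1L)]
  global <- c(sum(expected_n[rep$count_pass]), sum(maximal_n[rep$count_pass]))
  need_test <- rep$count_pass &
    (config$phase_test_all | rep$maximal_phase != rep$expected_phase)
  rep$chi2 <- NA_real_
  rep$p_value <- NA_real_
  rep$phase_pass <- TRUE
  for (i in which(need_test)) {
    res <- phase_consistency_test(c(expected_n[i], maximal_n[i]), global,
                                  alpha = config$alpha,
                                  correct = config$correct)
    rep$chi2[i] <- res$chi2
    rep$p_value[i] <- res$p
    rep$phase_pass[i] <- res$pass
  }
  rep <- rep %>%
    mutate(
      pass = .data$count_pass & .data$phase_pass,
      failure_reason = case_when(
        .data$reads_in_frame < config$min_reads ~ "min_reads",
        .data$distinct_locations < config$min_locations ~ "min_locations",
        !.data$phase_pass ~ "phase_test",
        TRUE ~ NA_character_
      )
    ) %>%
    select(-"count_pass", -"phase_pass")
  attr(rep, "config") <- config
  attr(rep, "focal_length") <- focal_length
  attr(rep, "global_counts") <- global
  class(rep) <- c("ribo_filter", class(rep))
  rep
}

#' @export
tidy.ribo_filter <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.ribo_filter <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_candidates = nrow(x),
    n_pass = sum(x$pass),
    focal_length = attr(x, "focal_length"),
    min_reads = cfg$min_reads,
    min_locations = cfg$min_locations,
    alpha = cfg$alpha
  )
}

#' Passing coding regions of a filter report
#'
#' @param report A [filter_cds()] report.
#' @return Tibble `cds_id`, `transcript_id`, `start`, `end` of the
#'   passing candidates.
#' @export
passing_cds <- function(report) {
  as_tibble(unclass(report)) %>%
    filter(.data$pass) %>%
    select("cds_id", "transcript_id", "start", "end")
}
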