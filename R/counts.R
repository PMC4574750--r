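#' Export per-CDS footprint counts over size-class/frame combinations
#'
#' Sums interior reads per passing coding region and sample over the
#' configured (length, phase) combinations — e.g. only 27-nt reads in
#' the expected phase — producing the count matrix consumed by
#' count-based differential-translation tools.
#'
#' @param reads Footprint read tibble.
#' @param passing_cds Tibble `cds_id`, `transcript_id`, `start`, `end`.
#' @param combos Tibble with columns `length` and `phase` (phase `NA`
#'   means any phase; phases are relative to each CDS's own start).
#' @param length_window Valid length range; combos outside it error.
#' @return Tibble of class `ribo_counts`: one row per CDS
#'   (`cds_id`, `transcript_id`, `cds_length`) with one integer count
#'   column per sample. The combination spec is attached as attribute
#'   `"combos"`.
#' @export
export_counts <- function(reads, passing_cds, combos,
                          length_window = c(20L, 40L)) {
  if (!nrow(combos)) abort("empty combination spec")
  if (any(combos$length < length_window[1] | combos$length > length_window[2])) {
    abort("combination references a length outside the length window")
  }
  interior <- interior_reads(reads, passing_cds)
  match_combo <- rep(FALSE, nrow(interior))
  for (i in seq_len(nrow(combos))) {
    hit <- interior$length == combos$length[i]
    if (!is.na(combos$phase[i])) hit <- hit & interior$phase == combos$phase[i]
    match_combo <- match_combo | hit
  }
  samples <- sort(unique(reads$sample))
  counts <- interior[match_combo, ] %>%
    group_by(.data$cds_id, .data$sample) %>%
    summarise(count = sum(.data$weight), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0)
  out <- passing_cds %>%
    mutate(cds_length = .data$end - .data$start) %>%
    select("cds_id", "transcript_id", "cds_length") %>%
    left_join(counts, by = "cds_id")
  for (s in samples) {
    if (is.null(out[[s]])) out[[s]] <- 0
    out[[s]] <- as.integer(dplyr::coalesce(out[[s]], 0))
  }
  attr(out, "combos") <- combos
  attr(out, "samples") <- samples
  class(out) <- c("ribo_counts", class(out))
  out
}

#' Pair footprint counts with RNA-seq counts per CDS
#'
#' RNA-seq counting uses any-overlap with the CDS interval (any frame,
#' any length); `interior_only = TRUE` restricts to fully contained
#' reads.
#'
#' @param ribo_matrix A [export_counts()] result.
#' @param rna_reads RNA-seq read tibble; sample labels must match the
#'   footprint matrix columns.
#' @param cds_set The CDS tibble the matrix was built on.
#' @param interior_only Count only fully contained RNA reads.
#' @return Long tibble `cds_id`, `transcript_id`, `sample`, `ribo`,
#'   `rna` (CDSs absent from the RNA store get `rna = 0`).
#' @export
pair_with_rna <- function(ribo_matrix, rna_reads, cds_set,
                          interior_only = FALSE) {
  samples <- attr(ribo_matrix, "samples") %||%
    setdiff(names(ribo_matrix), c("cds_id", "transcript_id", "cds_length"))
  rna_samples <- unique(rna_reads$sample)
  unmatched <- setdiff(samples, rna_samples)
  if (length(unmatched)) {
    abort(paste0("samples missing from the RNA store: ",
                 paste(unmatched, collapse = ", ")))
  }
  overlapped <- rna_reads %>%
    inner_join(select(cds_set, "cds_id", "transcript_id",
                      cds_start = "start", cds_end = "end"),
               by = "transcript_id", relationship = "many-to-many")
  overlapped <- if (interior_only) {
    filter(overlapped, .data$cds_start <= .data$five_prime,
           .data$five_prime + .data$length <= .data$cds_end)
  } else {
    filter(overlapped, .data$five_prime < .data$cds_end,
           .data$five_prime + .data$length > .data$cds_start)
  }
  rna_counts <- overlapped %>%
    group_by(.data$cds_id, .data$sample) %>%
    summarise(rna = sum(.data$weight), .groups = "drop")
  as_tibble(unclass(ribo_matrix)) %>%
    tidyr::pivot_longer(all_of(samples), names_to = "sample",
                        values_to = "ribo") %>%
    left_join(rna_counts, by = c("cds_id", "sample")) %>%
    mutate(rna = as.integer(dplyr::coalesce(.data$rna, 0))) %>%
    select("cds_id", "transcript_id", "sample", "ribo", "rna")
}

#' Write a count matrix with its provenance sidecar
#'
#' @param matrix A [export_counts()] result.
#' @param path Output TSV path; a JSON sidecar recording the
#'   combination spec is written next to it (`<path>.json`).
#' @param provenance Optional named list merged into the sidecar
#'   (filters, seeds, versions).
#' @return `path`, invisibly.
#' @export
write_counts <- function(matrix, path, provenance = list()) {
  readr::write_tsv(as_tibble(unclass(matrix)), path)
  sidecar <- c(
    list(combos = as.data.frame(attr(matrix, "combos")),
         samples = attr(matrix, "samples")),
    provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
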