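#' De novo ORF scan of a transcriptome
#'
#' Identifies, in every reading frame of every transcript, each start
#' codon paired with its nearest downstream in-frame stop codon
#' (TAG/TAA/TGA). Nested starts sharing a stop yield distinct
#' candidates; starts with no in-frame stop are omitted; codons
#' containing `N` never match. The candidate interval includes the stop
#' codon; `codon_length` counts sense codons only (stop excluded), so
#' the smallest reported ORF `ATG <stop>` has `codon_length` 1.
#'
#' @param transcripts Transcript tibble.
#' @param min_codons Minimum sense-codon count (default 1).
#' @param start_codons Codons accepted as starts. Default canonical
#'   `"ATG"`; near-cognate initiators (e.g. `"GTG"`, `"CTG"`) may be
#'   added when footprint evidence warrants.
#' @return Tibble `cds_id`, `transcript_id`, `frame` (0..2 relative to
#'   transcript nt 1), `start`, `end` (0-based half-open, stop
#'   included), `start_codon`, `codon_length`, `provenance =
#'   "de_novo"`, ordered by transcript then start.
#' @export
scan_orfs <- function(transcripts, min_codons = 1L, start_codons = "ATG") {
  stops <- c("TAG", "TAA", "TGA")
  one <- function(id, seq) {
    spos <- sort(unique(unname(unlist(
      stringi::stri_locate_all_fixed(seq, start_codons) |>
        lapply(function(m) m[, 1])
    ))))
    spos <- spos[!is.na(spos)]
    tpos <- sort(unname(unlist(
      stringi::stri_locate_all_fixed(seq, stops) |> lapply(function(m) m[, 1])
    )))
    tpos <- tpos[!is.na(tpos)]
    if (!length(spos) || !length(tpos)) return(NULL)
    res <- vector("list", 3L)
    for (f in 0:2) {
      sf <- spos[(spos - 1L) %% 3L == f]
      tf <- tpos[(tpos - 1L) %% 3L == f]
      if (!length(sf) || !length(tf)) next
      idx <- findInterval(sf + 2L, tf) + 1L
      ok <- idx <= length(tf)
      if (!any(ok)) next
      sf <- sf[ok]
      stop1 <- tf[idx[ok]]
      res[[f + 1L]] <- tibble(
        transcript_id = id, frame = f,
        start = sf - 1L, end = stop1 + 2L,
        start_codon = substr(rep(seq, length(sf)), sf, sf + 2L)
      )
    }
    bind_rows(res)
  }
  out <- purrr::map2(transcripts$transcript_id, transcripts$sequence, one) %>%
    bind_rows()
  if (!nrow(out)) {
    return(tibble(cds_id = character(), transcript_id = character(),
                  frame = integer(), start = integer(), end = integer(),
                  start_codon = character(), codon_length = integer(),
                  provenance = character()))
  }
  out %>%
    mutate(
      codon_length = (.data$end - .data$start) %/% 3L - 1L,
      cds_id = paste0(.data$transcript_id, ":", .data$start, "-", .data$end),
      provenance = "de_novo"
    ) %>%
    filter(.data$codon_length >= min_codons) %>%
    arrange(match(.data$transcript_id, transcripts$transcript_id), .data$start) %>%
    select("cds_id", "transcript_id", "frame", "start", "end",
           "start_codon", "codon_length", "provenance")
}

#' Compare de novo ORFs against annotation
#'
#' An annotated coding region is *recovered* when some de novo candidate
#' on the same transcript shares its stop (hence its frame); a recovered
#' region is an *exact* match when the start coordinate agrees too.
#'
#' @param de_novo_pass De novo candidates passing the support filter.
#' @param annotated_pass Annotated CDSs passing the same filter
#'   (`transcript_id`, `start`, `end`).
#' @param annotated_all Optional full annotated CDS set, used for the
#'   fraction of all annotated CDSs that pass the filter.
#' @return One-row tibble: `n_annotated_pass`, `n_recovered`,
#'   `recovered_fraction`, `exact_fraction` (of recovered),
#'   `annotated_pass_fraction` (`NA` unless `annotated_all` given).
#' @export
match_annotation <- function(de_novo_pass, annotated_pass,
                             annotated_all = NULL) {
  ann <- annotated_pass %>%
    mutate(
      recovered = paste(.data$transcript_id, .data$end) %in%
        paste(de_novo_pass$transcript_id, de_novo_pass$end),
      exact = paste(.data$transcript_id, .data$start, .data$end) %in%
        paste(de_novo_pass$transcript_id, de_novo_pass$start,
              de_novo_pass$end)
    )
  tibble(
    n_annotated_pass = nrow(ann),
    n_recovered = sum(ann$recovered),
    recovered_fraction = mean(ann$recovered),
    exact_fraction = if (any(ann$recovered)) {
      sum(ann$exact) / sum(ann$recovered)
    } else NA_real_,
    annotated_pass_fraction = if (is.null(annotated_all)) NA_real_ else {
      nrow(ann) / nrow(annotated_all)
    }
  )
}

#' Classify ORF candidates relative to a main coding region
#'
#' Assigns each candidate exactly one relation to the designated main
#' CDS of its transcript: `main` (identical interval), `uORF` (entirely
#' 5' of the main start), `overlapping_uORF` (starts 5' of the main
#' start and overlaps it out of frame), `internal_overlapping`
#' (contained within the main CDS, different frame),
#' `readthrough_extension` (in frame with the main CDS, starting at its
#' stop codon — the footprint signature of stop-codon readthrough, e.g.
#' selenocysteine insertion), `dORF` (entirely 3' of the main stop), or
#' `other` for overlaps not covered by these definitions.
#'
#' @param candidates Candidate tibble (`transcript_id`, `start`, `end`,
#'   ...).
#' @param main_cds Tibble `transcript_id`, `start`, `end`, one row per
#'   transcript. Candidates on transcripts absent from it raise an
#'   error.
#' @return `candidates` with added `relation` and `codon_length`
#'   columns.
#' @export
classify_relative <- function(candidates, main_cds) {
  missing_tx <- setdiff(candidates$transcript_id, main_cds$transcript_id)
  if (length(missing_tx)) {
    abort(paste0("no main CDS for transcript(s): ",
                 paste(head(missing_tx, 5), collapse = ", ")))
  }
  m <- main_cds[match(candidates$transcript_id, main_cds$transcript_id), ]
  same_frame <- (candidates$start - m$start) %% 3L == 0L
  candidates %>%
    mutate(
      codon_length = (.data$end - .data$start) %/% 3L - 1L,
      relation = case_when(
        .data$start == m$start & .data$end == m$end ~ "main",
        same_frame & .data$start == m$end - 3L ~ "readthrough_extension",
        .data$end <= m$start ~ "uORF",
        .data$start < m$start & .data$end > m$start & !same_frame ~
          "overlapping_uORF",
        .data$start >= m$start & .data$end <= m$end & !same_frame ~
          "internal_overlapping",
        .data$start >= m$end ~ "dORF",
        TRUE ~ "other"
      )
    )
}

#' Export ORF candidates as a CDS annotation TSV or BED
#'
#' @param candidates Candidate tibble.
#' @param path Output path.
#' @param format `"tsv"` (3-column CDS annotation, round-trips through
#'   [read_cds_annotation()]) or `"bed"` (transcript-space BED).
#' @return `path`, invisibly.
#' @export
write_orfs <- function(candidates, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(select(candidates, "transcript_id", "start", "end"),
                     path, col_names = FALSE)
  } else {
    if (is.null(candidates[["cds_id"]])) {
      candidates$cds_id <- paste0(candidates$transcript_id, ":",
                                  candidates$start, "-", candidates$end)
    }
    bed <- candidates %>%
      mutate(score = 0L, strand = "+") %>%
      select("transcript_id", "start", "end", name = "cds_id",
             "score", "strand")
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
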