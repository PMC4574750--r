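#' Read a transcriptome FASTA with optional CDS annotation
#'
#' Loads transcript sequences and normalises them into the internal data
#' model. Sequences are uppercased and RNA alphabet (`U`) is converted to
#' DNA (`T`). All coordinates in the package are 0-based, half-open
#' intervals in transcript space; plots display 1-based positions.
#'
#' @param fasta_path Path to a FASTA file of transcript sequences.
#' @param annotation_path Optional path to a 3-column TSV
#'   (`transcript_id`, `start`, `end`; 0-based half-open, stop codon
#'   included in the interval) of annotated coding regions.
#' @param category_path Optional path to a 2-column TSV
#'   (`transcript_id`, `category`) assigning each transcript to one of
#'   `mRNA`, `rRNA`, `gDNA`, `ncRNA`, `other`. Unlisted transcripts are
#'   assigned `mRNA`.
#'
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `sequence`, `length`, `cds_start`, `cds_end` (`NA` when
#'   unannotated) and `category`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "ATGAAATAG"), fa)
#' read_transcriptome(fa)
read_transcriptome <- function(fasta_path, annotation_path = NULL,
                               category_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate transcript ids in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sequence <- chartr("u", "T", chartr("U", "T", toupper(as.character(seqs))))
  tx <- tibble(
    transcript_id = ids,
    sequence = unname(sequence),
    length = nchar(sequence),
    cds_start = NA_integer_,
    cds_end = NA_integer_,
    category = "mRNA"
  )
  if (any(tx$length < 1)) {
    abort("zero-length sequence in FASTA")
  }
  if (!is.null(annotation_path)) {
    ann <- read_cds_annotation(annotation_path)
    tx <- attach_cds(tx, ann)
  }
  if (!is.null(category_path)) {
    cat_map <- readr::read_tsv(category_path, col_names = c("transcript_id", "category"),
                               col_types = "cc", progress = FALSE)
    tx <- tx %>%
      select(-"category") %>%
      left_join(cat_map, by = "transcript_id") %>%
      mutate(category = dplyr::coalesce(.data$category, "mRNA"))
  }
  tx
}

#' Read a CDS annotation table
#'
#' @param path 3-column TSV: `transcript_id`, `start`, `end` (0-based,
#'   half-open, stop codon included). A header line is optional.
#' @return Tibble with columns `transcript_id`, `start`, `end`.
#' @export
read_cds_annotation <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("transcript_id", first, fixed = TRUE)
  ann <- readr::read_tsv(path,
    col_names = if (has_header) TRUE else c("transcript_id", "start", "end"),
    col_types = "cii", progress = FALSE
  )
  names(ann)[1:3] <- c("transcript_id", "start", "end")
  as_tibble(ann[, 1:3])
}

#' Import CDS intervals from BED
#'
#' Thin shim: takes the first three BED columns (chrom = transcript id,
#' chromStart, chromEnd — already 0-based half-open) as a CDS table.
#'
#' @param path BED file in transcript space.
#' @return Tibble `transcript_id`, `start`, `end`.
#' @export
read_cds_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  tibble(
    transcript_id = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]])
  )
}

#' Attach CDS annotation to a transcript table
#'
#' Validates the intervals (in-bounds, length a multiple of 3) and fills
#' the `cds_start`/`cds_end` columns. One CDS per transcript; for
#' multi-CDS use keep the annotation as a separate table (see
#' [cds_table()]).
#'
#' @param transcripts Transcript tibble from [read_transcriptome()].
#' @param annotation Tibble `transcript_id`, `start`, `end`.
#' @return The transcript tibble with CDS columns filled.
#' @export
attach_cds <- function(transcripts, annotation) {
  unknown <- setdiff(annotation$transcript_id, transcripts$transcript_id)
  if (length(unknown)) {
    abort(paste0("annotation references unknown transcripts: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  ann <- annotation %>%
    left_join(select(transcripts, "transcript_id", "length"), by = "transcript_id")
  bad <- ann$start < 0 | ann$end > ann$length | ann$start >= ann$end
  if (any(bad)) {
    abort(paste0("CDS interval out of bounds on transcript(s): ",
                 paste(head(ann$transcript_id[bad], 5), collapse = ", ")))
  }
  notrip <- (ann$end - ann$start) %% 3L != 0L
  if (any(notrip)) {
    abort(paste0("CDS length not a multiple of 3 on transcript(s): ",
                 paste(head(ann$transcript_id[notrip], 5), collapse = ", ")))
  }
  idx <- match(transcripts$transcript_id, ann$transcript_id)
  transcripts$cds_start <- as.integer(ann$start[idx])
  transcripts$cds_end <- as.integer(ann$end[idx])
  transcripts
}

#' Extract the annotated CDS set from a transcript table
#'
#' @param transcripts Transcript tibble.
#' @return Tibble `cds_id`, `transcript_id`, `start`, `end` with one row
#'   per annotated CDS (`cds_id` is `transcript_id` for annotated CDSs).
#' @export
cds_table <- function(transcripts) {
  transcripts %>%
    filter(!is.na(.data$cds_start)) %>%
    mutate(cds_id = .data$transcript_id) %>%
    select("cds_id", "transcript_id", start = "cds_start", end = "cds_end")
}

#' Write transcripts to FASTA (and optionally their CDS annotation)
#'
#' @param transcripts Transcript tibble.
#' @param fasta_path Output FASTA path.
#' @param annotation_path Optional output TSV path for the annotated CDSs.
#' @return `fasta_path`, invisibly.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                            transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(annotation_path)) {
    ann <- cds_table(transcripts) %>% select("transcript_id", "start", "end")
    readr::write_tsv(ann, annotation_path, col_names = FALSE)
  }
  invisible(fasta_path)
}
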