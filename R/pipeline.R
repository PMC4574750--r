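#' Build a run configuration
#'
#' Collects paths, thresholds, windows and seeds for a staged pipeline
#' run. Values may come from a YAML file, from the argument list, or
#' from the defaults — precedence: arguments > file > defaults.
#'
#' @param path Optional YAML config file.
#' @param ... Named overrides of any config field: `fasta`,
#'   `annotation`, `ribo_sam` (named character vector, one per
#'   sample), `rna_sam`, `category_map`, `out_dir`, `seed`,
#'   `min_reads`, `min_locations`, `alpha`, `focal_length`,
#'   `length_window`, `window_codons`, `preset`, `n_reads`, `n_rna`,
#'   `n_transcripts`, `rrna_fraction`, `fidelity`.
#' @return Named list of class `run_config` with the merged settings.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    fasta = NULL, annotation = NULL, ribo_sam = NULL, rna_sam = NULL,
    category_map = NULL, out_dir = "ribostep_out", seed = 1L,
    min_reads = 50L, min_locations = 10L, alpha = 0.05,
    focal_length = NULL, length_window = c(20L, 40L), window_codons = 15L,
    preset = "cr27", n_reads = 100000L, n_rna = 20000L,
    n_transcripts = 50L, rrna_fraction = 0.05, fidelity = 0.95
  )
  cfg <- defaults
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Run pipeline stages end to end
#'
#' Executes the requested stages in order, writing each stage's TSV
#' outputs plus a provenance log (package version, seeds, thresholds)
#' into `config$out_dir`. With `stage = "simulate"` first (or no input
#' paths configured) the synthetic generator supplies the transcriptome
#' and alignments, so the whole pipeline runs with no external data.
#' Identical configs and seeds reproduce all TSV outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector from `simulate`, `framing`, `filter`,
#'   `discover`, `metagene`, `qc`, `counts` (default: all, in that
#'   order).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "framing", "filter",
                                    "discover", "metagene", "qc", "counts")) {
  known <- c("simulate", "framing", "filter", "discover", "metagene",
             "qc", "counts")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  state <- list()

  if ("simulate" %in% stages) {
    truth <- make_transcriptome(n_transcripts = config$n_transcripts,
                                seed = config$seed)
    preset <- geometry_preset(config$preset, fidelity = config$fidelity)
    sim <- simulate_reads(truth, preset, n_reads = config$n_reads,
                          seed = config$seed + 1L,
                          rrna_fraction = config$rrna_fraction,
                          n_rna = config$n_rna)
    fasta <- file.path(config$out_dir, "transcriptome.fa")
    ann <- file.path(config$out_dir, "annotation.tsv")
    write_transcriptome(truth$transcripts, fasta, ann)
    write_sam(sim$ribo, truth$transcripts,
              file.path(config$out_dir, "ribo.sam"))
    if (nrow(sim$rna)) {
      write_sam(sim$rna, truth$transcripts,
                file.path(config$out_dir, "rna.sam"))
    }
    jsonlite::write_json(
      list(seed = config$seed, preset = config$preset,
           orfs = as.data.frame(truth$orfs)),
      file.path(config$out_dir, "sim_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
    state$transcripts <- truth$transcripts
    state$ribo <- sim$ribo
    state$rna <- sim$rna
    state$truth <- truth
    out$simulate <- truth
  } else {
    for (p in c("fasta")) {
      if (is.null(config[[p]])) abort(paste0("config field missing: ", p))
      if (!file.exists(config[[p]])) {
        abort(paste0("input path does not exist: ", config[[p]]))
      }
    }
    state$transcripts <- read_transcriptome(config$fasta, config$annotation,
                                            config$category_map)
    load_sams <- function(paths) {
      if (is.null(paths)) return(empty_reads())
      nm <- names(paths) %||% paste0("sample", seq_along(paths))
      purrr::map2(unname(paths), nm, function(p, s) {
        if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
        read_alignments(p, state$transcripts, sample = s, seed = config$seed,
                        length_window = config$length_window)
      }) %>% bind_rows()
    }
    state$ribo <- load_sams(config$ribo_sam)
    state$rna <- load_sams(config$rna_sam)
  }

  cds <- cds_table(state$transcripts)

  if (any(c("framing", "filter", "metagene", "counts") %in% stages)) {
    interior <- interior_reads(state$ribo, cds)
    state$hist <- phase_by_length(interior, config$length_window)
    state$calls <- frame_call(state$hist)
  }

  if ("framing" %in% stages) {
    readr::write_tsv(as_tibble(unclass(state$hist)),
                     file.path(config$out_dir, "phase_histogram.tsv"))
    readr::write_tsv(tidy(state$calls),
                     file.path(config$out_dir, "frame_calls.tsv"))
    interior <- interior_reads(state$ribo, cds)
    readr::write_tsv(length_distribution(interior,
                                         length_window = config$length_window),
                     file.path(config$out_dir, "length_distribution.tsv"))
    out$framing <- state$calls
  }

  fcfg <- filter_config(min_reads = config$min_reads,
                        min_locations = config$min_locations,
                        focal_length = config$focal_length,
                        alpha = config$alpha)

  if (any(c("filter", "metagene", "counts") %in% stages)) {
    state$report <- filter_cds(cds, state$ribo, fcfg, calls = state$calls)
  }
  if ("filter" %in% stages) {
    readr::write_tsv(tidy(state$report),
                     file.path(config$out_dir, "filter_report.tsv"))
    out$filter <- state$report
  }

  if ("discover" %in% stages) {
    orfs <- scan_orfs(state$transcripts)
    dn_report <- filter_cds(orfs, state$ribo, fcfg, calls = state$calls)
    readr::write_tsv(tidy(dn_report),
                     file.path(config$out_dir, "orf_candidates.tsv"))
    if (!is.null(state$report)) {
      stats <- match_annotation(passing_cds(dn_report),
                                passing_cds(state$report),
                                annotated_all = cds)
      readr::write_tsv(stats,
                       file.path(config$out_dir, "annotation_match.tsv"))
    }
    out$discover <- dn_report
  }

  if ("metagene" %in% stages) {
    sel <- select_metagene_transcripts(state$ribo, cds, state$calls,
                                       config$min_reads,
                                       config$min_locations)
    lengths <- sort(unique(state$calls$length[state$calls$total >=
                                                0.05 * sum(state$calls$total)]))
    prof <- metagene_profile(state$ribo, sel, lengths)
    geo <- infer_offsets(prof)
    readr::write_tsv(as_tibble(unclass(prof)),
                     file.path(config$out_dir, "metagene_profile.tsv"))
    readr::write_tsv(tidy(geo),
                     file.path(config$out_dir, "footprint_geometry.tsv"))
    out$metagene <- geo
  }

  if ("qc" %in% stages) {
    comp <- composition(state$ribo, state$transcripts)
    readr::write_tsv(comp, file.path(config$out_dir, "composition.tsv"))
    fk <- fpkm(state$ribo, state$transcripts)
    readr::write_tsv(fk, file.path(config$out_dir, "fpkm.tsv"))
    out$qc <- comp
  }

  if ("counts" %in% stages) {
    cls <- predominant_class(state$calls)
    combos <- tibble(length = cls$length, phase = cls$phase)
    cm <- export_counts(state$ribo, passing_cds(state$report), combos,
                        config$length_window)
    write_counts(cm, file.path(config$out_dir, "cds_counts.tsv"),
                 provenance = list(seed = config$seed,
                                   min_reads = config$min_reads,
                                   min_locations = config$min_locations))
    if (!is.null(state$rna) && nrow(state$rna)) {
      paired <- pair_with_rna(cm, state$rna, passing_cds(state$report))
      readr::write_tsv(paired,
                       file.path(config$out_dir, "ribo_rna_counts.tsv"))
    }
    out$counts <- cm
  }

  jsonlite::write_json(
    list(package = "ribostep",
         version = as.character(utils::packageVersion("ribostep")),
         seed = config$seed, stages = stages,
         thresholds = list(min_reads = config$min_reads,
                           min_locations = config$min_locations,
                           alpha = config$alpha),
         length_window = config$length_window),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out)
}
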