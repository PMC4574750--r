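#' Library composition and mRNA enrichment
#'
#' Fractions of reads per category (rRNA / mRNA / gDNA / other) for each
#' sample, the core diagnostic of an rRNA-depletion treatment. Reads on
#' uncategorised transcripts are assigned `"other"` (logged).
#'
#' @param reads Read tibble (one or more samples).
#' @param transcripts Transcript tibble carrying `category`, or a
#'   2-column tibble `transcript_id`, `category`.
#' @return Tibble `sample`, `category`, `count`, `fraction`; fractions
#'   sum to 1 per sample.
#' @export
composition <- function(reads, transcripts) {
  cat_map <- select(transcripts, "transcript_id", "category")
  joined <- reads %>% left_join(cat_map, by = "transcript_id")
  n_uncat <- sum(is.na(joined$category))
  if (n_uncat) {
    inform(sprintf("%d reads on uncategorised transcripts assigned 'other'",
                   n_uncat))
    joined$category[is.na(joined$category)] <- "other"
  }
  joined %>%
    group_by(.data$sample, .data$category) %>%
    summarise(count = sum(.data$weight), .groups = "drop_last") %>%
    mutate(fraction = .data$count / sum(.data$count)) %>%
    ungroup()
}

#' mRNA enrichment factor between two samples
#'
#' @param comp A [composition()] table.
#' @param treated,untreated Sample labels.
#' @param category Category whose fraction is compared (default
#'   `"mRNA"`).
#' @return Scalar: fraction in treated / fraction in untreated.
#' @export
enrichment_factor <- function(comp, treated, untreated, category = "mRNA") {
  f <- function(s) {
    x <- comp$fraction[comp$sample == s & comp$category == category]
    if (!length(x)) 0 else x
  }
  f(treated) / f(untreated)
}

#' Per-transcript read density (FPKM)
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count / (length/1000) / (total/1e6)` per sample.
#'
#' @param reads Read tibble.
#' @param transcripts Transcript tibble.
#' @return Tibble `sample`, `transcript_id`, `count`, `fpkm` (all
#'   transcripts present, zero-filled).
#' @export
fpkm <- function(reads, transcripts) {
  if (any(transcripts$length <= 0)) abort("zero-length transcript")
  totals <- read_totals(reads)
  if (any(totals$total <= 0) || !nrow(totals)) abort("no mapped reads")
  tidyr::expand_grid(sample = totals$sample,
                     transcript_id = transcripts$transcript_id) %>%
    left_join(
      reads %>%
        group_by(.data$sample, .data$transcript_id) %>%
        summarise(count = sum(.data$weight), .groups = "drop"),
      by = c("sample", "transcript_id")
    ) %>%
    mutate(count = dplyr::coalesce(.data$count, 0)) %>%
    left_join(totals, by = "sample") %>%
    left_join(select(transcripts, "transcript_id", "length"),
              by = "transcript_id") %>%
    mutate(fpkm = .data$count / (.data$length / 1e3) / (.data$total / 1e6)) %>%
    select("sample", "transcript_id", "count", "fpkm")
}

#' Distinct read-species count table for two samples
#'
#' Species identity is the exact read sequence; species-level counts
#' drive the depletion-bias diagnostics. Requires `read_seq` on the
#' reads (kept by [read_alignments()] and the simulator) or falls back
#' to extracting the sequence from the transcript.
#'
#' @param reads Read tibble covering both samples.
#' @param sample_a,sample_b Sample labels: reference/untreated (A) and
#'   treated (B).
#' @param transcripts Transcript tibble (used when `read_seq` absent and
#'   to restrict to a category).
#' @param category Restrict to reads on transcripts of this category
#'   (default `"mRNA"`; `NULL` keeps all).
#' @return Tibble `species`, `count_a`, `count_b` with attributes
#'   `total_a`, `total_b` (per-sample mapped totals within the
#'   category).
#' @export
species_table <- function(reads, sample_a, sample_b, transcripts,
                          category = "mRNA") {
  if (!is.null(category)) {
    keep <- transcripts$transcript_id[transcripts$category == category]
    reads <- reads[reads$transcript_id %in% keep, ]
  }
  if (is.null(reads[["read_seq"]]) || anyNA(reads[["read_seq"]])) {
    idx <- match(reads$transcript_id, transcripts$transcript_id)
    reads$read_seq <- substr(transcripts$sequence[idx],
                             reads$five_prime + 1L,
                             reads$five_prime + reads$length)
  }
  ab <- reads[reads$sample %in% c(sample_a, sample_b), ]
  tab <- ab %>%
    group_by(species = .data$read_seq, .data$sample) %>%
    summarise(count = sum(.data$weight), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0)
  for (s in c(sample_a, sample_b)) if (is.null(tab[[s]])) tab[[s]] <- 0
  out <- tibble(species = tab$species,
                count_a = tab[[sample_a]], count_b = tab[[sample_b]])
  attr(out, "total_a") <- sum(ab$weight[ab$sample == sample_a])
  attr(out, "total_b") <- sum(ab$weight[ab$sample == sample_b])
  out
}

#' Fixed-slope R-squared of species counts between two samples
#'
#' Measures agreement of species counts with the no-depletion
#' expectation `y = s x`, where the slope `s = N_B / N_A` is the ratio
#' of total mapped mRNA-derived reads in the two samples — *not* a
#' fitted regression line, hence R-squared may be negative. Computed
#' over species with more than `min_count` occurrences in the reference
#' sample A.
#'
#' @param table A [species_table()] (or tibble `count_a`, `count_b`).
#' @param min_count Reference-sample count threshold (default 5,
#'   strict: species kept when `count_a > min_count`).
#' @param totals Optional numeric length-2 `(N_A, N_B)`; defaults to
#'   the table's `total_a`/`total_b` attributes, else column sums.
#' @param log_space Compute the residual statistic on log10 counts
#'   (default `FALSE`: linear count space).
#' @return One-row tibble `slope`, `r_squared`, `n_species`;
#'   `r_squared` is `NA` when the treated counts have zero variance.
#' @export
fixed_slope_r2 <- function(table, min_count = 5, totals = NULL,
                           log_space = FALSE) {
  if (is.null(totals)) {
    totals <- c(attr(table, "total_a") %||% sum(table$count_a),
                attr(table, "total_b") %||% sum(table$count_b))
  }
  s <- totals[2] / totals[1]
  keep <- table[table$count_a > min_count, ]
  if (!nrow(keep)) abort("no species pass the min_count filter")
  x <- keep$count_a
  y <- keep$count_b
  if (log_space) {
    resid2 <- (log10(pmax(y, 0.5)) - log10(s * x))^2
    tot2 <- (log10(pmax(y, 0.5)) - mean(log10(pmax(y, 0.5))))^2
  } else {
    resid2 <- (y - s * x)^2
    tot2 <- (y - mean(y))^2
  }
  r2 <- if (sum(tot2) == 0) NA_real_ else 1 - sum(resid2) / sum(tot2)
  tibble(slope = s, r_squared = r2, n_species = nrow(keep))
}

#' Chi-square envelope for species counts under no depletion
#'
#' Under no depletion a species with `n = x + y` total reads splits
#' between the samples in proportion to the totals,
#' `p_A = N_A / (N_A + N_B)`. The Pearson statistic
#' `(x - p_A n)^2 / (p_A n) + (y - p_B n)^2 / (p_B n)` then follows an
#' approximate chi-square distribution with one degree of freedom, and
#' the pointwise envelope at `coverage` is the set of `(x, y)` with
#' statistic below its `coverage` quantile.
#'
#' @param x Grid of reference-sample counts at which to evaluate the
#'   envelope bounds.
#' @param totals Numeric length-2 `(N_A, N_B)`.
#' @param coverage Nominal coverage (default 0.95).
#' @return Tibble `x`, `y_lower`, `y_upper` (the envelope boundary in
#'   the treated sample for each reference count).
#' @export
chi2_envelope <- function(x, totals, coverage = 0.95) {
  stopifnot(coverage > 0, coverage < 1)
  p_a <- totals[1] / sum(totals)
  p_b <- 1 - p_a
  q <- qchisq(coverage, df = 1)
  # (p_b x - p_a y)^2 <= q (x + y) p_a p_b, a quadratic in y
  a <- p_a^2
  b <- -(2 * p_a * p_b * x + q * p_a * p_b)
  cc <- p_b^2 * x^2 - q * x * p_a * p_b
  disc <- pmax(b^2 - 4 * a * cc, 0)
  tibble(
    x = x,
    y_lower = pmax((-b - sqrt(disc)) / (2 * a), 0),
    y_upper = (-b + sqrt(disc)) / (2 * a)
  )
}

#' Chi-square split statistic per species
#'
#' @param table A [species_table()] (columns `count_a`, `count_b`).
#' @param totals Numeric length-2 `(N_A, N_B)`; defaults to the table's
#'   attributes.
#' @param coverage Envelope coverage (default 0.95).
#' @return The table with added `chi2` and `inside` (statistic below
#'   the chi-square(1) `coverage` quantile) columns.
#' @export
species_envelope_test <- function(table, totals = NULL, coverage = 0.95) {
  if (is.null(totals)) {
    totals <- c(attr(table, "total_a") %||% sum(table$count_a),
                attr(table, "total_b") %||% sum(table$count_b))
  }
  p_a <- totals[1] / sum(totals)
  p_b <- 1 - p_a
  n <- table$count_a + table$count_b
  chi2 <- ifelse(n > 0,
                 (table$count_a - p_a * n)^2 / (p_a * n) +
                   (table$count_b - p_b * n)^2 / (p_b * n),
                 0)
  table$chi2 <- chi2
  table$inside <- chi2 <= qchisq(coverage, df = 1)
  table
}

#' GC fraction of sequences
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of G+C fractions.
#' @export
gc_content <- function(seq) {
  gc <- stringi::stri_count_charclass(seq, "[GCgc]")
  gc / nchar(seq)
}

#' Total variation distance between two discrete distributions
#'
#' @param p,q Non-negative weight vectors over the same support
#'   (normalised internally).
#' @return `0.5 * sum(|p - q|)` after normalisation.
#' @export
tv_distance <- function(p, q) {
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

#' Per-sample read-property distributions and divergences
#'
#' Normalised distributions of read length, GC content and any supplied
#' per-species properties (e.g. folding energies), per sample, plus the
#' total variation distance between each pair of samples for each
#' property — near-identical distributions across treatments indicate
#' an unbiased depletion.
#'
#' @param reads Read tibble (with `read_seq`, or `transcripts` given).
#' @param transcripts Optional transcript tibble used to reconstruct
#'   read sequences and restrict to a category.
#' @param properties Optional [read_property_table()] tibble of
#'   external per-species properties.
#' @param category Restrict to this transcript category (default
#'   `"mRNA"` when `transcripts` given).
#' @param bins Bin count for continuous properties (default 40).
#' @return List with `distributions` (tibble `property`, `sample`,
#'   `value` (bin midpoint), `fraction`) and `divergence` (tibble
#'   `property`, `sample_a`, `sample_b`, `tv_distance`). Properties
#'   with no matching species are skipped with a coverage note.
#' @export
property_distributions <- function(reads, transcripts = NULL,
                                   properties = NULL, category = "mRNA",
                                   bins = 40L) {
  if (!is.null(transcripts)) {
    if (!is.null(category)) {
      keep <- transcripts$transcript_id[transcripts$category == category]
      reads <- reads[reads$transcript_id %in% keep, ]
    }
    if (is.null(reads[["read_seq"]]) || anyNA(reads[["read_seq"]])) {
      idx <- match(reads$transcript_id, transcripts$transcript_id)
      reads$read_seq <- substr(transcripts$sequence[idx],
                               reads$five_prime + 1L,
                               reads$five_prime + reads$length)
    }
  }
  if (is.null(reads[["read_seq"]])) {
    abort("read sequences unavailable; supply transcripts")
  }
  vals <- list(
    length = as.numeric(reads$length),
    gc = gc_content(reads$read_seq)
  )
  if (!is.null(properties)) {
    for (p in unique(properties$property)) {
      v <- property_lookup(properties, reads$read_seq, p)
      cov <- mean(!is.na(v))
      if (!any(!is.na(v))) {
        inform(sprintf("property '%s': no species matched; skipped", p))
        next
      }
      if (cov < 1) {
        inform(sprintf("property '%s': %.1f%% of reads covered", p, 100 * cov))
      }
      vals[[p]] <- v
    }
  }
  dist_one <- function(v, name) {
    ok <- !is.na(v)
    d <- tibble(sample = reads$sample[ok], value = v[ok],
                weight = reads$weight[ok])
    if (name == "length") {
      d$bin <- d$value
    } else {
      brk <- seq(min(d$value), max(d$value), length.out = bins + 1L)
      if (brk[1] == brk[length(brk)]) brk <- brk[1] + c(-0.5, 0.5)
      mids <- (head(brk, -1) + brk[-1]) / 2
      d$bin <- mids[pmin(pmax(findInterval(d$value, brk,
                                           rightmost.closed = TRUE), 1L),
                         length(mids))]
    }
    d %>%
      group_by(.data$sample, value = .data$bin) %>%
      summarise(weight = sum(.data$weight), .groups = "drop_last") %>%
      mutate(fraction = .data$weight / sum(.data$weight)) %>%
      ungroup() %>%
      mutate(property = name) %>%
      select("property", "sample", "value", "fraction")
  }
  distributions <- purrr::imap(vals, dist_one) %>% bind_rows()
  samples <- unique(reads$sample)
  pairs <- if (length(samples) >= 2) utils::combn(samples, 2) else NULL
  divergence <- tibble(property = character(), sample_a = character(),
                       sample_b = character(), tv_distance = numeric())
  if (!is.null(pairs)) {
    divergence <- purrr::map(names(vals), function(pn) {
      dd <- distributions %>% filter(.data$property == pn)
      purrr::map(seq_len(ncol(pairs)), function(j) {
        wide <- dd %>%
          filter(.data$sample %in% pairs[, j]) %>%
          tidyr::pivot_wider(id_cols = "value", names_from = "sample",
                             values_from = "fraction", values_fill = 0)
        if (ncol(wide) < 3) return(NULL)
        tibble(property = pn, sample_a = pairs[1, j], sample_b = pairs[2, j],
               tv_distance = tv_distance(wide[[pairs[1, j]]],
                                         wide[[pairs[2, j]]]))
      }) %>% bind_rows()
    }) %>% bind_rows()
  }
  list(distributions = distributions, divergence = divergence)
}
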