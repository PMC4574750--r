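#' Stacked phase histogram by read-length class
#'
#' Codon positions 1/2/3 (phases 0/1/2) drawn red/green/blue, one bar
#' per length class — the frame-calling fingerprint plot.
#'
#' @param hist A [phase_by_length()] histogram.
#' @return A ggplot object.
#' @export
plot_phase_histogram <- function(hist) {
  d <- as_tibble(unclass(hist)) %>%
    mutate(codon_position = factor(.data$phase + 1L))
  d <- d %>%
    group_by(.data$sample, .data$length) %>%
    filter(sum(.data$count) > 0) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$length), y = .data$count,
                                  fill = .data$codon_position)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = .phase_cols, name = "codon\nposition") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "footprint length (nt)", y = "5' ends") +
    ggplot2::theme_minimal()
}

#' Read-length distribution plot
#'
#' @param ld A [length_distribution()] table.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$length, y = .data$fraction,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "footprint length (nt)", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Metagene profile plot
#'
#' Weighted 5'-end density around start and stop codons, coloured by
#' the codon position of each offset.
#'
#' @param object A [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ribo_metagene <- function(object, ...) {
  d <- as_tibble(unclass(object)) %>%
    mutate(codon_position = factor(((.data$offset %% 3L) + 3L) %% 3L + 1L),
           anchor = factor(.data$anchor, levels = c("start", "stop")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$density,
                                  fill = .data$codon_position)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = .phase_cols, name = "codon\nposition") +
    ggplot2::facet_grid(length ~ anchor, scales = "free_x") +
    ggplot2::labs(x = "offset of 5' end from first nt of codon (nt)",
                  y = "weighted mean density") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ribo_metagene
#' @export
plot_metagene <- function(object, ...) autoplot.ribo_metagene(object, ...)

#' Per-transcript profile plot
#'
#' Frame-coloured footprint 5'-end histogram with the RNA-seq coverage
#' underlay (grey), the ORF track above, and an optional sliding-window
#' mean below.
#'
#' @param object A [transcript_profile()].
#' @param window_codons Odd sliding-window size in codons (default 15);
#'   `NULL` suppresses the smoothed track.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ribo_transcript_profile <- function(object, window_codons = 15L, ...) {
  ribo <- object$ribo %>% mutate(codon_position = factor(.data$frame + 1L))
  rna <- object$rna
  ymax <- max(c(ribo$count, 1))
  rna_scale <- if (max(rna$coverage) > 0) ymax / max(rna$coverage) else 1
  p <- ggplot2::ggplot() +
    ggplot2::geom_col(data = rna,
                      ggplot2::aes(x = .data$position + 1L,
                                   y = .data$coverage * rna_scale),
                      fill = "grey80", width = 1) +
    ggplot2::geom_col(data = ribo[ribo$count > 0, ],
                      ggplot2::aes(x = .data$position + 1L, y = .data$count,
                                   fill = .data$codon_position),
                      width = 1) +
    ggplot2::scale_fill_manual(values = .phase_cols, name = "codon\nposition") +
    ggplot2::labs(title = object$transcript_id, x = "transcript position (nt)",
                  y = "footprint 5' ends") +
    ggplot2::theme_minimal()
  if (!is.null(object$orfs) && nrow(object$orfs)) {
    orfs <- object$orfs %>%
      mutate(frame = .data$start %% 3L,
             codon_position = factor(.data$frame + 1L),
             y = ymax * (1.05 + 0.06 * (row_number() %% 3L)))
    p <- p + ggplot2::geom_segment(
      data = orfs,
      ggplot2::aes(x = .data$start + 1L, xend = .data$end,
                   y = .data$y, yend = .data$y,
                   colour = .data$codon_position),
      linewidth = 2, show.legend = FALSE
    ) +
      ggplot2::scale_colour_manual(values = .phase_cols)
  }
  if (!is.null(window_codons)) {
    cc <- codon_counts(object)
    cc$smooth <- sliding_window_mean(cc$count, window_codons)
    sm_scale <- if (max(cc$smooth) > 0) 0.5 * ymax / max(cc$smooth) else 1
    p <- p + ggplot2::geom_line(
      data = cc,
      ggplot2::aes(x = .data$position + 1L, y = -0.1 * ymax -
                     .data$smooth * sm_scale * 0.5),
      colour = "grey30"
    )
  }
  p
}

#' Species-abundance scatter with chi-square envelope
#'
#' Distinct read-species counts in two samples on log axes, the
#' fixed-slope no-depletion guideline (grey) and the pointwise
#' chi-square envelope (pink).
#'
#' @param table A [species_table()].
#' @param coverage Envelope coverage (default 0.95).
#' @return A ggplot object.
#' @export
plot_species_scatter <- function(table, coverage = 0.95) {
  totals <- c(attr(table, "total_a") %||% sum(table$count_a),
              attr(table, "total_b") %||% sum(table$count_b))
  xmax <- max(table$count_a, 1)
  grid <- unique(round(exp(seq(0, log(xmax * 1.2), length.out = 200))))
  env <- chi2_envelope(grid, totals, coverage)
  s <- totals[2] / totals[1]
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = env,
                         ggplot2::aes(x = .data$x, ymin = .data$y_lower + 0.5,
                                      ymax = .data$y_upper + 0.5),
                         fill = "pink", alpha = 0.5) +
    ggplot2::geom_abline(slope = s, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(data = table,
                        ggplot2::aes(x = .data$count_a + 0.5,
                                     y = .data$count_b + 0.5),
                        size = 0.6, alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "species count, reference sample (+0.5)",
                  y = "species count, treated sample (+0.5)") +
    ggplot2::theme_minimal()
}

#' Library composition bar plot
#'
#' @param comp A [composition()] table.
#' @return A ggplot object.
#' @export
plot_composition <- function(comp) {
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "fraction of mapped reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
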