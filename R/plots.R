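#' Plot the windowed distribution of diagnostic markers along an arm
#'
#' Column plot of per-window marker counts (see
#' [summarize_marker_distribution()]), with dashed vertical lines at the
#' inversion breakpoints when supplied.
#'
#' @param windows Window-count tibble.
#' @param breakpoints Optional breakpoint tibble (`start`, `end`).
#' @return A ggplot object.
#' @export
plot_marker_distribution <- function(windows, breakpoints = NULL) {
  p <- ggplot2::ggplot(windows, ggplot2::aes(x = (win_start + win_end) / 2,
                                             y = n_markers)) +
    ggplot2::geom_col(width = windows$win_end[1] - windows$win_start[1],
                      fill = "grey35") +
    ggplot2::labs(x = "position (bp)", y = "diagnostic SNPs per window")
  if (!is.null(breakpoints)) {
    p <- p + ggplot2::geom_vline(xintercept = c(breakpoints$start, breakpoints$end),
                                 linetype = "dashed")
  }
  p
}

#' Plot inversion frequency trajectories
#'
#' Line plot of estimated inversion frequencies over time, one line per
#' replicate population, faceted by inversion when several are present.
#'
#' @param freqs Tibble with columns `generation` (or `time`), `frequency`,
#'   `replicate`, optionally `inversion` and `regime`.
#' @return A ggplot object.
#' @export
plot_frequency_trajectories <- function(freqs) {
  xvar <- if ("generation" %in% names(freqs)) "generation" else "time"
  p <- ggplot2::ggplot(freqs, ggplot2::aes(x = .data[[xvar]], y = frequency,
                                           group = replicate))
  if ("regime" %in% names(freqs)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(linetype = .data$regime))
  } else {
    p <- p + ggplot2::geom_line()
  }
  if ("inversion" %in% names(freqs) && dplyr::n_distinct(freqs$inversion) > 1) {
    p <- p + ggplot2::facet_wrap(~inversion)
  }
  p + ggplot2::ylim(0, 1) + ggplot2::labs(y = "inversion frequency")
}

#' Plot windowed diversity or differentiation along an arm
#'
#' @param stats Output of [window_pi()] or [window_fst()].
#' @param breakpoints Optional breakpoint tibble.
#' @return A ggplot object with one line per available statistic.
#' @export
plot_window_stats <- function(stats, breakpoints = NULL) {
  value_cols <- intersect(c("pi", "pi_a", "pi_b", "fst"), names(stats))
  long <- tidyr::pivot_longer(stats, dplyr::all_of(value_cols),
                              names_to = "statistic", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = (win_start + win_end) / 2,
                                          y = .data$value,
                                          colour = .data$statistic)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = NULL)
  if (!is.null(breakpoints)) {
    p <- p + ggplot2::geom_vline(xintercept = c(breakpoints$start, breakpoints$end),
                                 linetype = "dashed")
  }
  p
}

#' LD heatmap from long-format pairwise r-squared values
#'
#' @param pairs Long tibble `pos1`, `pos2`, `r2` from [ld_pairs()];
#'   an optional `group` column facets inverted vs standard panels.
#' @return A ggplot object (tile heatmap).
#' @export
plot_ld_heatmap <- function(pairs) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = pos1, y = pos2, fill = r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "position (bp)", y = "position (bp)", fill = expression(r^2))
  if ("group" %in% names(pairs)) p <- p + ggplot2::facet_wrap(~group)
  p
}
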