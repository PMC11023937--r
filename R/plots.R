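#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_col
#'   scale_x_log10 scale_y_log10 labs theme_minimal scale_fill_viridis_c
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Plot a distance-decay curve
#'
#' Log-log frequency versus genomic distance, aggregated into log-spaced
#' windows for display.
#'
#' @param object A [pc_curve()] result.
#' @param n_logbins Display windows.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.music_pc_curve <- function(object, n_logbins = 60L, ...) {
  s_min <- attr(object, "s_min"); s_max <- attr(object, "s_max")
  edges <- 10^seq(log10(max(s_min, 1)), log10(s_max),
                  length.out = n_logbins + 1L)
  df <- object |>
    mutate(lb = pmin(findInterval(.data$s_mid, edges), n_logbins)) |>
    group_by(.data$lb) |>
    summarise(freq = sum(.data$freq), .groups = "drop") |>
    mutate(dens = .data$freq / (edges[.data$lb + 1L] - edges[.data$lb]),
           s = sqrt(edges[.data$lb] * edges[.data$lb + 1L])) |>
    filter(.data$freq > 0)
  ggplot(df, aes(x = .data$s, y = .data$dens)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "genomic distance s (bp)", y = expression(P[c](s))) +
    theme_minimal()
}

#' Plot a contact matrix
#'
#' Heatmap of the visually transformed (log-scaled) upper-triangular map,
#' mirrored to full square.
#'
#' @param object A [contact_matrix()] result.
#' @param factor Linear scale-up before the log transform.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.music_matrix <- function(object, factor = 100, ...) {
  dense <- visual_transform(as_dense_matrix(object), factor)
  df <- tibble(bin_i = as.vector(row(dense)), bin_j = as.vector(col(dense)),
               w = as.vector(dense))
  ggplot(df, aes(x = .data$bin_j, y = .data$bin_i, fill = .data$w)) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10(1 + fw)") +
    labs(x = "bin", y = "bin") +
    theme_minimal()
}

#' Plot per-cell log-binned distance profiles as a heatmap
#'
#' Cells in columns, log-spaced distance bins in rows; color is the
#' per-cell-normalized frequency per bp.
#'
#' @param object A [logbin_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.music_logbin_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$cell_id, y = .data$bin, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "norm. freq") +
    labs(x = "cell", y = "distance bin (log-spaced)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot an RNA attachment-level track
#'
#' @param object A [ral_track()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.music_ral_track <- function(object, ...) {
  ggplot(object, aes(x = (.data$start + .data$end) / 2, y = .data$ral)) +
    geom_col(width = attr(object, "resolution") * 0.9) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "genomic position (bp)", y = "RNA attachment level") +
    theme_minimal()
}

#' Per-type odds-ratio forest plot
#'
#' @param fit A [chisq_and_or()] result.
#' @return A ggplot with the OR point estimates and 95% CIs.
#' @export
plot_odds_ratios <- function(fit) {
  df <- tidy(fit)
  ggplot(df, aes(x = .data$odds_ratio, y = .data$cell_type)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    scale_x_log10() +
    labs(x = "odds ratio (95% CI)", y = NULL) +
    theme_minimal()
}
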