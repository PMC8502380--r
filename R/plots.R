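# Optional diagnostics (ggplot2 is in Suggests).

#' Violin plots of per-individual metrics by treatment
#'
#' @param metrics Metrics table from \code{\link{trajectory_metrics}}.
#' @param vars Metric columns to plot.
#' @return A ggplot object.
#' @export
plot_violins <- function(metrics, vars = c("straightness", "mean_speed",
                                           "zeta_slope", "entropy")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(treatment = metrics$treatment, metric = v,
               value = metrics[[v]])))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment, y = .data$value,
                                     fill = .data$treatment)) +
    ggplot2::geom_violin(alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none")
}

#' Fan of zeta(q) functions for a dataset
#'
#' One zeta(q) curve per trajectory, with the Brownian (q/2, dashed) and
#' ballistic (q, dotted) reference lines.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param ... Passed to \code{\link{moment_curve}}.
#' @return A ggplot object.
#' @export
plot_zeta_fan <- function(dataset, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  rows <- lapply(dataset$trajectories, function(tr) {
    zf <- tryCatch(
      suppressWarnings(zeta_exponents(moment_curve(tr, ...))),
      error = function(e) NULL)
    if (is.null(zf)) return(NULL)
    data.frame(id = tr$id, treatment = tr$treatment, q = zf$q_grid,
               zeta = zf$zeta, slope = zf$slope)
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$zeta,
                                   group = .data$id,
                                   colour = .data$treatment,
                                   alpha = .data$slope)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = 0.5, intercept = 0, linetype = "dashed") +
    ggplot2::theme_minimal()
}
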