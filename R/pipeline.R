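# End-to-end orchestration: dataset -> per-individual metrics -> group
# inference -> machine-readable report.

#' Per-individual metrics table for a whole dataset
#'
#' One row per trajectory: kinematics (\code{\link{path_metrics}}), summary
#' zeta slope and directional entropy. Individuals too short for a metric
#' get \code{NA} there (with a logged message), never a dropped row:
#' trajectories with fewer than 8 positions skip the zeta slope and entropy,
#' fewer than 6 skip the initial heading.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param window Straightness window in steps (default 1).
#' @param bin_width Entropy bin width in radians (default 0.05).
#' @param q_grid,n_taus,max_tau_fraction Structure-function settings, see
#'   \code{\link{moment_curve}}.
#' @param initial_start See \code{\link{headings}}.
#' @param min_step See \code{\link{turning_angles}}.
#' @param verbose Emit per-individual exclusion messages (default TRUE).
#' @return Data frame with columns id, treatment, n_steps, duration_s,
#'   mean_speed, straightness, zeta_slope, entropy, initial_heading,
#'   final_heading.
#' @export
trajectory_metrics <- function(dataset, window = 1, bin_width = 0.05,
                               q_grid = seq(0.5, 3, by = 0.5), n_taus = 12,
                               max_tau_fraction = 0.25, initial_start = 0,
                               min_step = 0, verbose = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- lapply(dataset$trajectories, function(tr) {
    m <- path_metrics(tr, window = window, initial_start = initial_start)
    npos <- nrow(tr$positions)
    if (npos >= 8L) {
      m$zeta_slope <- zeta_slope(tr, q_grid, n_taus, max_tau_fraction)
      ang <- tryCatch(turning_angles(tr, min_step = min_step),
                      error = function(e) NULL)
      m$entropy <- if (is.null(ang)) NA_real_
                   else directional_entropy(ang, bin_width)$H
    } else {
      if (verbose)
        message("trajectory '", tr$id, "' has ", npos,
                " positions (< 8): zeta slope and entropy skipped")
      m$zeta_slope <- NA_real_
      m$entropy <- NA_real_
    }
    m
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[, c("id", "treatment", "n_steps", "duration_s", "mean_speed",
          "straightness", "zeta_slope", "entropy", "initial_heading",
          "final_heading")]
}

#' Analyse a two-treatment study end to end
#'
#' Runs the full analysis on a labelled dataset: per-individual metrics,
#' Rayleigh uniformity tests of the initial and final headings per
#' treatment, the four treatment models (straightness and speed linear
#' models, heteroscedastic GLS on the zeta slope with its motivating
#' Levene test, entropy ANCOVA) and per-treatment summaries with percent
#' differences of the second treatment relative to the first.
#'
#' @param dataset A \code{\link{study_dataset}} whose trajectories all carry
#'   one of exactly two treatment labels, each with >= 3 analysable
#'   trajectories.
#' @param gls_test \code{"LRT"} or \code{"Wald"} for the zeta-slope GLS.
#' @param ancova_ss \code{"sequential"} or \code{"marginal"} sums of squares
#'   for the entropy ANCOVA (see \code{\link{ancova_entropy}}).
#' @param ... Metric settings forwarded to \code{\link{trajectory_metrics}}.
#' @return Object of class \code{"study_report"}: list with
#'   \code{per_individual} (metrics data frame), \code{rayleigh} (named list
#'   of \code{rayleigh_result}, initial/final x treatment), \code{models}
#'   (named list of \code{model_result} plus the Levene test),
#'   \code{group_summaries} (means, SDs, percent differences), and
#'   \code{provenance}.
#' @examples
#' rep <- analyze_study(simulate_study(seed = 1), verbose = FALSE)
#' rep$group_summaries$percent_difference
#' @export
analyze_study <- function(dataset, gls_test = c("LRT", "Wald"),
                          ancova_ss = c("sequential", "marginal"), ...) {
  stopifnot(inherits(dataset, "study_dataset"))
  gls_test <- match.arg(gls_test)
  ancova_ss <- match.arg(ancova_ss)
  tr_levels <- treatments(dataset)
  if (length(tr_levels) != 2L)
    stop("the analysis needs exactly two treatments, found: ",
         paste(tr_levels, collapse = ", "), call. = FALSE)
  metrics <- trajectory_metrics(dataset, ...)
  g <- factor(metrics$treatment, levels = tr_levels)
  for (lev in tr_levels)
    if (sum(g == lev & is.finite(metrics$zeta_slope)) < 3L)
      stop("treatment '", lev, "' has fewer than 3 analysable trajectories",
           call. = FALSE)

  rayleigh <- list()
  for (which in c("initial", "final")) {
    col <- paste0(which, "_heading")
    for (lev in tr_levels) {
      a <- metrics[[col]][g == lev]
      a <- a[is.finite(a)]
      rayleigh[[paste(which, lev, sep = "_")]] <-
        if (length(a) >= 3L) rayleigh_test(a) else NULL
    }
  }

  safe_model <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e)); NULL
  })
  models <- list(
    straightness = safe_model(
      lm_treatment(metrics$straightness, g, "straightness index")),
    mean_speed = safe_model(
      lm_treatment(metrics$mean_speed, g, "mean speed")),
    levene_zeta = safe_model(levene_test(metrics$zeta_slope, g)),
    zeta_slope = safe_model(
      gls_heteroscedastic(metrics$zeta_slope, g, "zeta slope",
                          test = gls_test)),
    entropy = safe_model(
      ancova_entropy(metrics$entropy, metrics$zeta_slope, g,
                     ss = ancova_ss)))

  vars <- c("straightness", "mean_speed", "zeta_slope", "entropy")
  means <- sapply(vars, function(v)
    tapply(metrics[[v]], g, mean, na.rm = TRUE))
  sds <- sapply(vars, function(v)
    tapply(metrics[[v]], g, stats::sd, na.rm = TRUE))
  pct <- 100 * (means[2L, ] - means[1L, ]) / means[1L, ]
  group_summaries <- list(
    treatments = tr_levels,
    mean = means, sd = sds,
    percent_difference = pct)

  structure(list(
    per_individual = metrics, rayleigh = rayleigh, models = models,
    group_summaries = group_summaries,
    provenance = list(
      n_per_treatment = as.integer(table(g)),
      gls_test = gls_test, ancova_ss = ancova_ss,
      package_version = as.character(utils::packageVersion("protean")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d individuals (%s)\n",
              nrow(x$per_individual),
              paste(sprintf("%s: %d", x$group_summaries$treatments,
                            x$provenance$n_per_treatment),
                    collapse = ", ")))
  cat("\nPercent difference (2nd vs 1st treatment):\n")
  print(round(x$group_summaries$percent_difference, 2))
  cat("\nRayleigh tests (z, p):\n")
  for (nm in names(x$rayleigh)) {
    r <- x$rayleigh[[nm]]
    if (!is.null(r))
      cat(sprintf("  %-16s z = %6.3f  p = %.3f\n", nm, r$z, r$p_value))
  }
  cat("\nTreatment models:\n")
  for (nm in setdiff(names(x$models), "levene_zeta")) {
    m <- x$models[[nm]]
    if (is.null(m)) next
    e <- m$effects[1L, ]
    cat(sprintf("  %-14s %s = %7.3f  p = %.4f\n", m$response,
                e$statistic_name, e$statistic, e$p_value))
  }
  lv <- x$models$levene_zeta
  if (!is.null(lv))
    cat(sprintf("  %-14s F = %7.3f  p = %.4f\n", "levene (zeta)",
                lv$statistic, lv$p_value))
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes the report's tables and test results as a single JSON document
#' (model effects as arrays of records, the per-individual metrics table as
#' a data-frame record set).
#'
#' @param report A \code{\link{analyze_study}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  strip <- function(m) {
    if (is.null(m)) return(NULL)
    if (inherits(m, "model_result"))
      list(response = m$response, model_type = m$model_type,
           effects = m$effects, aic = m$aic,
           n_per_group = m$n_per_group, group_sd = m$group_sd,
           group_sd_ratio = m$group_sd_ratio)
    else unclass(m)
  }
  gs <- report$group_summaries
  gs$percent_difference <- as.list(gs$percent_difference)
  out <- list(
    per_individual = report$per_individual,
    rayleigh = lapply(report$rayleigh, unclass),
    models = lapply(report$models, strip),
    group_summaries = gs,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
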