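# Group-comparison statistics for the two-treatment design: one-way linear
# models for speed and straightness, a heteroscedastic GLS for the zeta
# slope, Levene's test motivating it, and the entropy ANCOVA.

check_two_groups <- function(values, groups, min_per_group = 2L) {
  if (length(values) != length(groups))
    stop("`values` and `groups` must have the same length", call. = FALSE)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (any(table(groups) < min_per_group))
    stop("insufficient data: each group needs at least ", min_per_group,
         " observations", call. = FALSE)
  list(values = values, groups = groups)
}

new_model_result <- function(response, model_type, effects, aic,
                             n_per_group, group_sd = NULL,
                             group_sd_ratio = NULL, coefficients = NULL) {
  structure(list(response = response, model_type = model_type,
                 effects = effects, aic = aic, n_per_group = n_per_group,
                 group_sd = group_sd, group_sd_ratio = group_sd_ratio,
                 coefficients = coefficients),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s (%s)\n", x$response, x$model_type))
  print(x$effects, row.names = FALSE)
  if (!is.null(x$group_sd_ratio))
    cat(sprintf("  group SD ratio (2nd/1st level): %.3f\n", x$group_sd_ratio))
  cat(sprintf("  AIC = %.2f\n", x$aic))
  invisible(x)
}

#' Levene's test for homogeneity of variance between groups
#'
#' A thin wrapper around \code{car::leveneTest} on absolute deviations from
#' the group centre (mean by default, the classical Levene statistic;
#' \code{center = "median"} gives the Brown-Forsythe variant).
#'
#' @param values Numeric observations.
#' @param groups Group labels (2 or more groups, each with >= 2
#'   observations).
#' @param center \code{"mean"} or \code{"median"}.
#' @return List with \code{statistic} (F), \code{df} (length 2), \code{p_value}.
#' @examples
#' levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$statistic
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values) != length(groups))
    stop("`values` and `groups` must have the same length", call. = FALSE)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("insufficient data: each group needs at least 2 observations",
         call. = FALSE)
  lt <- car::leveneTest(values, groups,
                        center = if (center == "mean") mean else median)
  list(statistic = lt[["F value"]][1L],
       df = c(lt[["Df"]][1L], lt[["Df"]][2L]),
       p_value = lt[["Pr(>F)"]][1L])
}

#' One-way linear model for a two-level treatment
#'
#' Fixed-effects comparison of a response between two groups; the F statistic
#' on 1 and n - 2 degrees of freedom equals the square of the pooled-variance
#' two-sample t statistic.
#'
#' @param values Numeric response, one value per individual.
#' @param groups Two-level group labels.
#' @param response Name of the response (for reporting).
#' @return A \code{model_result} with one treatment effect row
#'   (\code{term, df, statistic_name, statistic, p_value}), residual df,
#'   AIC and group sizes.
#' @examples
#' lm_treatment(c(1, 2, 3, 5, 6, 7), rep(c("a", "b"), each = 3))
#' @export
lm_treatment <- function(values, groups, response = "response") {
  d <- check_two_groups(values, groups)
  if (stats::var(d$values) == 0)
    stop("degenerate data: response has zero total variance", call. = FALSE)
  fit <- stats::lm(values ~ groups, data = d)
  an <- stats::anova(fit)
  effects <- data.frame(
    term = c("treatment", "residuals"),
    df = an$Df,
    statistic_name = c("F", NA),
    statistic = c(an$`F value`[1L], NA),
    p_value = c(an$`Pr(>F)`[1L], NA))
  new_model_result(response, "linear model", effects, stats::AIC(fit),
                   as.integer(table(d$groups)),
                   coefficients = stats::coef(fit))
}

# Exact ML log-likelihood of the two-group Gaussian model with per-group
# variance; means either free per group or constrained equal (the
# equal-means case has no closed form: the weighted mean and the group
# variances are iterated to a fixed point).
gls2_loglik <- function(x1, x2, equal_means = FALSE, tol = 1e-12,
                        max_iter = 200L) {
  n1 <- length(x1); n2 <- length(x2)
  if (!equal_means) {
    v1 <- mean((x1 - mean(x1))^2)
    v2 <- mean((x2 - mean(x2))^2)
    mu <- c(mean(x1), mean(x2))
  } else {
    mu_hat <- mean(c(x1, x2))
    v1 <- mean((x1 - mu_hat)^2); v2 <- mean((x2 - mu_hat)^2)
    for (i in seq_len(max_iter)) {
      w1 <- n1 / v1; w2 <- n2 / v2
      mu_new <- (w1 * mean(x1) + w2 * mean(x2)) / (w1 + w2)
      v1n <- mean((x1 - mu_new)^2); v2n <- mean((x2 - mu_new)^2)
      if (abs(mu_new - mu_hat) < tol * (1 + abs(mu_hat)) &&
          abs(v1n - v1) < tol * v1 && abs(v2n - v2) < tol * v2) {
        mu_hat <- mu_new; v1 <- v1n; v2 <- v2n
        break
      }
      mu_hat <- mu_new; v1 <- v1n; v2 <- v2n
    }
    mu <- c(mu_hat, mu_hat)
  }
  if (v1 <= 0 || v2 <= 0)
    stop("degenerate data: a group has zero variance", call. = FALSE)
  ll <- -0.5 * (n1 * (log(2 * pi * v1) + 1) + n2 * (log(2 * pi * v2) + 1))
  list(loglik = ll, mu = mu, sd = sqrt(c(v1, v2)))
}

#' Heteroscedastic two-group GLS comparison
#'
#' Maximum-likelihood fit of a Gaussian model with one mean and one residual
#' variance per group (the variance structure the study design needs when
#' one treatment is far more variable than the other). The treatment effect
#' is tested against the equal-means, variance-per-group null, by default
#' with a likelihood-ratio chi-square on 1 df (exact closed-form fits in the
#' two-group case); a Wald chi-square is available as an option.
#'
#' @param values Numeric response, one value per individual.
#' @param groups Two-level group labels (each group >= 3 observations).
#' @param response Name of the response (for reporting).
#' @param test \code{"LRT"} (default) or \code{"Wald"}.
#' @return A \code{model_result}; \code{group_sd} holds the ML residual SD
#'   per group (in level order) and \code{group_sd_ratio} their
#'   second-to-first-level ratio; \code{aic} is that of the
#'   heteroscedastic alternative (4 parameters).
#' @examples
#' set.seed(1)
#' gls_heteroscedastic(c(rnorm(20, 0, 3), rnorm(20, 1, 0.5)),
#'                     rep(c("ctl", "prd"), each = 20))
#' @export
gls_heteroscedastic <- function(values, groups, response = "response",
                                test = c("LRT", "Wald")) {
  test <- match.arg(test)
  d <- check_two_groups(values, groups, min_per_group = 3L)
  lev <- levels(d$groups)
  x1 <- d$values[d$groups == lev[1L]]
  x2 <- d$values[d$groups == lev[2L]]
  alt <- gls2_loglik(x1, x2, equal_means = FALSE)
  if (test == "LRT") {
    null <- gls2_loglik(x1, x2, equal_means = TRUE)
    chi2 <- max(0, 2 * (alt$loglik - null$loglik))
  } else {
    se <- sqrt(alt$sd[1L]^2 / length(x1) + alt$sd[2L]^2 / length(x2))
    chi2 <- ((alt$mu[2L] - alt$mu[1L]) / se)^2
  }
  effects <- data.frame(
    term = "treatment", df = 1L, statistic_name = "chi2",
    statistic = chi2,
    p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
  names(alt$sd) <- lev
  new_model_result(
    response, paste0("heteroscedastic GLS (", test, ")"), effects,
    aic = 2 * 4 - 2 * alt$loglik,
    n_per_group = as.integer(table(d$groups)),
    group_sd = alt$sd, group_sd_ratio = alt$sd[[2L]] / alt$sd[[1L]],
    coefficients = c(mean_1 = alt$mu[1L], mean_2 = alt$mu[2L]))
}

#' ANCOVA of directional entropy on treatment and zeta slope
#'
#' Linear model \code{entropy ~ treatment + slope + treatment:slope} with
#' F tests on 1 df per term; residual df = n - 4. The default is sequential
#' (type-I) sums of squares, matching a single-ordering ANOVA table. Note
#' that when the covariate has a real effect, the sequential first-term F
#' for treatment absorbs chance between-group imbalance in the covariate
#' and is anticonservative under a true null; \code{ss = "marginal"}
#' (type-II, each main effect adjusted for the other) gives the calibrated
#' treatment test.
#'
#' @param entropy Numeric response (directional entropy per individual).
#' @param zeta_slope Numeric covariate (summary zeta slope per individual).
#' @param groups Two-level treatment labels.
#' @param ss \code{"sequential"} (type-I, default) or \code{"marginal"}
#'   (type-II via \code{car::Anova}).
#' @param response Name for reporting.
#' @return A \code{model_result} with three effect rows (treatment, slope,
#'   interaction) plus residuals; \code{coefficients} holds the fitted
#'   linear coefficients.
#' @export
ancova_entropy <- function(entropy, zeta_slope, groups,
                           ss = c("sequential", "marginal"),
                           response = "directional entropy") {
  ss <- match.arg(ss)
  if (length(entropy) != length(zeta_slope) ||
      length(entropy) != length(groups))
    stop("inputs must have equal length", call. = FALSE)
  ok <- is.finite(entropy) & is.finite(zeta_slope) & !is.na(groups)
  entropy <- entropy[ok]; zeta_slope <- zeta_slope[ok]
  groups <- droplevels(factor(groups[ok]))
  n <- length(entropy)
  if (n < 8L)
    stop("insufficient data: the ANCOVA needs at least 8 observations",
         call. = FALSE)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (all(tapply(zeta_slope, groups, stats::var) == 0))
    stop("collinear predictors: slope is constant within both groups",
         call. = FALSE)
  fit <- stats::lm(entropy ~ groups * zeta_slope)
  if (ss == "sequential") {
    an <- stats::anova(fit)
    Fv <- an$`F value`[1:3]; pv <- an$`Pr(>F)`[1:3]; dfs <- an$Df
  } else {
    an <- car::Anova(fit, type = 2)
    Fv <- an$`F value`[1:3]; pv <- an$`Pr(>F)`[1:3]
    dfs <- c(an$Df[1:3], an$Df[4L])
  }
  effects <- data.frame(
    term = c("treatment", "slope", "treatment:slope", "residuals"),
    df = dfs,
    statistic_name = c("F", "F", "F", NA),
    statistic = c(Fv, NA),
    p_value = c(pv, NA))
  new_model_result(response, paste0("linear model (", ss, " ANCOVA)"),
                   effects, stats::AIC(fit), as.integer(table(groups)),
                   coefficients = stats::coef(fit))
}
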