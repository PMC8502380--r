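#' qth-order structure function of a trajectory
#'
#' For each temporal increment tau (in frames) and each moment order q, the
#' time-averaged qth moment of the displacement modulus,
#' \deqn{M(q, \tau) = \langle \| X_{t+\tau} - X_t \|^q \rangle,}
#' averaged over all ordered position pairs separated by tau (overlapping
#' time average). For an anomalously diffusing path the moments scale as
#' \eqn{M(q, \tau) \sim \tau^{\zeta(q)}}; the exponents are estimated by
#' \code{\link{zeta_exponents}}.
#'
#' The tau grid is log-spaced so the points are equally spaced in the log-log
#' regression: \code{n_taus} candidates from 1 to
#' \code{floor(max_tau_fraction * n_steps)}, rounded to integers and
#' de-duplicated. Capping tau at a quarter of the path keeps many pairs per
#' estimate and limits autocorrelation-induced bias.
#'
#' @param traj A \code{\link{trajectory}} with at least 8 positions.
#' @param q_grid Positive moment orders. Default \code{seq(0.5, 3, by = 0.5)}:
#'   moderate orders avoid heavy-tail noise on short paths.
#' @param n_taus Number of log-spaced tau candidates (default 12).
#' @param max_tau_fraction Largest tau as a fraction of the number of steps
#'   (in (0, 0.5]; default 0.25).
#' @return Object of class \code{"moment_curve"}: list with \code{q_grid},
#'   \code{tau_grid}, \code{moments} (q x tau matrix), \code{n_pairs},
#'   \code{degenerate} (TRUE when the path never moves).
#' @examples
#' tr <- trajectory("u", cbind(0:19, 0))
#' mc <- moment_curve(tr)
#' mc$moments["2", "1"]  # 1: unit steps
#' @export
moment_curve <- function(traj, q_grid = seq(0.5, 3, by = 0.5), n_taus = 12,
                         max_tau_fraction = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(!is.finite(q_grid)) || any(q_grid <= 0))
    stop("`q_grid` must be positive", call. = FALSE)
  if (max_tau_fraction <= 0 || max_tau_fraction > 0.5)
    stop("`max_tau_fraction` must be in (0, 0.5]", call. = FALSE)
  p <- traj$positions
  n <- nrow(p)
  if (n < 8L)
    stop("insufficient data: structure functions need at least 8 positions",
         call. = FALSE)
  q_grid <- sort(q_grid)
  max_tau <- max(1L, floor(max_tau_fraction * (n - 1L)))
  tau_grid <- unique(round(exp(seq(log(1), log(max_tau),
                                   length.out = n_taus))))
  tau_grid <- as.integer(tau_grid[tau_grid >= 1L & tau_grid < n])
  M <- matrix(NA_real_, length(q_grid), length(tau_grid),
              dimnames = list(q = q_grid, tau = tau_grid))
  n_pairs <- integer(length(tau_grid))
  for (j in seq_along(tau_grid)) {
    tau <- tau_grid[j]
    d <- p[(1L + tau):n, , drop = FALSE] - p[1L:(n - tau), , drop = FALSE]
    mod <- sqrt(d[, 1L]^2 + d[, 2L]^2)
    n_pairs[j] <- length(mod)
    M[, j] <- vapply(q_grid, function(q) mean(mod^q), numeric(1))
  }
  degenerate <- all(M == 0)
  if (degenerate)
    warning("degenerate trajectory '", traj$id,
            "': all positions identical, moments are zero")
  structure(list(q_grid = q_grid, tau_grid = tau_grid, moments = M,
                 n_pairs = n_pairs, degenerate = degenerate),
            class = "moment_curve")
}

#' @export
print.moment_curve <- function(x, ...) {
  cat(sprintf("<moment_curve> %d q x %d tau (tau in [%d, %d])%s\n",
              length(x$q_grid), length(x$tau_grid), min(x$tau_grid),
              max(x$tau_grid), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Scaling exponents zeta(q) and their summary slope
#'
#' For each moment order q, zeta(q) is the ordinary-least-squares slope of
#' \code{log M(q, tau)} on \code{log tau}. The whole function is summarised
#' by the slope of zeta(q) on q constrained through the origin (zeta(0) = 0
#' is forced by the definition of the moments), which places a path on the
#' Brownian-to-ballistic continuum: 0.5 for an uncorrelated random walk, 1
#' for straight-line motion, in between for superdiffusion.
#'
#' Non-positive moments cannot enter a log-log fit: such tau points are
#' dropped per q with a warning, and a q with fewer than 3 surviving points
#' gets \code{NA} and is excluded from the summary fit.
#'
#' @param curve A \code{\link{moment_curve}}.
#' @return Object of class \code{"zeta_function"}: list with \code{q_grid},
#'   \code{zeta}, \code{zeta_se}, \code{r_squared} (per q), \code{slope},
#'   \code{slope_se}, \code{n_tau} (tau points used per q).
#' @examples
#' tr <- trajectory("u", cbind(0:99, 0))    # constant velocity
#' zf <- zeta_exponents(moment_curve(tr))
#' zf$slope  # 1 (ballistic)
#' @export
zeta_exponents <- function(curve) {
  stopifnot(inherits(curve, "moment_curve"))
  q <- curve$q_grid
  nq <- length(q)
  zeta <- zeta_se <- r2 <- rep(NA_real_, nq)
  n_tau <- integer(nq)
  log_tau <- log(curve$tau_grid)
  for (i in seq_len(nq)) {
    m <- curve$moments[i, ]
    ok <- is.finite(m) & m > 0
    if (any(!ok) && any(ok))
      warning("dropping ", sum(!ok), " non-positive moment(s) at q = ", q[i])
    n_tau[i] <- sum(ok)
    if (n_tau[i] < 3L) next
    fit <- ols_line(log_tau[ok], log(m[ok]))
    zeta[i] <- fit$slope
    zeta_se[i] <- fit$se
    r2[i] <- fit$r_squared
  }
  use <- !is.na(zeta)
  if (!any(use)) {
    slope <- slope_se <- NA_real_
  } else {
    # through-origin least squares of zeta(q) on q
    qq <- q[use]; zz <- zeta[use]
    slope <- sum(qq * zz) / sum(qq^2)
    rss <- sum((zz - slope * qq)^2)
    slope_se <- if (sum(use) > 1L)
      sqrt(rss / (sum(use) - 1L) / sum(qq^2)) else NA_real_
  }
  structure(list(q_grid = q, zeta = zeta, zeta_se = zeta_se,
                 r_squared = r2, n_tau = n_tau,
                 slope = slope, slope_se = slope_se),
            class = "zeta_function")
}

#' @export
print.zeta_function <- function(x, ...) {
  cat(sprintf("<zeta_function> slope = %.4f over %d moment orders\n",
              x$slope, sum(!is.na(x$zeta))))
  invisible(x)
}

#' Convenience: summary zeta slope of a trajectory
#'
#' \code{zeta_exponents(moment_curve(traj, ...))$slope} in one call.
#'
#' @inheritParams moment_curve
#' @return Numeric scalar (NA when the path is degenerate or too short for
#'   3 positive-moment tau points).
#' @export
zeta_slope <- function(traj, q_grid = seq(0.5, 3, by = 0.5), n_taus = 12,
                       max_tau_fraction = 0.25) {
  curve <- suppressWarnings(
    moment_curve(traj, q_grid, n_taus, max_tau_fraction))
  suppressWarnings(zeta_exponents(curve))$slope
}

#' Classify the diffusive regime from a summary zeta slope
#'
#' Reference points: slope 0.5 is Brownian motion, slope 1 ballistic
#' (straight-line) motion; the band half-width sets how close a slope must
#' be to count as one of the reference regimes.
#'
#' @param slope Finite summary slope from \code{\link{zeta_exponents}}.
#' @param band_halfwidth Half-width b of the classification bands
#'   (0 < b < 0.25, default 0.05): below \code{0.5 - b} is subdiffusive,
#'   within b of 0.5 Brownian, at or above \code{1 - b} ballistic,
#'   in between superdiffusive.
#' @return Object of class \code{"diffusion_class"}: list with \code{label}
#'   (one of "subdiffusive", "brownian", "superdiffusive", "ballistic"),
#'   \code{slope}, \code{band_halfwidth}.
#' @examples
#' classify_diffusion(0.75)$label  # "superdiffusive"
#' @export
classify_diffusion <- function(slope, band_halfwidth = 0.05) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("`slope` must be a single finite number", call. = FALSE)
  b <- band_halfwidth
  if (!is.numeric(b) || b <= 0 || b >= 0.25)
    stop("`band_halfwidth` must be in (0, 0.25)", call. = FALSE)
  label <-
    if (slope < 0.5 - b) "subdiffusive"
    else if (abs(slope - 0.5) <= b) "brownian"
    else if (slope < 1 - b) "superdiffusive"
    else "ballistic"
  structure(list(label = label, slope = slope, band_halfwidth = b),
            class = "diffusion_class")
}

#' @export
print.diffusion_class <- function(x, ...) {
  cat(sprintf("<diffusion_class> %s (slope = %.3f, band = %.2f)\n",
              x$label, x$slope, x$band_halfwidth))
  invisible(x)
}
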