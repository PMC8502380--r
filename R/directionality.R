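#' Directional entropy of turning angles
#'
#' Bins the relative (turning) angles on a fixed grid over \code{(-pi, pi]}
#' and returns the Shannon entropy of the bin counts: the plug-in
#' (maximum-likelihood) estimator \eqn{H = -\sum p_i \log p_i} in nats, with
#' empty bins contributing zero. Low entropy means the animal's heading
#' changes are concentrated and hence predictable.
#'
#' Bins are half-open intervals \code{(lo, hi]} anchored at \code{-pi}; when
#' \code{2*pi} is not a multiple of \code{bin_width} the last bin is
#' narrower (the default 0.05 rad gives 126 bins). Anchoring and the wrap
#' convention of \code{\link{turning_angles}} make counts deterministic.
#'
#' @param angles Numeric vector of angles in \code{(-pi, pi]}.
#' @param bin_width Bin width in radians (> 0), default 0.05.
#' @return Object of class \code{"entropy_result"}: list with \code{H}
#'   (nats), \code{counts}, \code{breaks}, \code{bin_width}, \code{n_angles}.
#' @examples
#' directional_entropy(rep(0.3, 40))$H                      # 0
#' directional_entropy(c(0.01, 0.06, 0.11, 0.16))$H          # log(4)
#' @export
directional_entropy <- function(angles, bin_width = 0.05) {
  if (length(angles) < 1L)
    stop("insufficient data: at least one angle is required", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  if (any(!is.finite(angles)) || any(angles <= -pi | angles > pi))
    stop("angles must be finite and in (-pi, pi]", call. = FALSE)
  breaks <- seq(-pi, pi, by = bin_width)
  if (breaks[length(breaks)] < pi) breaks <- c(breaks, pi)
  counts <- tabulate(findInterval(angles, breaks, left.open = TRUE,
                                  rightmost.closed = FALSE) ,
                     nbins = length(breaks) - 1L)
  n <- length(angles)
  p <- counts[counts > 0] / n
  structure(list(H = -sum(p * log(p)), counts = counts, breaks = breaks,
                 bin_width = bin_width, n_angles = n),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> H = %.4f nats (%d angles, %d bins)\n",
              x$H, x$n_angles, length(x$counts)))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of uniformly distributed angles against a unimodal
#' alternative with unknown direction. The statistic is \eqn{z = n
#' \bar{R}^2} with \eqn{\bar{R}} the mean resultant length; the p-value uses
#' the standard second-order series approximation
#' \deqn{p = e^{-z}\left[1 + \frac{2z - z^2}{4n}
#'       - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\right]}
#' clamped to \code{[0, 1]}.
#'
#' @param angles Numeric vector of at least 3 angles (radians; any real
#'   values, only their direction matters).
#' @return Object of class \code{"rayleigh_result"}: list with \code{n},
#'   \code{mean_resultant_length}, \code{z}, \code{p_value}.
#' @examples
#' rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))$p_value  # 1: balanced
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 3L)
    stop("insufficient data: the Rayleigh test needs at least 3 angles",
         call. = FALSE)
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  structure(list(n = n, mean_resultant_length = rbar, z = z,
                 p_value = min(1, max(0, p))),
            class = "rayleigh_result")
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf("<rayleigh_result> n = %d, Rbar = %.3f, z = %.3f, p = %.3g\n",
              x$n, x$mean_resultant_length, x$z, x$p_value))
  invisible(x)
}
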