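#' Signed turning angles along a trajectory
#'
#' For each interior position, the signed difference between the headings of
#' the outgoing and incoming steps, wrapped to \code{(-pi, pi]} (an exact
#' reversal maps to \code{+pi}). Headings are undefined on zero-length steps,
#' so steps shorter than \code{min_step} are dropped and each turning angle is
#' taken between the surviving flanking steps.
#'
#' @param traj A \code{\link{trajectory}} with at least 3 positions.
#' @param min_step Minimum step displacement (length units) for a step to
#'   carry a heading. The default 0 drops only exactly-zero steps (a resting
#'   animal contributes no turn).
#' @return Numeric vector of turning angles in radians, one per pair of
#'   consecutive usable steps.
#' @examples
#' turning_angles(trajectory("u", rbind(c(0, 0), c(1, 0), c(1, 1))))  # pi/2
#' @export
turning_angles <- function(traj, min_step = 0) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj$positions) < 3L)
    stop("insufficient data: turning angles need at least 3 positions",
         call. = FALSE)
  if (min_step < 0) stop("`min_step` must be >= 0", call. = FALSE)
  d <- step_vectors(traj)
  len <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  keep <- len > 0 & len >= min_step
  if (sum(keep) < 2L)
    stop("insufficient data: fewer than 2 usable steps", call. = FALSE)
  h <- atan2(d[keep, 2L], d[keep, 1L])
  wrap_angle(diff(h))
}

#' Initial and final heading angles
#'
#' The final heading is the direction of the vector from the first to the
#' last position. The initial heading is taken after a settling period: the
#' direction of the vector spanning the first five steps, i.e. from position
#' \code{initial_start} (0-based, default 0) to position 5. Both are
#' four-quadrant arctangents in \code{(-pi, pi]}, counterclockwise from +x.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param initial_start 0-based index of the position the initial-heading
#'   vector starts from (0 or 1 are the two defensible readings of a
#'   "first-to-fifth-step" vector; 0 is the default).
#' @return List with numeric scalars \code{initial} and \code{final};
#'   \code{initial} is \code{NA} (with a warning) when the trajectory has
#'   fewer than 6 positions.
#' @examples
#' tr <- trajectory("u", cbind(0:6, 0:6))
#' headings(tr)  # both pi/4
#' @export
headings <- function(traj, initial_start = 0) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  n <- nrow(p)
  if (n < 2L)
    stop("insufficient data: final heading needs at least 2 positions",
         call. = FALSE)
  if (!initial_start %in% c(0, 1))
    stop("`initial_start` must be 0 or 1", call. = FALSE)
  heading_of <- function(v, which) {
    if (v[1L] == 0 && v[2L] == 0)
      stop("undefined heading: zero-length ", which, " vector", call. = FALSE)
    unname(atan2(v[2L], v[1L]))
  }
  final <- heading_of(p[n, ] - p[1L, ], "final")
  if (n < 6L) {
    warning("trajectory '", traj$id,
            "' too short for the initial heading (needs 6 positions)")
    initial <- NA_real_
  } else {
    initial <- heading_of(p[6L, ] - p[initial_start + 1L, ], "initial")
  }
  list(initial = initial, final = final)
}

#' Mean speed of a trajectory
#'
#' Per-step speeds (step length over the frame interval) averaged over the
#' whole path.
#'
#' @param traj A \code{\link{trajectory}}.
#' @return Mean speed in length units per second; 0 iff the animal never
#'   moved.
#' @examples
#' mean_speed(trajectory("u", cbind(c(0, 2, 4), 0), frame_interval = 30))
#' @export
mean_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  mean(step_lengths(traj)) / traj$frame_interval
}

#' Straightness index
#'
#' The ratio of the net displacement (first to last position) to the path
#' length resampled at a window of \code{window} steps: the sum of Euclidean
#' hops between positions \code{0, w, 2w, ...}, with a trailing remainder
#' shorter than the window contributing its own hop so the numerator and
#' denominator span the same endpoints. Ranges from 1 (perfectly straight)
#' to 0 (closed path); a path with no net movement at all returns 0.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param window Window width in steps (>= 1). Default 1 (every sampled
#'   step), the study's reporting choice at 30-s frames.
#' @return Straightness in \code{[0, 1]}, dimensionless and invariant to
#'   rotation, translation and uniform scaling.
#' @examples
#' straightness_index(trajectory("u", cbind(0:9, 0)))  # 1
#' @export
straightness_index <- function(traj, window = 1) {
  stopifnot(inherits(traj, "trajectory"))
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  p <- traj$positions
  n <- nrow(p)
  if (n < window + 1L)
    stop("insufficient data: window of ", window, " steps needs at least ",
         window + 1L, " positions", call. = FALSE)
  idx <- seq(1L, n, by = window)
  if (idx[length(idx)] != n) idx <- c(idx, n)
  seg <- p[idx[-1L], , drop = FALSE] - p[idx[-length(idx)], , drop = FALSE]
  denom <- sum(sqrt(seg[, 1L]^2 + seg[, 2L]^2))
  if (denom == 0) return(0)
  num <- sqrt(sum((p[n, ] - p[1L, ])^2))
  num / denom
}

#' Per-trajectory kinematic summary
#'
#' Bundles the descriptive metrics of one path. Metrics whose preconditions a
#' short trajectory fails come back as \code{NA} rather than an error, so a
#' whole dataset can be summarised in one pass (see
#' \code{\link{trajectory_metrics}}).
#'
#' @param traj A \code{\link{trajectory}}.
#' @param window Straightness window in steps.
#' @param initial_start See \code{\link{headings}}.
#' @return One-row data frame: id, treatment, n_steps, duration_s,
#'   mean_speed, straightness, initial_heading, final_heading.
#' @export
path_metrics <- function(traj, window = 1, initial_start = 0) {
  stopifnot(inherits(traj, "trajectory"))
  ns <- n_steps(traj)
  h <- tryCatch(suppressWarnings(headings(traj, initial_start)),
                error = function(e) list(initial = NA_real_,
                                         final = NA_real_))
  s <- tryCatch(straightness_index(traj, window),
                error = function(e) NA_real_)
  data.frame(
    id = traj$id, treatment = traj$treatment, n_steps = ns,
    duration_s = ns * traj$frame_interval,
    mean_speed = mean_speed(traj), straightness = s,
    initial_heading = h$initial, final_heading = h$final,
    row.names = NULL)
}
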