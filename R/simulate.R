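# Synthetic trajectories with known diffusive properties, and whole
# two-treatment study datasets emulating a predator-cue escape experiment,
# so every pipeline stage is testable without the lab data.

#' Simulate a single trajectory with a known movement model
#'
#' Four generative models spanning the diffusive taxonomy:
#' \describe{
#'   \item{brownian}{i.i.d. Gaussian displacements per frame, SD =
#'     \code{step_scale} per coordinate (uncorrelated random walk;
#'     zeta slope 0.5, MSD \code{2 * step_scale^2 * tau}).}
#'   \item{ballistic}{constant speed \code{step_scale} and constant heading,
#'     plus optional per-step Gaussian heading jitter (zeta slope 1 when
#'     jitter is 0).}
#'   \item{crw}{correlated random walk: step lengths from a gamma
#'     distribution with mean \code{step_scale}, turning angles from a
#'     wrapped normal with concentration \code{persistence} (kappa; angle SD
#'     \code{1/sqrt(kappa)}). kappa near 0 approaches Brownian-like
#'     dispersal, large kappa near-ballistic motion.}
#'   \item{levy}{constant speed with heavy-tailed run durations (discrete
#'     Pareto, tail exponent \code{levy_exponent}) between uniform
#'     reorientations.}
#' }
#' Defaults emulate the study's sampling: 30-s frames and a step of about
#' one body length per frame (3.6 cm, expressed as 36 units of 0.1 cm).
#'
#' @param model One of \code{"brownian"}, \code{"ballistic"}, \code{"crw"},
#'   \code{"levy"}.
#' @param n_steps Number of steps (>= 2); the path has \code{n_steps + 1}
#'   positions.
#' @param frame_interval Seconds per frame (default 30).
#' @param step_scale Displacement scale in length units per frame
#'   (default 36).
#' @param persistence Turning-angle concentration kappa >= 0 (crw only).
#' @param levy_exponent Tail exponent mu in (1, 3] (levy only).
#' @param heading_jitter Per-step heading SD in radians (ballistic only).
#' @param shape Gamma shape of crw step lengths (default 9, giving a
#'   coefficient of variation of 1/3).
#' @param start Starting position (default origin).
#' @param id,treatment Metadata passed to \code{\link{trajectory}}.
#' @param seed Optional integer; the same seed gives a bit-identical path
#'   and the caller's RNG stream is left untouched.
#' @return A \code{\link{trajectory}}.
#' @examples
#' tr <- simulate_trajectory("crw", n_steps = 50, persistence = 5, seed = 1)
#' @export
simulate_trajectory <- function(model = c("brownian", "ballistic", "crw",
                                          "levy"),
                                n_steps = 100, frame_interval = 30,
                                step_scale = 36, persistence = 5,
                                levy_exponent = 2, heading_jitter = 0,
                                shape = 9, start = c(0, 0), id = "sim",
                                treatment = NA_character_, seed = NULL) {
  model <- match.arg(model)
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("`n_steps` must be >= 2", call. = FALSE)
  if (step_scale <= 0) stop("`step_scale` must be > 0", call. = FALSE)
  steps <- with_seed(seed, switch(
    model,
    brownian = matrix(stats::rnorm(2L * n_steps, 0, step_scale),
                      ncol = 2L),
    ballistic = {
      h <- rep(stats::runif(1, -pi, pi), n_steps)
      if (heading_jitter > 0)
        h <- h + cumsum(stats::rnorm(n_steps, 0, heading_jitter))
      step_scale * cbind(cos(h), sin(h))
    },
    crw = {
      if (persistence < 0) stop("`persistence` must be >= 0", call. = FALSE)
      len <- stats::rgamma(n_steps, shape = shape,
                           rate = shape / step_scale)
      turns <- if (persistence == 0) stats::runif(n_steps, -pi, pi)
               else wrap_angle(stats::rnorm(n_steps, 0,
                                            1 / sqrt(persistence)))
      h <- wrap_angle(stats::runif(1, -pi, pi) + cumsum(turns))
      len * cbind(cos(h), sin(h))
    },
    levy = {
      if (levy_exponent <= 1 || levy_exponent > 3)
        stop("`levy_exponent` must be in (1, 3]", call. = FALSE)
      h <- numeric(0)
      while (length(h) < n_steps) {
        run <- ceiling(stats::runif(1)^(-1 / (levy_exponent - 1)))
        h <- c(h, rep(stats::runif(1, -pi, pi), run))
      }
      h <- h[seq_len(n_steps)]
      step_scale * cbind(cos(h), sin(h))
    }))
  pos <- rbind(0, apply(steps, 2L, cumsum))
  pos[, 1L] <- pos[, 1L] + start[1L]
  pos[, 2L] <- pos[, 2L] + start[2L]
  trajectory(id = id, positions = pos, frame_interval = frame_interval,
             treatment = treatment, unit = "0.1cm")
}

#' Configuration for a synthetic two-treatment study
#'
#' Defaults mirror the emulated experiment: 29 control and 21 predator-cue
#' individuals released at the centre of a 3-m circular arena (radius 150 cm
#' = 1500 units of 0.1 cm), trials truncated within 10 cm of the edge,
#' trial durations of 16-208 steps at 30 s per step (8-104 min). Control
#' individuals draw a widely heterogeneous persistence (Brownian through
#' near-ballistic); predator-cue individuals draw concentrated high
#' persistence and move 34% faster on average.
#'
#' @param n_control,n_predator Group sizes.
#' @param arena_radius Arena radius in length units (0.1 cm).
#' @param stop_margin Edge margin triggering truncation, in length units.
#' @param steps_range Integer range trial durations are drawn from.
#' @param frame_interval Seconds per frame.
#' @param step_scale Mean control step length per frame (length units).
#' @param control_log10_kappa Range of log10 persistence for controls (drawn
#'   uniformly per individual: kappa 0.25-250 spans Brownian-like to
#'   near-ballistic paths at these trial lengths).
#' @param predator_log10_kappa Range of log10 persistence for predator-cue
#'   individuals (kappa 80-600: concentrated, near-ballistic).
#' @param predator_speed_multiplier Mean speed ratio predator/control
#'   (default 1.34, the emulated 34% increase).
#' @param individual_speed_sd SD of the per-individual log-normal speed
#'   multiplier (between-animal variability; 0 disables it).
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(n_control = 29, n_predator = 21,
                         arena_radius = 1500, stop_margin = 100,
                         steps_range = c(16, 208), frame_interval = 30,
                         step_scale = 36,
                         control_log10_kappa = c(-0.6, 2.4),
                         predator_log10_kappa = c(1.9, 2.8),
                         predator_speed_multiplier = 1.34,
                         individual_speed_sd = 0.2) {
  if (n_control < 1 || n_predator < 1)
    stop("group sizes must be >= 1", call. = FALSE)
  if (stop_margin >= arena_radius)
    stop("`stop_margin` must be smaller than `arena_radius`", call. = FALSE)
  if (steps_range[1L] < 2 || steps_range[2L] < steps_range[1L])
    stop("invalid `steps_range`", call. = FALSE)
  structure(as.list(environment()), class = "study_config")
}

# Truncate a trajectory at the first frame within `margin` of the arena
# edge. That frame is kept as the trial's last observation unless the step
# overshot the wall itself (positions outside the tank are unobservable),
# in which case the trial ends one frame earlier.
truncate_at_edge <- function(traj, arena_radius, margin) {
  p <- traj$positions
  r <- sqrt(p[, 1L]^2 + p[, 2L]^2)
  hit <- which(r > arena_radius - margin)
  if (length(hit)) {
    cut_at <- if (r[hit[1L]] <= arena_radius) hit[1L] else hit[1L] - 1L
    cut_at <- min(max(2L, cut_at), nrow(p))
    traj$positions <- p[seq_len(cut_at), , drop = FALSE]
  }
  traj
}

#' Simulate a full two-treatment study dataset
#'
#' Draws one correlated-random-walk trajectory per individual under the
#' group-level distributions of \code{\link{study_config}}: all start at the
#' arena centre, run for a uniformly drawn duration, and are truncated at
#' the first frame within \code{stop_margin} of the edge. Deterministic
#' given \code{seed}.
#'
#' @param config A \code{\link{study_config}}.
#' @param seed Optional integer seed (the caller's RNG stream is preserved).
#' @return A \code{\link{study_dataset}} with treatments \code{"control"}
#'   and \code{"predator"}.
#' @examples
#' d <- simulate_study(study_config(), seed = 1)
#' length(d)  # 50
#' @export
simulate_study <- function(config = study_config(), seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  with_seed(seed, {
    make_group <- function(n, label, kappa_range, speed_mult) {
      lapply(seq_len(n), function(i) {
        kappa <- 10^stats::runif(1, kappa_range[1L], kappa_range[2L])
        n_steps <- sample(seq(config$steps_range[1L],
                              config$steps_range[2L]), 1L)
        mult <- speed_mult *
          exp(stats::rnorm(1, 0, config$individual_speed_sd))
        tr <- simulate_trajectory(
          "crw", n_steps = n_steps,
          frame_interval = config$frame_interval,
          step_scale = config$step_scale * mult,
          persistence = kappa,
          id = sprintf("%s_%02d", label, i), treatment = label)
        truncate_at_edge(tr, config$arena_radius, config$stop_margin)
      })
    }
    study_dataset(c(
      make_group(config$n_control, "control",
                 config$control_log10_kappa, 1),
      make_group(config$n_predator, "predator",
                 config$predator_log10_kappa,
                 config$predator_speed_multiplier)))
  })
}
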