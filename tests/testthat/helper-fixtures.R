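# Small in-code fixtures shared across test files.

make_traj <- function(xy, id = "t", dt = 30, treatment = NA_character_) {
  trajectory(id, as.matrix(xy), frame_interval = dt, treatment = treatment)
}

# Straight line along a given direction, n positions, unit step.
straight_traj <- function(n = 10, angle = 0, step = 1, id = "line") {
  k <- seq_len(n) - 1
  make_traj(cbind(k * step * cos(angle), k * step * sin(angle)), id = id)
}

# Brute-force structure-function oracle: explicit double loop over all
# ordered pairs (t, t + tau). Independent of moment_curve's vectorised path.
brute_moments <- function(positions, q_grid, tau_grid) {
  n <- nrow(positions)
  M <- matrix(NA_real_, length(q_grid), length(tau_grid))
  for (j in seq_along(tau_grid)) {
    tau <- tau_grid[j]
    mods <- c()
    for (t in 1:(n - tau)) {
      dx <- positions[t + tau, 1] - positions[t, 1]
      dy <- positions[t + tau, 2] - positions[t, 2]
      mods <- c(mods, sqrt(dx^2 + dy^2))
    }
    for (i in seq_along(q_grid)) M[i, j] <- mean(mods^q_grid[i])
  }
  M
}

# Random walk with finite positions, for property tests.
random_traj <- function(n_pos, id = "rw") {
  make_traj(cbind(cumsum(rnorm(n_pos)), cumsum(rnorm(n_pos))), id = id)
}
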