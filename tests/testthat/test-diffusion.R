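test_that("moment curve matches hand-enumerated moments on a unit-step path", {
  # staircase of unit steps: all tau = 1 displacements have modulus 1,
  # all tau = 2 displacements modulus sqrt(2)
  p <- rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2), c(3, 2),
             c(3, 3), c(4, 3))
  mc <- moment_curve(make_traj(p), q_grid = 2, max_tau_fraction = 0.5)
  expect_equal(unname(mc$moments[1, mc$tau_grid == 1]), 1)
  expect_equal(unname(mc$moments[1, mc$tau_grid == 2]), 2)
})

test_that("constant-velocity paths have exactly M(q, tau) = (v tau)^q", {
  v <- 2.5
  tr <- make_traj(cbind(v * 0:40 * 0.6, v * 0:40 * 0.8))
  mc <- moment_curve(tr)
  for (i in seq_along(mc$q_grid))
    expect_equal(unname(mc$moments[i, ]),
                 (v * mc$tau_grid)^mc$q_grid[i], tolerance = 1e-12)
})

test_that("a stationary path yields all-zero moments and a flag", {
  expect_warning(mc <- moment_curve(make_traj(matrix(2, 10, 2))),
                 "degenerate")
  expect_true(all(mc$moments == 0))
  expect_true(mc$degenerate)
})

test_that("moment curve equals the brute-force all-pairs oracle", {
  set.seed(101)
  for (i in 1:100) {
    tr <- random_traj(sample(8:50, 1))
    mc <- moment_curve(tr, q_grid = c(0.5, 1, 2, 3))
    expect_equal(mc$moments,
                 brute_moments(tr$positions, c(0.5, 1, 2, 3), mc$tau_grid),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("the tau grid is log-spaced integers capped at the tau fraction", {
  tr <- straight_traj(101)  # 100 steps
  mc <- moment_curve(tr, n_taus = 12, max_tau_fraction = 0.25)
  expect_identical(mc$tau_grid, unique(as.integer(round(
    exp(seq(log(1), log(25), length.out = 12))))))
  expect_lte(max(mc$tau_grid), 25)
  expect_error(moment_curve(tr, max_tau_fraction = 0.7), "max_tau_fraction")
  expect_error(moment_curve(straight_traj(7)), "8 positions")
  expect_error(moment_curve(tr, q_grid = c(1, -2)), "positive")
})

test_that("zeta exponents recover analytic scaling laws", {
  # ballistic: zeta(q) = q, summary slope 1
  zf <- zeta_exponents(moment_curve(straight_traj(201, angle = 0.7,
                                                  step = 3)))
  expect_equal(zf$zeta, zf$q_grid, tolerance = 1e-9)
  expect_equal(zf$slope, 1, tolerance = 1e-9)
  expect_true(all(zf$r_squared > 1 - 1e-12))

  # synthetic curve M(q, tau) = tau^(q/2): slope exactly 0.5
  q <- seq(0.5, 3, 0.5); tau <- c(1, 2, 4, 8, 16)
  curve <- structure(list(q_grid = q, tau_grid = tau,
                          moments = outer(q, tau, function(q, t) t^(q / 2)),
                          n_pairs = rep(50L, 5), degenerate = FALSE),
                     class = "moment_curve")
  zf2 <- zeta_exponents(curve)
  expect_equal(zf2$slope, 0.5, tolerance = 1e-12)
  expect_equal(zf2$zeta, q / 2, tolerance = 1e-12)
})

test_that("zeta handles non-positive moments by dropping and excluding", {
  q <- c(1, 2); tau <- c(1, 2, 4, 8)
  M <- outer(q, tau, function(q, t) t^q)
  M[2, 3] <- 0  # one bad cell: that tau dropped for q = 2 only
  curve <- structure(list(q_grid = q, tau_grid = tau, moments = M,
                          n_pairs = rep(10L, 4), degenerate = FALSE),
                     class = "moment_curve")
  expect_warning(zf <- zeta_exponents(curve), "non-positive")
  expect_equal(zf$n_tau, c(4L, 3L))
  expect_equal(zf$zeta[1], 1, tolerance = 1e-12)

  M[2, ] <- c(1, 0, 0, 2)  # < 3 usable points: zeta(2) undefined
  curve$moments <- M
  expect_warning(zf2 <- zeta_exponents(curve))
  expect_true(is.na(zf2$zeta[2]))
  expect_equal(zf2$slope, 1, tolerance = 1e-12)  # from q = 1 alone
})

test_that("moments are unit-covariant and zeta unit-invariant", {
  set.seed(31)
  tr <- random_traj(60)
  scaled <- make_traj(tr$positions * 7)
  mc <- moment_curve(tr); mcs <- moment_curve(scaled)
  for (i in seq_along(mc$q_grid))
    expect_equal(mcs$moments[i, ], 7^mc$q_grid[i] * mc$moments[i, ],
                 tolerance = 1e-10)
  expect_equal(zeta_exponents(mcs)$slope, zeta_exponents(mc)$slope,
               tolerance = 1e-10)
})

test_that("zeta(q) is non-decreasing in q across random walks", {
  set.seed(77)
  for (i in 1:25) {
    zf <- zeta_exponents(moment_curve(random_traj(80)))
    expect_true(all(diff(zf$zeta) > -1e-8))
  }
})

test_that("diffusion regimes classify against the reference slopes", {
  expect_identical(classify_diffusion(0.5)$label, "brownian")
  expect_identical(classify_diffusion(1.0)$label, "ballistic")
  expect_identical(classify_diffusion(0.75)$label, "superdiffusive")
  expect_identical(classify_diffusion(0.3)$label, "subdiffusive")
  # near the band edges (exact edges are floating-point knife edges)
  expect_identical(classify_diffusion(0.549)$label, "brownian")
  expect_identical(classify_diffusion(0.951)$label, "ballistic")
  expect_identical(classify_diffusion(0.449)$label, "subdiffusive")
  expect_error(classify_diffusion(NaN), "finite")
  expect_error(classify_diffusion(0.5, band_halfwidth = 0.3), "0.25")
})

test_that("simulated regimes order and recover their slopes", {
  set.seed(140)
  n <- 40
  bm <- replicate(n, zeta_slope(simulate_trajectory("brownian",
                                                    n_steps = 200)))
  cw <- replicate(n, zeta_slope(simulate_trajectory("crw", n_steps = 200,
                                                    persistence = 5)))
  ba <- replicate(n, zeta_slope(simulate_trajectory("ballistic",
                                                    n_steps = 200)))
  expect_equal(mean(ba), 1, tolerance = 1e-8)
  expect_equal(mean(bm), 0.5, tolerance = 0.05)
  expect_gt(median(cw), median(bm))
  expect_lt(median(cw), median(ba))
  expect_gte(mean(bm < cw & cw < ba), 0.95)
})
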