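test_that("Levene's test is zero for identical groups and validates input", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  lt <- levene_test(v, g)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p_value, 1)
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Levene's test detects a 9-fold variance ratio with power", {
  set.seed(61)
  rej <- mean(replicate(200, {
    levene_test(c(rnorm(200, 0, 1), rnorm(200, 0, 3)),
                rep(c("a", "b"), each = 200))$p_value < 0.01
  }))
  expect_gte(rej, 0.95)
})

test_that("Levene's type-I error is calibrated under equal variances", {
  set.seed(62)
  rej <- mean(replicate(2000, {
    levene_test(rnorm(50), rep(c("a", "b"), c(29, 21)))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("lm_treatment equals the squared pooled two-sample t", {
  set.seed(63)
  for (i in 1:200) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    v <- c(rnorm(n1), rnorm(n2, 0.4))
    g <- rep(c("a", "b"), c(n1, n2))
    m <- lm_treatment(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(m$effects$statistic[1], unname(tt$statistic)^2,
                 tolerance = 1e-8)
    expect_equal(m$effects$p_value[1], tt$p.value, tolerance = 1e-8)
    expect_equal(m$effects$df, c(1L, n1 + n2 - 2L))
  }
})

test_that("lm_treatment handles identity and degeneracy", {
  m <- lm_treatment(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(m$effects$statistic[1], 0)
  expect_equal(m$effects$p_value[1], 1)
  expect_error(lm_treatment(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero total variance")
  sep <- suppressWarnings(lm_treatment(c(0, 0, 0, 0, 1, 1, 1, 1) +
                        c(1e-9, -1e-9, 2e-9, 0, 1e-9, 0, -1e-9, 0),
                      rep(c("a", "b"), each = 4)))
  expect_lt(sep$effects$p_value[1], 1e-10)
})

test_that("heteroscedastic GLS is null on identical groups and matches
           the nlme varIdent fit", {
  skip_if_not_installed("nlme")
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  m <- gls_heteroscedastic(v, g)
  expect_equal(m$effects$statistic[1], 0, tolerance = 1e-10)
  expect_equal(m$effects$p_value[1], 1, tolerance = 1e-6)
  expect_equal(m$group_sd_ratio, 1, tolerance = 1e-10)

  set.seed(64)
  for (i in 1:10) {
    v <- c(rnorm(29, 0.75, 0.15), rnorm(21, 0.95, 0.05))
    g <- factor(rep(c("control", "predator"), c(29, 21)))
    m <- gls_heteroscedastic(v, g)
    d <- data.frame(v = v, g = g)
    full <- nlme::gls(v ~ g, data = d, method = "ML",
                      weights = nlme::varIdent(form = ~1 | g))
    null <- nlme::gls(v ~ 1, data = d, method = "ML",
                      weights = nlme::varIdent(form = ~1 | g))
    chi2_ref <- 2 * (as.numeric(logLik(full)) -
                       as.numeric(logLik(null)))
    expect_equal(m$effects$statistic[1], chi2_ref, tolerance = 1e-4)
    expect_equal(m$aic, AIC(full), tolerance = 1e-6)
    sd_ref <- sigma(full) * coef(full$modelStruct$varStruct,
                                 unconstrained = FALSE, allCoef = TRUE)
    # nlme's sigma is REML-style-normalised by n - p; rescale to ML
    expect_equal(unname(m$group_sd_ratio),
                 unname(sd_ref[["predator"]] / sd_ref[["control"]]),
                 tolerance = 1e-5)
  }
})

test_that("GLS chi2 agrees with the homoscedastic LRT when variances are
           truly equal", {
  set.seed(65)
  ratios <- replicate(300, {
    v <- c(rnorm(25, 0, 1), rnorm(25, 0.3, 1))
    g <- rep(c("a", "b"), each = 25)
    m <- gls_heteroscedastic(v, g)
    fit1 <- lm(v ~ g); fit0 <- lm(v ~ 1)
    chi2_hom <- 2 * (as.numeric(logLik(fit1)) - as.numeric(logLik(fit0)))
    m$effects$statistic[1] / chi2_hom
  })
  expect_equal(median(ratios), 1, tolerance = 0.05)
})

test_that("GLS has power at the study's effect and variance structure", {
  set.seed(66)
  rej <- mean(replicate(200, {
    v <- c(rnorm(29, 0.75, 0.15), rnorm(21, 0.95, 0.05))
    g <- rep(c("control", "predator"), c(29, 21))
    gls_heteroscedastic(v, g)$effects$p_value[1] < 0.01
  }))
  expect_gte(rej, 0.90)
})

test_that("Wald and LRT chi2 agree to first order", {
  set.seed(67)
  v <- c(rnorm(40, 0, 2), rnorm(40, 0.5, 0.5))
  g <- rep(c("a", "b"), each = 40)
  lrt <- gls_heteroscedastic(v, g, test = "LRT")$effects$statistic[1]
  wald <- gls_heteroscedastic(v, g, test = "Wald")$effects$statistic[1]
  expect_equal(lrt, wald, tolerance = 0.2)
})

test_that("the heteroscedastic model wins on AIC when SDs differ 3-fold", {
  set.seed(68)
  wins <- mean(replicate(200, {
    v <- c(rnorm(25, 0, 1), rnorm(25, 0, 3))
    g <- rep(c("a", "b"), each = 25)
    gls_heteroscedastic(v, g)$aic < AIC(lm(v ~ g))
  }))
  expect_gte(wins, 0.90)
})

test_that("ANCOVA reproduces a deterministic linear dependence", {
  set.seed(69)
  slope <- runif(40, 0.5, 1)
  g <- rep(c("a", "b"), each = 20)
  ent <- 2 - slope
  m <- suppressWarnings(ancova_entropy(ent, slope, g))
  expect_equal(m$effects$term,
               c("treatment", "slope", "treatment:slope", "residuals"))
  expect_lt(m$effects$p_value[2], 1e-10)
  # the interaction explains nothing: its coefficient and F are negligible
  expect_equal(unname(m$coefficients[4]), 0, tolerance = 1e-8)
  expect_gt(m$effects$p_value[3], 0.9)
  expect_equal(m$effects$df, c(1L, 1L, 1L, 36L))
})

test_that("ANCOVA terms are null-calibrated when entropy is pure noise", {
  set.seed(70)
  ps <- t(replicate(600, {
    slope <- runif(50, 0.5, 1)
    g <- rep(c("a", "b"), c(29, 21))
    m <- ancova_entropy(rnorm(50), slope, g)
    m$effects$p_value[1:3]
  }))
  for (j in 1:3) {
    ks <- ks.test(ps[, j], "punif")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("ANCOVA detects a slope-entropy relation plus group offset", {
  set.seed(71)
  hits <- replicate(200, {
    g <- rep(c("a", "b"), each = 25)
    slope <- c(runif(25, 0.5, 0.9), runif(25, 0.8, 1))
    ent <- 3 - 1.5 * slope - 0.3 * (g == "b") + rnorm(50, 0, 0.25)
    m <- ancova_entropy(ent, slope, g)
    c(m$effects$p_value[1] < 0.05, m$effects$p_value[2] < 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.90)
  expect_gte(mean(hits[2, ]), 0.90)
})

test_that("ANCOVA validates its preconditions", {
  expect_error(ancova_entropy(1:5, 1:5, rep(c("a", "b"), c(3, 2))),
               "at least 8")
  g <- rep(c("a", "b"), each = 5)
  expect_error(ancova_entropy(rnorm(10), rep(c(1, 2), each = 5), g),
               "collinear")
})

test_that("tests are location invariant and scale invariant", {
  set.seed(72)
  v <- c(rnorm(15, 0, 2), rnorm(15, 1, 0.5))
  g <- rep(c("a", "b"), each = 15)
  for (shift in c(0, 13.7)) for (scale in c(1, 4.2)) {
    w <- scale * (v + shift)
    expect_equal(lm_treatment(w, g)$effects$statistic[1],
                 lm_treatment(v, g)$effects$statistic[1],
                 tolerance = 1e-8)
    expect_equal(gls_heteroscedastic(w, g)$effects$statistic[1],
                 gls_heteroscedastic(v, g)$effects$statistic[1],
                 tolerance = 1e-8)
    expect_equal(levene_test(w, g)$statistic,
                 levene_test(v, g)$statistic, tolerance = 1e-8)
  }
})
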