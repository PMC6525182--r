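test_that("closed-form OLS matches lm and the exact-line cases", {
  f <- olsFit(0:2, 0:2)
  expect_equal(coef(f), c(slope = 1, intercept = 0), tolerance = 1e-12)
  expect_equal(f@r2, 1)
  g <- olsFit(1:5, rep(2, 5))
  expect_equal(g@slope, 0)
  expect_equal(g@r2, 0)
  for (s in 1:5) {
    set.seed(s)
    x <- runif(30); y <- 0.3 * x - 0.1 + rnorm(30, 0, 0.2)
    mine <- olsFit(x, y)
    ref <- summary(stats::lm(y ~ x))
    expect_equal(mine@slope, ref$coefficients["x", "Estimate"], tolerance = 1e-10)
    expect_equal(mine@intercept, ref$coefficients["(Intercept)", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(mine@slopeSE, ref$coefficients["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(mine@pSlope, ref$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(mine@r2, ref$r.squared, tolerance = 1e-10)
  }
  expect_error(olsFit(rep(1, 5), 1:5), "degenerate")
  expect_error(olsFit(1:2, 1:2), "at least 3")
})

test_that("near-noise-free allometry data recover the generating slope", {
  set.seed(42)
  x <- runif(50, 0.1, 1.2)
  y <- 0.43 * x - 0.016 + rnorm(50, 0, 1e-6)
  f <- olsFit(x, y)
  expect_equal(f@slope, 0.43, tolerance = 1e-3)
  expect_equal(f@intercept, -0.016, tolerance = 1e-4)
})

test_that("allometric NLS recovers noise-free curves exactly", {
  x <- seq(0.1, 1.0, length.out = 10)
  y <- (0.5 + 0.1 / x)^2 + 0.05
  f <- nlsAllometricFit(x, y)
  expect_true(f@converged)
  expect_equal(coef(f), c(a = 0.5, b = 0.1, d = 0.05), tolerance = 1e-6)
  expect_lt(f@residualSS, 1e-12)
  # negative-b direction (the falling-RTD shape)
  y2 <- (0.3 - 0.05 / x)^2 + 0.1
  f2 <- nlsAllometricFit(x, y2)
  expect_equal(coef(f2), c(a = 0.3, b = -0.05, d = 0.1), tolerance = 1e-6)
  expect_gte(f2@a, 0)   # sign symmetry resolved toward a >= 0
})

test_that("constant response is a flagged degenerate NLS result", {
  f <- nlsAllometricFit(seq(0.1, 1, length.out = 12), rep(3, 12))
  expect_true(f@degenerate)
  expect_equal(f@d, 3)
})

test_that("NLS R-squared is invariant to observation order and beats minpack on RSS", {
  skip_if_not_installed("minpack.lm")
  set.seed(9)
  x <- runif(80, 0.1, 1.2)
  y <- (0.45 + 0.06 / x)^2 + 0.02 + rnorm(80, 0, 0.03)
  f <- nlsAllometricFit(x, y)
  perm <- sample(80)
  f2 <- nlsAllometricFit(x[perm], y[perm])
  expect_equal(f@r2, f2@r2, tolerance = 1e-9)
  ref <- minpack.lm::nlsLM(y ~ (a + b / x)^2 + d,
                           start = list(a = 0.4, b = 0.1, d = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_lte(f@residualSS, sum(stats::residuals(ref)^2) * (1 + 1e-8))
})

test_that("nonlinear fit quality degrades as generative noise grows", {
  x <- seq(0.1, 1.2, length.out = 200)
  mu <- (0.45 + 0.06 / x)^2 + 0.02
  r2s <- vapply(c(0.005, 0.02, 0.08), function(s) {
    set.seed(100 + round(1000 * s))
    nlsAllometricFit(x, mu + rnorm(length(x), 0, s))@r2
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("SMA slope is the sd ratio signed by the correlation", {
  x <- runif(30)
  f <- smaFit(x, 2 * x)
  expect_equal(f@slope, 2, tolerance = 1e-12)
  swapped <- smaFit(2 * x, x)
  expect_equal(swapped@slope, 1 / f@slope, tolerance = 1e-12)  # SMA symmetry
  # constructed sample: sd(y)/sd(x) = 3, negative correlation
  set.seed(5)
  x2 <- rnorm(100)
  y2 <- -3 * x2 + rnorm(100, 0, 0.5)
  y2 <- (y2 - mean(y2)) / stats::sd(y2) * 3 * stats::sd(x2)
  f2 <- smaFit(x2, y2)
  expect_equal(f2@slope, -3, tolerance = 1e-9)
  expect_lt(f2@slopeCI[1], f2@slope)
  expect_gt(f2@slopeCI[2], f2@slope)
  # slope^2 equals the variance ratio exactly
  expect_equal(f2@slope^2, stats::var(y2) / stats::var(x2), tolerance = 1e-12)
  expect_error(smaFit(rep(1, 5), 1:5), "variance")
})

test_that("common-slope test separates equal from unequal SMA slopes", {
  # identical data in both groups: statistic at (machine) zero
  set.seed(1)
  x <- runif(30); y <- 0.5 * x + rnorm(30, 0, 0.05)
  same <- smaCommonSlopeTest(list(list(x = x, y = y), list(x = x, y = y)))
  expect_lt(same$statistic, 1e-6)
  # two groups from one line, large n: chi-square path, no signal
  set.seed(2)
  x1 <- runif(200, 0.1, 1.2); y1 <- 0.4 * x1 + rnorm(200, 0, 0.02)
  x2 <- runif(200, 0.1, 1.2); y2 <- 0.4 * x2 + rnorm(200, 0, 0.02)
  nul <- smaCommonSlopeTest(list(list(x = x1, y = y1), list(x = x2, y = y2)))
  expect_gt(nul$p, 0.05)
  expect_match(nul$method, "chi-square")
  # the woody vs non-woody contrast: slopes 0.43 vs 0.32, strong separation
  set.seed(3)
  xa <- runif(500, 0.1, 1.2); ya <- 0.43 * xa + rnorm(500, 0, 0.02)
  xb <- runif(500, 0.1, 1.2); yb <- 0.32 * xb + rnorm(500, 0, 0.02)
  alt <- smaCommonSlopeTest(list(list(x = xa, y = ya), list(x = xb, y = yb)))
  expect_lt(alt$p, 0.001)
  # small groups trigger the seeded permutation fallback
  set.seed(4)
  xs <- runif(12, 0.1, 1); ys <- 0.4 * xs + rnorm(12, 0, 0.02)
  xt <- runif(12, 0.1, 1); yt <- 0.4 * xt + rnorm(12, 0, 0.02)
  perm <- smaCommonSlopeTest(list(list(x = xs, y = ys), list(x = xt, y = yt)),
                             nPerm = 999, seed = 10)
  expect_match(perm$method, "permutation")
  expect_gt(perm$p, 0.05)
  expect_error(smaCommonSlopeTest(list(list(x = 1:5, y = rep(1, 5)),
                                       list(x = 1:5, y = 1:5))), "group 1")
})

test_that("anatomy allometry fit packages OLS output as model parameters", {
  x <- seq(0.1, 1.2, length.out = 40)
  exact <- fitAnatomyAllometry(x, 0.43 * x - 0.016)
  expect_equal(paramK(exact$params), 0.43, tolerance = 1e-12)
  expect_equal(paramC(exact$params), -0.016, tolerance = 1e-12)
  samp <- generateAnatomySample(400, woodyParams(), seed = 21, sigmaT = 0.02)
  rec <- fitAnatomyAllometry(samp$diameter, samp$tToS)
  expect_lt(abs(paramK(rec$params) - 0.43), 2 * rec$fit@slopeSE)
  # minimum size runs with wide uncertainty
  tiny <- fitAnatomyAllometry(c(0.1, 0.5, 1.0), c(0.03, 0.2, 0.44))
  expect_equal(tiny$fit@n, 3L)
  expect_gt(tiny$fit@slopeSE, 0)
})

test_that("fit reports serialize cleanly to JSON-ready lists", {
  f <- olsFit(1:10, (1:10) * 0.5 + rnorm(10, 0, 0.01))
  rep <- fitReport(f)
  expect_equal(rep$model, "linear")
  expect_true(all(c("params", "r2", "n", "p") %in% names(rep)))
  nf <- nlsAllometricFit(seq(0.1, 1, length.out = 12),
                         (0.4 + 0.05 / seq(0.1, 1, length.out = 12))^2)
  expect_true(fitReport(nf)$converged)
})
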