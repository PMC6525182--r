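test_that("Newick reading validates structure and branch lengths", {
  tr <- readNewick("((a:1,b:1):1,c:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(tr$Nnode, 2L)
  expect_error(readNewick("((a:1,b:1):1,c:2;"), "malformed")
  expect_error(readNewick("((a:1,b):1,c:2);"), "branch length")
})

test_that("Newick round-trip preserves topology and branch lengths", {
  for (s in 1:5) {
    tr <- simulateTree(20, seed = s)
    back <- readNewick(writeNewick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    C1 <- vcvMatrix(tr); C2 <- vcvMatrix(back)
    expect_equal(C2[rownames(C1), colnames(C1)], C1, tolerance = 1e-9)
  }
  # file path round-trip
  f <- tempfile(fileext = ".nwk")
  tr <- simulateTree(8, seed = 3)
  writeNewick(tr, f)
  expect_equal(sort(readNewick(f)$tip.label), sort(tr$tip.label))
})

test_that("polytomy resolution is binary, seeded, and path-preserving", {
  poly <- readNewick("(a:1,b:1,c:1,d:2);")
  r1 <- resolvePolytomies(poly, seed = 5)
  r2 <- resolvePolytomies(poly, seed = 5)
  r3 <- resolvePolytomies(poly, seed = 6)
  expect_true(ape::is.binary(r1))
  expect_identical(writeNewick(r1), writeNewick(r2))   # deterministic per seed
  expect_false(identical(writeNewick(r1), writeNewick(r3)))
  expect_equal(sum(r1$edge.length), sum(poly$edge.length))  # zero-length insertions
  # tip-to-root depths unchanged
  expect_equal(diag(vcvMatrix(r1))[sort(poly$tip.label)],
               diag(vcvMatrix(resolvePolytomies(poly, 99)))[sort(poly$tip.label)])
  expect_equal(unname(diag(vcvMatrix(r1))[c("a", "b", "c", "d")]), c(1, 1, 1, 2))
  # already-binary trees pass through unchanged
  bin <- simulateTree(6, seed = 2)
  expect_identical(resolvePolytomies(bin, 1), bin)
})

test_that("Yule simulation is seeded and handles the 2-tip edge", {
  t1 <- simulateTree(15, seed = 4)
  t2 <- simulateTree(15, seed = 4)
  expect_identical(writeNewick(t1), writeNewick(t2))
  cherry <- simulateTree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
  expect_equal(cherry$Nnode, 1L)
  expect_error(simulateTree(1), ">= 2")
})

test_that("phylogenetic covariance matches hand tracing and the ape oracle", {
  C <- vcvMatrix(readNewick("((a:1,b:1):1,c:2);"))
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "a"], 2)
  expect_equal(C["a", "c"], 0)
  # two tips from the root: identity-like
  C2 <- vcvMatrix(readNewick("(a:1,b:1);"))
  expect_equal(unname(C2), diag(2))
  for (s in 1:5) {
    tr <- simulateTree(25, seed = 10 + s)
    mine <- vcvMatrix(tr)
    ref <- ape::vcv(tr)
    expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
    expect_equal(stats::sd(diag(mine)), 0, tolerance = 1e-9)  # ultrametric
  }
})

test_that("Brownian trait simulation honors its degenerate limits", {
  tr <- simulateTree(10, seed = 1)
  z0 <- simulateBMTrait(tr, sigma2 = 0, rootValue = 3.5, seed = 2)
  expect_equal(unname(z0), rep(3.5, 10))
  # lambda = 0: star-like covariance, empirical tip correlation near zero
  sib <- readNewick("((a:0.1,b:0.1):0.9,(c:0.1,d:0.1):0.9);")
  reps <- t(vapply(1:400, function(i)
    simulateBMTrait(sib, 1, 0, lambda = 0, seed = 100 + i), numeric(4)))
  expect_lt(abs(stats::cor(reps[, "a"], reps[, "b"])), 0.15)
  expect_equal(unname(apply(reps, 2, stats::var)), rep(1, 4), tolerance = 0.3)
  repsBM <- t(vapply(1:400, function(i)
    simulateBMTrait(sib, 1, 0, lambda = 1, seed = 500 + i), numeric(4)))
  expect_equal(stats::cov(repsBM[, "a"], repsBM[, "b"]), 0.9, tolerance = 0.2)
})

test_that("independent contrasts match the two-taxon closed form and ape", {
  cherry <- readNewick("(a:1,b:1);")
  pc <- picContrasts(cherry, c(a = 3, b = 1))
  expect_equal(abs(unname(picValues(pc))), 2 / sqrt(2), tolerance = 1e-12)
  tr <- simulateTree(30, seed = 7)
  flat <- stats::setNames(rep(2, 30), tr$tip.label)
  expect_equal(unname(picValues(picContrasts(tr, flat))), rep(0, 29))
  for (s in 1:4) {
    tr <- simulateTree(40, seed = 20 + s)
    z <- simulateBMTrait(tr, 1, 0, 1, seed = 30 + s)
    mine <- picValues(picContrasts(tr, z))
    ref <- ape::pic(z, tr)
    expect_equal(sort(abs(unname(mine))), sort(abs(unname(ref))), tolerance = 1e-9)
  }
  expect_error(picContrasts(simulateTree(5, seed = 1), c(a = 1)), "named|missing")
})

test_that("contrast variance calibrates to the Brownian rate", {
  v <- vapply(1:200, function(i) {
    tr <- simulateTree(20, seed = 300 + i)
    z <- simulateBMTrait(tr, sigma2 = 2, rootValue = 0, seed = 700 + i)
    mean(picValues(picContrasts(tr, z))^2)
  }, numeric(1))
  expect_equal(mean(v), 2, tolerance = 0.15)
})

test_that("PIC regression has the exact-proportionality closed form", {
  tr <- simulateTree(25, seed = 2)
  x <- simulateBMTrait(tr, 1, 0, 1, seed = 3)
  res <- picRegression(tr, x, 2 * x)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$nContrasts, 24L)
})

test_that("independent Brownian traits give a PIC slope centered on zero", {
  sl <- vapply(1:100, function(i) {
    tr <- simulateTree(30, seed = 1000 + i)
    x <- simulateBMTrait(tr, 1, 0, 1, seed = 2000 + i)
    y <- simulateBMTrait(tr, 1, 0, 1, seed = 3000 + i)
    picRegression(tr, x, y)$slope
  }, numeric(1))
  expect_lt(abs(mean(sl)), 2 * stats::sd(sl) / sqrt(100))
})

test_that("Blomberg's K matches picante and rejects degenerate traits", {
  skip_if_not_installed("picante")
  for (s in 1:3) {
    tr <- simulateTree(30, seed = 40 + s)
    z <- simulateBMTrait(tr, 1, 0, 1, seed = 50 + s)
    expect_equal(signalEstimate(blombergK(tr, z, nPerm = 0)),
                 as.numeric(picante::Kcalc(z[tr$tip.label], tr)), tolerance = 1e-8)
  }
  tr <- simulateTree(10, seed = 1)
  expect_error(blombergK(tr, stats::setNames(rep(1, 10), tr$tip.label)),
               "constant")
})

test_that("shuffled traits lose phylogenetic signal", {
  tr <- simulateTree(60, seed = 8)
  z <- simulateBMTrait(tr, 1, 0, 1, seed = 9)
  set.seed(11)
  shuf <- stats::setNames(sample(z), names(z))
  res <- blombergK(tr, shuf, nPerm = 199, seed = 12)
  expect_lt(signalEstimate(res), 1)
  expect_gt(signalP(res), 0.05)
})

test_that("Pagel's lambda ML is the grid optimum and flags star trees", {
  tr <- simulateTree(40, seed = 13)
  z <- simulateBMTrait(tr, 1, 0, 0.7, seed = 14)
  fit <- pagelLambdaML(tr, z)
  C <- vcvMatrix(tr, minEdge = 1e-8)
  gridLL <- vapply(seq(0, 1, length.out = 51), function(l)
    rootAllometry:::.lambdaLogLik(C, stats::setNames(z[tr$tip.label], tr$tip.label), l),
    numeric(1))
  atHat <- rootAllometry:::.lambdaLogLik(C, z[tr$tip.label], signalEstimate(fit))
  expect_gte(atHat, max(gridLL) - 1e-9)
  star <- readNewick("(a:1,b:1,c:1,d:1);")
  expect_error(pagelLambdaML(star, c(a = 1, b = 2, c = 3, d = 4)), "star")
})

test_that("lambda end members are recovered from simulated traits", {
  tr <- simulateTree(150, seed = 15)
  z1 <- simulateBMTrait(tr, 1, 0, lambda = 1, seed = 16)
  z0 <- simulateBMTrait(tr, 1, 0, lambda = 0, seed = 17)
  expect_gte(signalEstimate(pagelLambdaML(tr, z1)), 0.85)
  expect_lte(signalEstimate(pagelLambdaML(tr, z0)), 0.1)
})

test_that("PGLS reduces to OLS on a star tree and recovers exact signals", {
  star <- readNewick("(a:1,b:1,c:1,d:1,e:1,f:1);")   # C = identity
  set.seed(18)
  dat <- data.frame(species = star$tip.label,
                    x = rnorm(6), y = rnorm(6))
  pg <- pglsFit(star, y ~ x, dat)
  ref <- stats::lm(y ~ x, dat)
  expect_equal(pg$coefficients$estimate, unname(stats::coef(ref)), tolerance = 1e-10)
  expect_equal(pg$coefficients$se,
               unname(summary(ref)$coefficients[, "Std. Error"]), tolerance = 1e-10)
  # exact linear signal on a real tree: zero residual, beta recovered
  tr <- simulateTree(20, seed = 19)
  x <- simulateBMTrait(tr, 1, 0, 1, seed = 20)
  dat2 <- data.frame(species = tr$tip.label, x = as.numeric(x),
                     y = 2 + 3 * as.numeric(x))
  pg2 <- pglsFit(tr, y ~ x, dat2)
  expect_equal(pg2$coefficients$estimate, c(2, 3), tolerance = 1e-9)
  expect_equal(pg2$sigma2, 0, tolerance = 1e-12)
  # rank deficiency names the collinear column
  dat2$x2 <- dat2$x
  expect_error(pglsFit(tr, y ~ x + x2, dat2), "x2")
})

test_that("PGLS agrees with the nlme GLS oracle under Brownian correlation", {
  skip_if_not_installed("nlme")
  tr <- simulateTree(30, seed = 21)
  x <- simulateBMTrait(tr, 1, 0, 1, seed = 22)
  set.seed(23)
  y <- 1 + 0.5 * x + simulateBMTrait(tr, 0.2, 0, 1, seed = 24)
  dat <- data.frame(species = tr$tip.label, x = as.numeric(x), y = as.numeric(y))
  pg <- pglsFit(tr, y ~ x, dat)
  ref <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corBrownian(1, tr, form = ~species))
  expect_equal(pg$coefficients$estimate, unname(stats::coef(ref)), tolerance = 1e-6)
})

test_that("comparative statistics are invariant to tip order and branch rescaling", {
  tr <- simulateTree(25, seed = 25)
  z <- simulateBMTrait(tr, 1, 0, 1, seed = 26)
  y <- simulateBMTrait(tr, 1, 0, 1, seed = 27)
  scaled <- tr; scaled$edge.length <- tr$edge.length * 7.3
  expect_equal(signalEstimate(blombergK(tr, z, nPerm = 0)),
               signalEstimate(blombergK(scaled, z, nPerm = 0)), tolerance = 1e-8)
  expect_equal(signalEstimate(pagelLambdaML(tr, z)),
               signalEstimate(pagelLambdaML(scaled, z)), tolerance = 1e-4)
  expect_equal(picRegression(tr, z, y)$r, picRegression(scaled, z, y)$r,
               tolerance = 1e-10)
  dat <- data.frame(species = tr$tip.label, x = as.numeric(z), y = as.numeric(y))
  expect_equal(pglsFit(tr, y ~ x, dat)$coefficients$estimate,
               pglsFit(scaled, y ~ x, dat)$coefficients$estimate, tolerance = 1e-9)
  # tip reordering: permute the trait vector's storage order
  perm <- sample(length(z))
  expect_equal(signalEstimate(blombergK(tr, z[perm], nPerm = 0)),
               signalEstimate(blombergK(tr, z, nPerm = 0)), tolerance = 1e-12)
})

test_that("species name reconciliation normalizes spaces and underscores", {
  tr <- readNewick("((Abies_alba:1,Picea_abies:1):1,Pinus_mugo:2);")
  trait <- c(`Abies alba` = 1, ` Picea_abies ` = 2, `Pinus mugo` = 3)
  pc <- picContrasts(resolvePolytomies(tr, 1), trait)
  expect_length(picValues(pc), 2)
})
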