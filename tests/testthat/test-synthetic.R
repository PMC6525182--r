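test_that("the generator is deterministic given config and seed", {
  cfg <- smallConfig(seed = 31)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(traits(d1), traits(d2))
  expect_identical(writeNewick(phylogeny(d1)), writeNewick(phylogeny(d2)))
  d3 <- generateDataset(smallConfig(seed = 32))
  expect_false(identical(traits(d1)$diameter, traits(d3)$diameter))
})

test_that("noise-free generation lets OLS recover the allometry exactly", {
  samp <- generateAnatomySample(200, woodyParams(), seed = 33, sigmaT = 0)
  f <- olsFit(samp$diameter, samp$tToS)
  expect_equal(f@slope, 0.43, tolerance = 1e-10)
  expect_equal(f@intercept, -0.016, tolerance = 1e-10)
  # complement mode: SR slope is exactly 0.5 - k
  fs <- olsFit(samp$diameter, samp$SR)
  expect_equal(fs@slope, 0.5 - 0.43, tolerance = 1e-10)
  expect_equal(fs@intercept, 0.016, tolerance = 1e-10)
})

test_that("default woody data carry the negative diameter-RTD association", {
  d <- generateDataset(generatorConfig(seed = 34))
  tab <- traits(d)
  w <- tab[tab$growth_form == "woody", ]
  expect_lt(stats::cor(w$diameter, w$RTD), 0)
  # and the mixture makes PRS-RTD positive, PRS-RN negative where anatomy exists
  a <- w[is.finite(w$PRS), ]
  expect_gt(stats::cor(a$PRS, a$RTD), 0)
  expect_lt(stats::cor(a$PRS, a$RN), 0)
})

test_that("generated tables have the configured sizes and vocabularies", {
  cfg <- generatorConfig(seed = 35)
  tab <- traits(generateDataset(cfg))
  expect_equal(nrow(tab), 866)
  expect_equal(sum(tab$growth_form == "woody"), 505)
  expect_equal(sum(tab$growth_form == "non-woody"), 361)
  expect_true(all(tab$mycorrhiza %in%
                    c("AM", "EM", "ERM", "NM", "AM+EM", "unknown")))
  expect_true(all(tab$root_sampling %in% c("first_order", "up_to_third")))
  expect_true(all(tab$climatic_zone %in%
                    c("tropical", "subtropical", "temperate", "boreal",
                      "Mediterranean")))
  expect_true(all(tab$diameter > 0))
  # anatomy restricted to the configured subsets
  expect_equal(sum(is.finite(tab$tToS[tab$growth_form == "woody"])), 158)
  expect_lte(sum(is.finite(tab$PRS[tab$growth_form == "non-woody"])), 13)
  prsOK <- tab$PRS[is.finite(tab$PRS)]
  expect_true(all(prsOK >= 0 & prsOK <= 1))
})

test_that("a config pushing the stele past the root wall errors out", {
  bad <- generatorConfig(seed = 36, srModeWoody = "independent",
                         srSlopeWoody = 0.4, srInterceptWoody = 0.1,
                         sigmaSR = 0.1)
  expect_error(generateDataset(bad), "out-of-domain")
})

test_that("seed is mandatory and substreams differ by stage", {
  expect_error(generatorConfig(), "seed")
  s1 <- rootAllometry:::stageSeed(7, "tree")
  s2 <- rootAllometry:::stageSeed(7, "traits")
  expect_false(s1 == s2)
  expect_identical(s1, rootAllometry:::stageSeed(7, "tree"))
})

test_that("data-source classes realize the configured thin-pool frequencies", {
  tab <- traits(generateDataset(generatorConfig(seed = 37)))
  w <- tab[tab$growth_form == "woody", ]
  cl <- makeDataSourceClasses(w, 0.53, 0.17, seed = 38)
  fC <- mean(cl$thin_high_rtd[cl$data_source_class == "correlated"])
  fU <- mean(cl$thin_high_rtd[cl$data_source_class == "uncorrelated"])
  expect_equal(fC, 0.53, tolerance = 0.02)
  expect_equal(fU, 0.17, tolerance = 0.02)
  expect_equal(100 * (fC - fU), 36, tolerance = 4)
  # the thin pool really is the high-RTD pool on the allometric curve
  expect_gt(mean(cl$RTD[cl$thin_high_rtd]), mean(cl$RTD[!cl$thin_high_rtd]))
  # and the observed high-RTD frequency gap carries the configured sign
  thr <- mean(w$RTD)
  expect_gt(mean(cl$RTD[cl$data_source_class == "correlated"] >= thr),
            mean(cl$RTD[cl$data_source_class == "uncorrelated"] >= thr))
  # equal fractions: classes statistically indistinguishable in RTD
  cl2 <- makeDataSourceClasses(w, 0.4, 0.4, seed = 39)
  f1 <- mean(cl2$RTD[cl2$data_source_class == "correlated"] >= thr)
  f2 <- mean(cl2$RTD[cl2$data_source_class == "uncorrelated"] >= thr)
  expect_lt(abs(f1 - f2), 0.1)
  expect_error(makeDataSourceClasses(w[0, ], 0.5, 0.2), "empty")
  expect_error(makeDataSourceClasses(w, 0.5, 0.45, seed = 1), "infeasible")
})

test_that("outlier injection marks exactly the requested records", {
  tab <- traits(generateDataset(smallConfig(seed = 40)))
  out <- injectOutliers(tab, nRN = 1, nPRS = 1, magnitude = 4, seed = 41)
  expect_equal(sum(out$outlier_injected), 2)
  expect_equal(nrow(out), nrow(tab))
  none <- injectOutliers(tab, nRN = 0, nPRS = 0)
  expect_equal(sum(none$outlier_injected), 0)
  expect_identical(none$RN, tab$RN)
  prsOK <- out$PRS[is.finite(out$PRS)]
  expect_true(all(prsOK <= 1))
})

test_that("species-mean aggregation averages duplicate study records", {
  cfg <- smallConfig(seed = 42, duplicateFraction = 0.2)
  tab <- traits(generateDataset(cfg))
  expect_gt(nrow(tab), 200)
  agg <- aggregateSpeciesMeans(tab)
  expect_equal(nrow(agg), 200)
  expect_equal(anyDuplicated(agg$species), 0)
  dupSp <- names(which(table(tab$species) == 2))[1]
  expect_equal(agg$RTD[agg$species == dupSp],
               mean(tab$RTD[tab$species == dupSp]), tolerance = 1e-12)
  # diameter identical across a species' studies: mean is a no-op
  expect_equal(agg$diameter[agg$species == dupSp],
               tab$diameter[tab$species == dupSp][1], tolerance = 1e-12)
})
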