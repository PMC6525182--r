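#' Generator configuration for the synthetic trait dataset
#'
#' Holds every knob of the synthetic global absorptive-root dataset: group
#' sizes, the tToS-diameter allometry truth per growth form, noise standard
#' deviations, the tissue mixture, the lognormal diameter marginals, the
#' phylogenetic-signal settings for diameter evolution, and the master seed.
#' Defaults are the study conditions: woody tToS slope 0.43 / intercept
#' -0.016 mm and non-woody 0.32 / 0.011 mm, an independently regressed woody
#' stele-radius line with slope 0.068, 505 woody and 361 non-woody species
#' with the reported mycorrhizal composition, and diameter signal lambda 0.83.
#'
#' @slot nWoody,nNonWoody species counts per growth form
#' @slot woodyParams,nonWoodyParams [AllometryParams-class] truths
#' @slot srModeWoody,srModeNonWoody "independent" (SR from its own regression
#'   line) or "complement" (SR = x/2 - tToS exactly)
#' @slot srSlopeWoody,srInterceptWoody the independent woody SR line
#' @slot sigmaT,sigmaSR,sigmaRTD,sigmaRN Gaussian noise sd for tToS (mm),
#'   SR (mm), RTD (g cm^-3) and RN (mg g^-1)
#' @slot mixture a [TissueMixture-class]
#' @slot meanlogWoody,sdlogWoody,meanlogNonWoody,sdlogNonWoody lognormal
#'   diameter marginals (mm)
#' @slot mycWoody,mycNonWoody named mycorrhizal composition counts
#' @slot lambda,sigma2 Pagel's lambda and Brownian rate for latent diameter
#'   evolution on the tree
#' @slot anatomyWoody,anatomyNonWoody how many species per growth form carry
#'   anatomy columns (tToS, SR, PRS); the rest are NA
#' @slot duplicateFraction fraction of species measured in a second study
#' @slot seed master RNG seed (mandatory); stage seeds derive from it
#' @export
setClass("GeneratorConfig", representation(
  nWoody = "numeric", nNonWoody = "numeric",
  woodyParams = "AllometryParams", nonWoodyParams = "AllometryParams",
  srModeWoody = "character", srModeNonWoody = "character",
  srSlopeWoody = "numeric", srInterceptWoody = "numeric",
  sigmaT = "numeric", sigmaSR = "numeric",
  sigmaRTD = "numeric", sigmaRN = "numeric",
  mixture = "TissueMixture",
  meanlogWoody = "numeric", sdlogWoody = "numeric",
  meanlogNonWoody = "numeric", sdlogNonWoody = "numeric",
  mycWoody = "numeric", mycNonWoody = "numeric",
  lambda = "numeric", sigma2 = "numeric",
  anatomyWoody = "numeric", anatomyNonWoody = "numeric",
  duplicateFraction = "numeric", seed = "numeric"))

setValidity("GeneratorConfig", function(object) {
  if (length(object@seed) != 1 || !is.finite(object@seed))
    return("a single finite master seed is mandatory")
  if (object@nWoody < 0 || object@nNonWoody < 0) return("group sizes must be >= 0")
  if (object@nWoody + object@nNonWoody < 2) return("need at least 2 species in total")
  if (!all(c(object@srModeWoody, object@srModeNonWoody) %in%
           c("independent", "complement")))
    return("SR modes must be 'independent' or 'complement'")
  if (any(c(object@sigmaT, object@sigmaSR, object@sigmaRTD, object@sigmaRN) < 0))
    return("noise sds must be >= 0")
  if (object@lambda < 0 || object@lambda > 1) return("lambda must lie in [0, 1]")
  if (object@duplicateFraction < 0 || object@duplicateFraction > 1)
    return("duplicateFraction must lie in [0, 1]")
  TRUE
})

#' Construct a generator configuration
#'
#' @param seed master RNG seed (required)
#' @param nWoody,nNonWoody species counts (defaults 505 and 361)
#' @param woodyParams,nonWoodyParams tToS-diameter truths
#' @param srModeWoody,srModeNonWoody stele-radius generation mode
#' @param srSlopeWoody,srInterceptWoody independent woody SR line
#' @param sigmaT,sigmaSR,sigmaRTD,sigmaRN noise sds
#' @param mixture tissue property mixture
#' @param meanlogWoody,sdlogWoody,meanlogNonWoody,sdlogNonWoody diameter
#'   lognormal marginals
#' @param mycWoody,mycNonWoody mycorrhizal composition counts
#' @param lambda,sigma2 diameter-evolution signal settings
#' @param anatomyWoody,anatomyNonWoody anatomy-subset sizes
#' @param duplicateFraction fraction of species with a second study record
#' @return a [GeneratorConfig-class]
#' @export
generatorConfig <- function(seed,
                            nWoody = 505, nNonWoody = 361,
                            woodyParams = AllometryParams(0.43, -0.016),
                            nonWoodyParams = AllometryParams(0.32, 0.011),
                            srModeWoody = "independent",
                            srModeNonWoody = "complement",
                            srSlopeWoody = 0.068, srInterceptWoody = 0.016,
                            sigmaT = 0.02, sigmaSR = 0.004,
                            sigmaRTD = 0.05, sigmaRN = 2,
                            mixture = TissueMixture(),
                            meanlogWoody = log(0.35), sdlogWoody = 0.45,
                            meanlogNonWoody = log(0.25), sdlogNonWoody = 0.4,
                            mycWoody = c(AM = 376, EM = 89, ERM = 13, NM = 3,
                                         `AM+EM` = 17, unknown = 7),
                            mycNonWoody = c(AM = 352, NM = 6, unknown = 3),
                            lambda = 0.83, sigma2 = 1,
                            anatomyWoody = 158, anatomyNonWoody = 13,
                            duplicateFraction = 0) {
  if (missing(seed)) stop("seed is mandatory")
  new("GeneratorConfig", nWoody = nWoody, nNonWoody = nNonWoody,
      woodyParams = woodyParams, nonWoodyParams = nonWoodyParams,
      srModeWoody = srModeWoody, srModeNonWoody = srModeNonWoody,
      srSlopeWoody = srSlopeWoody, srInterceptWoody = srInterceptWoody,
      sigmaT = sigmaT, sigmaSR = sigmaSR,
      sigmaRTD = sigmaRTD, sigmaRN = sigmaRN, mixture = mixture,
      meanlogWoody = meanlogWoody, sdlogWoody = sdlogWoody,
      meanlogNonWoody = meanlogNonWoody, sdlogNonWoody = sdlogNonWoody,
      mycWoody = mycWoody, mycNonWoody = mycNonWoody,
      lambda = lambda, sigma2 = sigma2,
      anatomyWoody = anatomyWoody, anatomyNonWoody = anatomyNonWoody,
      duplicateFraction = duplicateFraction, seed = seed)
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: %d woody + %d non-woody species, seed %d\n",
              object@nWoody, object@nNonWoody, as.integer(object@seed)))
  cat(sprintf("  woody tToS = %.3g x %+.3g (SR mode %s), non-woody %.3g x %+.3g (%s)\n",
              object@woodyParams@k, object@woodyParams@c, object@srModeWoody,
              object@nonWoodyParams@k, object@nonWoodyParams@c,
              object@srModeNonWoody))
})

# deterministic per-stage seed derived from the master seed and a stage name
stageSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}

#' Simulate an anatomy sample (diameter, tToS, SR)
#'
#' The core generative step: lognormal diameters, tToS on the allometric
#' line with Gaussian noise, and SR either from its own regression line
#' ("independent") or as the exact cylinder complement x/2 - tToS
#' ("complement").
#'
#' @param n number of roots
#' @param params [AllometryParams-class] truth for tToS = k x + c
#' @param seed RNG seed
#' @param sigmaT,sigmaSR Gaussian noise sds, mm
#' @param srMode "independent" or "complement"
#' @param srSlope,srIntercept the independent SR line
#' @param meanlog,sdlog lognormal diameter marginal, mm
#' @return data.frame with columns diameter, tToS, SR
#' @export
generateAnatomySample <- function(n, params, seed,
                                  sigmaT = 0.02, sigmaSR = 0.004,
                                  srMode = c("complement", "independent"),
                                  srSlope = 0.068, srIntercept = 0.016,
                                  meanlog = log(0.35), sdlog = 0.45) {
  srMode <- match.arg(srMode)
  stopifnot(is(params, "AllometryParams"), n >= 3)
  set.seed(seed)
  x <- stats::rlnorm(n, meanlog, sdlog)
  tToS <- params@k * x + params@c + stats::rnorm(n, 0, sigmaT)
  SR <- if (srMode == "complement") x / 2 - tToS
        else srSlope * x + srIntercept + stats::rnorm(n, 0, sigmaSR)
  data.frame(diameter = x, tToS = tToS, SR = SR)
}

#' Generate the full synthetic trait dataset and tree
#'
#' Simulates a Yule tree over all species, evolves a latent diameter trait by
#' Brownian motion with the configured lambda, maps it into each growth
#' form's lognormal diameter marginal (rank-preserving, so phylogenetic
#' signal survives), builds anatomy from the allometry, derives the stele
#' proportion, mixes tissue properties into RTD and RN with noise, computes
#' SRL from the cylinder identity, and assigns the categorical structure
#' (mycorrhizal type, root sampling class, climatic zone, study). All truth
#' values are kept in the returned object for parameter-recovery tests.
#'
#' @param config a [GeneratorConfig-class]
#' @return a [RootTraitData-class]: trait table, tree, truth list
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  nW <- config@nWoody; nNW <- config@nNonWoody
  n <- nW + nNW
  sp <- sprintf("sp%04d", seq_len(n))
  tree <- simulateTree(n, seed = stageSeed(config@seed, "tree"))
  tree$tip.label <- sp      # relabel tips sp0001..spN in tip order
  set.seed(stageSeed(config@seed, "form"))
  form <- rep("non-woody", n)
  form[sample(n, nW)] <- "woody"
  z <- simulateBMTrait(tree, sigma2 = config@sigma2, rootValue = 0,
                       lambda = config@lambda,
                       seed = stageSeed(config@seed, "bm"))
  x <- numeric(n)
  for (g in c("woody", "non-woody")) {
    i <- which(form == g)
    if (!length(i)) next
    u <- stats::pnorm(scale(z[i])[, 1])
    u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
    ml <- if (g == "woody") config@meanlogWoody else config@meanlogNonWoody
    sl <- if (g == "woody") config@sdlogWoody else config@sdlogNonWoody
    x[i] <- stats::qlnorm(u, ml, sl)
  }
  set.seed(stageSeed(config@seed, "anatomy"))
  tToS <- SR <- numeric(n)
  for (g in c("woody", "non-woody")) {
    i <- which(form == g)
    if (!length(i)) next
    pp <- if (g == "woody") config@woodyParams else config@nonWoodyParams
    mode <- if (g == "woody") config@srModeWoody else config@srModeNonWoody
    tToS[i] <- pp@k * x[i] + pp@c + stats::rnorm(length(i), 0, config@sigmaT)
    SR[i] <- if (mode == "complement") x[i] / 2 - tToS[i]
             else config@srSlopeWoody * x[i] + config@srInterceptWoody +
                  stats::rnorm(length(i), 0, config@sigmaSR)
  }
  prsRaw <- (2 * SR / x)^2
  # PRS > 1 (stele wider than the root) is the config-level red flag; a noise
  # draw pushing a thin stele below zero is flagged as missing anatomy only
  outOfDomain <- 2 * SR > x
  invalid <- SR < 0 | outOfDomain
  if (mean(outOfDomain) > 0.01)
    stop(sprintf(paste0("%.1f%% of roots have out-of-domain stele geometry; ",
                        "reduce noise sds or move the allometry away from the boundary"),
                 100 * mean(outOfDomain)))
  prs <- ifelse(invalid, NA_real_, prsRaw)
  prsPhys <- pmin(pmax(prsRaw, 0), 1)   # latent physical fraction driving tissue
  mx <- config@mixture
  set.seed(stageSeed(config@seed, "traits"))
  rtd <- pmax(mixtureTrait(prsPhys, mx@rhoStele, mx@rhoOuter) +
                stats::rnorm(n, 0, config@sigmaRTD), 0.01)
  rn <- pmax(mixtureTrait(prsPhys, mx@nuStele, mx@nuOuter) +
               stats::rnorm(n, 0, config@sigmaRN), 0.5)
  srlv <- srl(x, rtd)
  set.seed(stageSeed(config@seed, "groups"))
  myc <- character(n)
  iW <- which(form == "woody"); iNW <- which(form == "non-woody")
  if (length(iW)) myc[iW] <- sample(names(config@mycWoody), length(iW),
                                    replace = TRUE, prob = config@mycWoody)
  if (length(iNW)) myc[iNW] <- sample(names(config@mycNonWoody), length(iNW),
                                      replace = TRUE, prob = config@mycNonWoody)
  sampling <- sample(c("first_order", "up_to_third"), n, replace = TRUE)
  zone <- sample(c("tropical", "subtropical", "temperate", "boreal",
                   "Mediterranean"), n, replace = TRUE)
  study <- sprintf("study%02d", sample(40, n, replace = TRUE))
  # anatomy masking: only the configured subset of species carries anatomy
  set.seed(stageSeed(config@seed, "mask"))
  keepW <- if (length(iW)) sample(iW, min(config@anatomyWoody, length(iW))) else integer(0)
  keepNW <- if (length(iNW)) sample(iNW, min(config@anatomyNonWoody, length(iNW))) else integer(0)
  hasAnatomy <- seq_len(n) %in% c(keepW, keepNW)
  tab <- data.frame(
    species = sp, diameter = x,
    tToS = ifelse(hasAnatomy, tToS, NA_real_),
    SR = ifelse(hasAnatomy, SR, NA_real_),
    PRS = ifelse(hasAnatomy, prs, NA_real_),
    RTD = rtd, RN = rn, SRL = srlv,
    growth_form = form, mycorrhiza = myc, root_sampling = sampling,
    data_source_class = NA_character_, climatic_zone = zone, study = study,
    stringsAsFactors = FALSE)
  if (config@duplicateFraction > 0) {
    set.seed(stageSeed(config@seed, "dup"))
    ndup <- round(config@duplicateFraction * n)
    if (ndup > 0) {
      di <- sample(n, ndup)
      dup <- tab[di, , drop = FALSE]
      dup$study <- sprintf("study%02d", sample(40, ndup, replace = TRUE))
      dup$RTD <- pmax(dup$RTD + stats::rnorm(ndup, 0, config@sigmaRTD), 0.01)
      dup$RN <- pmax(dup$RN + stats::rnorm(ndup, 0, config@sigmaRN), 0.5)
      dup$SRL <- srl(dup$diameter, dup$RTD)
      tab <- rbind(tab, dup)
      rownames(tab) <- NULL
    }
  }
  truth <- list(
    woodyParams = c(k = config@woodyParams@k, c = config@woodyParams@c),
    nonWoodyParams = c(k = config@nonWoodyParams@k, c = config@nonWoodyParams@c),
    srLineWoody = c(slope = config@srSlopeWoody, intercept = config@srInterceptWoody),
    srModes = c(woody = config@srModeWoody, nonwoody = config@srModeNonWoody),
    mixture = c(rhoStele = mx@rhoStele, rhoOuter = mx@rhoOuter,
                nuStele = mx@nuStele, nuOuter = mx@nuOuter),
    noise = c(sigmaT = config@sigmaT, sigmaSR = config@sigmaSR,
              sigmaRTD = config@sigmaRTD, sigmaRN = config@sigmaRN),
    lambda = config@lambda, sigma2 = config@sigma2,
    seed = config@seed, outOfDomainFraction = mean(outOfDomain),
    invalidAnatomyFraction = mean(invalid))
  new("RootTraitData", traits = tab, tree = tree, truth = truth)
}

#' Assign data-source classes with a thin-root sampling bias
#'
#' Emulates the literature split between studies reporting correlated trait
#' relationships and studies reporting uncorrelated traits. On the allometric
#' curve the steep, high-RTD region is the thin-diameter region, so sampling
#' bias is implemented as selection on the curve position: records in the
#' thinnest `thinQuantile` of the diameter distribution are the "thin,
#' high-RTD" pool, and the "correlated" class is drawn to contain them at
#' frequency `highFracCorrelated` (default 53%) versus `highFracUncorrelated`
#' (17%) in the "uncorrelated" class. Selecting on diameter rather than on
#' measured RTD keeps the within-class diameter-RTD relationship unbiased by
#' measurement noise (selecting on the noisy response would itself distort
#' the correlations being compared). Class sizes are solved from the pool
#' size so both target frequencies hold simultaneously; infeasible targets
#' are an error. The selection marker is kept in a `thin_high_rtd` column.
#'
#' @param table trait data.frame with a diameter column
#' @param highFracCorrelated,highFracUncorrelated target frequency of the
#'   thin/high-RTD pool in each class
#' @param seed RNG seed
#' @param thinQuantile diameter quantile defining the thin, steep-region pool
#' @return the table with `data_source_class` and `thin_high_rtd` filled in
#' @export
makeDataSourceClasses <- function(table, highFracCorrelated = 0.53,
                                  highFracUncorrelated = 0.17, seed = 1L,
                                  thinQuantile = 0.35) {
  if (!nrow(table)) stop("empty table")
  if (any(c(highFracCorrelated, highFracUncorrelated) < 0) ||
      any(c(highFracCorrelated, highFracUncorrelated) > 1))
    stop("fractions must lie in [0, 1]")
  N <- nrow(table)
  H <- round(thinQuantile * N)
  thin <- order(table$diameter)[seq_len(H)]
  marker <- seq_len(N) %in% thin
  set.seed(seed)
  if (abs(highFracCorrelated - highFracUncorrelated) < 1e-12) {
    table$data_source_class <-
      sample(rep(c("correlated", "uncorrelated"), length.out = N))
    table$thin_high_rtd <- marker
    return(table)
  }
  n1 <- round((H - highFracUncorrelated * N) /
                (highFracCorrelated - highFracUncorrelated))
  k1 <- round(highFracCorrelated * n1)
  if (n1 < 1 || n1 > N - 1 || k1 > H || k1 < 0 || (n1 - k1) > (N - H))
    stop(sprintf(paste0("infeasible targets: %d of %d records are in the ",
                        "thin/high-RTD pool; cannot realize frequencies ",
                        "%.2f vs %.2f"),
                 H, N, highFracCorrelated, highFracUncorrelated))
  c1 <- c(sample(which(marker), k1), sample(which(!marker), n1 - k1))
  cl <- rep("uncorrelated", N)
  cl[c1] <- "correlated"
  table$data_source_class <- cl
  table$thin_high_rtd <- marker
  table
}

#' Inject trait outliers
#'
#' Inflates RN for `nRN` random records and PRS for `nPRS` random records
#' (PRS capped at 1, then flagged), marking them in a truth column
#' `outlier_injected` so downstream exclusion rules can be scored.
#'
#' @param table trait data.frame
#' @param nRN,nPRS how many RN and PRS outliers to inject
#' @param magnitude multiplicative inflation factor
#' @param seed RNG seed
#' @return the table with inflated values and an `outlier_injected` column
#' @export
injectOutliers <- function(table, nRN = 1L, nPRS = 1L, magnitude = 4, seed = 1L) {
  if (nRN + nPRS > nrow(table)) stop("more outliers requested than records")
  table$outlier_injected <- FALSE
  if (nRN + nPRS == 0) return(table)
  set.seed(seed)
  if (nRN > 0) {
    cand <- which(is.finite(table$RN))
    i <- sample(cand, nRN)
    table$RN[i] <- table$RN[i] * magnitude
    table$outlier_injected[i] <- TRUE
  }
  if (nPRS > 0) {
    cand <- which(is.finite(table$PRS) & !table$outlier_injected)
    i <- sample(cand, nPRS)
    table$PRS[i] <- pmin(table$PRS[i] * magnitude, 1)
    table$outlier_injected[i] <- TRUE
  }
  table
}

#' Species-mean aggregation across studies
#'
#' When one species is measured in several studies the analysis uses the
#' mean trait value: one row per species, the mean of every numeric column
#' (NA-aware) and the first value of every categorical column.
#'
#' @param table trait data.frame with a `species` column
#' @return aggregated data.frame, one row per species
#' @export
aggregateSpeciesMeans <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  split_ <- split(seq_len(nrow(table)), table$species)
  rows <- lapply(split_, function(i) {
    r <- table[i[1], , drop = FALSE]
    for (cn in names(table)[num]) {
      v <- table[[cn]][i]
      r[[cn]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}
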