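#' Allometric nonlinear fits per group level
#'
#' Fits the allometry-form curve y = (a + b/x)^2 + d of a trait on root
#' diameter separately within each level of a grouping factor. Levels with
#' fewer than `minN` records are reported as skipped rather than fitted
#' (mirroring analyses restricted to the main mycorrhizal types).
#'
#' @param table trait data.frame
#' @param y name of the response column (e.g. "RTD", "RN")
#' @param grouping name of the factor column (e.g. "mycorrhiza")
#' @param x name of the diameter column
#' @param minN minimum records per fitted level
#' @return list with `fits` (named list of [NonlinearFit-class]), `skipped`
#'   (named integer vector of level sizes below `minN`), `r2` (named vector),
#'   and `n` per fitted level
#' @export
fitByGroup <- function(table, y, grouping, x = "diameter", minN = 10L) {
  for (cn in c(y, grouping, x))
    if (!cn %in% names(table)) stop("unknown column: ", cn)
  lev <- split(seq_len(nrow(table)), table[[grouping]])
  fits <- list(); skipped <- integer(0)
  for (g in names(lev)) {
    i <- lev[[g]]
    ok <- i[is.finite(table[[x]][i]) & is.finite(table[[y]][i])]
    if (length(ok) < minN) { skipped[g] <- length(ok); next }
    fits[[g]] <- nlsAllometricFit(table[[x]][ok], table[[y]][ok])
  }
  list(fits = fits,
       skipped = skipped,
       r2 = vapply(fits, function(f) f@r2, numeric(1)),
       n = vapply(fits, function(f) f@n, integer(1)))
}

#' ANCOVA interaction test: does a factor change the trait-diameter slope?
#'
#' F-test comparing the additive model y ~ x + factor against the
#' interaction model y ~ x * factor by OLS. (This deliberately replaces a
#' REML mixed model with study as a blocking structure: the interaction
#' p-value is the quantity used downstream, and the OLS ANCOVA reproduces it
#' without the mixed-model machinery; reports label the substitution.)
#'
#' @param table trait data.frame
#' @param y response column name
#' @param factor grouping column name (>= 2 levels, each n >= 3)
#' @param x diameter column name
#' @param covariates optional additional covariate column names entering both
#'   models additively (e.g. climatic zone)
#' @return list with `F`, `p`, `df`, `method`
#' @export
interactionTest <- function(table, y, factor, x = "diameter", covariates = NULL) {
  for (cn in c(y, factor, x, covariates))
    if (!cn %in% names(table)) stop("unknown column: ", cn)
  keep <- is.finite(table[[y]]) & is.finite(table[[x]]) & !is.na(table[[factor]])
  tab <- table[keep, , drop = FALSE]
  f <- base::factor(tab[[factor]])
  if (nlevels(f) < 2) stop("factor must have at least 2 levels")
  if (any(table(f) < 3)) stop("every factor level needs n >= 3")
  tab[[factor]] <- f
  covTerm <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  f0 <- stats::as.formula(sprintf("%s ~ %s + %s %s", y, x, factor, covTerm))
  f1 <- stats::as.formula(sprintf("%s ~ %s * %s %s", y, x, factor, covTerm))
  m0 <- stats::lm(f0, data = tab)
  m1 <- stats::lm(f1, data = tab)
  if (any(is.na(stats::coef(m1)))) stop("rank-deficient interaction design")
  a <- stats::anova(m0, m1)
  list(F = a$F[2], p = a$`Pr(>F)`[2], df = c(a$Df[2], a$Res.Df[2]),
       method = "OLS ANCOVA interaction F-test (substitutes the REML mixed model)")
}

#' Data-source split analysis and high-RTD frequency comparison
#'
#' For each data-source class ("correlated" vs "uncorrelated" studies) fits
#' the allometric curve of RTD and RN on diameter and counts the frequency
#' of high-RTD records above the threshold, reporting the R-squared ordering
#' and the frequency gap — the sampling-bias mechanism that reconciles
#' conflicting literature correlations.
#'
#' @param table trait data.frame with `data_source_class` filled in
#' @param threshold RTD threshold separating low- and high-RTD roots
#'   (default 0.236 g cm^-3, the cross-study mean)
#' @return list with `fits` (per class, per trait), `r2` matrix, `highRTDFreq`
#'   per class, `freqGap` (correlated minus uncorrelated, percentage points),
#'   and `r2Ordering` (is the correlated-class RTD fit better?)
#' @export
dataSourceAnalysis <- function(table, threshold = 0.236) {
  if (!"data_source_class" %in% names(table)) stop("data_source_class column missing")
  classes <- c("correlated", "uncorrelated")
  if (!all(classes %in% table$data_source_class))
    stop("both data-source classes must be present; missing: ",
         paste(setdiff(classes, unique(table$data_source_class)), collapse = ", "))
  fits <- list(); r2 <- matrix(NA_real_, 2, 2, dimnames = list(classes, c("RTD", "RN")))
  freq <- stats::setNames(numeric(2), classes)
  for (cl in classes) {
    i <- which(table$data_source_class == cl)
    for (tr in c("RTD", "RN")) {
      ok <- i[is.finite(table$diameter[i]) & is.finite(table[[tr]][i])]
      fit <- nlsAllometricFit(table$diameter[ok], table[[tr]][ok])
      fits[[cl]][[tr]] <- fit
      r2[cl, tr] <- fit@r2
    }
    freq[cl] <- mean(table$RTD[i] >= threshold, na.rm = TRUE)
  }
  list(fits = fits, r2 = r2, highRTDFreq = freq,
       freqGap = 100 * (freq["correlated"] - freq["uncorrelated"]),
       r2Ordering = r2["correlated", "RTD"] > r2["uncorrelated", "RTD"],
       threshold = threshold)
}

#' Exclude extreme RN / PRS records
#'
#' Implements the outlier rule used before the stele-proportion analyses:
#' records farther than 4 interquartile ranges from the median of RN or of
#' PRS are removed, and every exclusion is logged with its species and
#' reason. With clean data the rule excludes nothing.
#'
#' @param table trait data.frame with RN and PRS columns
#' @param iqrMultiple distance threshold in IQR units (default 4)
#' @return list with `table` (kept rows) and `log` (data.frame of excluded
#'   species and reasons; zero rows when nothing is excluded)
#' @export
excludeOutliers <- function(table, iqrMultiple = 4) {
  for (cn in c("RN", "PRS"))
    if (!cn %in% names(table)) stop("column missing: ", cn)
  flagFor <- function(v) {
    i <- which(is.finite(v))
    if (length(i) < 4) return(integer(0))
    md <- stats::median(v[i]); iq <- stats::IQR(v[i])
    if (iq == 0) return(integer(0))
    i[abs(v[i] - md) > iqrMultiple * iq]
  }
  rnBad <- flagFor(table$RN)
  prsBad <- flagFor(table$PRS)
  bad <- sort(unique(c(rnBad, prsBad)))
  log <- data.frame(
    species = table$species[bad],
    reason = vapply(bad, function(i) {
      r <- c(if (i %in% rnBad) "RN" else NULL, if (i %in% prsBad) "PRS" else NULL)
      paste(r, collapse = "+")
    }, character(1)),
    stringsAsFactors = FALSE)
  keep <- if (length(bad)) table[-bad, , drop = FALSE] else table
  stopifnot(nrow(keep) + nrow(log) == nrow(table))  # record conservation
  list(table = keep, log = log)
}

#' Flat-region attenuation of a convex decreasing relationship
#'
#' The sampling-bias mechanism in one number: restricting a monotone convex
#' decreasing trait-diameter relationship to its flat (thick-root) region
#' attenuates the absolute correlation relative to the steep (thin-root)
#' region. Compares |cor(x, y)| on x < median versus x >= median.
#'
#' @param x diameters
#' @param y trait values
#' @return list with `rSteep`, `rFlat` (signed correlations on the two
#'   halves) and `attenuated` (|rFlat| < |rSteep|)
#' @export
flatRegionAttenuation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  md <- stats::median(x)
  lo <- x < md
  rSteep <- stats::cor(x[lo], y[lo])
  rFlat <- stats::cor(x[!lo], y[!lo])
  list(rSteep = rSteep, rFlat = rFlat, attenuated = abs(rFlat) < abs(rSteep))
}
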