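#' @import methods
#' @importFrom stats coef
NULL

#' Parameters of the tToS-diameter allometry
#'
#' An absorptive root is modelled as a cylinder with a central stele of radius
#' SR wrapped in tissues outside the stele (epidermis, exodermis, cortex) of
#' thickness tToS, with tToS a linear function of root diameter x:
#' tToS = k*x + c. The slope k must lie in (0, 0.5): the stele-radius line
#' implied by the geometry, SR = (0.5 - k)*x - c, would otherwise have a
#' non-positive slope.
#'
#' @slot k dimensionless slope of tToS vs. diameter
#' @slot c intercept of tToS vs. diameter (mm); its sign controls whether the
#'   stele proportion rises or falls with diameter
#' @export
setClass("AllometryParams", representation(k = "numeric", c = "numeric"))

setValidity("AllometryParams", function(object) {
  if (length(object@k) != 1L || length(object@c) != 1L)
    return("k and c must be scalars")
  if (!is.finite(object@k) || !is.finite(object@c))
    return("k and c must be finite")
  if (object@k <= 0 || object@k >= 0.5)
    return("k must lie in (0, 0.5): the stele-radius slope 0.5 - k must be positive")
  TRUE
})

#' Construct allometry parameters
#'
#' @param k slope of the tToS-diameter line (dimensionless, in (0, 0.5))
#' @param c intercept of the tToS-diameter line (mm)
#' @return an [AllometryParams-class] object
#' @examples
#' woody <- AllometryParams(k = 0.43, c = -0.016)
#' @export
AllometryParams <- function(k, c) new("AllometryParams", k = k, c = c)

#' @describeIn AllometryParams-class slope accessor
#' @param object,x an `AllometryParams` object
#' @export
paramK <- function(object) object@k

#' @describeIn AllometryParams-class intercept accessor
#' @export
paramC <- function(object) object@c

setMethod("show", "AllometryParams", function(object) {
  cat("AllometryParams: tToS = k*x + c with k =", format(object@k),
      ", c =", format(object@c), "mm\n")
  cat("  implied stele-radius slope 0.5 - k =", format(0.5 - object@k), "\n")
})

#' Two-tissue property mixture
#'
#' Stele tissue is lignified vascular tissue: denser and poorer in nitrogen
#' than the tissues outside the stele. Whole-root tissue density (RTD) and
#' nitrogen concentration (RN) are modelled as cross-sectional area-weighted
#' mixtures of the two tissue classes.
#'
#' @slot rhoStele,rhoOuter tissue densities, g cm^-3 (stele > outer > 0)
#' @slot nuStele,nuOuter tissue N concentrations, mg g^-1 (outer > stele > 0)
#' @export
setClass("TissueMixture", representation(
  rhoStele = "numeric", rhoOuter = "numeric",
  nuStele = "numeric", nuOuter = "numeric"))

setValidity("TissueMixture", function(object) {
  v <- c(object@rhoStele, object@rhoOuter, object@nuStele, object@nuOuter)
  if (length(v) != 4L || any(!is.finite(v))) return("all four values must be finite scalars")
  if (!(object@rhoStele > object@rhoOuter && object@rhoOuter > 0))
    return("densities must satisfy rhoStele > rhoOuter > 0")
  if (!(object@nuOuter > object@nuStele && object@nuStele > 0))
    return("N concentrations must satisfy nuOuter > nuStele > 0")
  TRUE
})

#' Construct a tissue mixture
#'
#' Defaults place mixture RTD and RN inside the ranges typical of global
#' absorptive-root datasets; they parameterize the generator, they are not
#' estimates from data.
#'
#' @param rhoStele,rhoOuter stele and outer-tissue density, g cm^-3
#' @param nuStele,nuOuter stele and outer-tissue N concentration, mg g^-1
#' @return a [TissueMixture-class] object
#' @export
TissueMixture <- function(rhoStele = 0.45, rhoOuter = 0.12,
                          nuStele = 6, nuOuter = 14) {
  new("TissueMixture", rhoStele = rhoStele, rhoOuter = rhoOuter,
      nuStele = nuStele, nuOuter = nuOuter)
}

setMethod("show", "TissueMixture", function(object) {
  cat("TissueMixture:\n")
  cat("  density   (g cm^-3): stele", format(object@rhoStele),
      "| outer", format(object@rhoOuter), "\n")
  cat("  nitrogen  (mg g^-1): stele", format(object@nuStele),
      "| outer", format(object@nuOuter), "\n")
})

#' Ordinary least squares fit
#'
#' @slot slope,intercept coefficient estimates
#' @slot slopeSE,interceptSE standard errors
#' @slot r2 coefficient of determination
#' @slot pSlope two-sided t-test p-value for the slope
#' @slot n number of observations
#' @export
setClass("LinearFit", representation(
  slope = "numeric", intercept = "numeric",
  slopeSE = "numeric", interceptSE = "numeric",
  r2 = "numeric", pSlope = "numeric", n = "integer"))

setMethod("show", "LinearFit", function(object) {
  cat(sprintf("LinearFit (n = %d): y = %.6g x + %.6g\n",
              object@n, object@slope, object@intercept))
  cat(sprintf("  slope SE %.3g, p = %.3g, R^2 = %.4f\n",
              object@slopeSE, object@pSlope, object@r2))
})

#' @describeIn LinearFit-class named coefficient vector
#' @param object a fit object
#' @export
setMethod("coef", "LinearFit", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))

#' Allometry-form nonlinear fit y = (a + b/x)^2 + d
#'
#' @slot a,b,d curve parameters (a constrained >= 0 for identifiability; the
#'   sign of b carries the biological direction of the curve)
#' @slot r2 1 - SSres/SStot (can be negative for a fit worse than the mean)
#' @slot nIterations iterations used by the best start
#' @slot converged whether the relative SS change fell below tolerance
#' @slot residualSS residual sum of squares
#' @slot n number of observations
#' @slot degenerate TRUE when the response had no usable curvature (e.g.
#'   constant y), in which case d = mean(y) and a, b are not identified
#' @export
setClass("NonlinearFit", representation(
  a = "numeric", b = "numeric", d = "numeric", r2 = "numeric",
  nIterations = "integer", converged = "logical",
  residualSS = "numeric", n = "integer", degenerate = "logical"))

setMethod("show", "NonlinearFit", function(object) {
  cat(sprintf("NonlinearFit (n = %d): y = (%.6g + %.6g/x)^2 + %.6g\n",
              object@n, object@a, object@b, object@d))
  cat(sprintf("  R^2 = %.4f, converged = %s (%d iterations)%s\n",
              object@r2, object@converged, object@nIterations,
              if (object@degenerate) ", DEGENERATE" else ""))
})

#' @describeIn NonlinearFit-class named coefficient vector
#' @export
setMethod("coef", "NonlinearFit", function(object, ...)
  c(a = object@a, b = object@b, d = object@d))

#' Standardized major axis fit
#'
#' @slot slope SMA slope, sign(cor(x, y)) * sd(y)/sd(x)
#' @slot intercept mean(y) - slope * mean(x)
#' @slot slopeCI 95% confidence interval for the slope
#' @slot n number of observations
#' @export
setClass("SMAFit", representation(
  slope = "numeric", intercept = "numeric",
  slopeCI = "numeric", n = "integer"))

setMethod("show", "SMAFit", function(object) {
  cat(sprintf("SMAFit (n = %d): slope %.6g [%.6g, %.6g], intercept %.6g\n",
              object@n, object@slope, object@slopeCI[1], object@slopeCI[2],
              object@intercept))
})

#' @describeIn SMAFit-class named coefficient vector
#' @export
setMethod("coef", "SMAFit", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))

#' Phylogenetic signal result
#'
#' @slot statistic "K" (Blomberg) or "lambda" (Pagel)
#' @slot estimate the signal estimate (K >= 0; lambda in \[0, 1\])
#' @slot pValue permutation p (K) or likelihood-ratio p (lambda)
#' @slot nTips number of tips used
#' @slot detail method detail: permutation count or LR degrees of freedom
#' @export
setClass("SignalResult", representation(
  statistic = "character", estimate = "numeric",
  pValue = "numeric", nTips = "integer", detail = "character"))

setMethod("show", "SignalResult", function(object) {
  cat(sprintf("SignalResult: %s = %.4g (n = %d tips), p = %.4g [%s]\n",
              object@statistic, object@estimate, object@nTips,
              object@pValue, object@detail))
})

#' @describeIn SignalResult-class estimate accessor
#' @param object a `SignalResult`
#' @export
signalEstimate <- function(object) object@estimate

#' @describeIn SignalResult-class p-value accessor
#' @export
signalP <- function(object) object@pValue

#' Phylogenetic independent contrasts
#'
#' @slot contrasts standardized contrasts, one per internal node of a binary
#'   tree (n_tips - 1 values), named by node number
#' @slot expectedSD the square-root branch-length sums each raw contrast was
#'   divided by
#' @slot nodes internal node numbers in the order contrasts were computed
#' @export
setClass("PICSet", representation(
  contrasts = "numeric", expectedSD = "numeric", nodes = "integer"))

setMethod("show", "PICSet", function(object) {
  cat(sprintf("PICSet: %d contrasts\n", length(object@contrasts)))
  if (length(object@contrasts) > 0)
    print(utils::head(object@contrasts, 5))
})

#' @describeIn PICSet-class contrasts accessor
#' @param object a `PICSet`
#' @export
picValues <- function(object) object@contrasts

#' A species trait table paired with a phylogeny
#'
#' Container for a species-level absorptive-root trait table, an optional
#' phylogeny whose tips match the species column, and (for generated data)
#' the truth parameters used by the generator.
#'
#' @slot traits data.frame with one row per species-by-study record
#' @slot tree an ape `phylo` object or NULL
#' @slot truth list of generator truth values (empty for user data)
#' @export
setClass("RootTraitData", representation(
  traits = "data.frame", tree = "ANY", truth = "list"))

setValidity("RootTraitData", function(object) {
  if (!"species" %in% names(object@traits))
    return("traits must have a 'species' column")
  if (!is.null(object@tree) && !inherits(object@tree, "phylo"))
    return("tree must be an ape 'phylo' or NULL")
  TRUE
})

#' @describeIn RootTraitData-class trait table accessor
#' @param object a `RootTraitData`
#' @export
traits <- function(object) object@traits

#' @describeIn RootTraitData-class phylogeny accessor (NULL if absent)
#' @export
phylogeny <- function(object) object@tree

#' @describeIn RootTraitData-class generator truth accessor
#' @export
generatorTruth <- function(object) object@truth

setMethod("show", "RootTraitData", function(object) {
  cat(sprintf("RootTraitData: %d records, %d species%s\n",
              nrow(object@traits), length(unique(object@traits$species)),
              if (is.null(object@tree)) ", no tree"
              else sprintf(", tree with %d tips", length(object@tree$tip.label))))
  if ("growth_form" %in% names(object@traits))
    print(table(object@traits$growth_form))
})
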