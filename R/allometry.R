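#' Stele proportion from the tToS-diameter allometry
#'
#' With tToS = k*x + c, the stele radius is SR = x/2 - tToS and the proportion
#' of root cross-sectional area occupied by the stele is
#' PRS = (2*SR/x)^2 = (1 - 2k - 2c/x)^2. The inner term 1 - 2k - 2c/x must lie
#' in \[0, 1\] for the geometry to be realizable (stele radius between 0 and
#' x/2); diameters where it does not are returned as NA and flagged, never
#' clipped, so out-of-domain points cannot fabricate curvature downstream.
#'
#' @param x root diameter, mm (positive)
#' @param params an [AllometryParams-class] object
#' @return numeric vector of PRS fractions, NA where the geometry is
#'   unrealizable, with a logical attribute `outOfDomain` marking those points
#' @examples
#' woody <- AllometryParams(0.43, -0.016)
#' prsFromDiameter(0.3, woody)  # 0.060846...
#' @export
prsFromDiameter <- function(x, params) {
  stopifnot(is(params, "AllometryParams"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("diameter x must be positive and finite")
  inner <- 1 - 2 * params@k - 2 * params@c / x
  bad <- inner < 0 | inner > 1
  prs <- inner^2
  prs[bad] <- NA_real_
  attr(prs, "outOfDomain") <- bad
  prs
}

#' Stele proportion from measured anatomy
#'
#' Geometric restatement: the stele occupies (2*SR/x)^2 of the cross-section.
#'
#' @param sr stele radius, mm
#' @param x root diameter, mm
#' @return PRS fraction in \[0, 1\]
#' @export
prsFromAnatomy <- function(sr, x) {
  if (!is.numeric(sr) || !is.numeric(x) || any(!is.finite(sr)) || any(!is.finite(x)))
    stop("sr and x must be finite")
  if (any(x <= 0)) stop("diameter x must be positive")
  if (any(sr < 0)) stop("geometry error: stele radius must be non-negative")
  if (any(2 * sr > x + 1e-12)) stop("geometry error: stele diameter 2*SR exceeds root diameter")
  (2 * sr / x)^2
}

#' Area-weighted two-tissue mixture
#'
#' A whole-root property (density or N concentration) as the cross-sectional
#' area-weighted average of a stele value and an outer-tissue value. With a
#' denser, N-poor stele this makes RTD increase and RN decrease in PRS.
#'
#' @param prs stele proportion in \[0, 1\]
#' @param vStele property value of stele tissue
#' @param vOuter property value of the tissues outside the stele
#' @return mixture value, same units as the inputs
#' @export
mixtureTrait <- function(prs, vStele, vOuter) {
  if (any(!is.finite(prs)) || any(prs < 0) || any(prs > 1))
    stop("prs must lie in [0, 1]")
  prs * vStele + (1 - prs) * vOuter
}

#' Specific root length of a cylindrical root
#'
#' SRL = 4 / (pi * RTD * x^2) for a cylinder. Diameter is given in mm (the
#' data-model unit) and converted to cm internally to match RTD in g cm^-3;
#' output is m g^-1 by default or cm g^-1.
#'
#' @param x root diameter (see `diameterUnit`)
#' @param rtd root tissue density, g cm^-3
#' @param diameterUnit "mm" (default) or "cm"
#' @param outputUnit "m" (default, m g^-1) or "cm" (cm g^-1)
#' @return specific root length
#' @examples
#' srl(0.5, 0.2)  # 25.46 m g^-1
#' @export
srl <- function(x, rtd, diameterUnit = c("mm", "cm"), outputUnit = c("m", "cm")) {
  diameterUnit <- match.arg(diameterUnit)
  outputUnit <- match.arg(outputUnit)
  if (any(!is.finite(x)) || any(x <= 0)) stop("diameter must be positive")
  if (any(!is.finite(rtd)) || any(rtd <= 0)) stop("RTD must be positive")
  xcm <- if (diameterUnit == "mm") x / 10 else x
  out <- 4 / (pi * rtd * xcm^2)            # cm g^-1
  if (outputUnit == "m") out / 100 else out
}

#' Dry mass per unit length of a cylindrical root
#'
#' m(x) = pi * (x/2)^2 * RTD for a cylinder of diameter x; diameter in mm is
#' converted to cm so the result is g cm^-1.
#'
#' @param x root diameter, mm
#' @param rtd root tissue density, g cm^-3 (zero allowed: zero mass)
#' @return dry mass per length, g cm^-1
#' @export
dryMassPerLength <- function(x, rtd) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("diameter must be positive")
  if (any(!is.finite(rtd)) || any(rtd < 0)) stop("RTD must be non-negative")
  xcm <- x / 10
  pi * (xcm / 2)^2 * rtd
}

#' Monotonicity of dry mass along the diameter axis
#'
#' Evaluates m(x) = pi*(x/2)^2 * RTD(x) on a diameter grid, where RTD(x) is
#' the two-tissue mixture driven by the allometric stele proportion. Even
#' though RTD itself falls with diameter (for c < 0), the x^2 volume term can
#' dominate so that dry mass rises monotonically; this reports whether it
#' does, rather than asserting it.
#'
#' @param params an [AllometryParams-class] object
#' @param mixture a [TissueMixture-class] object
#' @param xGrid strictly increasing diameters, mm, inside the valid PRS domain
#' @return list with `increasing` (strictly increasing over the whole grid),
#'   `minSlope` (minimum finite-difference slope, g cm^-1 per mm), `mass`
#'   (the evaluated masses) and `outOfDomain` (indices of flagged grid points)
#' @export
dryMassMonotonicity <- function(params, mixture, xGrid) {
  stopifnot(is(params, "AllometryParams"), is(mixture, "TissueMixture"))
  if (length(xGrid) < 2 || any(diff(xGrid) <= 0))
    stop("xGrid must be strictly increasing with at least two points")
  prs <- prsFromDiameter(xGrid, params)
  bad <- which(attr(prs, "outOfDomain"))
  ok <- setdiff(seq_along(xGrid), bad)
  rtd <- rep(NA_real_, length(xGrid))
  rtd[ok] <- mixtureTrait(prs[ok], mixture@rhoStele, mixture@rhoOuter)
  mass <- dryMassPerLength(xGrid, ifelse(is.na(rtd), 0, rtd))
  mass[is.na(rtd)] <- NA_real_
  slopes <- diff(mass[ok]) / diff(xGrid[ok])
  list(increasing = length(bad) == 0 && all(slopes > 0),
       minSlope = if (length(slopes)) min(slopes) else NA_real_,
       mass = mass,
       outOfDomain = bad)
}
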