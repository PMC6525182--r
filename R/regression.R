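#' Ordinary least squares of y on x (closed form)
#'
#' Minimizes squared residuals with the normal-equation closed form; slope
#' p-value is a two-sided t-test on n - 2 degrees of freedom.
#'
#' @param x,y finite numeric vectors, length >= 3, sd(x) > 0
#' @return a [LinearFit-class] object
#' @export
olsFit <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate x: zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  s2 <- rss / (n - 2)
  slopeSE <- sqrt(s2 / sxx)
  interceptSE <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  p <- if (slopeSE > 0) 2 * stats::pt(-abs(slope / slopeSE), df = n - 2) else 0
  new("LinearFit", slope = slope, intercept = intercept,
      slopeSE = slopeSE, interceptSE = interceptSE,
      r2 = max(0, r2), pSlope = p, n = as.integer(n))
}

# One Levenberg-Marquardt run for y = (a + b/x)^2 + d with analytic Jacobian.
# Returns list(theta, rss, iter, converged).
.lmRun <- function(x, y, theta, maxIter = 500L, tol = 1e-10) {
  resid <- function(th) y - ((th[1] + th[2] / x)^2 + th[3])
  rss <- function(th) sum(resid(th)^2)
  lambda <- 1e-3
  r <- resid(theta)
  ss <- sum(r^2)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    u <- theta[1] + theta[2] / x
    # d resid / d theta = -(d model / d theta)
    J <- cbind(2 * u, 2 * u / x, 1)
    g <- crossprod(J, r)        # = -gradient/2 of RSS wrt theta (sign folded below)
    JtJ <- crossprod(J)
    step <- NULL
    repeat {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12, 3)
      step <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(step)) break
      lambda <- lambda * 10
      if (lambda > 1e12) return(list(theta = theta, rss = ss, iter = iter, converged = FALSE))
    }
    thNew <- theta + as.numeric(step)
    if (thNew[1] < 0) { thNew[1] <- -thNew[1]; thNew[2] <- -thNew[2] }  # (a,b) ~ (-a,-b)
    ssNew <- rss(thNew)
    if (is.finite(ssNew) && ssNew <= ss) {
      relChange <- (ss - ssNew) / max(ss, .Machine$double.eps)
      theta <- thNew
      r <- resid(theta)
      ss <- ssNew
      lambda <- max(lambda / 10, 1e-12)
      if (relChange < tol) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  list(theta = theta, rss = ss, iter = iter, converged = converged)
}

#' Allometry-form nonlinear least squares y = (a + b/x)^2 + d
#'
#' Fits the squared-hyperbola curve the stele/cortex geometry predicts for
#' trait-diameter relationships, by Levenberg-Marquardt least squares with an
#' analytic Jacobian and a multi-start grid over the sign and scale of b
#' (8 starts). The reflection symmetry (a, b) -> (-a, -b) leaves the curve
#' unchanged, so a is constrained >= 0 and the sign of b carries the
#' direction of the relationship. In `anchored` mode a and b are fixed at the
#' values implied by supplied allometry parameters (a = 1 - 2k, b = -2c up to
#' the trait mixture scale is not assumed; the anchor fixes the shape via the
#' PRS curve) and only the affine trait map is estimated by OLS on the PRS
#' regressor.
#'
#' @param x positive diameters
#' @param y trait values
#' @param mode "free" (default): a, b, d all estimated; "anchored": shape
#'   taken from `params` and the trait scale fitted linearly on the PRS curve
#' @param params an [AllometryParams-class] object, required for anchored mode
#' @param maxIter,tol Levenberg-Marquardt iteration cap and relative
#'   sum-of-squares convergence tolerance
#' @return a [NonlinearFit-class] object; in anchored mode a and b are the
#'   anchored shape values rescaled into the trait units
#' @export
nlsAllometricFit <- function(x, y, mode = c("free", "anchored"), params = NULL,
                             maxIter = 500L, tol = 1e-10) {
  mode <- match.arg(mode)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10) stop("need at least 10 finite observations")
  if (any(x <= 0)) stop("diameters must be positive")
  tss <- sum((y - mean(y))^2)

  if (mode == "anchored") {
    stopifnot(is(params, "AllometryParams"))
    prs <- prsFromDiameter(x, params)
    ok <- !attr(prs, "outOfDomain")
    if (sum(ok) < 10) stop("anchored mode: too few in-domain points")
    fit <- olsFit(prs[ok], y[ok])        # y = alpha * PRS + beta
    alpha <- fit@slope; beta <- fit@intercept
    # y = alpha*(A + B/x)^2 + beta with A = 1-2k, B = -2c
    s <- sqrt(abs(alpha))
    a <- s * (1 - 2 * params@k); b <- s * (-2 * params@c) * sign(alpha)
    if (a < 0) { a <- -a; b <- -b }
    res <- y[ok] - (alpha * prs[ok] + beta)
    rss <- sum(res^2)
    tssOk <- sum((y[ok] - mean(y[ok]))^2)
    return(new("NonlinearFit", a = a, b = b, d = beta,
               r2 = if (tssOk > 0) 1 - rss / tssOk else 0,
               nIterations = 0L, converged = TRUE, residualSS = rss,
               n = as.integer(sum(ok)), degenerate = FALSE))
  }

  if (tss == 0) {
    return(new("NonlinearFit", a = 0, b = 0, d = mean(y), r2 = 0,
               nIterations = 0L, converged = TRUE, residualSS = 0,
               n = as.integer(n), degenerate = TRUE))
  }

  # multi-start grid: sign and scale of b, a from the response spread
  aScale <- sqrt(max(diff(range(y)), stats::sd(y), 1e-8))
  bScales <- stats::median(x) * aScale * c(0.1, 1)
  starts <- list()
  for (sgn in c(-1, 1)) for (bs in bScales) for (as in c(0.5, 1.5) * aScale)
    starts[[length(starts) + 1L]] <- c(as, sgn * bs, min(y))
  best <- NULL
  for (th0 in starts) {
    run <- .lmRun(x, y, th0, maxIter = maxIter, tol = tol)
    if (is.null(best) || (run$converged && !best$converged) ||
        (run$converged == best$converged && run$rss < best$rss))
      best <- run
  }
  if (!best$converged)
    return(new("NonlinearFit", a = best$theta[1], b = best$theta[2],
               d = best$theta[3], r2 = 1 - best$rss / tss,
               nIterations = as.integer(best$iter), converged = FALSE,
               residualSS = best$rss, n = as.integer(n), degenerate = FALSE))
  new("NonlinearFit", a = best$theta[1], b = best$theta[2], d = best$theta[3],
      r2 = 1 - best$rss / tss, nIterations = as.integer(best$iter),
      converged = TRUE, residualSS = best$rss, n = as.integer(n),
      degenerate = FALSE)
}

#' Standardized major axis fit
#'
#' Symmetric line fit: slope = sign(cor(x, y)) * sd(y)/sd(x), intercept
#' through the means. The 95% slope CI is the standard SMA likelihood
#' interval slope * (sqrt(B + 1) +/- sqrt(B)) with
#' B = F(0.95; 1, n-2) * (1 - r^2)/(n - 2).
#'
#' @param x,y numeric vectors with positive variance, n >= 3
#' @return an [SMAFit-class] object
#' @export
smaFit <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stop("need equal-length x, y with n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  slope <- sign(if (r == 0) 1 else r) * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qf(0.95, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  new("SMAFit", slope = slope, intercept = intercept,
      slopeCI = sort(ci), n = as.integer(n))
}

# -sum over groups of (n_i - 2.5) * log(1 - cor(resid, fit)^2) at common slope b
.smaLRStat <- function(groups, b) {
  s <- 0
  for (g in groups) {
    u <- g$y - b * g$x
    v <- g$y + b * g$x
    r <- suppressWarnings(stats::cor(u, v))
    if (!is.finite(r)) r <- 0
    r2 <- min(r^2, 1 - 1e-12)
    s <- s - (length(g$x) - 2.5) * log(1 - r2)
  }
  s
}

#' Likelihood-ratio test of a common SMA slope across groups
#'
#' Tests whether several samples share one standardized-major-axis slope.
#' The common slope is the value minimizing the Warton-Weber modified
#' likelihood-ratio statistic
#' -sum_i (n_i - 2.5) log(1 - r_i(b)^2), where r_i(b) is the correlation
#' between SMA residual (y - b x) and fitted-axis (y + b x) scores in group
#' i; at each group's own SMA slope that correlation is zero. The minimized
#' statistic is compared to chi-square with (groups - 1) df. When any group
#' has n < 20 a permutation reference (group labels shuffled) replaces the
#' chi-square, with at least 999 permutations.
#'
#' @param groups list of length >= 2; each element a list or data.frame with
#'   numeric `x` and `y`, each of length >= 3 and positive variance
#' @param nPerm permutations for the small-sample fallback (>= 999)
#' @param seed RNG seed for the permutation fallback
#' @return list with `statistic`, `p`, `commonSlope`, `df`, `method`
#' @export
smaCommonSlopeTest <- function(groups, nPerm = 999L, seed = 1L) {
  if (length(groups) < 2) stop("need at least 2 groups")
  groups <- lapply(groups, function(g) list(x = as.numeric(g$x), y = as.numeric(g$y)))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g$x) < 3 || length(g$x) != length(g$y))
      stop(sprintf("group %d is degenerate: need matched x, y with n >= 3", i))
    if (stats::sd(g$x) == 0 || stats::sd(g$y) == 0)
      stop(sprintf("group %d is degenerate: zero variance", i))
  }
  slopes <- vapply(groups, function(g) smaFit(g$x, g$y)@slope, numeric(1))
  if (max(abs(diff(sort(slopes)))) < 1e-14 && length(unique(sign(slopes))) == 1) {
    # identical slopes: optimum is that slope, statistic ~ 0
    b <- slopes[1]
    stat <- .smaLRStat(groups, b)
  } else {
    opt <- stats::optimize(function(b) .smaLRStat(groups, b),
                           interval = range(slopes) + c(-1, 1) * max(abs(slopes), 1))
    b <- opt$minimum
    stat <- opt$objective
  }
  df <- length(groups) - 1L
  ns <- vapply(groups, function(g) length(g$x), integer(1))
  if (any(ns < 20)) {
    set.seed(seed)
    nPerm <- max(nPerm, 999L)
    allx <- unlist(lapply(groups, `[[`, "x"))
    ally <- unlist(lapply(groups, `[[`, "y"))
    lab <- rep(seq_along(groups), ns)
    exceed <- 0L
    for (p in seq_len(nPerm)) {
      sh <- sample(lab)
      pg <- lapply(seq_along(groups), function(i)
        list(x = allx[sh == i], y = ally[sh == i]))
      ok <- all(vapply(pg, function(g) length(g$x) >= 3 &&
                         stats::sd(g$x) > 0 && stats::sd(g$y) > 0, logical(1)))
      if (!ok) { exceed <- exceed + 1L; next }
      sl <- vapply(pg, function(g) smaFit(g$x, g$y)@slope, numeric(1))
      o <- stats::optimize(function(b) .smaLRStat(pg, b),
                           interval = range(sl) + c(-1, 1) * max(abs(sl), 1))
      if (o$objective >= stat) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (nPerm + 1)
    method <- sprintf("permutation (%d)", nPerm)
  } else {
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    method <- "chi-square LR"
  }
  list(statistic = stat, p = p, commonSlope = b, df = df, method = method)
}

#' Fit the tToS-diameter allometry and package it as model parameters
#'
#' OLS of tToS on diameter; the fitted slope and intercept become the (k, c)
#' parameters that drive PRS prediction downstream.
#'
#' @param x root diameters, mm
#' @param tToS thickness of tissues outside the stele, mm
#' @return list with `params` ([AllometryParams-class]) and `fit`
#'   ([LinearFit-class])
#' @export
fitAnatomyAllometry <- function(x, tToS) {
  fit <- olsFit(x, tToS)
  list(params = AllometryParams(k = fit@slope, c = fit@intercept), fit = fit)
}

#' Serialize a fit object to a plain list for JSON reports
#'
#' @param fit a [LinearFit-class], [NonlinearFit-class] or [SMAFit-class]
#' @return named list: model, params, se (where defined), r2, n, p, converged
#' @export
fitReport <- function(fit) {
  if (is(fit, "LinearFit"))
    return(list(model = "linear", params = as.list(coef(fit)),
                se = list(slope = fit@slopeSE, intercept = fit@interceptSE),
                r2 = fit@r2, n = fit@n, p = fit@pSlope, converged = TRUE))
  if (is(fit, "NonlinearFit"))
    return(list(model = "allometric_nls", params = as.list(coef(fit)),
                se = NULL, r2 = fit@r2, n = fit@n, p = NULL,
                converged = fit@converged && !fit@degenerate))
  if (is(fit, "SMAFit"))
    return(list(model = "sma", params = as.list(coef(fit)),
                se = NULL, r2 = NULL, n = fit@n, p = NULL, converged = TRUE,
                slope_ci = as.list(fit@slopeCI)))
  stop("unsupported fit object")
}
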