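#' @importFrom ape read.tree write.tree rphylo reorder.phylo is.binary
NULL

# species-name reconciliation: trim, collapse whitespace, underscores->spaces
.normalizeSpecies <- function(s) {
  s <- gsub("_", " ", trimws(as.character(s)))
  gsub("[[:space:]]+", " ", s)
}

# Match a named trait vector to tree tips; returns values ordered as
# tree$tip.label. Unmatched tips are an error listing the species.
.matchTraitToTips <- function(tree, trait, what = "trait") {
  if (is.null(names(trait))) stop(what, " must be a named vector (species names)")
  key <- .normalizeSpecies(names(trait))
  tips <- .normalizeSpecies(tree$tip.label)
  idx <- match(tips, key)
  if (anyNA(idx)) {
    miss <- tree$tip.label[is.na(idx)]
    stop(what, " missing for species: ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else "")
  }
  out <- as.numeric(trait)[idx]
  names(out) <- tree$tip.label
  out
}

#' Read a Newick tree
#'
#' Parses a Newick string or file into an ape `phylo`, requiring branch
#' lengths on every edge (the comparative statistics need them).
#'
#' @param source a Newick string or path to a file containing one
#' @return an ape `phylo` object
#' @export
readNewick <- function(source) {
  txt <- if (length(source) == 1 && !grepl("[(;]", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "") else source
  bal <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                       ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (any(bal < 0) || utils::tail(bal, 1) != 0)
    stop("malformed Newick: unbalanced parenthesis near position ",
         which(bal < 0)[1] %||% length(bal))
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e)
    stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  if (is.null(tree$edge.length))
    stop("missing branch lengths on every edge")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    child <- tree$edge[bad, 2]
    lab <- if (child <= length(tree$tip.label)) tree$tip.label[child]
           else paste0("internal node ", child)
    stop("missing branch length on the edge above ", lab)
  }
  tree
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write a tree as Newick text
#'
#' @param tree an ape `phylo`
#' @param file optional path; if NULL the Newick string is returned
#' @return the Newick string (invisibly when written to file)
#' @export
writeNewick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Resolve polytomies into an arbitrary binary tree
#'
#' Each multifurcation is broken into a random sequence of bifurcations with
#' zero-length inserted edges, so every tip-to-root path length and the total
#' tree length are unchanged. The resolution order is drawn from the seeded
#' RNG, so a given seed gives one deterministic binary tree.
#'
#' @param tree a rooted ape `phylo` with branch lengths
#' @param seed integer RNG seed
#' @return a binary ape `phylo`
#' @export
resolvePolytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.12g", x)
  build <- function(node, len) {
    if (node <= ntip)
      return(paste0(tree$tip.label[node], ":", fmt(len)))
    kid <- children[[as.character(node)]]
    parts <- vapply(kid, function(e)
      build(tree$edge[e, 2], tree$edge.length[e]), character(1))
    while (length(parts) > 2) {
      pick <- sample(length(parts), 2)
      merged <- paste0("(", parts[pick[1]], ",", parts[pick[2]], "):0")
      parts <- c(parts[-pick], merged)
    }
    paste0("(", paste(parts, collapse = ","), "):", fmt(len))
  }
  root <- ntip + 1L
  kid <- children[[as.character(root)]]
  parts <- vapply(kid, function(e)
    build(tree$edge[e, 2], tree$edge.length[e]), character(1))
  while (length(parts) > 2) {
    pick <- sample(length(parts), 2)
    merged <- paste0("(", parts[pick[1]], ",", parts[pick[2]], "):0")
    parts <- c(parts[-pick], merged)
  }
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Simulate a pure-birth (Yule) tree
#'
#' Stands in for a real phylogeny in synthetic runs: a Yule tree with
#' speciation rate 1, conditioned on the tip count, seeded for
#' reproducibility.
#'
#' @param nTips number of tips (>= 2)
#' @param seed integer RNG seed
#' @return an ape `phylo` with tips "t1".."tn"
#' @export
simulateTree <- function(nTips, seed = 1L) {
  if (nTips < 2) stop("nTips must be >= 2")
  set.seed(seed)
  ape::rphylo(nTips, birth = 1, death = 0)
}

#' Phylogenetic variance-covariance matrix
#'
#' C\[i, j\] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds tip depths. This is the trait covariance (up to sigma^2)
#' under Brownian motion on the tree.
#'
#' @param tree a rooted ape `phylo` with non-negative branch lengths
#' @param minEdge floor applied to branch lengths before accumulation; the
#'   comparative statistics use 1e-8 so zero-length edges from polytomy
#'   resolution cannot make C singular
#' @return a symmetric positive semi-definite matrix with tip-label dimnames
#' @export
vcvMatrix <- function(tree, minEdge = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  el <- pmax(tree$edge.length, minEdge)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- numeric(ntip + nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  elPre <- pmax(pre$edge.length, minEdge)
  for (e in seq_len(nrow(pre$edge)))
    depth[pre$edge[e, 2]] <- depth[pre$edge[e, 1]] + elPre[e]
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  diag(C) <- depth[seq_len(ntip)]
  po <- ape::reorder.phylo(tree, "postorder")
  tipsUnder <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tipsUnder[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    prev <- tipsUnder[[p]]
    fresh <- tipsUnder[[ch]]
    if (length(prev)) {
      C[prev, fresh] <- depth[p]
      C[fresh, prev] <- depth[p]
    }
    tipsUnder[[p]] <- c(prev, fresh)
  }
  C
}

# Pagel lambda transform: off-diagonal shrunk by lambda, diagonal untouched
.lambdaVCV <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

#' Simulate one Brownian-motion trait on a tree
#'
#' Draws a single multivariate normal sample with covariance
#' sigma2 * C(lambda), where C(lambda) multiplies off-diagonal entries of the
#' Brownian covariance by lambda (diagonal untouched), centred on the root
#' value.
#'
#' @param tree ape `phylo`
#' @param sigma2 Brownian rate (> 0; 0 allowed and gives constant traits)
#' @param rootValue trait value at the root
#' @param lambda signal strength in \[0, 1\]
#' @param seed integer RNG seed
#' @return named numeric vector over the tips
#' @export
simulateBMTrait <- function(tree, sigma2 = 1, rootValue = 0, lambda = 1, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    out <- rep(rootValue, n); names(out) <- tree$tip.label
    return(out)
  }
  C <- .lambdaVCV(vcvMatrix(tree, minEdge = 1e-8), lambda)
  L <- tryCatch(chol(sigma2 * C), error = function(e)
    stop("transformed covariance is not positive definite"))
  set.seed(seed)
  out <- rootValue + as.numeric(t(L) %*% stats::rnorm(n))
  names(out) <- tree$tip.label
  out
}

#' Phylogenetic independent contrasts (Felsenstein pruning)
#'
#' At each internal node of a binary tree the standardized contrast is
#' (v_i - v_j)/sqrt(b_i + b_j) between the two daughter values, the node's
#' ancestral value is the branch-length-weighted average of the daughters,
#' and the node's parent branch is lengthened by b_i*b_j/(b_i + b_j).
#'
#' @param tree a binary rooted ape `phylo` with branch lengths
#' @param trait named numeric vector; names matched to tip labels after
#'   underscore/space normalization
#' @return a [PICSet-class]
#' @export
picContrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) stop("tree must be binary; resolvePolytomies() first")
  z <- .matchTraitToTips(tree, trait)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  val <- c(z, numeric(nnode))
  extra <- numeric(ntip + nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  kidOf <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  nodes <- unique(po$edge[, 1])        # postorder parents: children first
  cons <- numeric(nnode); esd <- numeric(nnode); ord <- integer(nnode)
  k <- 0L
  for (nd in nodes) {
    e <- kidOf[[as.character(nd)]]
    if (length(e) != 2) stop("tree must be binary")
    c1 <- po$edge[e[1], 2]; c2 <- po$edge[e[2], 2]
    b1 <- po$edge.length[e[1]] + extra[c1]
    b2 <- po$edge.length[e[2]] + extra[c2]
    b1 <- max(b1, 1e-8); b2 <- max(b2, 1e-8)
    k <- k + 1L
    esd[k] <- sqrt(b1 + b2)
    cons[k] <- (val[c1] - val[c2]) / esd[k]
    ord[k] <- nd
    val[nd] <- (val[c1] / b1 + val[c2] / b2) / (1 / b1 + 1 / b2)
    extra[nd] <- b1 * b2 / (b1 + b2)
  }
  names(cons) <- ord
  new("PICSet", contrasts = cons, expectedSD = esd, nodes = ord)
}

#' Through-origin regression of independent contrasts
#'
#' Contrast pairs are oriented so each x-contrast is positive (the standard
#' sign convention: contrast direction at a node is arbitrary), then the
#' y-contrasts are regressed on the x-contrasts through the origin.
#'
#' @param tree a binary ape `phylo`
#' @param xTrait,yTrait named numeric vectors over the tips
#' @return list with `slope`, `r` (through-origin correlation), `p`
#'   (two-sided t on n_contrasts - 1 df) and `nContrasts`
#' @export
picRegression <- function(tree, xTrait, yTrait) {
  cx <- picContrasts(tree, xTrait)@contrasts
  cy <- picContrasts(tree, yTrait)@contrasts
  flip <- sign(cx); flip[flip == 0] <- 1
  cx <- cx * flip; cy <- cy * flip
  sxx <- sum(cx^2); sxy <- sum(cx * cy); syy <- sum(cy^2)
  if (sxx == 0) stop("all x-contrasts are zero")
  slope <- sxy / sxx
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else 0
  n <- length(cx)
  rss <- syy - slope * sxy
  se <- sqrt(max(rss, 0) / (n - 1) / sxx)
  p <- if (se > 0) 2 * stats::pt(-abs(slope / se), df = n - 1) else 0
  list(slope = slope, r = r, p = p, nContrasts = n)
}

# phylogenetic GLS pieces shared by K, lambda and PGLS
.phyloGLS <- function(C, z) {
  n <- length(z)
  Ci <- solve(C)
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Ci %*% one)
  ahat <- as.numeric(t(one) %*% Ci %*% z) / denom
  resid <- z - ahat
  list(Ci = Ci, ahat = ahat, resid = resid, denom = denom)
}

#' Blomberg's K phylogenetic signal
#'
#' K compares the observed ratio of tip variance to phylogenetically
#' corrected variance with its Brownian-motion expectation, so K = 1 is the
#' Brownian calibration, K < 1 weaker-than-Brownian signal. Significance is
#' assessed by shuffling trait values across tips: p is the proportion of
#' permuted K values at least as large as the observed one (with the
#' observed draw counted once).
#'
#' @param tree ape `phylo` (binary not required); n_tips >= 4
#' @param trait named numeric vector over the tips, non-constant
#' @param nPerm permutations for the p-value (0 skips the test, p = NA)
#' @param seed integer RNG seed for the permutation
#' @return a [SignalResult-class] with statistic "K"
#' @export
blombergK <- function(tree, trait, nPerm = 999L, seed = 1L) {
  z <- .matchTraitToTips(tree, trait)
  n <- length(z)
  if (n < 4) stop("need at least 4 tips")
  if (stats::sd(z) == 0) stop("constant trait: K is degenerate (zero MSE)")
  C <- vcvMatrix(tree, minEdge = 1e-8)
  Ci <- solve(C)
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Ci %*% one)
  Ci1 <- as.numeric(Ci %*% one)
  expected <- (sum(diag(C)) - n / denom) / (n - 1)
  kstat <- function(zv) {
    ahat <- sum(Ci1 * zv) / denom
    resid <- zv - ahat
    mse0 <- sum(resid^2) / (n - 1)
    mse <- as.numeric(t(resid) %*% Ci %*% resid) / (n - 1)
    (mse0 / mse) / expected
  }
  K <- kstat(z)
  p <- NA_real_
  if (nPerm > 0) {
    set.seed(seed)
    exceed <- sum(vapply(seq_len(nPerm),
                         function(i) kstat(sample(z)) >= K, logical(1)))
    p <- (exceed + 1) / (nPerm + 1)
  }
  new("SignalResult", statistic = "K", estimate = K, pValue = p,
      nTips = as.integer(n),
      detail = sprintf("%d permutations", as.integer(nPerm)))
}

# profile log-likelihood of lambda: mean and sigma2 profiled analytically
.lambdaLogLik <- function(C, z, lambda) {
  Cl <- .lambdaVCV(C, lambda)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  n <- length(z)
  logdet <- 2 * sum(log(diag(L)))
  Ciz <- backsolve(L, forwardsolve(t(L), z))
  Ci1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  denom <- sum(Ci1)
  ahat <- sum(Ciz) / denom
  r <- z - ahat
  Cir <- backsolve(L, forwardsolve(t(L), r))
  s2 <- sum(r * Cir) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(2 * pi * s2) - logdet / 2 - n / 2
}

#' Maximum-likelihood Pagel's lambda
#'
#' Profiles the Gaussian log-likelihood with covariance sigma^2 * C(lambda)
#' over lambda in \[0, 1\] (mean and sigma^2 profiled analytically, bounded
#' scalar optimization to 1e-6, endpoints checked), and tests lambda = 0 by
#' a likelihood-ratio chi-square with 1 df.
#'
#' @param tree ape `phylo`; n_tips >= 4 and not a star tree
#' @param trait named numeric vector over the tips
#' @return a [SignalResult-class] with statistic "lambda"
#' @export
pagelLambdaML <- function(tree, trait) {
  z <- .matchTraitToTips(tree, trait)
  n <- length(z)
  if (n < 4) stop("need at least 4 tips")
  if (stats::sd(z) == 0) stop("constant trait: lambda is unidentifiable")
  C <- vcvMatrix(tree, minEdge = 1e-8)
  off <- C[upper.tri(C)]
  if (max(off) <= 1e-10 * max(diag(C)))
    stop("star tree: lambda is unidentifiable (no shared branches)")
  ll <- function(l) .lambdaLogLik(C, z, l)
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll(0)), c(1, ll(1)))
  best <- cand[which.max(cand[, 2]), ]
  LR <- 2 * (best[2] - ll(0))
  p <- stats::pchisq(max(LR, 0), df = 1, lower.tail = FALSE)
  new("SignalResult", statistic = "lambda", estimate = best[1],
      pValue = min(max(p, .Machine$double.xmin), 1), nTips = as.integer(n),
      detail = "LR vs lambda = 0, 1 df")
}

#' Phylogenetic generalized least squares
#'
#' GLS with residual covariance from the tree: beta =
#' (X' C^-1 X)^-1 X' C^-1 y, with C the Brownian covariance or its
#' lambda-ML transform. The design is given as a formula so interactions
#' (e.g. diameter x growth form) expand through `model.matrix`.
#'
#' @param tree ape `phylo`
#' @param formula model formula, e.g. `RTD ~ diameter * growth_form`
#' @param data data.frame with a `species` column (or species rownames)
#'   matching the tip labels
#' @param correlation "BM" (default) or "lambda" (lambda estimated by ML on
#'   the model residual trait, i.e. the response)
#' @return list with `coefficients` (estimate, se, t, p per term), `sigma2`,
#'   `lambda` (NA under BM), `n`, `correlation`
#' @export
pglsFit <- function(tree, formula, data, correlation = c("BM", "lambda")) {
  correlation <- match.arg(correlation)
  sp <- if ("species" %in% names(data)) data$species else rownames(data)
  if (is.null(sp)) stop("data needs a 'species' column or species rownames")
  key <- .normalizeSpecies(sp)
  tips <- .normalizeSpecies(tree$tip.label)
  idx <- match(tips, key)
  if (anyNA(idx))
    stop("species missing from data: ",
         paste(utils::head(tree$tip.label[is.na(idx)], 5), collapse = ", "))
  dat <- data[idx, , drop = FALSE]
  mf <- stats::model.frame(formula, dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(drop, collapse = ", "))
  }
  C <- vcvMatrix(tree, minEdge = 1e-8)
  lam <- NA_real_
  if (correlation == "lambda") {
    lam <- pagelLambdaML(tree, stats::setNames(y, tree$tip.label))@estimate
    C <- .lambdaVCV(C, lam)
  }
  Ci <- solve(C)
  XtCi <- t(X) %*% Ci
  cov <- solve(XtCi %*% X)
  beta <- cov %*% (XtCi %*% y)
  r <- y - X %*% beta
  n <- length(y); pp <- ncol(X)
  sigma2 <- as.numeric(t(r) %*% Ci %*% r) / (n - pp)
  se <- sqrt(diag(cov) * sigma2)
  tval <- as.numeric(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - pp)
  coefs <- data.frame(estimate = as.numeric(beta), se = se,
                      t = tval, p = pval, row.names = colnames(X))
  list(coefficients = coefs, sigma2 = sigma2, lambda = lam,
       n = n, correlation = correlation)
}
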