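# Expected SNV multiplicity spectra of a route as a function of its event
# timings, plus uniform sampling of timings on a route's constrained region.

## Resolve symbolic edge endpoints to times. `theta` is a matrix of free
## parameters (draws x params); returns draws x edges start/end matrices.
.symValues <- function(sym, theta, twgd) {
  n <- nrow(theta)
  vapply(sym, function(s) {
    if (s == 0L) rep(0, n)
    else if (s == -1L) rep(twgd, n)
    else if (s == -2L) rep(1, n)
    else theta[, s]
  }, numeric(n))
}

#' Expected multiplicity spectrum of a route at given timings
#'
#' For each surviving-lineage tree edge spanning mutation-time interval
#' \code{[a, b]} and carrying \code{lambda} surviving final copies, a
#' mutation falling on the edge ends up on \code{lambda} copies. With SNVs
#' accruing uniformly per unit time per copy, the probability that a
#' (surviving) SNV has multiplicity m is the total length of
#' lambda-equal-m edges divided by the total surviving branch length.
#'
#' @param route a [GainRoute-class].
#' @param timings numeric vector of the route's free gain times, in
#'   parameter-id order (length \code{route@nParams}).
#' @param wgdTime the shared WGD time (required when the route has a WGD).
#' @return named numeric vector of weights for multiplicities
#'   \code{1..majorCn}, summing to 1.
#' @examples
#' r <- enumerateRoutes(2, 2, wgd = TRUE)[[1]]  # WGD-only route
#' multiplicitySpectrum(r, numeric(0), wgdTime = 0.5)
#' @export
multiplicitySpectrum <- function(route, timings, wgdTime = NA_real_) {
  stopifnot(is(route, "GainRoute"))
  if (route@wgd && (is.na(wgdTime) || wgdTime < 0 || wgdTime > 1))
    stop("a WGD route needs a wgdTime in [0, 1]")
  timings <- as.numeric(timings)
  if (length(timings) != route@nParams)
    stop("expected ", route@nParams, " timing value(s)")
  if (route@nParams > 0L) {
    lo <- ifelse(route@params$phase == "post", wgdTime, 0)
    hi <- ifelse(route@params$phase == "pre", wgdTime, 1)
    if (any(timings < lo) || any(timings > hi))
      stop("timings violate the route's pre/post-WGD ranges")
    pp <- route@params$parent
    bad <- pp > 0L & timings[match(pp, route@params$id)] > timings
    if (any(bad, na.rm = TRUE))
      stop("timings violate the route's tree order")
  }
  theta <- matrix(timings, nrow = 1L)
  W <- spectrumMatrix(route, theta, wgdTime)
  stats::setNames(as.numeric(W[1L, ]), seq_len(ncol(W)))
}

#' Spectra for many timing draws at once
#'
#' Vectorised form of [multiplicitySpectrum()]: rows of \code{theta} are
#' timing draws (assumed valid).
#'
#' @param route a [GainRoute-class].
#' @param theta draws x params matrix of gain times.
#' @param twgd the WGD time shared by all draws.
#' @return draws x majorCn matrix of normalised spectra.
#' @keywords internal
spectrumMatrix <- function(route, theta, twgd = NA_real_) {
  ed <- route@edges
  n <- max(nrow(theta), 1L)
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = n)
  st <- .symValues(ed$start, theta, twgd)
  en <- .symValues(ed$end, theta, twgd)
  if (is.null(dim(st))) { st <- matrix(st, nrow = n); en <- matrix(en, nrow = n) }
  len <- en - st
  M <- route@majorCn
  W <- matrix(0, nrow = n, ncol = M)
  for (j in seq_len(nrow(ed))) {
    lam <- ed$lambda[j]
    W[, lam] <- W[, lam] + len[, j]
  }
  W / rowSums(W)
}

## Validity of iid-uniform draws against the route's tree order. The
## pre/post transforms below are monotone in u, so order constraints can be
## checked once on u, independent of the WGD time.
.validU <- function(route, U) {
  ok <- rep(TRUE, nrow(U))
  pp <- route@params$parent
  for (k in which(pp > 0L)) {
    pcol <- match(pp[k], route@params$id)
    ok <- ok & U[, pcol] < U[, k]
  }
  ok
}

## Map iid uniforms to gain times given the WGD time: pre-WGD gains live on
## (0, t_w), post-WGD on (t_w, 1), free gains on (0, 1).
.timesFromU <- function(route, U, twgd) {
  theta <- U
  ph <- route@params$phase
  pre <- ph == "pre"; post <- ph == "post"
  if (any(pre)) theta[, pre] <- U[, pre, drop = FALSE] * twgd
  if (any(post)) theta[, post] <- twgd + U[, post, drop = FALSE] * (1 - twgd)
  theta
}

#' Uniform timing draws on a route's constrained region
#'
#' Draws gain times uniformly on the region defined by the route's tree
#' order and pre/post-WGD ranges, by rejection from iid uniforms (exact).
#'
#' @param route a [GainRoute-class].
#' @param n number of draws required.
#' @param wgdTime the WGD time (ignored for non-WGD routes).
#' @return n x nParams matrix of gain times (0 columns when the route has
#'   no free timings).
#' @export
sampleRouteTimings <- function(route, n, wgdTime = NA_real_) {
  U <- routeUniforms(route, n)
  .timesFromU(route, U, wgdTime)
}

## Probability that iid uniforms respect the route's tree order: hook
## length formula for forest posets (product over gain nodes of one over
## the size of the subtree rooted there). Sizes the rejection batches.
.orderProbability <- function(route) {
  pp <- route@params
  if (!nrow(pp)) return(1)
  size <- rep(1, nrow(pp))
  for (k in rev(seq_len(nrow(pp)))) {
    kids <- which(pp$parent == pp$id[k])
    size[k] <- 1 + sum(size[kids])
  }
  prod(1 / size)
}

## Accepted iid-uniform draws (order constraints only); shared by evidence
## integration so the same accepted u can be reused across WGD-grid values.
routeUniforms <- function(route, n) {
  p <- route@nParams
  if (p == 0L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  pAcc <- .orderProbability(route)
  batchRows <- max(4L * n, ceiling(1.5 * n / pAcc))
  out <- matrix(NA_real_, nrow = 0L, ncol = p)
  guard <- 0L
  while (nrow(out) < n && guard < 60L) {
    batch <- matrix(stats::runif(batchRows * p), ncol = p)
    batch <- batch[.validU(route, batch), , drop = FALSE]
    out <- rbind(out, batch)
    guard <- guard + 1L
  }
  if (nrow(out) < n)
    stop("rejection sampling failed for route ", route@label)
  out[seq_len(n), , drop = FALSE]
}
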