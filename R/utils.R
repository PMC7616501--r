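# Internal numerical helpers shared across the package.

logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logMeanExp <- function(x) logSumExp(x) - log(length(x))

## Derive a child RNG seed from a root seed and a counter, staying inside
## the 32-bit integer range R requires of set.seed().
deriveSeed <- function(seed, counter) {
  s <- (as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483629
  as.integer(s) + 1L
}

## Equal-tailed quantiles of a weighted sample (type-1 inverse CDF).
weightedQuantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w))
  keep <- is.finite(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w[o])
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

weightedMedian <- function(x, w) weightedQuantile(x, w, 0.5)

## Weighted standard deviation (population form, weights normalised).
weightedSd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
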