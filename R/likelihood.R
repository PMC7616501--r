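# SNV read-count likelihoods: binomial mixtures over the multiplicity
# spectrum, and Monte-Carlo route evidence.

#' Expected variant allele fraction
#'
#' Expected fraction of reads carrying a clonal SNV present on \code{m} of
#' the tumor's \code{totalCn} copies at the locus, in a sample of purity
#' \code{purity} (contaminating normal cells contribute two unmutated
#' copies).
#'
#' @param m SNV multiplicity (copies carrying the variant), 1..totalCn.
#' @param totalCn total tumor copy number at the locus.
#' @param purity tumor cell fraction in (0, 1].
#' @return expected VAF \code{m * purity / (purity * totalCn + 2 * (1 - purity))}.
#' @examples
#' expectedVaf(1, 2, 1)    # heterozygous SNV, pure diploid: 0.5
#' expectedVaf(2, 4, 0.8)
#' @export
expectedVaf <- function(m, totalCn, purity) {
  stopifnot(purity > 0, purity <= 1)
  if (any(m < 1) || any(m > totalCn))
    stop("multiplicity must satisfy 1 <= m <= totalCn")
  m * purity / (purity * totalCn + 2 * (1 - purity))
}

## Binomial pmf matrix: SNVs x multiplicities, reused across all routes and
## timing draws of a segment.
snvLikMatrix <- function(alt, depth, totalCn, purity, maxM) {
  p <- expectedVaf(seq_len(maxM), totalCn, purity)
  B <- vapply(p, function(pm) stats::dbinom(alt, depth, pm), numeric(length(alt)))
  matrix(B, nrow = length(alt), ncol = maxM)
}

## Mixture log-likelihood for each spectrum in the rows of W.
mixtureLogLik <- function(B, W) {
  lik <- B %*% t(W)                     # SNVs x draws
  colSums(log(pmax(lik, 1e-300)))
}

#' Log-likelihood of SNV read counts under a multiplicity spectrum
#'
#' Each SNV's alt count is a binomial draw whose success probability is the
#' expected VAF of its (latent) multiplicity; the spectrum supplies the
#' mixture weights.
#'
#' @param snvs data.frame (or \code{GRanges} metadata) with columns
#'   \code{alt_count} and \code{total_depth}. Zero-depth records are
#'   excluded with a warning.
#' @param spectrum numeric vector of multiplicity weights (normalised),
#'   as returned by [multiplicitySpectrum()].
#' @param totalCn total tumor copy number of the segment.
#' @param purity tumor purity.
#' @return the summed log-likelihood.
#' @export
segmentLogLik <- function(snvs, spectrum, totalCn, purity) {
  snvs <- as.data.frame(snvs)
  stopifnot(nrow(snvs) >= 1L, abs(sum(spectrum) - 1) < 1e-8)
  if (any(snvs$total_depth == 0)) {
    warning("excluding ", sum(snvs$total_depth == 0), " zero-depth SNV(s)")
    snvs <- snvs[snvs$total_depth > 0, , drop = FALSE]
  }
  B <- snvLikMatrix(snvs$alt_count, snvs$total_depth, totalCn, purity,
                    length(spectrum))
  as.numeric(mixtureLogLik(B, matrix(spectrum, nrow = 1L)))
}

#' Monte-Carlo model evidence of one route for one segment
#'
#' Estimates the marginal likelihood of the segment's SNV read counts under
#' the route, integrating the mixture likelihood over the route's gain
#' times with a uniform prior on the constrained timing region. The WGD
#' coordinate is either held fixed (joint inference conditions on the
#' sample-shared WGD time) or integrated uniformly over (0, 1).
#'
#' @param snvs data.frame with \code{alt_count}, \code{total_depth}.
#' @param route a [GainRoute-class].
#' @param totalCn,purity segment total copy number and sample purity.
#' @param wgdTime fixed WGD time, or \code{NA} to integrate over it (only
#'   meaningful for WGD routes).
#' @param nDraws Monte-Carlo draws.
#' @param seed RNG seed for reproducibility.
#' @return list with \code{logZ} (log evidence), \code{theta} (the timing
#'   draws), \code{twgd} (per-draw WGD times) and \code{logLik} (per-draw
#'   log-likelihoods, for importance resampling).
#' @export
routeEvidence <- function(snvs, route, totalCn, purity, wgdTime = NA_real_,
                          nDraws = 2000L, seed = 1L) {
  snvs <- as.data.frame(snvs)
  snvs <- snvs[snvs$total_depth > 0, , drop = FALSE]
  set.seed(seed)
  freeTw <- route@wgd && is.na(wgdTime)
  U <- routeUniforms(route, nDraws)
  tw <- if (freeTw) stats::runif(nDraws) else rep(wgdTime, nDraws)
  B <- snvLikMatrix(snvs$alt_count, snvs$total_depth, totalCn, purity,
                    route@majorCn)
  if (freeTw) {
    theta <- U
    ll <- numeric(nDraws)
    for (i in seq_len(nDraws)) {
      th <- .timesFromU(route, U[i, , drop = FALSE], tw[i])
      theta[i, ] <- th
      ll[i] <- mixtureLogLik(B, spectrumMatrix(route, th, tw[i]))
    }
  } else {
    theta <- .timesFromU(route, U, if (route@wgd) wgdTime else NA_real_)
    W <- spectrumMatrix(route, theta, if (route@wgd) wgdTime else NA_real_)
    ll <- mixtureLogLik(B, W)
  }
  list(logZ = logMeanExp(ll), theta = theta, twgd = tw, logLik = ll)
}
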