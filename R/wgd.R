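# WGD status calling from the synchrony of major-copy-number-two gain
# timings across the genome.

## Posterior over the (synchronised) gain time of one major-CN-2 segment,
## on a fixed grid. Minor allele 2 is assumed gained at the same time (the
## WGD hypothesis under test); minor 0/1 contribute only multiplicity-1
## branch length.
.mcn2TimingPosterior <- function(alt, depth, minorCn, purity, grid) {
  g <- 1L + as.integer(minorCn == 2L)          # synchronised gained alleles
  extra <- as.integer(minorCn == 1L)           # ungained unit-length branch
  totalCn <- 2L + minorCn
  L <- g * (2 - grid) + extra                  # total branch length
  w2 <- g * grid / L
  W <- cbind(1 - w2, w2)
  B <- snvLikMatrix(alt, depth, totalCn, purity, 2L)
  ll <- mixtureLogLik(B, W)
  w <- exp(ll - max(ll))
  w / sum(w)
}

.gridCi <- function(grid, post, ci) {
  cdf <- cumsum(post)
  a <- (1 - ci) / 2
  c(lo = grid[which(cdf >= a)[1L]], hi = grid[which(cdf >= 1 - a)[1L]])
}

#' Call whole-genome duplication status from copy-number synchrony
#'
#' Computes the bp-weighted mode of the clonal major copy number. A mode of
#' one is called non-WGD; a mode of three or more is flagged
#' \code{ambiguous_multi} (possible multiple WGDs; excluded from timing).
#' When the mode is two, every major-copy-number-two segment with enough
#' SNVs is timed independently under a single synchronised gain; the sample
#' is called WGD if at least \code{config$wgdOverlap} (default 60 percent) of the
#' base pairs spanned by those segments have gain-timing credible intervals
#' (mass \code{config$ci}, default 90 percent) that overlap one common time
#' point. The time point of maximal overlap is reported as the WGD time
#' estimate of the call.
#'
#' @param sample a [TumorSample-class].
#' @param config a [timingConfig()] list.
#' @return a [WgdCall-class].
#' @export
callWgd <- function(sample, config = timingConfig()) {
  stopifnot(is(sample, "TumorSample"))
  segs <- .segmentFrame(sample)
  if (!nrow(segs)) stop("sample has no segments")
  bpByMajor <- tapply(segs$bp, segs$major_cn, sum)
  best <- max(bpByMajor)
  modes <- as.integer(names(bpByMajor)[bpByMajor == best])
  mode <- max(modes)        # ties resolved toward the larger copy number
  emptyTab <- data.frame(segment_id = character(), bp = numeric(),
                         ci_lo = numeric(), ci_hi = numeric())
  if (mode == 1L)
    return(new("WgdCall", sampleId = sampleId(sample), status = "non_wgd",
               majorMode = mode, overlapFraction = NA_real_,
               wgdTime = NA_real_, segmentTable = emptyTab))
  if (mode >= 3L)
    return(new("WgdCall", sampleId = sampleId(sample),
               status = "ambiguous_multi", majorMode = mode,
               overlapFraction = NA_real_, wgdTime = NA_real_,
               segmentTable = emptyTab))
  m2 <- segs[segs$major_cn == 2L & segs$n_snvs >= config$minSnvs, ,
             drop = FALSE]
  if (!nrow(m2))
    return(new("WgdCall", sampleId = sampleId(sample),
               status = "insufficient_data", majorMode = mode,
               overlapFraction = NA_real_, wgdTime = NA_real_,
               segmentTable = emptyTab))
  snvAll <- as.data.frame(S4Vectors::mcols(snvs(sample)))
  grid <- (seq_len(config$wgdCallGrid) - 0.5) / config$wgdCallGrid
  cis <- t(vapply(seq_len(nrow(m2)), function(i) {
    sub <- snvAll[!is.na(snvAll$segment_id) &
                    snvAll$segment_id == m2$segment_id[i] &
                    snvAll$total_depth > 0, , drop = FALSE]
    post <- .mcn2TimingPosterior(sub$alt_count, sub$total_depth,
                                 m2$minor_cn[i], purity(sample), grid)
    .gridCi(grid, post, config$ci)
  }, numeric(2)))
  tab <- data.frame(segment_id = m2$segment_id, bp = m2$bp,
                    ci_lo = cis[, 1L], ci_hi = cis[, 2L])
  ## interval stabbing: the candidate time covering the most base pairs
  cand <- sort(unique(c(tab$ci_lo, tab$ci_hi)))
  cover <- vapply(cand, function(p)
    sum(tab$bp[tab$ci_lo <= p & p <= tab$ci_hi]), numeric(1))
  frac <- max(cover) / sum(tab$bp)
  tmax <- cand[which.max(cover)]
  status <- if (frac >= config$wgdOverlap) "wgd" else "insufficient_overlap"
  new("WgdCall", sampleId = sampleId(sample), status = status,
      majorMode = mode, overlapFraction = frac, wgdTime = tmax,
      segmentTable = tab)
}

#' Call WGD (when needed) and time all gains of a sample
#'
#' Thin pipeline wrapper: resolves the sample's WGD status with
#' [callWgd()] when it is \code{"unknown"} (a mode-two sample below the
#' overlap threshold is timed as non-WGD; an \code{ambiguous_multi} sample
#' is not timed), then runs [sampleJointPosterior()].
#'
#' @inheritParams sampleJointPosterior
#' @return a [SamplePosterior-class], or \code{NULL} (with a warning) for
#'   samples whose WGD status precludes timing.
#' @export
timeGains <- function(sample, config = timingConfig(), seed = 1L) {
  if (wgdStatus(sample) == "unknown") {
    call <- callWgd(sample, config)
    st <- switch(call@status,
                 wgd = "wgd",
                 non_wgd = , insufficient_overlap = ,
                 insufficient_data = "non_wgd",
                 ambiguous_multi = "ambiguous_multi")
    wgdStatus(sample) <- st
  }
  if (wgdStatus(sample) == "ambiguous_multi") {
    warning("sample ", sampleId(sample),
            ": major copy-number mode >= 3 (possible multiple WGDs); not timed")
    return(NULL)
  }
  sampleJointPosterior(sample, config, seed)
}
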