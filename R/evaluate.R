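# Comparison of inferred gain timing against simulated ground truth.

.parseTimes <- function(s) {
  if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ",")[[1L]])
}

## Full sorted bifurcation-time list of one history: independent gain times
## plus the WGD time repeated once per WGD bifurcation. Its length,
## major + minor - 2 (counting only non-lost alleles), is route-invariant
## for a given state, which is what makes rank-wise pairing well defined.
.fullTimingVector <- function(gains, twgd, majorCn, minorCn) {
  nBif <- max(majorCn - 1L, 0L) + max(minorCn - 1L, 0L)
  nW <- nBif - length(gains)
  sort(c(gains, rep(twgd, nW)))
}

#' Pairwise rank comparison of inferred and true gain timings
#'
#' For each timed segment and posterior draw, sorts the draw's full
#' bifurcation times (independent gains plus WGD duplications at the WGD
#' time) and the matching true times, pairs them by rank, and keeps the
#' pairs whose true entry is an independent gain. Pairs accumulate with
#' weight 1/draws, so each route contributes in proportion to its
#' posterior probability.
#'
#' @param posteriors list of [SamplePosterior-class].
#' @param truth truth data.frame from [simulateCohort()].
#' @param nBins histogram resolution on each axis.
#' @return list with \code{pairs} (data.frame: sample, segment, true and
#'   inferred time per kept comparison, with weights), \code{histogram}
#'   (nBins x nBins matrix over (true, inferred)), and \code{nSkipped}
#'   (segments present in truth but missing from the posteriors).
#' @export
evaluateTiming <- function(posteriors, truth, nBins = 20L) {
  if (is(posteriors, "SamplePosterior")) posteriors <- list(posteriors)
  names(posteriors) <- vapply(posteriors, sampleId, character(1))
  pairRows <- list()
  nSkipped <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    post <- posteriors[[tr$sample_id]]
    timed <- !is.null(post) && nrow(post@segments) &&
      tr$segment_id %in% post@segments$segment_id[post@segments$timed]
    if (!timed) { nSkipped <- nSkipped + 1L; next }
    gains <- .parseTimes(tr$gain_times)
    trueFull <- .fullTimingVector(gains, tr$t_w, tr$major_cn, tr$minor_cn)
    keepRank <- which(trueFull %in% gains)
    if (!length(keepRank)) next
    ds <- post@drawSummary[post@drawSummary$segment_id == tr$segment_id, ]
    gg <- post@draws[post@draws$segment_id == tr$segment_id, ]
    gainsByDraw <- split(gg$timing, factor(gg$draw, levels = ds$draw))
    nDraws <- nrow(ds)
    nBif <- length(trueFull)
    infMat <- matrix(vapply(seq_len(nDraws), function(d)
      .fullTimingVector(gainsByDraw[[d]], ds$t_w[d], tr$major_cn,
                        tr$minor_cn), numeric(nBif)), nrow = nBif)
    pairRows[[length(pairRows) + 1L]] <- data.frame(
      sample_id = tr$sample_id, segment_id = tr$segment_id,
      rank = rep(keepRank, times = nDraws),
      true_time = rep(trueFull[keepRank], times = nDraws),
      inferred_time = as.numeric(infMat[keepRank, , drop = FALSE]),
      weight = 1 / nDraws, bp = tr$bp)
  }
  pairs <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame(sample_id = character(), segment_id = character(),
               rank = integer(), true_time = numeric(),
               inferred_time = numeric(), weight = numeric(), bp = numeric())
  brk <- seq(0, 1, length.out = nBins + 1L)
  cut2 <- function(x) pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                                1L), nBins)
  hist <- matrix(0, nBins, nBins)
  if (nrow(pairs)) {
    lin <- cut2(pairs$true_time) + (cut2(pairs$inferred_time) - 1L) * nBins
    s <- rowsum(pairs$weight, lin)
    hist[as.integer(rownames(s))] <- s[, 1L]
  }
  list(pairs = pairs, histogram = hist, nSkipped = nSkipped)
}

#' Gain-timing recovery summary
#'
#' Per true independent gain (rank-matched as in [evaluateTiming()]):
#' posterior median and equal-tailed credible interval of the matched
#' inferred times, alongside the truth. The bp-weighted RMSE of posterior
#' medians and the credible-interval coverage are the headline accuracy
#' numbers for simulated cohorts; WGD-time recovery is summarised per
#' sample.
#'
#' @param posteriors list of [SamplePosterior-class].
#' @param truth truth data.frame from [simulateCohort()].
#' @param ci credible mass for the coverage intervals.
#' @return list with \code{perGain} (data.frame), \code{rmse}
#'   (bp-weighted), \code{coverage} (fraction of true gains inside their
#'   interval, bp-weighted), and \code{wgd} (data.frame of true and median
#'   inferred WGD time per WGD sample).
#' @export
timingRecovery <- function(posteriors, truth, ci = 0.90) {
  ev <- evaluateTiming(posteriors, truth)
  pairs <- ev$pairs
  a <- (1 - ci) / 2
  perGain <- do.call(rbind, lapply(
    split(pairs, list(pairs$sample_id, pairs$segment_id, pairs$rank),
          drop = TRUE),
    function(g) data.frame(
      sample_id = g$sample_id[1L], segment_id = g$segment_id[1L],
      rank = g$rank[1L], true_time = g$true_time[1L], bp = g$bp[1L],
      median = weightedQuantile(g$inferred_time, g$weight, 0.5),
      lo = weightedQuantile(g$inferred_time, g$weight, a),
      hi = weightedQuantile(g$inferred_time, g$weight, 1 - a))))
  rmse <- sqrt(sum(perGain$bp * (perGain$median - perGain$true_time)^2) /
                 sum(perGain$bp))
  inCi <- perGain$true_time >= perGain$lo & perGain$true_time <= perGain$hi
  coverage <- sum(perGain$bp * inCi) / sum(perGain$bp)
  if (is(posteriors, "SamplePosterior")) posteriors <- list(posteriors)
  wgdRows <- list()
  for (post in posteriors) {
    if (!length(post@twDraws)) next
    tw <- unique(truth$t_w[truth$sample_id == sampleId(post)])
    wgdRows[[length(wgdRows) + 1L]] <- data.frame(
      sample_id = sampleId(post), true_t_w = tw[1L],
      median_t_w = stats::median(post@twDraws))
  }
  list(perGain = perGain, rmse = rmse, coverage = coverage,
       wgd = if (length(wgdRows)) do.call(rbind, wgdRows) else
         data.frame(sample_id = character(), true_t_w = numeric(),
                    median_t_w = numeric()))
}
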