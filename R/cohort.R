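# Cohort-level statistics of gain timing relative to WGD: gain-rate
# curves, post-WGD gain prevalence, timing proximity, punctuated bursts,
# and within-tumor timing ranks.

.isWgdPost <- function(post) post@wgdStatus == "wgd" && length(post@twDraws)

## Gain draws of one sample joined with segment bp (weight bp / draws).
.gainDrawTable <- function(post) {
  d <- post@draws
  if (!nrow(d)) return(d)
  seg <- post@segments
  d$bp <- seg$bp[match(d$segment_id, seg$segment_id)]
  nDraws <- max(d$draw)
  d$weight <- d$bp / nDraws
  d
}

#' Rate of copy-number gain relative to the WGD
#'
#' Bins the bp-weighted posterior density of (gain time - WGD time) across
#' a cohort of WGD tumors, and normalises it by the same quantity computed
#' with gain times replaced by a uniform distribution over mutation time
#' (same samples, same WGD-time posteriors, each sample contributing
#' equally). The normaliser captures how much offset range is available
#' given each tumor's WGD timing, so the normalised curve is flat at 1
#' when gains accrue at a constant rate irrespective of the WGD.
#'
#' @param posteriors list of [SamplePosterior-class]; non-WGD samples are
#'   ignored.
#' @param binWidth offset bin width in mutation time (default 0.1; one bin
#'   always spans -binWidth/2..binWidth/2).
#' @param span quantile range of the offset distribution covered by the
#'   bins.
#' @return data.frame per bin: \code{mid}, \code{lo}, \code{hi},
#'   \code{raw} (bp-weighted posterior mass), \code{normalizer},
#'   \code{rate} (raw / scaled normaliser; \code{NA} where the normaliser
#'   is empty).
#' @export
gainRateRelativeToWgd <- function(posteriors, binWidth = 0.1,
                                  span = c(0.01, 0.99)) {
  posteriors <- Filter(.isWgdPost, posteriors)
  if (!length(posteriors)) stop("no WGD samples with posterior draws")
  gd <- lapply(posteriors, .gainDrawTable)
  off <- unlist(lapply(gd, function(d) d$timing - d$t_w))
  w <- unlist(lapply(gd, function(d) d$weight))
  qs <- weightedQuantile(off, w, span)
  kLo <- ceiling((-binWidth / 2 - qs[1L]) / binWidth)
  kHi <- ceiling((qs[2L] - binWidth / 2) / binWidth)
  edges <- seq(-binWidth / 2 - kLo * binWidth, binWidth / 2 + kHi * binWidth,
               by = binWidth)
  nb <- length(edges) - 1L
  binOf <- function(x) findInterval(x, edges, rightmost.closed = TRUE)
  binOne <- function(offs, ws) {
    out <- rep(0, nb)
    keep <- offs >= edges[1L] & offs <= edges[nb + 1L]
    if (any(keep)) {
      s <- rowsum(ws[keep], binOf(offs[keep]))
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
  ## raw: absolute bp-weighted posterior mass; rate: per-sample equalised
  ## raw against the per-sample equalised uniform-gain normaliser, so that
  ## heterogeneous genome sizes cannot tilt the ratio
  raw <- rep(0, nb); rawEq <- rep(0, nb); norm <- rep(0, nb)
  for (i in seq_along(gd)) {
    d <- gd[[i]]
    rb <- binOne(d$timing - d$t_w, d$weight)
    raw <- raw + rb
    if (sum(rb) > 0) rawEq <- rawEq + rb / sum(d$weight)
    tws <- posteriors[[i]]@twDraws
    contrib <- vapply(seq_len(nb), function(b) {
      lo <- pmax(edges[b], -tws); hi <- pmin(edges[b + 1L], 1 - tws)
      mean(pmax(hi - lo, 0))
    }, numeric(1))
    norm <- norm + contrib        # each sample's uniform mass integrates to 1
  }
  data.frame(mid = (edges[-1L] + edges[-(nb + 1L)]) / 2,
             lo = edges[-(nb + 1L)], hi = edges[-1L],
             raw = raw, normalizer = norm,
             rate = ifelse(norm > 0, rawEq / norm, NA_real_))
}

## Fraction of posterior draws in which a segment has >= 1 post-WGD gain,
## judged against a supplied WGD-time draw vector (recycled across draws).
.segPostGainFraction <- function(post, twVec = NULL) {
  ds <- post@drawSummary
  if (!nrow(ds)) return(numeric(0))
  if (is.null(twVec)) {
    frac <- tapply(ds$n_post >= 1L, ds$segment_id, mean)
  } else {
    d <- post@draws
    if (!nrow(d)) return(stats::setNames(numeric(0), character(0)))
    tw <- twVec[(d$draw - 1L) %% length(twVec) + 1L]
    hasPost <- tapply(d$timing > tw, list(d$segment_id, d$draw), any)
    frac <- rowMeans(hasPost, na.rm = TRUE)
    frac[is.nan(frac)] <- 0
  }
  frac
}

#' Prevalence of post-WGD gains, with a pseudo-WGD control
#'
#' A tumor has post-WGD gains when at least half of the joint posterior
#' draws of any of its segments contain at least one gain after the WGD.
#' Non-WGD tumors form the control: each receives the WGD-time posterior
#' of a randomly chosen WGD tumor of the same cancer type, and the same
#' rule is applied to its (independent) gain draws. Only cancer types with
#' at least \code{minPerGroup} tumors in both groups contribute.
#'
#' @param posteriors list of [SamplePosterior-class] (both statuses).
#' @param minPerGroup per-cancer-type group size filter (default 10).
#' @param drawFraction per-segment draw fraction required (default 0.5).
#' @param nPerm label permutations for the p-value.
#' @param seed RNG seed.
#' @return list with \code{fractionWgd}, \code{fractionControl},
#'   \code{pValue}, and \code{perSample} (data.frame of indicators).
#' @export
postWgdGainPrevalence <- function(posteriors, minPerGroup = 10L,
                                  drawFraction = 0.5, nPerm = 1000L,
                                  seed = 1L) {
  set.seed(seed)
  ct <- vapply(posteriors, cancerType, character(1))
  isW <- vapply(posteriors, .isWgdPost, logical(1))
  tw <- table(factor(ct[isW], levels = sort(unique(ct))))
  tn <- table(factor(ct[!isW], levels = sort(unique(ct))))
  keepTypes <- names(which(tw >= minPerGroup & tn >= minPerGroup))
  if (!length(keepTypes))
    return(list(fractionWgd = NA_real_, fractionControl = NA_real_,
                pValue = NA_real_, perSample = data.frame()))
  rows <- list()
  for (i in seq_along(posteriors)) {
    if (!ct[i] %in% keepTypes) next
    post <- posteriors[[i]]
    if (isW[i]) {
      frac <- .segPostGainFraction(post)
      ind <- length(frac) && any(frac >= drawFraction)
    } else {
      donors <- which(isW & ct == ct[i])
      donor <- posteriors[[donors[sample.int(length(donors), 1L)]]]
      frac <- .segPostGainFraction(post, twVec = donor@twDraws)
      ind <- length(frac) && any(frac >= drawFraction)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sampleId(post), cancer_type = ct[i], wgd = isW[i],
      has_post_wgd_gain = ind)
  }
  perSample <- do.call(rbind, rows)
  fw <- mean(perSample$has_post_wgd_gain[perSample$wgd])
  fc <- mean(perSample$has_post_wgd_gain[!perSample$wgd])
  obs <- fw - fc
  permDiff <- replicate(nPerm, {
    g <- sample(perSample$wgd)
    mean(perSample$has_post_wgd_gain[g]) -
      mean(perSample$has_post_wgd_gain[!g])
  })
  p <- (1 + sum(permDiff >= obs)) / (nPerm + 1)
  list(fractionWgd = fw, fractionControl = fc, pValue = p,
       perSample = perSample)
}

#' Timing proximity between independent gains and the WGD
#'
#' For each WGD tumor, draws \code{nTw} WGD times from its posterior; for
#' each, takes the bp-weighted median absolute difference between all gain
#' draws and that WGD time; and averages the medians. The control
#' recomputes the same statistic after permuting the WGD-time posteriors
#' between tumors of the same cancer type, so it preserves every marginal
#' but breaks the within-tumor coupling.
#'
#' @param posteriors list of [SamplePosterior-class] (non-WGD ignored).
#' @param nTw WGD-time draws per tumor (default 25).
#' @param seed RNG seed.
#' @return list with \code{perSample} (observed and control proximity per
#'   tumor) and \code{pValue} (one-sided Wilcoxon rank-sum, observed <
#'   control).
#' @export
wgdGainProximity <- function(posteriors, nTw = 25L, seed = 1L) {
  posteriors <- Filter(.isWgdPost, posteriors)
  if (length(posteriors) < 2L) stop("need at least two WGD samples")
  set.seed(seed)
  ct <- vapply(posteriors, cancerType, character(1))
  prox <- function(post, twDonor) {
    d <- .gainDrawTable(post)
    if (!nrow(d)) return(NA_real_)
    tws <- twDonor[sample.int(length(twDonor), nTw, replace = TRUE)]
    mean(vapply(tws, function(tw)
      weightedMedian(abs(d$timing - tw), d$weight), numeric(1)))
  }
  observed <- vapply(posteriors, function(p) prox(p, p@twDraws), numeric(1))
  perm <- seq_along(posteriors)
  for (type in unique(ct)) {
    idx <- which(ct == type)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  control <- vapply(seq_along(posteriors), function(i)
    prox(posteriors[[i]], posteriors[[perm[i]]]@twDraws), numeric(1))
  p <- stats::wilcox.test(observed, control, alternative = "less",
                          exact = FALSE)$p.value
  list(perSample = data.frame(
    sample_id = vapply(posteriors, sampleId, character(1)),
    cancer_type = ct, observed = observed, control = control),
    pValue = p)
}

## Per-segment posterior-median gain times of the timed, gained segments.
.segmentMedianGains <- function(post) {
  d <- post@draws
  if (!nrow(d)) return(data.frame())
  med <- tapply(d$timing, d$segment_id, stats::median)
  seg <- post@segments
  idx <- match(names(med), seg$segment_id)
  data.frame(segment_id = names(med), chrom = seg$chrom[idx],
             bp = seg$bp[idx], median_time = as.numeric(med),
             stringsAsFactors = FALSE)
}

#' Pool of per-segment gain timings by cancer type
#'
#' @param posteriors list of [SamplePosterior-class].
#' @return named list (cancer type) of numeric vectors of per-segment
#'   posterior-median gain times, for [classifyPunctuated()].
#' @export
cancerTypeGainPool <- function(posteriors) {
  rows <- lapply(posteriors, function(post) {
    sm <- .segmentMedianGains(post)
    if (!nrow(sm)) return(NULL)
    data.frame(cancer_type = cancerType(post), t = sm$median_time)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(list())
  split(df$t, df$cancer_type)
}

#' Classify a tumor's gains as punctuated
#'
#' Tests whether a tumor's gains cluster in mutation time more tightly
#' than expected given the cancer type's overall gain-timing distribution.
#' The dispersion statistic is the bp-weighted standard deviation of the
#' per-segment posterior-median gain times; the null replaces each
#' segment's timing by one resampled from the cancer-type pool (keeping
#' the tumor's segment count and bp weights). Tumors whose gains span
#' fewer than \code{minChroms} chromosomes are uninformative.
#'
#' @param post a [SamplePosterior-class].
#' @param pool numeric vector of cancer-type gain timings
#'   (see [cancerTypeGainPool()]).
#' @param nPerm permutation replicas (default 1000).
#' @param seed RNG seed.
#' @param minChroms minimum distinct chromosomes with gains (default 3).
#' @param alpha punctuated when the observed dispersion falls below this
#'   permutation quantile (default 0.05).
#' @return list with \code{status} (\code{"punctuated"},
#'   \code{"non_punctuated"} or \code{"uninformative"}), \code{dispersion},
#'   \code{permP} (fraction of replicas at or below the observed),
#'   \code{burstTime} (bp-weighted median gain time) and \code{postWgd}
#'   (is the burst after the posterior-median WGD time; \code{NA} for
#'   non-WGD samples).
#' @export
classifyPunctuated <- function(post, pool, nPerm = 1000L, seed = 1L,
                               minChroms = 3L, alpha = 0.05) {
  if (!length(pool)) stop("empty cancer-type gain pool")
  sm <- .segmentMedianGains(post)
  burst <- if (nrow(sm)) weightedMedian(sm$median_time, sm$bp) else NA_real_
  postWgd <- if (.isWgdPost(post) && !is.na(burst))
    burst > stats::median(post@twDraws) else NA
  if (nrow(sm) < 2L || length(unique(sm$chrom)) < minChroms)
    return(list(status = "uninformative", dispersion = NA_real_,
                permP = NA_real_, burstTime = burst, postWgd = postWgd))
  disp <- weightedSd(sm$median_time, sm$bp)
  set.seed(seed)
  permDisp <- replicate(nPerm, weightedSd(
    pool[sample.int(length(pool), nrow(sm), replace = TRUE)], sm$bp))
  permP <- (1 + sum(permDisp <= disp)) / (nPerm + 1)
  status <- if (sum(permDisp <= disp) < alpha * nPerm) "punctuated"
            else "non_punctuated"
  list(status = status, dispersion = disp, permP = permP,
       burstTime = burst, postWgd = postWgd)
}

#' Punctuated-gain classification across a cohort
#'
#' @param posteriors list of [SamplePosterior-class].
#' @param nPerm,seed,minChroms,alpha as [classifyPunctuated()].
#' @return data.frame: one row per sample with status, dispersion,
#'   permutation quantile, burst time and pre/post-WGD placement.
#' @export
classifyPunctuatedCohort <- function(posteriors, nPerm = 1000L, seed = 1L,
                                     minChroms = 3L, alpha = 0.05) {
  pools <- cancerTypeGainPool(posteriors)
  rows <- lapply(seq_along(posteriors), function(i) {
    post <- posteriors[[i]]
    pool <- pools[[cancerType(post)]]
    cl <- classifyPunctuated(post, pool, nPerm = nPerm,
                             seed = deriveSeed(seed, i),
                             minChroms = minChroms, alpha = alpha)
    data.frame(sample_id = sampleId(post), cancer_type = cancerType(post),
               wgd = post@wgdStatus == "wgd", status = cl$status,
               dispersion = cl$dispersion, perm_p = cl$permP,
               burst_time = cl$burstTime, post_wgd = cl$postWgd)
  })
  do.call(rbind, rows)
}

#' Expected pre-/post-WGD gain counts and loss classes per segment
#'
#' Averages, over the joint posterior draws of a WGD sample, the number of
#' independent gains placed before and after the WGD in each segment, and
#' classifies losses from the minor copy number: 0 implies a pre-WGD loss
#' (LOH doubled by the WGD), 1 a post-WGD loss (one of the two doubled
#' minor copies lost), 2 or more no loss call.
#'
#' @param post a [SamplePosterior-class] of a WGD sample.
#' @return data.frame per gained segment: \code{mean_pre}, \code{mean_post},
#'   \code{loss_class}.
#' @export
classifyPrePostEvents <- function(post) {
  stopifnot(post@wgdStatus == "wgd")
  seg <- post@segments
  ds <- post@drawSummary
  pre <- tapply(ds$n_pre, ds$segment_id, mean)
  pst <- tapply(ds$n_post, ds$segment_id, mean)
  idx <- match(seg$segment_id, names(pre))
  data.frame(
    segment_id = seg$segment_id, chrom = seg$chrom, bp = seg$bp,
    major_cn = seg$major_cn, minor_cn = seg$minor_cn,
    mean_pre = as.numeric(pre[idx]), mean_post = as.numeric(pst[idx]),
    loss_class = ifelse(seg$minor_cn == 0L, "pre_wgd_loss",
                        ifelse(seg$minor_cn == 1L, "post_wgd_loss", "none")),
    stringsAsFactors = FALSE)
}

#' Within-tumor percentile ranks of gain timing, by major copy number
#'
#' Converts every posterior gain-timing draw into its percentile rank
#' within the tumor's combined draw set, either over all gains or over
#' only the initial (earliest) gain of each segment per draw, and returns
#' the ranks keyed by the segment's major copy number. Earlier-starting
#' amplifications show lower initial-gain ranks.
#'
#' @param posteriors list of [SamplePosterior-class].
#' @param scope \code{"all_gains"} or \code{"initial_gain_only"}.
#' @return data.frame: \code{sample_id}, \code{segment_id},
#'   \code{major_cn}, \code{rank} (one row per draw in scope).
#' @export
timingQuantileRanks <- function(posteriors,
                                scope = c("all_gains", "initial_gain_only")) {
  scope <- match.arg(scope)
  if (is(posteriors, "SamplePosterior")) posteriors <- list(posteriors)
  rows <- list()
  for (post in posteriors) {
    d <- post@draws
    if (!nrow(d)) next
    if (scope == "initial_gain_only") {
      key <- paste(d$segment_id, d$draw)
      first <- tapply(d$timing, key, min)
      d <- d[!duplicated(key), ]
      d$timing <- as.numeric(first[paste(d$segment_id, d$draw)])
    }
    n <- nrow(d)
    rk <- if (n == 1L) 0.5 else (rank(d$timing) - 0.5) / n
    seg <- post@segments
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sampleId(post), segment_id = d$segment_id,
      major_cn = seg$major_cn[match(d$segment_id, seg$segment_id)],
      rank = rk, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
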