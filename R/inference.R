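# Joint posterior inference over routes, gain timings and the sample-shared
# WGD time; the event-count penalty; the WGD caller.

#' Timing configuration
#'
#' Bundles the thresholds and schedule of the timing engine. Defaults are
#' the package's standard operating point.
#'
#' @param minSnvs minimum SNVs for a segment to be timed (default 20).
#' @param maxRoutes route cap: segments of states admitting more canonical
#'   routes are reported, never timed (default 500).
#' @param minReadsPerClonalCopy sample-level coverage filter (default 5).
#' @param penalty strength l of the event-count penalty \code{exp(-n * l)}
#'   applied to each route's evidence (default 2.7).
#' @param penaltyEnabled whether the penalty is applied (default TRUE).
#' @param wgdOverlap minimum fraction of major-copy-number-two base pairs
#'   with overlapping credible intervals for a WGD call (default 0.60).
#' @param ci credible-interval mass used by the WGD caller (default 0.90).
#' @param nDraws Monte-Carlo draws per route and WGD-grid cell used for the
#'   evidence integrals (default 120).
#' @param twGridCells number of cells of the WGD-time grid (default 40).
#' @param nPosteriorDraws stored joint posterior draws (default 250).
#' @param wgdCallGrid grid size for the single-gain timing posteriors used
#'   by the WGD caller (default 400).
#' @return a named list.
#' @export
timingConfig <- function(minSnvs = 20L, maxRoutes = 500L,
                         minReadsPerClonalCopy = 5,
                         penalty = 2.7, penaltyEnabled = TRUE,
                         wgdOverlap = 0.60, ci = 0.90,
                         nDraws = 120L, twGridCells = 40L,
                         nPosteriorDraws = 250L, wgdCallGrid = 400L) {
  stopifnot(minSnvs >= 1, maxRoutes >= 1, penalty >= 0,
            ci > 0, ci < 1, wgdOverlap > 0, wgdOverlap <= 1)
  list(minSnvs = as.integer(minSnvs), maxRoutes = as.integer(maxRoutes),
       minReadsPerClonalCopy = minReadsPerClonalCopy,
       penalty = penalty, penaltyEnabled = penaltyEnabled,
       wgdOverlap = wgdOverlap, ci = ci,
       nDraws = as.integer(nDraws), twGridCells = as.integer(twGridCells),
       nPosteriorDraws = as.integer(nPosteriorDraws),
       wgdCallGrid = as.integer(wgdCallGrid))
}

#' Apply the event-count penalty to route evidences
#'
#' Multiplies each route's evidence by \code{exp(-n * l)}, where n is the
#' route's total event count, and renormalises. With \code{l = 0} this
#' reduces to the evidence-only posterior; adding a constant to all event
#' counts leaves the result unchanged.
#'
#' @param logEvidence numeric vector of per-route log evidences.
#' @param nEvents integer vector of per-route event counts (aligned).
#' @param l penalty strength (>= 0).
#' @return normalised route probabilities.
#' @examples
#' applyPenalty(c(0, 0), c(2, 3), l = 2.7)
#' @export
applyPenalty <- function(logEvidence, nEvents, l = 2.7) {
  stopifnot(length(logEvidence) == length(nEvents), l >= 0)
  lw <- logEvidence - nEvents * l
  w <- exp(lw - max(lw))
  w / sum(w)
}

.colLogMeanExp <- function(LL) {
  m <- apply(LL, 2L, max)
  log(colMeans(exp(sweep(LL, 2L, m)))) + m
}

## Per-segment summary table used by SamplePosterior.
.segmentFrame <- function(sample) {
  seg <- cnSegments(sample)
  mc <- S4Vectors::mcols(seg)
  snv <- snvs(sample)
  nS <- table(factor(S4Vectors::mcols(snv)$segment_id, levels = mc$segment_id))
  data.frame(
    segment_id = mc$segment_id,
    chrom = as.character(GenomicRanges::seqnames(seg)),
    start = GenomicRanges::start(seg),
    end = GenomicRanges::end(seg),
    bp = GenomicRanges::width(seg),
    major_cn = mc$major_cn,
    minor_cn = mc$minor_cn,
    total_cn = mc$major_cn + mc$minor_cn,
    n_snvs = as.integer(nS),
    stringsAsFactors = FALSE)
}

## Evidence of every route of one segment across the WGD-time grid.
## Returns log-evidence matrix (routes x cells) plus per-route accepted
## uniforms and per-draw log-likelihoods for posterior resampling.
.segmentGridEvidence <- function(snvdf, routes, totalCn, purity, twCells,
                                 nDraws, seed) {
  B <- snvLikMatrix(snvdf$alt_count, snvdf$total_depth, totalCn, purity,
                    routes[[1L]]@majorCn)
  K <- length(twCells)
  R <- length(routes)
  logZ <- matrix(NA_real_, R, K,
                 dimnames = list(vapply(routes, routeId, character(1)), NULL))
  Ulist <- vector("list", R)
  LLlist <- vector("list", R)
  for (r in seq_len(R)) {
    route <- routes[[r]]
    set.seed(deriveSeed(seed, r))
    U <- routeUniforms(route, nDraws)
    LL <- matrix(NA_real_, nDraws, K)
    for (k in seq_len(K)) {
      tw <- if (route@wgd) twCells[k] else NA_real_
      theta <- .timesFromU(route, U, tw)
      LL[, k] <- mixtureLogLik(B, spectrumMatrix(route, theta, tw))
    }
    logZ[r, ] <- .colLogMeanExp(LL)
    Ulist[[r]] <- U
    LLlist[[r]] <- LL
  }
  list(logZ = logZ, U = Ulist, LL = LLlist, routes = routes)
}

## Marginal route probabilities given evidence curves and the WGD-time
## posterior over grid cells: P(r) = sum_k P(k) softmax_r(logZ[,k] - n_r l).
.marginalRouteProbs <- function(logZ, nEv, cellPost, l) {
  A <- logZ - nEv * l
  m <- apply(A, 2L, max)
  P <- exp(sweep(A, 2L, m))
  P <- sweep(P, 2L, colSums(P), "/")
  as.numeric(P %*% cellPost)
}

## Sample posterior cell probabilities for the WGD time, given per-segment
## evidence curves: p(k | data) prop.to prod_seg mean_r exp(logZ - n l).
.twCellPosterior <- function(evList, nEvList, l) {
  K <- ncol(evList[[1L]])
  logPost <- numeric(K)
  for (i in seq_along(evList)) {
    A <- evList[[i]] - nEvList[[i]] * l
    mix <- apply(A, 2L, logSumExp) - log(nrow(A))
    logPost <- logPost + mix
  }
  w <- exp(logPost - max(logPost))
  w / sum(w)
}

#' Joint posterior over gain routes, gain times and WGD time
#'
#' The core inference of the package. For each timed segment, the evidence
#' of every candidate route is estimated by uniform Monte-Carlo integration
#' over the route's constrained timing region, conditioned on each cell of
#' a grid over the sample-shared WGD time. For WGD samples, the WGD-time
#' posterior is then obtained by combining all segments' route-mixture
#' evidence curves (the simultaneity of the WGD across the genome is the
#' constraint that sharpens all timings), and joint draws of
#' (WGD time, per-segment route, gain times) are sampled by the chain rule:
#' WGD time from its gridded marginal, then each segment's route and
#' timings conditionally, by importance resampling of the stored
#' integration draws. Segments of non-WGD samples are independent.
#'
#' Segments are timed when their major copy number is at least two, they
#' carry at least \code{config$minSnvs} assigned clonal SNVs, and their
#' state admits at most \code{config$maxRoutes} canonical routes; others
#' are reported with a skip reason.
#'
#' @param sample a [TumorSample-class] with \code{wgdStatus} set to
#'   \code{"wgd"} or \code{"non_wgd"} (see [callWgd()] / [timeGains()]).
#' @param config a [timingConfig()] list.
#' @param seed integer seed; all randomness derives from it.
#' @return a [SamplePosterior-class].
#' @export
sampleJointPosterior <- function(sample, config = timingConfig(), seed = 1L) {
  stopifnot(is(sample, "TumorSample"))
  status <- wgdStatus(sample)
  if (!status %in% c("wgd", "non_wgd"))
    stop("wgdStatus must be 'wgd' or 'non_wgd'; run callWgd()/timeGains() first")
  isWgd <- status == "wgd"
  segs <- .segmentFrame(sample)
  segs$gained <- segs$major_cn >= 2L
  segs$timed <- FALSE
  segs$reason <- ifelse(segs$gained, "", "not_gained")
  snvAll <- as.data.frame(S4Vectors::mcols(snvs(sample)))

  evList <- list(); nEvList <- list(); routesList <- list()
  store <- list()
  twCells <- if (isWgd) (seq_len(config$twGridCells) - 0.5) / config$twGridCells
             else 0.5  # single dummy cell; routes carry no WGD
  for (i in which(segs$gained)) {
    sid <- segs$segment_id[i]
    if (segs$n_snvs[i] < config$minSnvs) {
      segs$reason[i] <- "too_few_snvs"; next
    }
    routes <- tryCatch(
      enumerateRoutes(segs$major_cn[i], segs$minor_cn[i], wgd = isWgd,
                      maxRoutes = config$maxRoutes),
      gainTiming_too_complex = function(e) e)
    if (inherits(routes, "condition")) {
      segs$reason[i] <- sprintf("too_complex(%d_routes)", routes$count); next
    }
    snvdf <- snvAll[!is.na(snvAll$segment_id) & snvAll$segment_id == sid &
                      snvAll$total_depth > 0, , drop = FALSE]
    ev <- .segmentGridEvidence(snvdf, routes, segs$total_cn[i],
                               purity(sample), twCells, config$nDraws,
                               deriveSeed(seed, i * 1000L))
    segs$timed[i] <- TRUE
    evList[[sid]] <- ev$logZ
    nEvList[[sid]] <- vapply(routes, nEvents, integer(1))
    routesList[[sid]] <- routes
    store[[sid]] <- ev
  }

  l <- if (config$penaltyEnabled) config$penalty else 0
  nOut <- config$nPosteriorDraws
  set.seed(deriveSeed(seed, 999983L))

  if (length(evList) == 0L) {
    return(new("SamplePosterior", sampleId = sampleId(sample),
               cancerType = cancerType(sample), purity = purity(sample),
               wgdStatus = status, segments = segs,
               routeProbs = data.frame(), evidence = list(),
               twGrid = numeric(), twPosterior = numeric(),
               twDraws = numeric(),
               draws = data.frame(), drawSummary = data.frame(),
               penalty = l, config = config))
  }

  if (isWgd) {
    cellPost <- .twCellPosterior(evList, nEvList, l)
    cellPost0 <- .twCellPosterior(evList, nEvList, 0)
    h <- 1 / config$twGridCells
    cells <- sample.int(length(twCells), nOut, replace = TRUE, prob = cellPost)
    twDraws <- twCells[cells] + (stats::runif(nOut) - 0.5) * h
  } else {
    cellPost <- 1; cellPost0 <- 1
    cells <- rep(1L, nOut)
    twDraws <- numeric(0)
  }

  rpList <- list(); gainRows <- list(); sumRows <- list()
  for (sid in names(evList)) {
    logZ <- evList[[sid]]; nEv <- nEvList[[sid]]
    routes <- routesList[[sid]]; ev <- store[[sid]]
    pm <- .marginalRouteProbs(logZ, nEv, cellPost, l)
    pm0 <- .marginalRouteProbs(logZ, nEv, cellPost0, 0)
    rpList[[sid]] <- data.frame(
      segment_id = sid, route_id = rownames(logZ),
      n_events = nEv, parsimonious = nEv == min(nEv),
      prob = pm, prob_no_penalty = pm0, stringsAsFactors = FALSE)
    ## joint draws: route then timings, conditionally on each drawn cell
    routeDraw <- integer(nOut)
    for (k in unique(cells)) {
      idx <- which(cells == k)
      pr <- applyPenalty(logZ[, k], nEv, l)
      routeDraw[idx] <- sample.int(length(routes), length(idx),
                                   replace = TRUE, prob = pr)
    }
    sumRows[[sid]] <- data.frame(
      segment_id = sid, draw = seq_len(nOut),
      route_id = rownames(logZ)[routeDraw],
      n_pre = vapply(routes, function(r)
        sum(r@params$phase == "pre"), integer(1))[routeDraw],
      n_post = vapply(routes, function(r)
        sum(r@params$phase == "post"), integer(1))[routeDraw],
      n_losses = vapply(routes, function(r) r@nLosses, integer(1))[routeDraw],
      t_w = if (isWgd) twDraws else NA_real_,
      stringsAsFactors = FALSE)
    ## timings: importance-resample stored integration draws per
    ## (route, cell) group, then map uniforms with each draw's WGD time
    for (r in unique(routeDraw)) {
      route <- routes[[r]]
      if (route@nParams == 0L) next
      dd <- which(routeDraw == r)
      picks <- integer(length(dd))
      for (k in unique(cells[dd])) {
        j <- which(cells[dd] == k)
        lw <- ev$LL[[r]][, k]
        w <- exp(lw - max(lw))
        picks[j] <- sample.int(length(w), length(j), replace = TRUE, prob = w)
      }
      Uu <- ev$U[[r]][picks, , drop = FALSE]
      twd <- if (isWgd) twDraws[dd] else rep(NA_real_, length(dd))
      theta <- Uu
      ph <- route@params$phase
      if (any(ph == "pre"))
        theta[, ph == "pre"] <- Uu[, ph == "pre", drop = FALSE] * twd
      if (any(ph == "post"))
        theta[, ph == "post"] <- twd +
          Uu[, ph == "post", drop = FALSE] * (1 - twd)
      gainRows[[length(gainRows) + 1L]] <- data.frame(
        segment_id = sid,
        draw = rep(dd, times = route@nParams),
        route_id = route@label,
        phase = rep(ph, each = length(dd)),
        timing = as.numeric(theta),
        t_w = rep(twd, times = route@nParams),
        stringsAsFactors = FALSE)
    }
  }

  draws <- if (length(gainRows)) do.call(rbind, gainRows) else
    data.frame(segment_id = character(), draw = integer(),
               route_id = character(), phase = character(),
               timing = numeric(), t_w = numeric())
  new("SamplePosterior", sampleId = sampleId(sample),
      cancerType = cancerType(sample), purity = purity(sample),
      wgdStatus = status, segments = segs,
      routeProbs = do.call(rbind, c(rpList, list(make.row.names = FALSE))),
      evidence = evList,
      twGrid = if (isWgd) twCells else numeric(),
      twPosterior = if (isWgd) cellPost else numeric(),
      twDraws = twDraws,
      draws = draws,
      drawSummary = do.call(rbind, c(sumRows, list(make.row.names = FALSE))),
      penalty = l, config = config)
}

## Recompute route probabilities (and the WGD-time posterior) from stored
## evidence curves under a different penalty strength.
.reweightPosterior <- function(post, l) {
  evList <- post@evidence
  if (!length(evList)) return(post@routeProbs)
  rp <- post@routeProbs
  nEvList <- lapply(names(evList), function(sid)
    rp$n_events[rp$segment_id == sid])
  names(nEvList) <- names(evList)
  cellPost <- if (post@wgdStatus == "wgd")
    .twCellPosterior(evList, nEvList, l) else 1
  out <- lapply(names(evList), function(sid) {
    pm <- .marginalRouteProbs(evList[[sid]], nEvList[[sid]], cellPost, l)
    data.frame(segment_id = sid, route_id = rownames(evList[[sid]]),
               n_events = nEvList[[sid]],
               parsimonious = nEvList[[sid]] == min(nEvList[[sid]]),
               prob = pm, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Posterior probability of non-parsimonious route histories
#'
#' For each timed segment, the total posterior mass on routes with more
#' events than the segment's most parsimonious route; plus the cohort
#' average (each gained segment weighted equally) and the distribution of
#' posterior mass over the excess event count.
#'
#' @param posteriors a [SamplePosterior-class] or a list of them.
#' @param penalty \code{NULL} to use each posterior's stored probabilities,
#'   or a penalty strength l to re-apply to the stored evidence curves
#'   (0 disables the penalty).
#' @return list with \code{perSegment} (data.frame), \code{average}
#'   (cohort mean non-parsimony probability) and \code{excessHistogram}
#'   (named vector: mean posterior mass by excess event count).
#' @export
measureNonParsimony <- function(posteriors, penalty = NULL) {
  if (is(posteriors, "SamplePosterior")) posteriors <- list(posteriors)
  segRows <- list()
  for (post in posteriors) {
    rp <- if (is.null(penalty)) post@routeProbs else
      .reweightPosterior(post, penalty)
    if (!nrow(rp)) next
    for (sid in unique(rp$segment_id)) {
      sub <- rp[rp$segment_id == sid, ]
      excess <- sub$n_events - min(sub$n_events)
      segRows[[length(segRows) + 1L]] <- data.frame(
        sample_id = post@sampleId, segment_id = sid,
        p_non_parsimonious = sum(sub$prob[excess > 0]),
        mean_excess = sum(sub$prob * excess),
        stringsAsFactors = FALSE)
      attr(segRows[[length(segRows)]], "excess") <-
        tapply(sub$prob, excess, sum)
    }
  }
  if (!length(segRows))
    return(list(perSegment = data.frame(), average = NA_real_,
                excessHistogram = numeric()))
  perSegment <- do.call(rbind, segRows)
  maxEx <- max(vapply(segRows, function(x)
    max(as.integer(names(attr(x, "excess")))), integer(1)))
  hist <- rep(0, maxEx + 1L)
  names(hist) <- 0:maxEx
  for (x in segRows) {
    e <- attr(x, "excess")
    hist[names(e)] <- hist[names(e)] + e
  }
  list(perSegment = perSegment,
       average = mean(perSegment$p_non_parsimonious),
       excessHistogram = hist / nrow(perSegment))
}

#' Tune the event-count penalty to a target non-parsimony level
#'
#' Bisection on the penalty strength l so that the cohort-average posterior
#' probability of non-parsimonious routes, recomputed from the stored
#' evidence curves, matches \code{target}. Intended for cohorts simulated
#' with exclusively parsimonious histories, where any non-parsimony mass is
#' an artifact of route ambiguity.
#'
#' @param posteriors list of [SamplePosterior-class] (penalty-free
#'   evidence curves are reused; the stored penalty does not matter).
#' @param target desired average non-parsimony probability (default 0.05).
#' @param interval search interval for l.
#' @param tol bisection tolerance on l.
#' @return the tuned penalty strength l.
#' @export
tunePenalty <- function(posteriors, target = 0.05, interval = c(0, 20),
                        tol = 1e-3) {
  f <- function(l) measureNonParsimony(posteriors, penalty = l)$average - target
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) return(lo)
  if (fhi > 0) stop("target non-parsimony unreachable within interval")
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
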