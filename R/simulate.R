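# Tumor simulator: synthetic samples with known gain routes, timings and
# WGD status, and read counts with realistic purity/coverage noise.

#' Simulation configuration
#'
#' Defines the cohort the simulator generates. The defaults describe a
#' mixed cohort of moderately complex clonal gains at the purity and
#' purity-corrected coverage typical of bulk tumor whole genomes.
#'
#' @param nSamples number of tumors.
#' @param segmentsPerSample copy-number segments per tumor.
#' @param states list of \code{c(major, minor)} integer pairs the segment
#'   states are drawn from.
#' @param stateWeights sampling weights over \code{states} (default equal).
#' @param wgdFraction fraction of tumors carrying a WGD.
#' @param twRange WGD times are uniform on this interval.
#' @param parsimoniousOnly restrict generating routes to the most
#'   parsimonious route(s) of each state.
#' @param purityRange tumor purity uniform on this interval.
#' @param rpcRange reads per clonal copy uniform on this interval (5 is the
#'   conventional minimum usable coverage).
#' @param snvRate clonal SNVs per bp per allele copy per unit mutation
#'   time. The default (1e-6 with 20-60 Mb segments) yields on the order of
#'   50-150 SNVs per gained segment.
#' @param segmentBpRange segment lengths uniform on this interval.
#' @param minSnvsPerSegment when positive, segments are re-drawn until they
#'   carry at least this many SNVs (used to emulate cohorts filtered for
#'   timeable segments).
#' @param nChromosomes chromosomes the segments are cycled over.
#' @return named list.
#' @export
simulationConfig <- function(nSamples = 10L, segmentsPerSample = 15L,
                             states = list(c(2L, 1L), c(2L, 2L), c(3L, 1L),
                                           c(3L, 2L), c(4L, 2L), c(4L, 3L)),
                             stateWeights = NULL,
                             wgdFraction = 1, twRange = c(0.2, 0.8),
                             parsimoniousOnly = FALSE,
                             purityRange = c(0.4, 0.9),
                             rpcRange = c(5, 15),
                             snvRate = 1e-6,
                             segmentBpRange = c(2e7, 6e7),
                             minSnvsPerSegment = 0L,
                             nChromosomes = 22L) {
  stopifnot(snvRate > 0, wgdFraction >= 0, wgdFraction <= 1)
  list(nSamples = as.integer(nSamples),
       segmentsPerSample = as.integer(segmentsPerSample),
       states = states,
       stateWeights = stateWeights %||% rep(1, length(states)),
       wgdFraction = wgdFraction, twRange = twRange,
       parsimoniousOnly = parsimoniousOnly,
       purityRange = purityRange, rpcRange = rpcRange,
       snvRate = snvRate, segmentBpRange = segmentBpRange,
       minSnvsPerSegment = as.integer(minSnvsPerSegment),
       nChromosomes = as.integer(nChromosomes))
}

## Edge spans of a route at concrete timings: start, end, lambda.
.edgeSpans <- function(route, theta, twgd) {
  ed <- route@edges
  val <- function(s) {
    if (s == 0L) 0 else if (s == -1L) twgd else if (s == -2L) 1 else theta[s]
  }
  data.frame(start = vapply(ed$start, val, numeric(1)),
             end = vapply(ed$end, val, numeric(1)),
             lambda = ed$lambda)
}

## SNV read counts for one segment given its route realisation.
.simulateSegmentSnvs <- function(route, theta, twgd, bp, totalCn, purity,
                                 rpc, snvRate, minSnvs) {
  spans <- .edgeSpans(route, theta, twgd)
  len <- spans$end - spans$start
  meanDepth <- rpc * (purity * totalCn + 2 * (1 - purity)) / purity
  for (attempt in seq_len(200L)) {
    nPer <- stats::rpois(nrow(spans), snvRate * bp * len)
    if (sum(nPer) >= max(minSnvs, 1L)) break
  }
  if (sum(nPer) < max(minSnvs, 1L))
    stop("simulator could not reach the requested SNV count; raise snvRate")
  m <- rep(spans$lambda, nPer)
  t0 <- rep(spans$start, nPer)
  t1 <- rep(spans$end, nPer)
  n <- length(m)
  depth <- pmax(stats::rpois(n, meanDepth), 1L)
  alt <- stats::rbinom(n, depth, expectedVaf(m, totalCn, purity))
  data.frame(multiplicity = m,
             mutation_time = t0 + stats::runif(n) * (t1 - t0),
             alt_count = alt, total_depth = depth)
}

#' Simulate one tumor sample with known gain history
#'
#' Draws a WGD status and time, per-segment copy-number states, a
#' generating route per segment (uniform over the state's canonical
#' routes, optionally only the most parsimonious), gain times uniform on
#' each route's constrained region, and SNVs as a Poisson process along
#' surviving-lineage branches (rate proportional to branch length and
#' segment size). Each SNV's multiplicity is the surviving-copy count of
#' its branch; read counts follow Poisson depth and binomial alt sampling
#' at the expected VAF.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed; identical seeds give identical samples.
#' @param sampleId identifier for the generated sample.
#' @param wgd force WGD status (\code{NA} = Bernoulli(config$wgdFraction)).
#' @param cancerType label recorded on the sample.
#' @return list with \code{sample} (a [TumorSample-class]) and
#'   \code{truth} (data.frame: one row per segment with the generating
#'   route, sorted gain times, WGD time and status).
#' @export
simulateSample <- function(config = simulationConfig(), seed = 1L,
                           sampleId = "sim1", wgd = NA,
                           cancerType = "simulated") {
  set.seed(seed)
  isWgd <- if (is.na(wgd)) stats::runif(1) < config$wgdFraction else wgd
  twgd <- if (isWgd) stats::runif(1, config$twRange[1], config$twRange[2])
          else NA_real_
  purity <- stats::runif(1, config$purityRange[1], config$purityRange[2])
  rpc <- stats::runif(1, config$rpcRange[1], config$rpcRange[2])
  nSeg <- config$segmentsPerSample
  stateIdx <- sample.int(length(config$states), nSeg, replace = TRUE,
                         prob = config$stateWeights)
  bp <- round(stats::runif(nSeg, config$segmentBpRange[1],
                           config$segmentBpRange[2]))
  chrom <- paste0("chr", (seq_len(nSeg) - 1L) %% config$nChromosomes + 1L)
  ## lay segments end to end per chromosome with a 1 Mb gap
  offset <- integer(nSeg)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    offset[i] <- cumsum(c(1e6, utils::head(bp[i] + 1e6, -1L)))
  }
  segRows <- list(); snvRows <- list(); truthRows <- list()
  for (i in seq_len(nSeg)) {
    st <- config$states[[stateIdx[i]]]
    major <- st[1L]; minor <- st[2L]
    routes <- enumerateRoutes(major, minor, wgd = isWgd, maxRoutes = Inf)
    if (config$parsimoniousOnly) routes <- mostParsimonious(routes)
    route <- routes[[sample.int(length(routes), 1L)]]
    theta <- as.numeric(sampleRouteTimings(route, 1L, twgd))
    sid <- sprintf("seg%03d", i)
    segRows[[i]] <- data.frame(chrom = chrom[i], start = offset[i],
                               end = offset[i] + bp[i] - 1L,
                               major_cn = major, minor_cn = minor,
                               segment_id = sid)
    if (major >= 1L && (major + minor) >= 1L) {
      sv <- .simulateSegmentSnvs(route, theta, twgd, bp[i], major + minor,
                                 purity, rpc, config$snvRate,
                                 config$minSnvsPerSegment)
      if (nrow(sv)) {
        sv$chrom <- chrom[i]
        sv$pos <- offset[i] + sort(sample.int(bp[i], nrow(sv)))
        snvRows[[length(snvRows) + 1L]] <- sv
      }
    }
    ph <- route@params$phase
    truthRows[[i]] <- data.frame(
      sample_id = sampleId, segment_id = sid,
      major_cn = major, minor_cn = minor, bp = bp[i],
      route_id = route@label, n_events = route@nEvents,
      n_gains = route@nParams,
      gain_times = paste(sprintf("%.6f", sort(theta)), collapse = ","),
      gain_phases = paste(ph[order(theta)], collapse = ","),
      gain_times_param = paste(sprintf("%.10f", theta), collapse = ","),
      t_w = twgd, wgd = isWgd, stringsAsFactors = FALSE)
  }
  segdf <- do.call(rbind, segRows)
  segments <- GenomicRanges::GRanges(
    segdf$chrom, IRanges::IRanges(segdf$start, segdf$end),
    major_cn = segdf$major_cn, minor_cn = segdf$minor_cn,
    segment_id = segdf$segment_id)
  snvdf <- if (length(snvRows)) do.call(rbind, snvRows) else
    data.frame(chrom = character(), pos = integer(), alt_count = integer(),
               total_depth = integer(), multiplicity = integer(),
               mutation_time = numeric())
  snvGr <- GenomicRanges::GRanges(
    snvdf$chrom, IRanges::IRanges(snvdf$pos, width = 1L),
    alt_count = snvdf$alt_count, total_depth = snvdf$total_depth,
    clonal = rep(TRUE, nrow(snvdf)), kataegis = rep(FALSE, nrow(snvdf)),
    true_multiplicity = snvdf$multiplicity,      # ground-truth annotation
    true_time = snvdf$mutation_time)
  sample <- suppressWarnings(TumorSample(
    sampleId = sampleId, segments = segments, snvs = snvGr,
    purity = purity, cancerType = cancerType,
    wgdStatus = if (isWgd) "wgd" else "non_wgd"))
  truth <- do.call(rbind, truthRows)
  truth$purity <- purity
  truth$reads_per_clonal_copy <- rpc
  list(sample = sample, truth = truth)
}

#' Simulate a cohort
#'
#' @param config a [simulationConfig()].
#' @param seed root seed; per-sample seeds are derived from it.
#' @param cancerTypes optional vector of labels recycled over samples
#'   (cohort analyses stratify by cancer type).
#' @param wgd optional logical vector forcing per-sample WGD status.
#' @return list with \code{samples} (list of [TumorSample-class]) and
#'   \code{truth} (combined data.frame).
#' @export
simulateCohort <- function(config = simulationConfig(), seed = 1L,
                           cancerTypes = "simulated", wgd = NULL) {
  n <- config$nSamples
  ct <- rep_len(cancerTypes, n)
  samples <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    res <- simulateSample(config, seed = deriveSeed(seed, i),
                          sampleId = sprintf("sim%03d", i),
                          wgd = if (is.null(wgd)) NA else wgd[i],
                          cancerType = ct[i])
    samples[[i]] <- res$sample
    truths[[i]] <- res$truth
  }
  list(samples = samples, truth = do.call(rbind, truths))
}

#' Simulate a cohort restricted to parsimonious histories
#'
#' Convenience wrapper over [simulateCohort()] with
#' \code{parsimoniousOnly = TRUE}; the cohort used to calibrate the
#' event-count penalty.
#'
#' @inheritParams simulateCohort
#' @return as [simulateCohort()].
#' @export
simulateParsimoniousCohort <- function(config = simulationConfig(),
                                       seed = 1L,
                                       cancerTypes = "simulated") {
  config$parsimoniousOnly <- TRUE
  simulateCohort(config, seed = seed, cancerTypes = cancerTypes)
}
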