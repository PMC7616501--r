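# Pre- vs post-WGD copy-number event landscapes at arm and fine (kb)
# resolution.

#' Correct the post-WGD loss frequency for mutual exclusivity
#'
#' A pre-WGD loss (minor copy number 0) and a post-WGD loss (minor copy
#' number 1) cannot both be observed for the same region of the same
#' sample, so the raw post-WGD loss proportion understates the rate among
#' samples that could still show one. The corrected proportion divides by
#' one minus the pre-WGD loss proportion, with the pre-WGD proportion
#' clipped at 0.95 to avoid division by ~zero in small cohorts.
#'
#' @param pre pre-WGD loss proportion(s) in `[0, 1]`.
#' @param post post-WGD loss proportion(s) in `[0, 1]`.
#' @return corrected post-WGD loss proportion(s).
#' @examples
#' correctedPostWgdLoss(0.5, 0.25)  # 0.5
#' correctedPostWgdLoss(0, 0.3)     # 0.3
#' @export
correctedPostWgdLoss <- function(pre, post) {
  stopifnot(all(pre >= 0 & pre <= 1), all(post >= 0 & post <= 1))
  post / (1 - pmin(pre, 0.95))
}

## Per-segment event classification of one WGD sample: a segment is
## pre-/post-WGD gained when at least `drawFraction` of its joint draws
## place >= 1 independent-or-WGD-independent gain on that side; losses come
## from the minor copy number.
.segmentEventClasses <- function(post, drawFraction = 0.5) {
  seg <- post@segments
  ds <- post@drawSummary
  out <- data.frame(segment_id = seg$segment_id, chrom = seg$chrom,
                    start = seg$start, end = seg$end, bp = seg$bp,
                    pre_gain = FALSE, post_gain = FALSE,
                    pre_loss = seg$minor_cn == 0L,
                    post_loss = seg$minor_cn == 1L,
                    stringsAsFactors = FALSE)
  if (nrow(ds)) {
    fracPre <- tapply(ds$n_pre >= 1L, ds$segment_id, mean)
    fracPost <- tapply(ds$n_post >= 1L, ds$segment_id, mean)
    i <- match(names(fracPre), out$segment_id)
    out$pre_gain[i] <- fracPre >= drawFraction
    out$post_gain[i] <- fracPost >= drawFraction
  }
  out
}

.classGRanges <- function(cls, what) {
  sub <- cls[cls[[what]], , drop = FALSE]
  GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$start, sub$end))
}

#' Build a chromosome-arm table from segment extents
#'
#' Synthetic arm coordinates for simulated genomes: each chromosome's
#' covered extent is split at a fixed fraction into a p and a q arm. Real
#' analyses should supply a cytoband-derived table instead.
#'
#' @param posteriors list of [SamplePosterior-class] (their segments define
#'   the covered extent).
#' @param centromereFraction where to split each chromosome (default 0.5).
#' @return data.frame with columns \code{chrom}, \code{arm}, \code{start},
#'   \code{end}.
#' @export
makeArmTable <- function(posteriors, centromereFraction = 0.5) {
  segs <- do.call(rbind, lapply(posteriors, function(p)
    p@segments[, c("chrom", "start", "end")]))
  rows <- lapply(split(segs, segs$chrom), function(s) {
    lo <- min(s$start); hi <- max(s$end)
    mid <- floor(lo + (hi - lo) * centromereFraction)
    data.frame(chrom = s$chrom[1L], arm = c("p", "q"),
               start = c(lo, mid + 1), end = c(mid, hi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$end >= out$start, ]
}

#' Arm-level pre- and post-WGD event rates
#'
#' An arm counts as pre-(post-)WGD gained in a WGD tumor when at least
#' \code{armFraction} of its base pairs lie in segments classified as
#' pre-(post-)WGD gained (at least half of the posterior draws placing a
#' gain on that side), and as pre-(post-)WGD lost when at least
#' \code{armFraction} of the arm has minor copy number 0 (1). Frequencies
#' are tabulated per cancer type, and the post-WGD loss frequency is also
#' reported with the mutual-exclusivity correction.
#'
#' @param posteriors list of [SamplePosterior-class]; non-WGD samples are
#'   skipped.
#' @param armTable data.frame \code{chrom}, \code{arm}, \code{start},
#'   \code{end} (see [makeArmTable()]).
#' @param armFraction bp fraction threshold (default 0.5).
#' @param drawFraction posterior draw fraction for segment gain classes.
#' @return data.frame per (cancer type, arm): event frequencies,
#'   \code{post_loss_corrected} and \code{n_samples}.
#' @export
armEventRates <- function(posteriors, armTable, armFraction = 0.5,
                          drawFraction = 0.5) {
  posteriors <- Filter(.isWgdPost, posteriors)
  if (!length(posteriors)) stop("no WGD samples")
  armGr <- GenomicRanges::GRanges(armTable$chrom,
                                  IRanges::IRanges(armTable$start,
                                                   armTable$end))
  armBp <- GenomicRanges::width(armGr)
  events <- c("pre_gain", "post_gain", "pre_loss", "post_loss")
  rows <- list()
  for (post in posteriors) {
    cls <- .segmentEventClasses(post, drawFraction)
    ## bp of each arm covered by event segments, per event type
    ovBp <- vapply(events, function(ev) {
      gr <- GenomicRanges::reduce(.classGRanges(cls, ev))
      hits <- GenomicRanges::findOverlaps(armGr, gr)
      w <- GenomicRanges::width(IRanges::pintersect(
        armGr[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
      out <- rep(0, length(armGr))
      if (length(hits)) {
        s <- rowsum(w, S4Vectors::queryHits(hits))
        out[as.integer(rownames(s))] <- s[, 1L]
      }
      out
    }, numeric(length(armGr)))
    ovBp <- matrix(ovBp, nrow = length(armGr),
                   dimnames = list(NULL, events))
    called <- ovBp / armBp >= armFraction
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sampleId(post), cancer_type = cancerType(post),
      chrom = armTable$chrom, arm = armTable$arm, called,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(df, list(df$cancer_type, df$chrom, df$arm), drop = TRUE),
    function(g) data.frame(
      cancer_type = g$cancer_type[1L], chrom = g$chrom[1L], arm = g$arm[1L],
      pre_gain = mean(g$pre_gain), post_gain = mean(g$post_gain),
      pre_loss = mean(g$pre_loss), post_loss = mean(g$post_loss),
      n_samples = nrow(g))))
  agg$post_loss_corrected <- correctedPostWgdLoss(agg$pre_loss, agg$post_loss)
  rownames(agg) <- NULL
  agg
}

#' Pan-genome pre- and post-WGD event landscape
#'
#' Event proportions across WGD tumors in fixed-width bins over the
#' genome covered by the cohort's segments: for each bin, the fraction of
#' samples whose pre-/post-WGD gain or loss segments overlap it. The
#' post-WGD loss track is also corrected for mutual exclusivity (0.95
#' clip), and each track is additionally returned normalised so its
#' integral over the genome equals 1e9, giving relative rates of magnitude
#' about one that can be compared between tracks.
#'
#' @param posteriors list of [SamplePosterior-class]; non-WGD skipped.
#' @param resolution bin width in bp (default 1000).
#' @param drawFraction posterior draw fraction for segment gain classes.
#' @param method \code{"stream"} accumulates per-sample coverage vectors;
#'   \code{"matrix"} materialises the samples x bins indicator matrix.
#'   Both give identical results.
#' @return list with \code{bins} (\code{GRanges}) and \code{table}
#'   (data.frame of raw, corrected and normalised proportions per bin).
#' @export
panGenomeLandscape <- function(posteriors, resolution = 1000L,
                               drawFraction = 0.5,
                               method = c("stream", "matrix")) {
  method <- match.arg(method)
  posteriors <- Filter(.isWgdPost, posteriors)
  if (!length(posteriors)) stop("no WGD samples")
  allSeg <- do.call(rbind, lapply(posteriors, function(p)
    p@segments[, c("chrom", "start", "end")]))
  extent <- GenomicRanges::reduce(GenomicRanges::GRanges(
    allSeg$chrom, IRanges::IRanges(allSeg$start, allSeg$end)))
  bins <- unlist(GenomicRanges::tile(extent, width = resolution))
  events <- c("pre_gain", "post_gain", "pre_loss", "post_loss")
  n <- length(posteriors)
  clsList <- lapply(posteriors, .segmentEventClasses, drawFraction)
  prop <- matrix(0, length(bins), length(events),
                 dimnames = list(NULL, events))
  if (method == "stream") {
    for (cls in clsList)
      for (ev in events)
        prop[, ev] <- prop[, ev] +
          IRanges::overlapsAny(bins, .classGRanges(cls, ev))
    prop <- prop / n
  } else {
    for (ev in events) {
      M <- vapply(clsList, function(cls)
        IRanges::overlapsAny(bins, .classGRanges(cls, ev)),
        logical(length(bins)))
      prop[, ev] <- rowMeans(matrix(M, nrow = length(bins)))
    }
  }
  tab <- as.data.frame(prop)
  tab$post_loss_corrected <- correctedPostWgdLoss(tab$pre_loss,
                                                  tab$post_loss)
  w <- GenomicRanges::width(bins)
  for (cn in colnames(tab)) {
    integ <- sum(tab[[cn]] * w)
    tab[[paste0(cn, "_norm")]] <- if (integ > 0) tab[[cn]] * 1e9 / integ
                                  else tab[[cn]]
  }
  tab$chrom <- as.character(GenomicRanges::seqnames(bins))
  tab$start <- GenomicRanges::start(bins)
  tab$end <- GenomicRanges::end(bins)
  list(bins = bins, table = tab)
}
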