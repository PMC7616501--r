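#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

#' Clonal tumor sample: copy-number segments, SNVs and metadata
#'
#' Container for the per-sample inputs of gain timing: clonal
#' allele-specific copy-number segments, clonal somatic SNVs with read
#' counts, tumor purity and a cancer-type label. SNVs are assigned to at
#' most one segment at construction time and sorted by genomic position so
#' that all downstream computations are independent of input order.
#'
#' @slot sampleId single sample identifier.
#' @slot purity tumor cell fraction in (0, 1].
#' @slot cancerType cancer-type label used by cohort analyses.
#' @slot segments \code{GRanges} with integer (or real, before rounding)
#'   metadata columns \code{major_cn} and \code{minor_cn} and a unique
#'   \code{segment_id}.
#' @slot snvs \code{GRanges} of width-1 SNV positions with metadata columns
#'   \code{alt_count}, \code{total_depth}, \code{clonal}, \code{kataegis}
#'   and the assigned \code{segment_id} (\code{NA} when outside all
#'   segments).
#' @slot wgdStatus one of \code{"wgd"}, \code{"non_wgd"}, \code{"unknown"},
#'   \code{"ambiguous_multi"}.
#'
#' @export
setClass("TumorSample", representation(
  sampleId = "character",
  purity = "numeric",
  cancerType = "character",
  segments = "GRanges",
  snvs = "GRanges",
  wgdStatus = "character"
))

setValidity("TumorSample", function(object) {
  msg <- character()
  if (length(object@purity) != 1L || is.na(object@purity) ||
      object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be a single value in (0, 1]")
  seg <- object@segments
  if (length(seg)) {
    mc <- S4Vectors::mcols(seg)
    if (!all(c("major_cn", "minor_cn", "segment_id") %in% colnames(mc))) {
      msg <- c(msg, "segments need major_cn, minor_cn and segment_id columns")
    } else {
      if (any(mc$minor_cn < 0) || any(mc$major_cn < mc$minor_cn))
        msg <- c(msg, "segments require major_cn >= minor_cn >= 0")
      if (anyDuplicated(mc$segment_id))
        msg <- c(msg, "segment_id must be unique")
      ov <- GenomicRanges::findOverlaps(seg, seg)
      if (length(ov) > length(seg))
        msg <- c(msg, "segments must be non-overlapping within a chromosome")
    }
  }
  snv <- object@snvs
  if (length(snv)) {
    mc <- S4Vectors::mcols(snv)
    if (!all(c("alt_count", "total_depth") %in% colnames(mc))) {
      msg <- c(msg, "snvs need alt_count and total_depth columns")
    } else if (any(mc$total_depth < 1) || any(mc$alt_count < 0) ||
               any(mc$alt_count > mc$total_depth)) {
      msg <- c(msg, "snvs require 0 <= alt_count <= total_depth, depth >= 1")
    }
  }
  if (!object@wgdStatus %in% c("wgd", "non_wgd", "unknown", "ambiguous_multi"))
    msg <- c(msg, "invalid wgdStatus")
  if (length(msg)) msg else TRUE
})

#' One candidate gain-route history for a copy-number state
#'
#' A route is a pair of per-parental-allele gain trees, each describing the
#' surviving-lineage duplication history that produces the observed allele
#' copy number, with at most one whole-genome duplication (WGD) shared by
#' both alleles. Internal nodes are independent gains (pre- or post-WGD) or
#' the WGD itself; lineages that cross the WGD without a surviving doubled
#' copy imply one loss each. Lost lineages are not represented as branches:
#' only their event count is retained, because loss times are
#' unidentifiable from SNV multiplicities.
#'
#' @slot label canonical route identifier (serialised unordered trees).
#' @slot majorCn,minorCn the final allele-specific copy-number state.
#' @slot wgd whether the route contains a WGD.
#' @slot nGainsPre,nGainsPost counts of independent gains before/after the
#'   WGD (all gains count as \code{nGainsPre} with phase \code{"free"} in
#'   non-WGD routes).
#' @slot nLosses implied losses (minimal placement).
#' @slot nEvents total events: gains + losses + (1 if WGD).
#' @slot nParams number of free timing parameters (independent gains).
#' @slot params data.frame with columns \code{id}, \code{phase}
#'   (\code{"pre"}, \code{"post"} or \code{"free"}) and \code{parent}
#'   (id of the nearest same-phase ancestor gain, or 0).
#' @slot edges data.frame of surviving-lineage tree edges with symbolic
#'   endpoints (\code{0} = time 0, \code{-1} = WGD time, \code{-2} = time 1,
#'   positive = parameter id) and \code{lambda}, the number of surviving
#'   final copies descending through the edge (the SNV multiplicity its
#'   mutations end up with).
#'
#' @export
setClass("GainRoute", representation(
  label = "character",
  majorCn = "integer",
  minorCn = "integer",
  wgd = "logical",
  nGainsPre = "integer",
  nGainsPost = "integer",
  nLosses = "integer",
  nEvents = "integer",
  nParams = "integer",
  params = "data.frame",
  edges = "data.frame"
))

#' Joint posterior over routes, gain times and WGD time for one sample
#'
#' Produced by [sampleJointPosterior()]. Holds, per timed segment, the
#' marginal route probabilities (with and without the event-count penalty),
#' the Monte-Carlo evidence curves over the WGD-time grid (so penalties can
#' be re-applied without re-running inference), and joint posterior draws
#' of (route, gain times, WGD time).
#'
#' @slot sampleId,cancerType,purity,wgdStatus sample metadata.
#' @slot segments data.frame of all gained segments considered, with bp
#'   lengths, SNV counts, and skip reasons for untimed segments.
#' @slot routeProbs data.frame: \code{segment_id}, \code{route_id},
#'   \code{n_events}, \code{parsimonious}, \code{prob} (under the
#'   configured penalty) and \code{prob_no_penalty}.
#' @slot evidence named list (by segment_id) of log-evidence matrices,
#'   routes x WGD-time grid cells (single column for non-WGD samples).
#' @slot twGrid centers of the WGD-time grid cells (length 0 for non-WGD).
#' @slot twPosterior posterior probability of each grid cell.
#' @slot twDraws posterior draws of the shared WGD time (length 0 for
#'   non-WGD samples).
#' @slot draws long-format data.frame of posterior draws: one row per
#'   independent gain per draw (\code{segment_id}, \code{draw},
#'   \code{route_id}, \code{phase}, \code{timing}, \code{t_w}).
#' @slot drawSummary one row per (segment, draw): route and pre/post gain
#'   counts.
#' @slot penalty penalty strength used for \code{prob} (0 = disabled).
#' @slot config the timing configuration used.
#'
#' @export
setClass("SamplePosterior", representation(
  sampleId = "character",
  cancerType = "character",
  purity = "numeric",
  wgdStatus = "character",
  segments = "data.frame",
  routeProbs = "data.frame",
  evidence = "list",
  twGrid = "numeric",
  twPosterior = "numeric",
  twDraws = "numeric",
  draws = "data.frame",
  drawSummary = "data.frame",
  penalty = "numeric",
  config = "list"
))

#' Whole-genome duplication call for one sample
#'
#' @slot sampleId sample identifier.
#' @slot status \code{"wgd"}, \code{"non_wgd"}, \code{"ambiguous_multi"}
#'   (major copy-number mode of three or more),
#'   \code{"insufficient_overlap"} (mode two but synchronous-gain support
#'   below the overlap threshold; treated as non-WGD downstream) or
#'   \code{"insufficient_data"} (mode two but no timeable mode-two
#'   segments).
#' @slot majorMode bp-weighted modal major copy number.
#' @slot overlapFraction fraction of major-copy-number-two base pairs whose
#'   90 percent credible gain-timing intervals overlap a single time point.
#' @slot wgdTime the time point of maximal overlap (NA unless mode is two).
#' @slot segmentTable per-segment timing intervals used for the call.
#'
#' @export
setClass("WgdCall", representation(
  sampleId = "character",
  status = "character",
  majorMode = "integer",
  overlapFraction = "numeric",
  wgdTime = "numeric",
  segmentTable = "data.frame"
))
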