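# Accessor generics and show() methods for the package's S4 classes.

#' @rdname TumorSample-class
#' @param object a package object.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname TumorSample-class
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))
#' @rdname TumorSample-class
#' @export
setGeneric("cancerType", function(object) standardGeneric("cancerType"))
#' @rdname TumorSample-class
#' @export
setGeneric("cnSegments", function(object) standardGeneric("cnSegments"))
#' @rdname TumorSample-class
#' @export
setGeneric("snvs", function(object) standardGeneric("snvs"))
#' @rdname TumorSample-class
#' @export
setGeneric("wgdStatus", function(object) standardGeneric("wgdStatus"))
#' @rdname TumorSample-class
#' @param value replacement value.
#' @export
setGeneric("wgdStatus<-", function(object, value) standardGeneric("wgdStatus<-"))
#' @rdname TumorSample-class
#' @export
setGeneric("tumorPloidy", function(object) standardGeneric("tumorPloidy"))

#' @rdname TumorSample-class
#' @export
setMethod("sampleId", "TumorSample", function(object) object@sampleId)
#' @rdname TumorSample-class
#' @export
setMethod("purity", "TumorSample", function(object) object@purity)
#' @rdname TumorSample-class
#' @export
setMethod("cancerType", "TumorSample", function(object) object@cancerType)
#' @rdname TumorSample-class
#' @export
setMethod("cnSegments", "TumorSample", function(object) object@segments)
#' @rdname TumorSample-class
#' @export
setMethod("snvs", "TumorSample", function(object) object@snvs)
#' @rdname TumorSample-class
#' @export
setMethod("wgdStatus", "TumorSample", function(object) object@wgdStatus)
#' @rdname TumorSample-class
#' @export
setMethod("wgdStatus<-", "TumorSample", function(object, value) {
  object@wgdStatus <- value
  validObject(object)
  object
})

#' @rdname TumorSample-class
#' @export
setMethod("tumorPloidy", "TumorSample", function(object) {
  seg <- object@segments
  if (!length(seg)) return(NA_real_)
  mc <- S4Vectors::mcols(seg)
  w <- GenomicRanges::width(seg)
  sum(w * (mc$major_cn + mc$minor_cn)) / sum(w)
})

setMethod("show", "TumorSample", function(object) {
  cat("TumorSample", object@sampleId,
      sprintf("(%s, purity %.2f, WGD status: %s)\n",
              object@cancerType, object@purity, object@wgdStatus))
  cat(" ", length(object@segments), "copy-number segments;",
      length(object@snvs), "SNVs (",
      sum(!is.na(S4Vectors::mcols(object@snvs)$segment_id)),
      "assigned to segments )\n")
  if (length(object@segments))
    cat(sprintf("  bp-weighted ploidy: %.2f\n", tumorPloidy(object)))
})

#' @rdname GainRoute-class
#' @param object a \code{GainRoute}.
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname GainRoute-class
#' @export
setMethod("nEvents", "GainRoute", function(object) object@nEvents)
#' @rdname GainRoute-class
#' @export
setGeneric("routeId", function(object) standardGeneric("routeId"))
#' @rdname GainRoute-class
#' @export
setMethod("routeId", "GainRoute", function(object) object@label)

setMethod("show", "GainRoute", function(object) {
  cat(sprintf("GainRoute %d+%d%s: %s\n", object@majorCn, object@minorCn,
              if (object@wgd) " (WGD)" else "", object@label))
  cat(sprintf("  %d pre-WGD gain(s), %d post-WGD gain(s), %d loss(es); %d event(s)\n",
              object@nGainsPre, object@nGainsPost, object@nLosses,
              object@nEvents))
})

#' @rdname SamplePosterior-class
#' @param object a \code{SamplePosterior}.
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))
#' @rdname SamplePosterior-class
#' @export
setMethod("posteriorDraws", "SamplePosterior", function(object) object@draws)
#' @rdname SamplePosterior-class
#' @export
setGeneric("routeProbabilities", function(object) standardGeneric("routeProbabilities"))
#' @rdname SamplePosterior-class
#' @export
setMethod("routeProbabilities", "SamplePosterior", function(object) object@routeProbs)
#' @rdname SamplePosterior-class
#' @export
setGeneric("wgdTimeDraws", function(object) standardGeneric("wgdTimeDraws"))
#' @rdname SamplePosterior-class
#' @export
setMethod("wgdTimeDraws", "SamplePosterior", function(object) object@twDraws)
#' @rdname SamplePosterior-class
#' @export
setMethod("sampleId", "SamplePosterior", function(object) object@sampleId)
#' @rdname SamplePosterior-class
#' @export
setMethod("wgdStatus", "SamplePosterior", function(object) object@wgdStatus)
#' @rdname SamplePosterior-class
#' @export
setMethod("cancerType", "SamplePosterior", function(object) object@cancerType)

setMethod("show", "SamplePosterior", function(object) {
  timed <- sum(object@segments$timed)
  cat("SamplePosterior", object@sampleId,
      sprintf("(%s)\n", object@wgdStatus))
  cat(" ", timed, "timed segment(s) of", nrow(object@segments),
      "gained; penalty l =", object@penalty, "\n")
  if (length(object@twDraws))
    cat(sprintf("  WGD time posterior median: %.3f\n",
                stats::median(object@twDraws)))
})

setMethod("show", "WgdCall", function(object) {
  cat("WgdCall", object@sampleId, ":", object@status, "\n")
  cat("  major copy-number mode:", object@majorMode,
      sprintf("; overlap fraction %.2f", object@overlapFraction))
  if (!is.na(object@wgdTime))
    cat(sprintf("; overlap time %.3f", object@wgdTime))
  cat("\n")
})
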