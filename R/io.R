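# Readers, writers, preprocessing filters, and the TumorSample constructor.

#' Construct a TumorSample
#'
#' Assembles segments, SNVs and metadata into a validated
#' [TumorSample-class]. SNVs are assigned to the unique overlapping segment
#' (segments are non-overlapping) and sorted by genomic position, so every
#' downstream result is invariant to SNV input order. SNVs lacking a
#' \code{clonal} flag default to clonal with a warning; missing
#' \code{kataegis} flags default to \code{FALSE}.
#'
#' @param sampleId sample identifier.
#' @param segments \code{GRanges} (from [readSegments()]) with integer
#'   \code{major_cn}/\code{minor_cn}; use [roundToClonal()] first when the
#'   caller's copy numbers are real-valued.
#' @param snvs \code{GRanges} of SNVs (from [readSnvTable()] or
#'   [readSnvVcf()]).
#' @param purity tumor purity in (0, 1].
#' @param cancerType cancer-type label.
#' @param wgdStatus prior WGD status, default \code{"unknown"}.
#' @param excludeKataegis,clonalOnly filters applied via [filterSnvs()].
#' @return a [TumorSample-class].
#' @export
TumorSample <- function(sampleId, segments, snvs, purity,
                        cancerType = "unknown", wgdStatus = "unknown",
                        excludeKataegis = TRUE, clonalOnly = TRUE) {
  mc <- S4Vectors::mcols(segments)
  if (is.null(mc$segment_id))
    S4Vectors::mcols(segments)$segment_id <- sprintf("seg%03d", seq_along(segments))
  if (!all(S4Vectors::mcols(segments)$major_cn %% 1 == 0))
    stop("segments carry non-integer copy numbers; apply roundToClonal() first")
  S4Vectors::mcols(segments)$major_cn <-
    as.integer(S4Vectors::mcols(segments)$major_cn)
  S4Vectors::mcols(segments)$minor_cn <-
    as.integer(S4Vectors::mcols(segments)$minor_cn)
  mcS <- S4Vectors::mcols(snvs)
  if (is.null(mcS$clonal)) {
    if (length(snvs))
      warning("SNVs carry no clonal flag; assuming all clonal")
    S4Vectors::mcols(snvs)$clonal <- rep(TRUE, length(snvs))
  }
  if (is.null(S4Vectors::mcols(snvs)$kataegis))
    S4Vectors::mcols(snvs)$kataegis <- rep(FALSE, length(snvs))
  snvs <- filterSnvs(snvs, excludeKataegis = excludeKataegis,
                     clonalOnly = clonalOnly)
  snvs <- GenomicRanges::sort(snvs)
  hits <- GenomicRanges::findOverlaps(snvs, segments)
  segId <- rep(NA_character_, length(snvs))
  segId[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(segments)$segment_id[S4Vectors::subjectHits(hits)]
  S4Vectors::mcols(snvs)$segment_id <- segId
  new("TumorSample", sampleId = sampleId, purity = purity,
      cancerType = cancerType, segments = segments, snvs = snvs,
      wgdStatus = wgdStatus)
}

#' Read allele-specific copy-number segments from TSV
#'
#' Expects a header with columns \code{chrom}, \code{start}, \code{end},
#' \code{major_cn}, \code{minor_cn}; copy numbers may be real-valued
#' (round later with [roundToClonal()]). Both common coordinate dialects
#' are accepted and normalised to the 1-based inclusive convention of
#' \code{GRanges}, so a 1-based row \code{(1, 1000)} and a 0-based
#' half-open row \code{(0, 1000)} describe the same 1000 bp.
#'
#' @param path TSV file path.
#' @param dialect coordinate dialect of the file.
#' @return \code{GRanges} with \code{major_cn}, \code{minor_cn},
#'   \code{segment_id} metadata, in file order.
#' @export
readSegments <- function(path,
                         dialect = c("one_based_inclusive",
                                     "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "major_cn", "minor_cn")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("segment file is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("empty segment file: ", path)
    return(GenomicRanges::GRanges(major_cn = numeric(), minor_cn = numeric(),
                                  segment_id = character()))
  }
  start1 <- if (dialect == "one_based_inclusive") df$start else df$start + 1L
  end1 <- df$end
  bad <- which(start1 > end1)
  if (length(bad))
    stop("segment row ", bad[1L], ": start >= end after normalisation")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = start1, end = end1),
    major_cn = df$major_cn, minor_cn = df$minor_cn,
    segment_id = if (!is.null(df$segment_id)) df$segment_id else
      sprintf("seg%03d", seq_len(nrow(df))))
}

#' Write segments to TSV
#'
#' Inverse of [readSegments()]: \code{readSegments(writeSegments(x))} is
#' the identity on normalised records.
#'
#' @param segments \code{GRanges} of segments.
#' @param path output path.
#' @param dialect coordinate dialect to emit.
#' @return the path, invisibly.
#' @export
writeSegments <- function(segments, path,
                          dialect = c("one_based_inclusive",
                                      "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  mc <- S4Vectors::mcols(segments)
  s <- GenomicRanges::start(segments)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(segments)),
    start = if (dialect == "one_based_inclusive") s else s - 1L,
    end = GenomicRanges::end(segments),
    major_cn = mc$major_cn, minor_cn = mc$minor_cn,
    segment_id = mc$segment_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Round real-valued allele copy numbers to clonal integers
#'
#' Each parental allele is rounded to the nearest integer independently;
#' exact half-integers round to the nearest even integer (deterministic and
#' unbiased).
#'
#' @param segments \code{GRanges} with real-valued \code{major_cn},
#'   \code{minor_cn}.
#' @return the same \code{GRanges} with integer copy numbers; major/minor
#'   are re-ordered where rounding inverts them.
#' @export
roundToClonal <- function(segments) {
  mc <- S4Vectors::mcols(segments)
  if (any(mc$major_cn < 0) || any(mc$minor_cn < 0))
    stop("negative copy numbers")
  a <- as.integer(round(mc$major_cn))
  b <- as.integer(round(mc$minor_cn))
  S4Vectors::mcols(segments)$major_cn <- pmax(a, b)
  S4Vectors::mcols(segments)$minor_cn <- pmin(a, b)
  segments
}

#' Reads per clonal tumor copy
#'
#' Purity-corrected sequencing coverage: the expected number of reads
#' covering one clonal tumor chromosome copy,
#' \code{meanDepth * purity / (purity * ploidy + 2 * (1 - purity))}.
#' Samples below 5 are conventionally excluded from timing.
#'
#' @param meanDepth mean sequencing depth of the sample.
#' @param purity tumor purity in (0, 1].
#' @param ploidy bp-weighted mean tumor copy number (see [tumorPloidy()]).
#' @return reads per clonal copy.
#' @examples
#' readsPerClonalCopy(60, 1, 2)      # 30
#' readsPerClonalCopy(60, 0.5, 4)    # 10
#' @export
readsPerClonalCopy <- function(meanDepth, purity, ploidy) {
  stopifnot(meanDepth > 0, purity > 0, purity <= 1, ploidy > 0)
  meanDepth * purity / (purity * ploidy + 2 * (1 - purity))
}

#' Filter SNVs on kataegis and clonality flags
#'
#' @param snvs \code{GRanges} (or data.frame) of SNVs with logical
#'   \code{kataegis} and \code{clonal} columns; absent columns are treated
#'   as all-\code{FALSE} / all-clonal.
#' @param excludeKataegis drop kataegis-flagged records (localised
#'   hypermutation violates the uniform-rate assumption of mutation time).
#' @param clonalOnly drop subclonal records.
#' @return the filtered object.
#' @export
filterSnvs <- function(snvs, excludeKataegis = TRUE, clonalOnly = TRUE) {
  mc <- if (is(snvs, "GRanges")) S4Vectors::mcols(snvs) else snvs
  keep <- rep(TRUE, NROW(mc))
  if (excludeKataegis && !is.null(mc$kataegis))
    keep <- keep & !mc$kataegis
  if (clonalOnly && !is.null(mc$clonal))
    keep <- keep & mc$clonal
  snvs[keep, ]
}

#' Read SNVs from TSV
#'
#' Expects columns \code{chrom}, \code{pos}, \code{alt_count},
#' \code{total_depth}, optionally \code{clonal} and \code{kataegis}.
#'
#' @param path TSV file path.
#' @return width-1 \code{GRanges} of SNVs.
#' @export
readSnvTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "alt_count", "total_depth")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("SNV file is missing column(s): ", paste(miss, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                               alt_count = df$alt_count,
                               total_depth = df$total_depth)
  if (!is.null(df$clonal)) S4Vectors::mcols(gr)$clonal <- as.logical(df$clonal)
  if (!is.null(df$kataegis))
    S4Vectors::mcols(gr)$kataegis <- as.logical(df$kataegis)
  gr
}

#' Read SNVs from a VCF
#'
#' Uses \pkg{VariantAnnotation} when available. Alt and total read counts
#' are taken from the \code{AD} genotype field, or reconstructed from
#' \code{AF x DP} when \code{AD} is absent.
#'
#' @param path VCF file path.
#' @param sampleName genotype column to use (default: first).
#' @return width-1 \code{GRanges} of SNVs.
#' @export
readSnvVcf <- function(path, sampleName = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readSnvVcf() needs the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)
  j <- if (is.null(sampleName)) 1L else match(sampleName, colnames(vcf))
  rr <- SummarizedExperiment::rowRanges(vcf)
  if ("AD" %in% names(gt)) {
    ad <- gt$AD[, j]
    alt <- vapply(ad, function(x) as.numeric(x[2L]), numeric(1))
    tot <- vapply(ad, function(x) sum(as.numeric(x)), numeric(1))
  } else if (all(c("AF", "DP") %in% names(gt))) {
    tot <- as.numeric(gt$DP[, j])
    alt <- round(as.numeric(unlist(gt$AF[, j])) * tot)
  } else stop("VCF carries neither AD nor AF+DP genotype fields")
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(rr),
    IRanges::IRanges(GenomicRanges::start(rr), width = 1L),
    alt_count = alt, total_depth = tot)
}

#' Export posterior draws as a long-format table
#'
#' One row per independent gain per joint posterior draw, plus one row per
#' draw for the WGD event of WGD samples.
#'
#' @param posterior a [SamplePosterior-class].
#' @param path optional TSV output path.
#' @return the data.frame (invisibly when \code{path} is given), with
#'   columns \code{sample}, \code{segment_id}, \code{draw_index},
#'   \code{route_id}, \code{event_type}, \code{timing}.
#' @export
writePosteriorDraws <- function(posterior, path = NULL) {
  d <- posterior@draws
  out <- data.frame(sample = posterior@sampleId,
                    segment_id = d$segment_id, draw_index = d$draw,
                    route_id = d$route_id,
                    event_type = ifelse(d$phase == "free", "gain",
                                        paste0("gain_", d$phase)),
                    timing = d$timing)
  if (length(posterior@twDraws)) {
    out <- rbind(out, data.frame(
      sample = posterior@sampleId, segment_id = NA_character_,
      draw_index = seq_along(posterior@twDraws), route_id = NA_character_,
      event_type = "wgd", timing = posterior@twDraws))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
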