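# End-to-end run orchestration: preprocess -> WGD call -> timing -> outputs,
# with a JSON manifest recording configuration, seeds and skipped samples.

#' Run the full timing pipeline for a set of samples
#'
#' For each sample: applies the reads-per-clonal-copy coverage filter (when
#' a mean depth is supplied), resolves WGD status, samples the joint
#' posterior, and writes per-sample TSV outputs plus a run manifest.
#'
#' @param samples list of [TumorSample-class].
#' @param outDir output directory (created if needed).
#' @param config a [timingConfig()].
#' @param seed root seed; per-sample seeds are derived from it.
#' @param meanDepths optional named numeric vector (by sample id) of mean
#'   sequencing depths, used for the reads-per-clonal-copy filter.
#' @return (invisibly) list with \code{posteriors} (named list; NULL for
#'   skipped samples) and \code{manifest}.
#' @export
runPipeline <- function(samples, outDir, config = timingConfig(),
                        seed = 1L, meanDepths = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  posteriors <- list()
  manifest <- list(config = config, seed = seed,
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   samples = list())
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    sid <- sampleId(sm)
    entry <- list(sample_id = sid, seed = deriveSeed(seed, i))
    t0 <- proc.time()[["elapsed"]]
    if (!is.null(meanDepths) && sid %in% names(meanDepths)) {
      rpc <- readsPerClonalCopy(meanDepths[[sid]], purity(sm),
                                tumorPloidy(sm))
      entry$reads_per_clonal_copy <- rpc
      if (rpc < config$minReadsPerClonalCopy) {
        entry$status <- "excluded_low_coverage"
        manifest$samples[[sid]] <- entry
        posteriors[sid] <- list(NULL)
        next
      }
    }
    post <- withCallingHandlers(
      timeGains(sm, config, seed = entry$seed),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(post)) {
      entry$status <- "not_timed_ambiguous_wgd"
      manifest$samples[[sid]] <- entry
      posteriors[sid] <- list(NULL)
      next
    }
    posteriors[[sid]] <- post
    saveRDS(post, file.path(outDir, paste0(sid, "_posterior.rds")))
    writePosteriorDraws(post, file.path(outDir, paste0(sid, "_draws.tsv")))
    utils::write.table(post@routeProbs,
                       file.path(outDir, paste0(sid, "_routes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    entry$status <- post@wgdStatus
    entry$n_timed_segments <- sum(post@segments$timed)
    entry$skipped_segments <- as.list(stats::setNames(
      post@segments$reason[!post@segments$timed],
      post@segments$segment_id[!post@segments$timed]))
    entry$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
    manifest$samples[[sid]] <- entry
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(posteriors = posteriors, manifest = manifest))
}
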