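# Shared fixtures. Heavy objects are built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

## a tiny hand-built diploid-ish sample with one gained segment
makeToySample <- function(altCounts, depths, majorCn = 2L, minorCn = 1L,
                          purity = 1, wgdStatus = "non_wgd") {
  n <- length(altCounts)
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 5e7),
                                major_cn = majorCn, minor_cn = minorCn,
                                segment_id = "seg001")
  snv <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(2e6, 4e7, length.out = n), width = 1L),
    alt_count = altCounts, total_depth = depths,
    clonal = rep(TRUE, n), kataegis = rep(FALSE, n))
  TumorSample("toy", seg, snv, purity = purity, wgdStatus = wgdStatus)
}

## mixed WGD / non-WGD cohort with posteriors, shared by cohort-level tests
cohortFixture <- function() fixture("cohort", function() {
  cfg <- simulationConfig(
    nSamples = 6L, segmentsPerSample = 6L,
    states = list(c(2L, 1L), c(2L, 2L), c(3L, 1L), c(3L, 2L)),
    minSnvsPerSegment = 20L)
  wgdFlags <- rep(c(TRUE, FALSE), each = 3L)
  cohort <- simulateCohort(cfg, seed = 404L, wgd = wgdFlags)
  posts <- lapply(seq_along(cohort$samples), function(i)
    sampleJointPosterior(cohort$samples[[i]],
                         timingConfig(nDraws = 80L, nPosteriorDraws = 120L),
                         seed = 1000L + i))
  list(cohort = cohort, posteriors = posts,
       wgdPosts = posts[wgdFlags], nonWgdPosts = posts[!wgdFlags])
})
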