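# WGD status calling from major-copy-number-two timing synchrony.

## one synchronised-gain (2+1) segment worth of SNVs at gain time t
.mcn2Snvs <- function(n, t, depth = 80L, seed = 1L) {
  set.seed(seed)
  w2 <- t / (3 - t)
  m <- sample(1:2, n, TRUE, prob = c(1 - w2, w2))
  d <- rpois(n, depth) + 1L
  data.frame(alt = rbinom(n, d, expectedVaf(m, 3L, 1)), depth = d)
}

## sample with k (2,1) segments gained at the given times
.mcn2Sample <- function(times, n = 60L, seed = 1L) {
  k <- length(times)
  seg <- GenomicRanges::GRanges(
    paste0("chr", seq_len(k)), IRanges::IRanges(1e6, 1e6 + 4e7),
    major_cn = rep(2L, k), minor_cn = rep(1L, k),
    segment_id = sprintf("seg%03d", seq_len(k)))
  snvList <- lapply(seq_len(k), function(i) {
    sv <- .mcn2Snvs(n, times[i], seed = seed + i)
    GenomicRanges::GRanges(paste0("chr", i),
                           IRanges::IRanges(seq(2e6, 3e7, length.out = n),
                                            width = 1),
                           alt_count = sv$alt, total_depth = sv$depth,
                           clonal = TRUE, kataegis = FALSE)
  })
  snv <- suppressWarnings(do.call(c, snvList))
  TumorSample("w1", seg, snv, purity = 1, wgdStatus = "unknown")
}

test_that("synchronised gains across the genome are called WGD", {
  sm <- .mcn2Sample(rep(0.5, 6L))
  call <- callWgd(sm)
  expect_identical(call@status, "wgd")
  expect_identical(call@majorMode, 2L)
  expect_equal(call@overlapFraction, 1)
  expect_lt(abs(call@wgdTime - 0.5), 0.1)
})

test_that("a modal major copy number of one is non-WGD without timing", {
  seg <- GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(1, c(9e7, 2e7)),
    major_cn = c(1L, 2L), minor_cn = c(1L, 1L))
  snv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e6, width = 1),
                                alt_count = 10L, total_depth = 20L,
                                clonal = TRUE, kataegis = FALSE)
  sm <- TumorSample("n1", seg, snv, purity = 1)
  call <- callWgd(sm)
  expect_identical(call@status, "non_wgd")
  expect_true(is.na(call@wgdTime))
})

test_that("a modal major copy number of three or more is ambiguous", {
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 9e7),
                                major_cn = 4L, minor_cn = 2L)
  snv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e6, width = 1),
                                alt_count = 10L, total_depth = 20L,
                                clonal = TRUE, kataegis = FALSE)
  sm <- TumorSample("a1", seg, snv, purity = 1)
  expect_identical(callWgd(sm)@status, "ambiguous_multi")
  ## and the pipeline wrapper refuses to time it
  expect_warning(post <- timeGains(sm), "not timed")
  expect_null(post)
})

test_that("asynchronous gains in two equal halves fall below the overlap rule", {
  ## two equal-bp groups timed far apart: stabbing covers only half the bp
  sm <- .mcn2Sample(c(0.15, 0.15, 0.15, 0.85, 0.85, 0.85), n = 120L)
  call <- callWgd(sm)
  expect_identical(call@status, "insufficient_overlap")
  expect_lt(call@overlapFraction, 0.60)
  expect_equal(call@overlapFraction, 0.5, tolerance = 0.01)
  ## the wrapper times such samples as non-WGD
  post <- timeGains(sm, timingConfig(nDraws = 40L), seed = 1L)
  expect_identical(wgdStatus(post), "non_wgd")
})

test_that("simulated WGD and non-WGD tumors are recalled accurately", {
  ## WGD tumors: mode-2 states gained by the WGD itself (parsimonious);
  ## non-WGD tumors: independent gains at free times
  nW <- 6L; nN <- 6L
  cfg <- simulationConfig(
    segmentsPerSample = 12L,
    states = list(c(2L, 1L), c(2L, 2L), c(1L, 1L)),
    stateWeights = c(0.5, 0.3, 0.2),
    parsimoniousOnly = TRUE, minSnvsPerSegment = 25L,
    purityRange = c(0.6, 0.9), rpcRange = c(8, 15))
  ## non-WGD tumors carry mostly diploid genomes with scattered gains
  cfgN <- cfg
  cfgN$parsimoniousOnly <- FALSE
  cfgN$stateWeights <- c(0.25, 0.1, 0.65)
  calls <- character(0)
  for (i in seq_len(nW)) {
    res <- simulateSample(cfg, seed = 100L + i, wgd = TRUE)
    calls <- c(calls, callWgd(res$sample)@status)
  }
  for (i in seq_len(nN)) {
    res <- simulateSample(cfgN, seed = 200L + i, wgd = FALSE)
    calls <- c(calls, callWgd(res$sample)@status)
  }
  truthW <- rep(c(TRUE, FALSE), c(nW, nN))
  calledW <- calls == "wgd"
  expect_gte(mean(calledW == truthW), 1 - 1 / (nW + nN))
})
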