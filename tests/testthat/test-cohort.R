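# Cohort analytics: gain-rate curve, post-WGD prevalence, proximity,
# punctuated classification, pre/post classes, timing ranks.

test_that("gain-rate curve is flat at 1 for WGD-independent uniform gains", {
  fx <- cohortFixture()
  ## build a synthetic cohort whose gain draws are uniform regardless of
  ## t_w, by replacing the draws of real posteriors
  posts <- lapply(fx$wgdPosts, function(p) {
    set.seed(1)
    d <- p@draws
    d$timing <- runif(nrow(d))
    p@draws <- d
    p
  })
  curve <- gainRateRelativeToWgd(posts, binWidth = 0.1)
  ## one bin is centred on zero
  expect_true(any(abs(curve$lo + 0.05) < 1e-9 & abs(curve$hi - 0.05) < 1e-9))
  ok <- !is.na(curve$rate) & curve$normalizer > 0.02
  expect_gt(sum(ok), 3L)
  expect_lt(max(abs(curve$rate[ok] - 1)), 0.35)
  ## conservation: binned raw mass equals the in-span bp-weighted mass
  d <- do.call(rbind, lapply(posts, function(p) {
    x <- p@draws
    seg <- p@segments
    x$bp <- seg$bp[match(x$segment_id, seg$segment_id)]
    x$w <- x$bp / max(x$draw)
    x
  }))
  off <- d$timing - d$t_w
  inSpan <- off >= min(curve$lo) & off <= max(curve$hi)
  expect_equal(sum(curve$raw), sum(d$w[inSpan]), tolerance = 1e-6)
})

test_that("gains pinned at the WGD put all mass in the central bin", {
  fx <- cohortFixture()
  posts <- lapply(fx$wgdPosts, function(p) {
    d <- p@draws
    d$timing <- d$t_w
    p@draws <- d
    p
  })
  curve <- gainRateRelativeToWgd(posts, binWidth = 0.1)
  central <- abs(curve$mid) < 1e-9
  expect_equal(sum(curve$raw[central]), sum(curve$raw), tolerance = 1e-9)
})

test_that("post-WGD gain prevalence applies the 50%-of-draws rule", {
  fx <- cohortFixture()
  posts <- c(fx$wgdPosts, fx$nonWgdPosts)
  res <- postWgdGainPrevalence(posts, minPerGroup = 3L, nPerm = 200L,
                               seed = 2L)
  expect_true(res$fractionWgd >= 0 && res$fractionWgd <= 1)
  expect_true(res$pValue >= 1 / 201 && res$pValue <= 1)
  ## counting rule on a hand-built case: exactly half the draws post-WGD
  p <- fx$wgdPosts[[1L]]
  ds <- p@drawSummary
  half <- ds$draw <= max(ds$draw) / 2
  ds$n_post <- ifelse(half, 1L, 0L)
  ds$n_pre <- 1L
  p@drawSummary <- ds
  frac <- gainTiming:::.segPostGainFraction(p)
  expect_true(all(abs(frac - 0.5) < 0.01))
})

test_that("cohorts with too few samples per type yield an empty prevalence", {
  fx <- cohortFixture()
  res <- postWgdGainPrevalence(c(fx$wgdPosts, fx$nonWgdPosts),
                               minPerGroup = 10L)
  expect_true(is.na(res$fractionWgd))
})

test_that("proximity is zero when gains coincide with the WGD and controls
           are symmetric for identical samples", {
  fx <- cohortFixture()
  posts <- lapply(fx$wgdPosts, function(p) {
    tw0 <- median(p@twDraws)
    d <- p@draws; d$timing <- tw0; d$t_w <- tw0; p@draws <- d
    p@twDraws <- rep(tw0, length(p@twDraws))
    p
  })
  res <- wgdGainProximity(posts, nTw = 5L, seed = 3L)
  expect_true(all(res$perSample$observed < 1e-9))
  ## identical twDraws across samples make permutation a no-op
  same <- lapply(posts, function(p) { p@twDraws <- rep(0.5, 50L); p })
  res2 <- wgdGainProximity(same, nTw = 5L, seed = 4L)
  expect_equal(res2$perSample$observed, res2$perSample$control,
               tolerance = 1e-9)
})

test_that("a burst-at-WGD cohort shows smaller proximity than its control", {
  fx <- cohortFixture()
  set.seed(9)
  posts <- lapply(fx$wgdPosts, function(p) {
    d <- p@draws
    d$timing <- pmin(pmax(d$t_w + rnorm(nrow(d), 0, 0.01), 0), 1)
    p@draws <- d
    p
  })
  res <- wgdGainProximity(posts, nTw = 10L, seed = 5L)
  expect_lt(mean(res$perSample$observed), mean(res$perSample$control))
})

test_that("punctuated classification follows the chromosome and dispersion rules", {
  fx <- cohortFixture()
  p <- fx$wgdPosts[[1L]]
  pool <- runif(500)
  ## gains on fewer than three chromosomes: uninformative
  d <- p@draws
  segs <- unique(d$segment_id)[1:2]
  p2 <- p; p2@draws <- d[d$segment_id %in% segs, ]
  expect_identical(classifyPunctuated(p2, pool, nPerm = 100L)$status,
                   "uninformative")
  ## all medians equal: dispersion zero, punctuated for a spread pool
  p3 <- p
  d3 <- p@draws; d3$timing <- 0.5; p3@draws <- d3
  if (length(unique(p@segments$chrom[p@segments$timed])) >= 3L) {
    cl <- classifyPunctuated(p3, pool, nPerm = 200L, seed = 1L)
    expect_identical(cl$status, "punctuated")
    expect_equal(cl$dispersion, 0)
  }
  expect_error(classifyPunctuated(p, numeric(0)), "empty")
})

test_that("samples drawn from the pool are punctuated at about the 5% rate", {
  ## type-I calibration of the permutation rule, scaled down
  set.seed(77)
  pool <- runif(400)
  nRep <- 150L
  segTemplate <- data.frame(
    segment_id = sprintf("s%02d", 1:6), chrom = paste0("chr", 1:6),
    bp = rep(3e7, 6))
  hits <- 0L
  for (r in seq_len(nRep)) {
    med <- pool[sample.int(length(pool), 6L, replace = TRUE)]
    draws <- data.frame(segment_id = segTemplate$segment_id, draw = 1L,
                        route_id = "r", phase = "post", timing = med,
                        t_w = NA_real_)
    segs <- data.frame(segment_id = segTemplate$segment_id,
                       chrom = segTemplate$chrom, start = 1, end = 3e7,
                       bp = segTemplate$bp, major_cn = 3L, minor_cn = 1L,
                       total_cn = 4L, n_snvs = 50L, gained = TRUE,
                       timed = TRUE, reason = "")
    p <- new("SamplePosterior", sampleId = paste0("r", r), cancerType = "x",
             purity = 1, wgdStatus = "non_wgd", segments = segs,
             routeProbs = data.frame(), evidence = list(),
             twGrid = numeric(), twPosterior = numeric(),
             twDraws = numeric(), draws = draws,
             drawSummary = data.frame(), penalty = 0, config = list())
    cl <- classifyPunctuated(p, pool, nPerm = 400L, seed = 1000L + r)
    if (cl$status == "punctuated") hits <- hits + 1L
  }
  rate <- hits / nRep
  ## binomial(150, 0.05): allow +/- 3 SD around 5%
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / nRep))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nRep))
})

test_that("pre/post event classes average draws and read the minor allele", {
  fx <- cohortFixture()
  p <- fx$wgdPosts[[1L]]
  cls <- classifyPrePostEvents(p)
  expect_true(all(cls$loss_class[cls$minor_cn == 0L] == "pre_wgd_loss"))
  expect_true(all(cls$loss_class[cls$minor_cn == 1L] == "post_wgd_loss"))
  expect_true(all(cls$loss_class[cls$minor_cn >= 2L] == "none"))
  ds <- p@drawSummary
  for (sid in unique(ds$segment_id)) {
    expect_equal(cls$mean_pre[cls$segment_id == sid],
                 mean(ds$n_pre[ds$segment_id == sid]))
  }
  ## a 50/50 pre/post split averages to 0.5 each
  half <- ds$draw <= max(ds$draw) / 2
  ds$n_pre <- as.integer(half); ds$n_post <- as.integer(!half)
  p@drawSummary <- ds
  cls2 <- classifyPrePostEvents(p)
  expect_true(all(abs(cls2$mean_pre[!is.na(cls2$mean_pre)] - 0.5) < 0.01))
})

test_that("timing quantile ranks are uniform for exchangeable draws", {
  fx <- cohortFixture()
  rk <- timingQuantileRanks(fx$wgdPosts, scope = "all_gains")
  expect_true(all(rk$rank >= 0 & rk$rank <= 1))
  ## within each tumor the rank transform of the pooled draws is uniform
  ## by construction: mean near 0.5
  mns <- tapply(rk$rank, rk$sample_id, mean)
  expect_true(all(abs(mns - 0.5) < 1e-6))
  rk1 <- timingQuantileRanks(fx$wgdPosts, scope = "initial_gain_only")
  ## initial-gain ranks only keep one entry per (segment, draw)
  expect_lte(nrow(rk1), nrow(rk))
})
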