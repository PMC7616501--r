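# Arm-level and pan-genome pre/post-WGD event landscapes.

test_that("corrected post-WGD loss follows the mutual-exclusivity formula", {
  expect_equal(correctedPostWgdLoss(0.5, 0.25), 0.5)
  expect_equal(correctedPostWgdLoss(0, 0.3), 0.3)
  ## clip at 0.95: a saturated pre-WGD loss cannot zero the denominator
  expect_equal(correctedPostWgdLoss(1, 0.05), 1)
  expect_error(correctedPostWgdLoss(1.2, 0.1))
})

test_that("arm event rates apply the 50% bp threshold", {
  fx <- cohortFixture()
  arms <- makeArmTable(fx$wgdPosts)
  rates <- armEventRates(fx$wgdPosts, arms)
  expect_true(all(rates$n_samples == length(fx$wgdPosts)))
  expect_true(all(rates[, c("pre_gain", "post_gain", "pre_loss",
                            "post_loss")] >= 0))
  expect_true(all(rates[, c("pre_gain", "post_gain", "pre_loss",
                            "post_loss")] <= 1))
  ## direct counting oracle: per sample and arm, pre-WGD loss means minor
  ## copy number zero over at least half the arm's base pairs
  for (k in seq_len(min(4L, nrow(arms)))) {
    arm1 <- arms[k, ]
    armBp <- arm1$end - arm1$start + 1
    flags <- vapply(fx$wgdPosts, function(p) {
      seg <- p@segments
      ov <- pmax(0, pmin(seg$end, arm1$end) - pmax(seg$start, arm1$start) + 1)
      ov[seg$chrom != arm1$chrom] <- 0
      sum(ov[seg$minor_cn == 0L]) / armBp >= 0.5
    }, logical(1))
    got <- rates[rates$chrom == arm1$chrom & rates$arm == arm1$arm, ]
    expect_identical(nrow(got), 1L)
    expect_equal(got$pre_loss, mean(flags))
  }
})

test_that("a whole-arm pre-WGD gained segment marks the arm; 40% does not", {
  mk <- function(frac) {
    bp <- 1e8
    twoSeg <- frac < 1
    segs <- data.frame(segment_id = c("s1", if (twoSeg) "s2"),
                       chrom = "chr1",
                       start = c(1, if (twoSeg) frac * bp + 1),
                       end = c(frac * bp, if (twoSeg) bp),
                       bp = c(frac * bp, if (twoSeg) (1 - frac) * bp),
                       major_cn = c(3L, if (twoSeg) 2L),
                       minor_cn = c(2L, if (twoSeg) 2L),
                       total_cn = c(5L, if (twoSeg) 4L), n_snvs = 50L,
                       gained = TRUE, timed = TRUE, reason = "")
    nDraws <- 20L
    ds <- rbind(
      data.frame(segment_id = "s1", draw = 1:nDraws, route_id = "r",
                 n_pre = 1L, n_post = 0L, n_losses = 0L, t_w = 0.5),
      if (twoSeg)
        data.frame(segment_id = "s2", draw = 1:nDraws, route_id = "r",
                   n_pre = 0L, n_post = 0L, n_losses = 0L, t_w = 0.5))
    new("SamplePosterior", sampleId = paste0("m", frac), cancerType = "x",
        purity = 1, wgdStatus = "wgd", segments = segs,
        routeProbs = data.frame(), evidence = list(),
        twGrid = numeric(), twPosterior = numeric(),
        twDraws = rep(0.5, nDraws),
        draws = data.frame(segment_id = "s1", draw = 1:nDraws,
                           route_id = "r", phase = "pre", timing = 0.3,
                           t_w = 0.5),
        drawSummary = ds, penalty = 0, config = list())
  }
  arms <- data.frame(chrom = "chr1", arm = "q", start = 1, end = 1e8)
  r100 <- armEventRates(list(mk(1.0)), arms)
  expect_equal(r100$pre_gain, 1)
  r40 <- armEventRates(list(mk(0.4)), arms)
  expect_equal(r40$pre_gain, 0)
})

test_that("pan-genome landscape normalises to 1e9 and is scale invariant", {
  fx <- cohortFixture()
  ls <- panGenomeLandscape(fx$wgdPosts, resolution = 1e6)
  tab <- ls$table
  w <- GenomicRanges::width(ls$bins)
  for (cn in c("pre_gain", "post_gain", "pre_loss", "post_loss",
               "post_loss_corrected")) {
    if (sum(tab[[cn]]) == 0) next
    expect_equal(sum(tab[[paste0(cn, "_norm")]] * w), 1e9)
    ## doubling raw proportions leaves the normalised track unchanged
    expect_equal(2 * tab[[cn]] * 1e9 / sum(2 * tab[[cn]] * w),
                 tab[[paste0(cn, "_norm")]])
  }
  expect_true(all(tab$pre_gain >= 0 & tab$pre_gain <= 1))
})

test_that("streaming and matrix landscape computations agree exactly", {
  fx <- cohortFixture()
  a <- panGenomeLandscape(fx$wgdPosts, resolution = 1e6, method = "stream")
  b <- panGenomeLandscape(fx$wgdPosts, resolution = 1e6, method = "matrix")
  expect_identical(a$table, b$table)
})
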