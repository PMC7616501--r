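# Tumor simulator: determinism, generative distributions, truth records.

test_that("identical seeds give identical samples", {
  cfg <- simulationConfig(segmentsPerSample = 5L)
  a <- simulateSample(cfg, seed = 12L)
  b <- simulateSample(cfg, seed = 12L)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(snvs(a$sample)), as.data.frame(snvs(b$sample)))
  c <- simulateSample(cfg, seed = 13L)
  expect_false(identical(a$truth$gain_times, c$truth$gain_times))
})

test_that("multiplicity-2 SNVs in a pure 2+1 tumor have mean VAF 2/3", {
  cfg <- simulationConfig(segmentsPerSample = 4L, states = list(c(2L, 1L)),
                          purityRange = c(1, 1), rpcRange = c(30, 30),
                          snvRate = 3e-6)
  res <- simulateSample(cfg, seed = 8L, wgd = FALSE)
  expect_equal(expectedVaf(2, 3, 1), 2 / 3)
  snv <- as.data.frame(snvs(res$sample))
  vaf <- snv$alt_count / snv$total_depth
  ## doubled SNVs cluster near 2/3, singles near 1/3; split at the midpoint
  hi <- vaf > 0.5
  expect_gt(sum(hi), 20L)
  expect_lt(abs(mean(vaf[hi]) - 2 / 3), 0.03)
  expect_lt(abs(mean(vaf[!hi]) - 1 / 3), 0.03)
})

test_that("empirical multiplicity proportions match the route spectrum", {
  ## one huge segment, ~1e5 SNVs: law of large numbers against the
  ## symbolic spectrum of the generating route
  cfg <- simulationConfig(segmentsPerSample = 1L, states = list(c(3L, 2L)),
                          segmentBpRange = c(2e8, 2e8), snvRate = 2e-4,
                          purityRange = c(0.9, 0.9))
  res <- simulateSample(cfg, seed = 5L, wgd = TRUE)
  tr <- res$truth
  snv <- as.data.frame(snvs(res$sample))
  expect_gt(nrow(snv), 5e4)
  ## evaluate the spectrum at the exact generating timings: recover the
  ## parameter-order times from the per-SNV truth annotations
  routes <- enumerateRoutes(3L, 2L, wgd = TRUE)
  route <- routes[[which(vapply(routes, routeId, "") == tr$route_id)]]
  th <- as.numeric(strsplit(tr$gain_times_param, ",")[[1L]])
  w <- multiplicitySpectrum(route, th, wgdTime = tr$t_w)
  emp <- as.numeric(table(factor(snv$true_multiplicity,
                                 levels = seq_along(w))) / nrow(snv))
  for (m in seq_along(w)) {
    se <- sqrt(max(w[m] * (1 - w[m]), 1e-12) / nrow(snv))
    expect_lt(abs(emp[m] - w[m]), 4 * se + 1e-9)
  }
})

test_that("per-segment SNV counts are Poisson with the branch-length mean", {
  ## moment check over replicates of one fixed-size segment
  cfg <- simulationConfig(segmentsPerSample = 1L, states = list(c(2L, 1L)),
                          segmentBpRange = c(3e7, 3e7), snvRate = 2e-6,
                          twRange = c(0.5, 0.5))
  nRep <- 200L
  counts <- integer(nRep)
  lens <- numeric(nRep)
  for (i in seq_len(nRep)) {
    res <- simulateSample(cfg, seed = 9000L + i, wgd = FALSE)
    counts[i] <- length(snvs(res$sample))
    t <- as.numeric(res$truth$gain_times)
    lens[i] <- (t + 2 * (1 - t)) + 1        # major branches + minor
  }
  lambda <- 2e-6 * 3e7 * lens
  z <- (sum(counts) - sum(lambda)) / sqrt(sum(lambda))
  expect_lt(abs(z), 4)                       # mean matches
  ## dispersion index of Poisson residuals near 1
  disp <- var(counts - lambda) / mean(lambda)
  expect_gt(disp, 0.7); expect_lt(disp, 1.4)
})

test_that("parsimonious-only cohorts use only most-parsimonious routes", {
  cfg <- simulationConfig(nSamples = 3L, segmentsPerSample = 6L,
                          parsimoniousOnly = TRUE)
  cohort <- simulateParsimoniousCohort(cfg, seed = 3L)
  for (i in seq_len(nrow(cohort$truth))) {
    tr <- cohort$truth[i, ]
    mp <- mostParsimonious(enumerateRoutes(tr$major_cn, tr$minor_cn,
                                           wgd = tr$wgd, maxRoutes = Inf))
    expect_true(tr$route_id %in% vapply(mp, routeId, character(1)))
  }
  ## truth has zero non-parsimony by construction
  minEv <- vapply(seq_len(nrow(cohort$truth)), function(i)
    min(vapply(enumerateRoutes(cohort$truth$major_cn[i],
                               cohort$truth$minor_cn[i],
                               wgd = cohort$truth$wgd[i], maxRoutes = Inf),
               nEvents, integer(1))), integer(1))
  expect_identical(cohort$truth$n_events, minEv)
})

test_that("deeper coverage tightens the timing posterior on matched seeds", {
  mkPost <- function(rpc) {
    cfg <- simulationConfig(segmentsPerSample = 3L, states = list(c(2L, 1L)),
                            rpcRange = c(rpc, rpc), minSnvsPerSegment = 30L,
                            purityRange = c(0.8, 0.8))
    res <- simulateSample(cfg, seed = 21L, wgd = FALSE)
    post <- sampleJointPosterior(res$sample, timingConfig(nDraws = 80L),
                                 seed = 4L)
    d <- posteriorDraws(post)
    mean(tapply(d$timing, d$segment_id, function(x)
      diff(quantile(x, c(0.05, 0.95)))))
  }
  expect_lt(mkPost(40), mkPost(6))
})
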