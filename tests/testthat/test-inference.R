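# Joint posterior inference: closed-form checks, penalty behaviour,
# non-parsimony accounting, determinism.

test_that("WGD time posterior matches the closed-form inversion on 2+2", {
  ## all SNVs at high depth in one 2+2 segment: w2 = t/(2-t) inverts to
  ## t = 2 n2 / (2 n2 + n1) on noiseless counts
  twTrue <- 0.5
  w2 <- twTrue / (2 - twTrue)
  n <- 300L
  n2 <- round(n * w2); n1 <- n - n2
  depth <- 400L
  alt <- c(rep(round(depth * 0.5), n2), rep(round(depth * 0.25), n1))
  sm <- makeToySample(alt, rep(depth, n), majorCn = 2L, minorCn = 2L,
                      purity = 1, wgdStatus = "wgd")
  post <- sampleJointPosterior(sm, timingConfig(nDraws = 60L), seed = 3L)
  tHat <- 2 * n2 / (2 * n2 + n1)
  expect_lt(abs(median(wgdTimeDraws(post)) - tHat), 0.03)
})

test_that("absent doubled SNVs force the gain time toward zero", {
  ## non-WGD 2+1 segment, deep coverage, no multiplicity-2 SNVs
  n <- 120L
  depth <- 500L
  sm <- makeToySample(rep(round(depth / 3), n), rep(depth, n),
                      majorCn = 2L, minorCn = 1L, purity = 1,
                      wgdStatus = "non_wgd")
  post <- sampleJointPosterior(sm, timingConfig(), seed = 2L)
  d <- posteriorDraws(post)
  expect_lt(median(d$timing), 0.1)
})

test_that("joint inference across segments tightens the WGD time", {
  cfg <- simulationConfig(nSamples = 1L, segmentsPerSample = 6L,
                          states = list(c(2L, 2L)),
                          minSnvsPerSegment = 25L,
                          purityRange = c(0.8, 0.9), rpcRange = c(8, 12))
  res <- simulateSample(cfg, seed = 77L, wgd = TRUE)
  post <- sampleJointPosterior(res$sample, timingConfig(), seed = 5L)
  jointSd <- sd(wgdTimeDraws(post))
  ## single-segment runs: keep one segment at a time
  seg <- cnSegments(res$sample)
  sds <- vapply(1:2, function(i) {
    sub <- suppressWarnings(TumorSample(
      "one", seg[i], snvs(res$sample), purity = purity(res$sample),
      wgdStatus = "wgd"))
    sd(wgdTimeDraws(sampleJointPosterior(sub, timingConfig(), seed = 5L)))
  }, numeric(1))
  expect_lt(jointSd, max(sds) + 1e-9)
})

test_that("non-parsimony accounting matches hand counts", {
  ## uniform posterior over four routes with events {2,3,3,4}
  fake <- new("SamplePosterior", sampleId = "f", cancerType = "x",
              purity = 1, wgdStatus = "non_wgd",
              segments = data.frame(segment_id = "s1", timed = TRUE),
              routeProbs = data.frame(
                segment_id = "s1", route_id = letters[1:4],
                n_events = c(2L, 3L, 3L, 4L),
                parsimonious = c(TRUE, FALSE, FALSE, FALSE),
                prob = rep(0.25, 4), prob_no_penalty = rep(0.25, 4)),
              evidence = list(), twGrid = numeric(), twPosterior = numeric(),
              twDraws = numeric(), draws = data.frame(),
              drawSummary = data.frame(), penalty = 0, config = list())
  np <- measureNonParsimony(fake)
  expect_equal(np$average, 0.75)
  expect_equal(unname(np$excessHistogram), c(0.25, 0.5, 0.25))
  ## all mass on the parsimonious route
  fake@routeProbs$prob <- c(1, 0, 0, 0)
  expect_equal(measureNonParsimony(fake)$average, 0)
})

test_that("penalty reweighting is monotone and tunable on real evidence", {
  cfg <- simulationConfig(nSamples = 2L, segmentsPerSample = 5L,
                          states = list(c(3L, 1L), c(3L, 2L)),
                          parsimoniousOnly = TRUE, minSnvsPerSegment = 20L)
  cohort <- simulateCohort(cfg, seed = 31L, wgd = c(TRUE, TRUE))
  posts <- lapply(1:2, function(i)
    sampleJointPosterior(cohort$samples[[i]],
                         timingConfig(nDraws = 80L), seed = i))
  ls <- c(0, 1, 2.7, 5, 10)
  np <- vapply(ls, function(l)
    measureNonParsimony(posts, penalty = l)$average, numeric(1))
  expect_true(all(diff(np) <= 1e-9))          # non-increasing in l
  ## l = 0 reproduces the stored no-penalty probabilities
  rp <- posts[[1L]]@routeProbs
  perSeg0 <- tapply(rp$prob_no_penalty * !rp$parsimonious, rp$segment_id, sum)
  np0 <- measureNonParsimony(posts[1], penalty = 0)
  expect_equal(sort(as.numeric(perSeg0)),
               sort(np0$perSegment$p_non_parsimonious), tolerance = 1e-10)
  target <- (np[1] + np[5]) / 2
  l <- tunePenalty(posts, target = target)
  expect_lt(abs(measureNonParsimony(posts, penalty = l)$average - target),
            0.02)
  expect_equal(tunePenalty(posts, target = 1), 0)
})

test_that("identical seeds give bit-identical posteriors; SNV order is irrelevant", {
  cfg <- simulationConfig(nSamples = 1L, segmentsPerSample = 4L,
                          states = list(c(2L, 1L), c(3L, 2L)),
                          minSnvsPerSegment = 20L)
  res <- simulateSample(cfg, seed = 55L, wgd = TRUE)
  p1 <- sampleJointPosterior(res$sample, timingConfig(nDraws = 60L), seed = 9L)
  p2 <- sampleJointPosterior(res$sample, timingConfig(nDraws = 60L), seed = 9L)
  expect_identical(p1@draws, p2@draws)
  expect_identical(p1@routeProbs, p2@routeProbs)
  ## permute SNV input order: assembly sorts positions, results unchanged
  snv <- snvs(res$sample)
  set.seed(1); snvShuf <- snv[sample(length(snv))]
  smShuf <- TumorSample(sampleId(res$sample), cnSegments(res$sample),
                        snvShuf, purity = purity(res$sample),
                        wgdStatus = "wgd")
  p3 <- sampleJointPosterior(smShuf, timingConfig(nDraws = 60L), seed = 9L)
  expect_identical(p1@draws$timing, p3@draws$timing)
  expect_identical(p1@evidence, p3@evidence)
})

test_that("segments are skipped for the documented reasons", {
  cfg <- simulationConfig(nSamples = 1L, segmentsPerSample = 3L,
                          states = list(c(1L, 1L), c(2L, 1L), c(5L, 5L)),
                          stateWeights = c(1, 1, 1), minSnvsPerSegment = 5L)
  ## build a sample with one of each state deterministically
  res <- simulateSample(cfg, seed = 2L, wgd = TRUE)
  segStates <- paste(res$truth$major_cn, res$truth$minor_cn)
  post <- sampleJointPosterior(res$sample, timingConfig(minSnvs = 1e5L),
                               seed = 1L)
  expect_true(all(!post@segments$timed))
  reasons <- post@segments$reason
  expect_true(all(reasons[post@segments$major_cn == 1L] == "not_gained"))
  expect_true(all(grepl("too_few_snvs|too_complex",
                        reasons[post@segments$major_cn >= 2L])))
})
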