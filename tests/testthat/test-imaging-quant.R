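test_that("spot pairing is optimal, thresholded strictly, and partitioning", {
  # one close pair
  m <- pairSpots(rbind(c(0, 0, 0)), rbind(c(100, 0, 0)))
  expect_equal(nrow(matchedPairs(m)), 1)
  expect_equal(unname(matchedPairs(m)[1, "distance"]), 100)

  # a single pair 500 nm apart dissolves into two lone ends
  m <- pairSpots(rbind(c(0, 0, 0)), rbind(c(500, 0, 0)))
  expect_equal(nrow(matchedPairs(m)), 0)
  expect_equal(loneEnds(m)$lone5p, 1L)
  expect_equal(loneEnds(m)$lone3p, 1L)

  # exactly 300 nm is not a pair (strict <)
  m <- pairSpots(rbind(c(0, 0, 0)), rbind(c(300, 0, 0)))
  expect_equal(nrow(matchedPairs(m)), 0)

  # configuration where greedy nearest-neighbour pairing is suboptimal
  s5 <- rbind(c(0, 0, 0), c(100, 0, 0))
  s3 <- rbind(c(40, 0, 0), c(-80, 0, 0))
  m <- pairSpots(s5, s3, maxDist = Inf)
  tot <- sum(matchedPairs(m)[, "distance"])
  D <- as.matrix(dist(rbind(s5, s3)))[1:2, 3:4]
  expect_equal(tot, bruteForceAssignment(D))
  greedy <- D[1, 1] + D[2, 2]   # greedy takes 40 then 140
  expect_lt(tot, greedy)

  # empty channels give an all-lone matching
  m <- pairSpots(matrix(numeric(0), 0, 3), rbind(c(0, 0, 0)))
  expect_equal(loneEnds(m)$lone3p, 1L)
})

test_that("pairing equals exhaustive enumeration on random small instances", {
  set.seed(88)
  for (k in 1:25) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    s5 <- matrix(runif(3 * n, 0, 1000), n, 3)
    s3 <- matrix(runif(3 * m, 0, 1000), m, 3)
    mt <- pairSpots(s5, s3, maxDist = Inf)
    D <- DecayDynamics:::.pairwiseDist(s5, s3)
    opt <- if (n <= m) bruteForceAssignment(D) else bruteForceAssignment(t(D))
    expect_equal(sum(matchedPairs(mt)[, "distance"]), opt, tolerance = 1e-9)
    # partition: every spot is paired or lone, never both
    expect_equal(unname(sort(c(matchedPairs(mt)[, "i5"],
                               loneEnds(mt)$lone5p))), seq_len(n))
    expect_equal(unname(sort(c(matchedPairs(mt)[, "i3"],
                               loneEnds(mt)$lone3p))), seq_len(m))
  }
})

test_that("end-to-end distances summarise pairs and recover compaction", {
  m <- pairSpots(rbind(c(0, 0, 0), c(1000, 0, 0)),
                 rbind(c(100, 0, 0), c(1200, 0, 0)))
  d <- endToEndDistances(m)
  expect_equal(d$mean, 150)
  expect_error(endToEndDistances(pairSpots(rbind(c(0, 0, 0)),
                                           rbind(c(500, 0, 0)))), "no pairs")

  # planted compaction 150 nm sd 30 recovered within 10 nm at n = 500
  sim <- simulateSpotField(500, loneFraction5p = 0, loneFraction3p = 0,
                           volume = rbind(c(0, 0, 0), c(5e4, 5e4, 1e4)),
                           seed = 3)
  mt <- pairSpots(sim$field@spots5p, sim$field@spots3p)
  expect_lt(abs(endToEndDistances(mt)$mean - 150), 10)

  # increasing planted compaction never decreases the recovered mean
  means <- vapply(c(100, 150, 200), function(mu) {
    s <- simulateSpotField(300, loneFraction5p = 0, loneFraction3p = 0,
                           compactionMean = mu,
                           volume = rbind(c(0, 0, 0), c(5e4, 5e4, 1e4)),
                           seed = 11)
    endToEndDistances(pairSpots(s$field@spots5p, s$field@spots3p))$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("P-body assignment uses a strict nearest-centre threshold", {
  pb <- rbind(c(1000, 1000, 1000))
  expect_true(assignToPBodies(rbind(c(1000, 1000, 1000)), pb))
  at150 <- rbind(c(1150, 1000, 1000))
  expect_true(assignToPBodies(at150, pb, radius = 200))
  expect_false(assignToPBodies(at150, pb, radius = 150))
  expect_equal(assignToPBodies(rbind(c(0, 0, 0)), matrix(numeric(0), 0, 3)),
               FALSE)

  # rigid translation of the whole field leaves flags unchanged
  set.seed(6)
  sp <- matrix(runif(300, 0, 5000), 100, 3)
  pb <- matrix(runif(60, 0, 5000), 20, 3)
  f1 <- assignToPBodies(sp, pb)
  f2 <- assignToPBodies(sp + 777, pb + 777)
  expect_equal(f1, f2)
})

test_that("random colocalisation matches the sphere-volume expectation", {
  set.seed(42)
  side <- 20000; r <- 200; nP <- 200; nS <- 5000
  vol <- rbind(c(0, 0, 0), c(side, side, side))
  sp <- DecayDynamics:::.runifVolume(nS, vol)
  pb <- DecayDynamics:::.runifVolume(nP, vol)
  hits <- sum(assignToPBodies(sp, pb, radius = r))
  p <- 1 - (1 - (4 / 3) * pi * r^3 / side^3)^nP
  expect_lt(abs(hits - nS * p), 3 * sqrt(nS * p * (1 - p)) + 1)
})

test_that("the colocalisation index normalises by mRNA and P-body counts", {
  expect_equal(colocalizationIndex(0, 100, 50), 0)
  expect_equal(colocalizationIndex(50, 200, 100), 0.0025)
  # doubling the P-body count halves C_P at equal colocalised fraction
  expect_equal(colocalizationIndex(50, 200, 200),
               colocalizationIndex(50, 200, 100) / 2)
  expect_error(colocalizationIndex(5, 0, 10))
  # range: C_P within [0, 1/N_P]
  expect_lte(colocalizationIndex(200, 200, 7), 1 / 7)
})

test_that("lone-end enrichment reports per-species P-body percentages", {
  # no P-bodies: zero percent everywhere
  sim <- simulateSpotField(50, seed = 5, nPbodies = 0,
                           volume = rbind(c(0, 0, 0), c(4e4, 4e4, 1e4)))
  mt <- pairSpots(sim$field@spots5p, sim$field@spots3p)
  enr <- loneEndEnrichment(mt, sim$field)
  expect_true(all(enr$percent[!enr$empty] == 0))

  # all lone 3' ends placed inside P-bodies: 100% (lone 5' species empty,
  # flagged rather than reported)
  sim <- simulateSpotField(60, loneFraction5p = 0, loneFraction3p = 0.5,
                           colocProbs = c(intact = 0, lone5 = 0, lone3 = 1),
                           volume = rbind(c(0, 0, 0), c(5e4, 5e4, 1e4)),
                           seed = 8)
  mt <- pairSpots(sim$field@spots5p, sim$field@spots3p)
  enr <- loneEndEnrichment(mt, sim$field)
  expect_equal(enr$percent[enr$species == "lone_3p"], 100)
  expect_true(enr$empty[enr$species == "lone_5p"])

  # planted 3' bias: recovered ordering 3' > 5' across seeds
  ord <- vapply(1:10, function(s) {
    sim <- simulateSpotField(300, loneFraction5p = 1, loneFraction3p = 1,
                             colocProbs = c(intact = 0, lone5 = 0.1,
                                            lone3 = 0.3),
                             volume = rbind(c(0, 0, 0), c(1e5, 1e5, 1e4)),
                             seed = s)
    mt <- pairSpots(sim$field@spots5p, sim$field@spots3p)
    enr <- loneEndEnrichment(mt, sim$field)
    enr$percent[enr$species == "lone_3p"] >
      enr$percent[enr$species == "lone_5p"]
  }, logical(1))
  expect_true(all(ord))
})

test_that("detection efficiency follows the lone-partner estimator", {
  # all spots paired: 100% both channels
  sim <- simulateSpotField(100, loneFraction5p = 0, loneFraction3p = 0,
                           volume = rbind(c(0, 0, 0), c(5e4, 5e4, 1e4)),
                           seed = 2)
  mt <- pairSpots(sim$field@spots5p, sim$field@spots3p)
  eff <- detectionEfficiency(mt)
  expect_equal(unname(eff), c(100, 100))

  # alternating-probe control with per-channel miss rates (0.3, 0.1)
  set.seed(19)
  n <- 1000
  pos <- DecayDynamics:::.runifVolume(n, rbind(c(0, 0, 0), c(2e5, 2e5, 2e4)))
  det5 <- runif(n) > 0.3; det3 <- runif(n) > 0.1
  mt <- pairSpots(pos[det5, ] + rnorm(3 * sum(det5), 0, 10),
                  pos[det3, ] + rnorm(3 * sum(det3), 0, 10))
  eff <- detectionEfficiency(mt)
  expect_lt(abs(eff[["efficiency5p"]] - 70), 5)
  expect_lt(abs(eff[["efficiency3p"]] - 90), 5)
})

test_that("exponential decay fits recover half-lives and flag flat data", {
  t <- seq(0, 240, by = 30)
  y <- 500 * exp(-log(2) / 30 * t)
  fit <- fitExponentialDecay(t, y)
  expect_equal(fit$tHalf, 30, tolerance = 1e-6)
  expect_false(fit$infinite)

  # noisy recovery within 15%
  set.seed(23)
  ok <- vapply(1:5, function(s) {
    yy <- y * (1 + rnorm(length(y), 0, 0.1))
    abs(fitExponentialDecay(t, pmax(yy, 0))$tHalf - 30) / 30 < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.8)

  flat <- fitExponentialDecay(t, rep(100, length(t)))
  expect_true(flat$infinite)
  expect_equal(flat$tHalf, Inf)
})

test_that("signal-to-noise compares mean change with replicate variance", {
  t <- rep(c(0, 60, 120), each = 3)
  expect_equal(signalToNoise(t, rep(100, 9))$snr, 0)
  set.seed(3)
  decaying <- rep(c(100, 50, 10), each = 3) + rnorm(9, 0, 2)
  expect_gt(signalToNoise(t, decaying)$snr, 1)
  zv <- signalToNoise(t, rep(c(100, 50, 10), each = 3))
  expect_true(zv$capped)
  expect_error(signalToNoise(c(0, 60, 120), c(5, 4, 3)), "replicated")
})
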