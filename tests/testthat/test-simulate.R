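test_that("the stationary renewal sampler has the right event rate", {
  set.seed(11)
  ## shape 1 is a Poisson process: expected count L / mu = 2
  counts <- replicate(3000, length(sampleStationaryGammaRenewal(100, 1, 50)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2), 2.5 * se + 1e-12)
  ## stationarity holds for strong interference too
  counts10 <- replicate(3000,
                        length(sampleStationaryGammaRenewal(100, 10, 50)))
  se10 <- sd(counts10) / sqrt(length(counts10))
  expect_lt(abs(mean(counts10) - 2), 2.5 * se10 + 1e-12)
})

test_that("large shapes degenerate to near-deterministic spacing", {
  set.seed(12)
  ev <- sampleStationaryGammaRenewal(100000, 400, 50)
  gaps <- diff(ev)
  expect_lt(abs(mean(gaps) - 50), 0.5)
  expect_lt(sd(gaps) / mean(gaps), 0.06)   # CV ~ 1/sqrt(400) = 0.05
})

test_that("interior gaps have the configured gamma moments", {
  set.seed(13)
  ev <- sampleStationaryGammaRenewal(10 * 40000, 10, 10)
  gaps <- diff(ev)
  expect_gt(length(gaps), 30000)
  cv <- sd(gaps) / mean(gaps)
  expect_lt(abs(cv - 1 / sqrt(10)), 0.01)
})

test_that("event counts are homogeneous across subintervals", {
  set.seed(14)
  ev <- sampleStationaryGammaRenewal(4 * 2500 * 2, 4, 2)
  bins <- cut(ev, breaks = seq(0, 4 * 2500 * 2, length.out = 5))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})

test_that("renewal sampler rejects bad parameters", {
  expect_error(sampleStationaryGammaRenewal(-1, 1, 1), "L")
  expect_error(sampleStationaryGammaRenewal(1, 0, 1), "shape")
  expect_error(sampleStationaryGammaRenewal(1, 1, 0), "meanSpacing")
})

test_that("detection loss thins focus counts as expected", {
  p0 <- recoveryParams(1, meanSpacing = 0.25, nCells = 40, seed = 21)
  ## detectionEff 0 removes everything
  pz <- p0; pz@detectionEff <- 0
  set.seed(1)
  bivs <- replicate(50, simulateBivalent(pz, 3))
  expect_true(all(vapply(bivs, function(b) length(b@positions), 1L) == 0))
  ## detectionEff 0.5 halves the expected count L / mu
  ph <- p0; ph@detectionEff <- 0.5
  set.seed(2)
  k <- replicate(4000, length(simulateBivalent(ph, 3)@positions))
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 0.5 * 1 / 0.25), 3 * se)
})

test_that("obligate enforcement leaves no zero-focus bivalents", {
  p <- recoveryParams(5, meanSpacing = 0.5, seed = 22)
  p@obligate <- TRUE
  set.seed(3)
  k <- replicate(500, length(simulateBivalent(p, 1)@positions))
  expect_true(all(k >= 1))
})

test_that("proximal suppression with zero retention empties the window", {
  p <- recoveryParams(2, meanSpacing = 0.3, seed = 23)
  p@proximalWindow <- 0.15
  p@proximalRetention <- 0
  set.seed(4)
  pos <- unlist(replicate(300, simulateBivalent(p, 1)@positions))
  expect_gt(length(pos), 100)
  expect_true(all(pos > 0.15))
  pt <- positionTable(simulateDataset(
    simulationParams("g", rep(10, 19), rep(0.5, 19), shape = 2,
                     meanSpacing = 0.3, proximalWindow = 0.15,
                     proximalRetention = 0, obligate = FALSE,
                     nCells = 3L, seed = 24)))
  expect_equal(regionFraction(pt, "proximal")$fraction, 0)
})

test_that("simulated datasets are seed-deterministic and valid", {
  p <- wildTypeParams(nCells = 3, seed = 77)
  t1 <- simulateDataset(p)
  t2 <- simulateDataset(p)
  expect_identical(focusData(t1), focusData(t2))
  expect_s4_class(t1, "FocusTable")
  ## a different seed changes the draw
  p2 <- wildTypeParams(nCells = 3, seed = 78)
  expect_false(identical(focusData(t1), focusData(simulateDataset(p2))))
})

test_that("per-rank SC lengths match the configured laws", {
  p <- wildTypeParams(nCells = 32, seed = 31)
  d <- focusData(simulateDataset(p))
  ## one record per bivalent (generative ranks)
  b <- unique(d[, c("cell_id", "chromosome_rank", "sc_length_um")])
  for (r in c(1, 5, 11, 16, 19)) {
    x <- b$sc_length_um[b$chromosome_rank == r]
    expect_length(x, 32L)
    se <- p@scLengthSd[r] / sqrt(32)
    expect_lt(abs(mean(x) - p@scLengthMean[r]), 3 * se)
  }
})

test_that("observable spacing tracks the configured stationary law", {
  ## with strong interference and two-focus bivalents dominating, the mean
  ## inter-focus distance approaches the large-n simulation expectation
  p <- recoveryParams(10.9, meanSpacing = 0.5, nCells = 40, seed = 32)
  ds <- interfocusDistances(simulateDataset(p), excludeRanks = NULL)
  ## oracle: large-n gap sample from the generative law, selected for
  ## fitting inside the unit SC exactly as observable gaps are
  set.seed(99)
  gapOracle <- function() {
    ev <- sampleStationaryGammaRenewal(1, 10.9, 0.5)
    if (length(ev) < 2) return(numeric(0)) else diff(ev)
  }
  ref <- unlist(replicate(4000, gapOracle())) * 100
  expect_gt(length(distances(ds)), 200)
  seDiff <- sqrt(sd(ref)^2 / length(ref) +
                   sd(distances(ds))^2 / length(distances(ds)))
  expect_lt(abs(mean(distances(ds)) - mean(ref)), 3 * seDiff)
})

test_that("stage count draws match published moments", {
  set.seed(41)
  cm <- countModelFor("RAD51/DMC1", "pachynema", "wild-type")
  x <- simulateStageCounts(cm, nCells = 200)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 18.2), 2 * 7.0 / sqrt(200))
  ## overdispersion is retained
  expect_gt(sd(x), 4)
  ## degenerate and empty models
  expect_equal(simulateStageCounts(countModel(18.4, 0), nCells = 5),
               rep(18L, 5))
  expect_equal(simulateStageCounts(countModel(0, 0), nCells = 4), rep(0L, 4))
  expect_equal(simulateStageCounts(countModel(0, 1), nCells = 4),
               integer(4))
})

test_that("built-in parameter sets encode the study conditions", {
  wt <- wildTypeParams()
  expect_equal(wt@shape, 10.9)
  expect_equal(sum(wt@scLengthMean), 171.8)
  expect_true(wt@obligate)
  mod <- trip13ModParams()
  expect_equal(mod@shape, 9.2)
  expect_lt(sum(mod@scLengthMean), sum(wt@scLengthMean))
  expect_false(mod@obligate)
  expect_error(countModelFor("DMC1", "pachynema", "Trip13-mod"), "no count")
})
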