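test_that("position tables stratify foci and drop 3-focus bivalents", {
  d <- frameFromBivalents(list(
    c1 = list(list(rank = 1L, len = 12, positions = 0.42),
              list(rank = 2L, len = 11, positions = c(0.25, 0.85)),
              list(rank = 3L, len = 10, positions = c(0.1, 0.5, 0.9)),
              list(rank = 4L, len = 9.5, positions = numeric(0)))))
  pt <- positionTable(FocusTable(d), rerank = FALSE)
  dat <- positionData(pt)
  expect_equal(pt@droppedThreeFocus, 1L)
  expect_equal(sort(dat$position), c(25, 42, 85))
  expect_equal(dat$focusClass[dat$position == 42], 1L)
  expect_true(all(dat$focusClass[dat$position %in% c(25, 85)] == 2L))
  ## class tallies equal the brute-force multiplicity count
  mult <- c(1, 2, 3, 0)
  expect_equal(sum(dat$focusClass == 1), sum(mult == 1))
  expect_equal(sum(dat$focusClass == 2), 2 * sum(mult == 2))
})

test_that("region fractions reproduce printed one-decimal percentages", {
  ## proximal counts reconstructed from printed numerators/denominators
  mut <- c(runif(43, 0, 15), runif(1021 - 43, 15.2, 100))
  expect_equal(regionFraction(mut, "proximal")$percent, 4.2)
  ctrl <- c(runif(99, 0, 15), runif(2311 - 99, 15.2, 100))
  expect_equal(regionFraction(ctrl, "proximal")$percent, 4.3)
  none <- regionFraction(runif(50, 20, 39), "proximal")
  expect_equal(none$percent, 0)
  expect_warning(und <- regionFraction(numeric(0), "proximal"), "undefined")
  expect_true(is.na(und$fraction))
  expect_error(regionFraction(1:10, "nope"), "unknown region")
})

test_that("fractions over a partition of the axis sum to one", {
  set.seed(101)
  x <- round(runif(500, 0, 100), 1)
  parts <- regionSpec(list(a = c(0, 33.3), b = c(33.4, 66.6),
                           c = c(66.7, 100)))
  total <- sum(vapply(c("a", "b", "c"), function(r)
    regionFraction(x, r, parts)$fraction, 1))
  expect_equal(total, 1)
})

test_that("boundary membership honours closed intervals after rounding", {
  ## 15.04 rounds to 15.0 and is inside; 15.06 rounds to 15.1 and is out
  expect_equal(regionFraction(c(15.04), "proximal")$count, 1L)
  expect_equal(regionFraction(c(15.06), "proximal")$count, 0L)
})

test_that("central occupancy folds compare genotypes", {
  same <- positionTableFrom(c(runif(30, 41, 74), runif(70, 1, 39)))
  res <- centralOccupancyFold(same, same)
  expect_equal(res$fold, 1)
  expect_equal(pValue(res$fisher), 1)
  ## constructed fractions 0.23 vs 0.10 give the 2.3-fold headline form
  a <- positionTableFrom(c(runif(23, 41, 74), runif(77, 1, 39)))
  b <- positionTableFrom(c(runif(10, 41, 74), runif(90, 1, 39)))
  expect_equal(centralOccupancyFold(a, b)$fold, 2.3)
})

test_that("relaxed positional bias is detected across seeds", {
  ## strong interference with wide spacing pushes two-focus foci to the
  ## chromosome ends; removing interference fills the central region in
  for (seed in 1:3) {
    wt <- positionTable(simulateDataset(
      recoveryParams(15, meanSpacing = 0.8, nCells = 100,
                     seed = 110 + seed)))
    mut <- positionTable(simulateDataset(
      recoveryParams(1, meanSpacing = 0.8, nCells = 100,
                     seed = 120 + seed)))
    res <- centralOccupancyFold(mut, wt)
    expect_gt(res$fold, 1)
    expect_lt(pValue(res$fisher), 0.05)
  }
})

test_that("weak interference raises central occupancy of two-focus foci", {
  ## directional property: with matched focus numbers, shape 1 fills the
  ## central region that strong interference empties
  strong <- positionTable(simulateDataset(
    recoveryParams(15, meanSpacing = 0.55, nCells = 60, seed = 131)))
  random <- positionTable(simulateDataset(
    recoveryParams(1, meanSpacing = 0.55, nCells = 60, seed = 132)))
  pick <- function(pt) positionData(pt)$position[
    positionData(pt)$focusClass == 2L]
  fStrong <- regionFraction(pick(strong), "central")$fraction
  fRandom <- regionFraction(pick(random), "central")$fraction
  expect_lt(fStrong, fRandom)
})

test_that("reflected kernel density conserves mass and finds structure", {
  set.seed(102)
  tight <- rnorm(200, 50, 3)
  prof <- kdeProfile(tight)
  expect_equal(prof$position[which.max(prof$density)], 50, tolerance = 1)
  ## trapezoid mass on [0, 100]
  mass <- function(p) sum(diff(p$position) *
                            (head(p$density, -1) + tail(p$density, -1)) / 2)
  expect_lt(abs(mass(prof) - 1), 1e-3)
  ## edge-heavy data would leak mass without reflection
  edgy <- kdeProfile(c(runif(100, 0, 6), runif(100, 94, 100)))
  expect_lt(abs(mass(edgy) - 1), 1e-3)
  ## a two-cluster mixture shows an antimode between the modes
  bim <- kdeProfile(c(rnorm(150, 25, 4), rnorm(150, 85, 4)))
  dens <- bim$density
  i25 <- which.min(abs(bim$position - 25))
  i85 <- which.min(abs(bim$position - 85))
  i55 <- which.min(abs(bim$position - 55))
  expect_lt(dens[i55], 0.4 * min(dens[i25], dens[i85]))
  expect_error(kdeProfile(c(1, 2, 3)), "at least 5")
})

test_that("the AD statistic matches a direct double-sum evaluation", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1.5, 2.5, 3.5, 4.5, 5.5)
  ## independent oracle: explicit loops over distinct pooled values,
  ## midrank (half-step) convention
  pooled <- c(a, b); N <- length(pooled)
  z <- sort(unique(pooled))
  inner <- 0
  for (sample_i in list(a, b)) {
    ni <- length(sample_i)
    si <- 0
    for (j in seq_along(z)) {
      lj <- sum(pooled == z[j])
      Bj <- sum(pooled < z[j]) + lj / 2
      Mij <- sum(sample_i < z[j]) + sum(sample_i == z[j]) / 2
      denom <- Bj * (N - Bj) - N * lj / 4
      si <- si + (lj / N) * (N * Mij - ni * Bj)^2 / denom
    }
    inner <- inner + si / ni
  }
  oracle <- (N - 1) / N * inner
  res <- adKSample(list(a, b))
  expect_equal(unname(statValue(res)["A2"]), oracle, tolerance = 1e-12)
})

test_that("identical samples give a null-typical AD statistic", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- adKSample(list(x, x), method = "permutation",
                   nPermutations = 400)
  ## the standardised statistic sits below its upper-tail critical range
  expect_lt(unname(statValue(res)["T"]), 0)
  expect_gt(pValue(res), 0.9)
})

test_that("well-separated samples are detected by permutation", {
  set.seed(103)
  pooledSd <- 1
  x <- rnorm(50, 0, pooledSd)
  y <- rnorm(50, 3 * pooledSd, pooledSd)
  res <- adKSample(list(x, y), method = "permutation",
                   nPermutations = 2000)
  expect_lt(pValue(res), 0.001)
})

test_that("the AD test is invariant under monotone transforms", {
  set.seed(104)
  x <- rexp(30) + 0.1
  y <- rexp(30, 0.5) + 0.1
  t1 <- statValue(adKSample(list(x, y)))["A2"]
  t2 <- statValue(adKSample(list(log(x), log(y))))["A2"]
  t3 <- statValue(adKSample(list(sqrt(x), sqrt(y))))["A2"]
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_equal(t1, t3, tolerance = 1e-12)
})

test_that("degenerate pooled samples are flagged", {
  res <- adKSample(list(c(2, 2, 2), c(2, 2)))
  expect_true(is.na(pValue(res)))
  expect_match(res@note, "degenerate")
})
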