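test_that("focus-count summaries use the sample SD", {
  s <- summarizeFocusCounts(c(18, 18, 18))
  expect_equal(s@mean, 18)
  expect_equal(s@sd, 0)
  s2 <- summarizeFocusCounts(1:4)
  expect_equal(s2@mean, 2.5)
  expect_equal(s2@sd, sqrt(5 / 3))
  expect_equal(round(s2@sd, 3), 1.291)
  expect_true(is.na(summarizeFocusCounts(7)@sd))
})

test_that("simulated stage counts summarise near their published mean", {
  set.seed(141)
  x <- simulateStageCounts(countModelFor("RAD51/DMC1", "pachynema",
                                         "wild-type"), nCells = 200)
  s <- summarizeFocusCounts(x)
  expect_lt(abs(s@mean - 18.2), 2 * 7.0 / sqrt(200))
})

test_that("fold changes follow the printing conventions", {
  expect_equal(ratio(foldChange(131.0, 18.2)), 7.2)
  expect_equal(ratio(foldChange(147.8, 0.4)), 369.5)
  expect_gt(ratio(foldChange(147.8, 0.4)), 300)   # printed bound
  expect_equal(ratio(foldChange(99.0, 18.2)), 5.4)
  expect_equal(ratio(foldChange(10, 10)), 1)
  expect_equal(ratio(foldChange(54.2, 6.5, "nearest-integer")), 8)
  expect_equal(ratio(foldChange(54.2, 0.9, "nearest-ten")), 60)
  expect_error(foldChange(1, 0), "positive")
  ## reciprocal property before rounding
  f <- foldChange(13.7, 3.1, "none")
  g <- foldChange(3.1, 13.7, "none")
  expect_equal(ratio(f) * ratio(g), 1, tolerance = 1e-12)
})

test_that("Fisher's exact matches canonical small-table values", {
  expect_equal(pValue(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))), 1)
  expect_equal(pValue(fisherExact2x2(matrix(c(2, 0, 0, 2), 2))), 1 / 3,
               tolerance = 1e-12)
  deg <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(pValue(deg), 1)
  expect_match(deg@note, "degenerate")
  ## one-sided tails are hypergeometric tails
  tab <- matrix(c(7, 3, 2, 8), 2, byrow = TRUE)
  expect_equal(pValue(fisherExact2x2(tab, "greater")),
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("Fisher's two-sided p agrees with the reference implementation", {
  set.seed(142)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)) + c(1, 0, 0, 1), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(pValue(fisherExact2x2(tab)),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("the G statistic and its refinement additivity hold", {
  ## observed equal to expected gives G = 0
  flat <- matrix(c(10, 20, 10, 20), 2, byrow = TRUE)
  r0 <- gTest(flat)
  expect_equal(unname(statValue(r0)["G"]), 0, tolerance = 1e-12)
  expect_equal(pValue(r0), 1)
  ## closed-form check
  r <- gTest(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(unname(statValue(r)["G"]),
               2 * (20 * log(2 / 3) + 40 * log(4 / 3)), tolerance = 1e-12)
  expect_equal(round(unname(statValue(r)["G"]), 2), 6.8)
  expect_equal(unname(r@parameter["df"]), 1)
  ## splitting a column into proportional sub-columns leaves G unchanged
  tab <- matrix(c(30, 50, 20, 40), 2, byrow = TRUE)
  refined <- cbind(tab[, 1], tab[, 2] * 0.6, tab[, 2] * 0.4)
  expect_equal(unname(statValue(gTest(tab))["G"]),
               unname(statValue(gTest(refined))["G"]), tolerance = 1e-10)
  expect_error(gTest(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)), "pool")
  ## Williams correction shrinks G
  rw <- gTest(matrix(c(10, 20, 20, 10), 2, byrow = TRUE), williams = TRUE)
  expect_lt(unname(statValue(rw)["G"]), unname(statValue(r)["G"]))
})

test_that("Mann-Whitney exact p equals full split enumeration", {
  expect_equal(pValue(mannWhitney(c(1, 2, 3), c(1, 2, 3))), 1)
  r <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(statValue(r)["U"]), 0)
  expect_equal(pValue(r), 0.1, tolerance = 1e-12)
  ## brute-force enumeration oracle over all C(n1+n2, n1) splits,
  ## tie-aware, on random small samples
  bruteP <- function(a, b) {
    n1 <- length(a); pooled <- c(a, b); N <- length(pooled)
    rk <- rank(pooled)
    obs <- abs(sum(rk[seq_len(n1)]) - n1 * (N + 1) / 2)
    splits <- combn(N, n1)
    devs <- apply(splits, 2, function(ix) abs(sum(rk[ix]) -
                                                n1 * (N + 1) / 2))
    mean(devs >= obs - 1e-9)
  }
  set.seed(143)
  for (i in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    a <- sample(0:5, n1, replace = TRUE)   # heavy ties, like focus counts
    b <- sample(0:7, n2, replace = TRUE)
    expect_equal(pValue(mannWhitney(a, b)), bruteP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree at moderate n", {
  set.seed(144)
  for (i in 1:5) {
    a <- rpois(15, 20); b <- rpois(15, 24)
    pe <- pValue(mannWhitney(a, b, exact = TRUE))
    pa <- pValue(mannWhitney(a, b, exact = FALSE))
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("focus multiplicity distributions tally bivalents", {
  d <- frameFromBivalents(list(
    c1 = list(list(rank = 1L, len = 12, positions = 0.4),
              list(rank = 2L, len = 11, positions = numeric(0)))))
  fd <- focusNumberDistribution(FocusTable(d))
  expect_equal(fd$fractions, c(0.5, 0.5, 0, 0))
  expect_equal(fd$n, 2L)
  ## obligate simulation has no zero-focus bivalents
  p <- recoveryParams(5, meanSpacing = 0.5, nCells = 5, seed = 145)
  p@obligate <- TRUE
  fo <- focusNumberDistribution(simulateDataset(p))
  expect_equal(fo$counts[["0"]], 0L)
  ## fractions times N reproduce the brute-force integer tally
  tab <- simulateDataset(recoveryParams(3, meanSpacing = 0.4, nCells = 6,
                                        seed = 146))
  fx <- focusNumberDistribution(tab)
  cells <- groupIntoMeiocytes(tab)
  k <- unlist(lapply(cells, function(m)
    vapply(m@bivalents, function(b) length(b@positions), 1L)))
  want <- c(sum(k == 0), sum(k == 1), sum(k == 2), sum(k >= 3))
  expect_equal(unname(fx$counts), want)
  expect_equal(sum(fx$fractions), 1)
})

test_that("rate comparisons mirror printed folds and flag zero rates", {
  rc <- rateComparison(10, 154, 1, 116)
  expect_equal(round(rc$rateA, 1), 6.5)
  expect_equal(round(rc$rateB, 1), 0.9)
  expect_equal(rc$fold, 7.2)
  expect_s4_class(rc$fisher, "StatResult")
  eq <- rateComparison(5, 50, 5, 50)
  expect_equal(eq$fold, 1)
  expect_equal(pValue(eq$fisher), 1)
  z <- rateComparison(3, 50, 0, 50)
  expect_equal(z$fold, Inf)
})

test_that("percent-derived counts reconstruct or are flagged", {
  seg <- reconstructCounts(c(32.5, 56.0, 11.5), 416)
  expect_equal(as.integer(seg), c(135L, 233L, 48L))
  expect_true(all(attr(seg, "ok")))
  ach <- reconstructCounts(c(3.0, 1.1), c(1808, 1083))
  expect_equal(as.integer(ach), c(54L, 12L))
  ## 14.5% of 93 cells admits no integer count: the guard must flag it
  expect_warning(bad <- reconstructCounts(14.5, 93), "reconstruction failed")
  expect_false(attr(bad, "ok"))
})

test_that("type-I error is controlled under the null", {
  set.seed(147)
  nrep <- 2000
  ## G test on independent 2x2 draws with generous counts
  pg <- replicate(nrep, {
    tab <- matrix(rpois(4, 50), 2)
    pValue(gTest(tab))
  })
  expect_lt(abs(mean(pg < 0.05) - 0.05), 0.02)
  ## Mann-Whitney (approximate) on continuous null samples
  pm <- replicate(nrep, pValue(mannWhitney(rnorm(30), rnorm(30),
                                           exact = FALSE)))
  expect_lt(abs(mean(pm < 0.05) - 0.05), 0.02)
  ## all p-values live in [0, 1]
  expect_true(all(pg >= 0 & pg <= 1 & pm >= 0 & pm <= 1))
})
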