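#' Build a stratified crossover-position table
#'
#' MLH1 focus positions are converted to percent of the source bivalent's
#' SC length (centromere = 0) and stratified by size group and by
#' focus-multiplicity class (bivalents with exactly one or exactly two
#' foci). Bivalents with three or more foci are rare and are dropped, with
#' their count recorded.
#'
#' @param dataset A [FocusTable].
#' @param scheme A [SizeGroupScheme].
#' @param marker Marker label to select.
#' @param rerank Re-rank bivalents by measured SC length (default).
#' @return A [PositionTable].
#' @export
positionTable <- function(dataset, scheme = sizeGroupScheme(),
                          marker = "MLH1", rerank = TRUE) {
  stopifnot(is(dataset, "FocusTable"))
  d <- dataset@data
  cells <- groupIntoMeiocytes(FocusTable(d[d$marker == marker, ,
                                           drop = FALSE]))
  if (rerank) cells <- lapply(cells, rankBivalents)
  rows <- list(); dropped <- 0L
  for (m in cells) {
    for (b in m@bivalents) {
      k <- length(b@positions)
      if (k == 0) next
      if (k > 2) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        position = b@positions * 100,
        group = groupOfRank(scheme, b@rank), focusClass = as.integer(k),
        genotype = m@genotype, cellId = m@cellId, rank = b@rank,
        stringsAsFactors = FALSE)
    }
  }
  dat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = numeric(0), group = character(0),
               focusClass = integer(0), genotype = character(0),
               cellId = character(0), rank = integer(0))
  rownames(dat) <- NULL
  new("PositionTable", data = dat, droppedThreeFocus = dropped)
}

#' Fraction of foci inside a named region
#'
#' Positions are rounded to 0.1% before testing membership in the closed
#' region interval, so the returned one-decimal percentage matches
#' published report precision exactly.
#'
#' @param positions A [PositionTable] or numeric vector of percent
#'   positions.
#' @param region Region name in `regions`.
#' @param regions A [RegionSpec].
#' @return A list with `count`, `total`, `fraction` and `percent`
#'   (rounded to one decimal). An empty table gives `NA` fraction with a
#'   warning.
#' @export
#' @examples
#' pos <- c(rep(10, 43), rep(50, 978))  # 43 of 1021 proximal
#' regionFraction(pos, "proximal")$percent
regionFraction <- function(positions, region, regions = regionSpec()) {
  x <- if (is(positions, "PositionTable")) positions@data$position else
    as.numeric(positions)
  if (!region %in% names(regions@regions))
    stop("unknown region: ", region)
  if (!length(x)) {
    warning("no positions; region fraction undefined")
    return(list(count = 0L, total = 0L, fraction = NA_real_,
                percent = NA_real_))
  }
  r <- regions@regions[[region]]
  xr <- round(x, 1)
  count <- sum(xr >= r[1] & xr <= r[2])
  list(count = count, total = length(x), fraction = count / length(x),
       percent = round(100 * count / length(x), 1))
}

#' Central-region occupancy fold between genotypes
#'
#' Compares how often crossover foci fall in the central region of the
#' chromosome between two position tables, restricted by default to
#' two-focus bivalents on the larger chromosomes (size ranks 1-5, the
#' stratum where relaxed interference manifests as in-filling of the
#' inter-crossover gap). Returns the ratio of central-region fractions
#' and a two-sided Fisher's exact test on the 2x2 (central vs not) x
#' genotype table.
#'
#' @param a,b [PositionTable] objects (numerator and denominator).
#' @param focusClass Focus-multiplicity class to keep (default 2).
#' @param groups Size-group labels to keep (default `c("1-2", "3-5")`).
#' @param region Region name (default `"central"`).
#' @param regions A [RegionSpec].
#' @return A list with `fold` (ratio of fractions, `Inf` sentinel on a
#'   zero denominator), `fractionA`, `fractionB`, counts, and `fisher`
#'   (a [StatResult]).
#' @export
centralOccupancyFold <- function(a, b, focusClass = 2L,
                                 groups = c("1-2", "3-5"),
                                 region = "central",
                                 regions = regionSpec()) {
  pick <- function(pt) {
    d <- pt@data
    d <- d[d$focusClass == focusClass, , drop = FALSE]
    if (!is.null(groups)) d <- d[d$group %in% groups, , drop = FALSE]
    d$position
  }
  xa <- pick(a); xb <- pick(b)
  fa <- regionFraction(xa, region, regions)
  fb <- regionFraction(xb, region, regions)
  fold <- if (!is.na(fb$fraction) && fb$fraction > 0)
    fa$fraction / fb$fraction else Inf
  fisher <- fisherExact2x2(matrix(c(fa$count, fa$total - fa$count,
                                    fb$count, fb$total - fb$count),
                                  nrow = 2, byrow = TRUE))
  list(fold = fold, fractionA = fa$fraction, fractionB = fb$fraction,
       countA = fa$count, totalA = fa$total, countB = fb$count,
       totalB = fb$total, fisher = fisher)
}

#' Boundary-reflected Gaussian kernel density profile
#'
#' Gaussian kernel density of focus positions on the percent-SC axis,
#' reflected at the chromosome ends (0 and 100) so that the estimate
#' conserves total mass on `[0, 100]`. Bandwidth defaults to Silverman's
#' rule of thumb.
#'
#' @param positions A [PositionTable] or numeric vector of percent
#'   positions (at least 5).
#' @param bandwidth Kernel SD in percent SC; `NULL` for Silverman's rule.
#' @param grid Evaluation grid (default 0 to 100 by 0.5).
#' @return A data.frame with columns `position` and `density`.
#' @export
kdeProfile <- function(positions, bandwidth = NULL,
                       grid = seq(0, 100, by = 0.5)) {
  x <- if (is(positions, "PositionTable")) positions@data$position else
    as.numeric(positions)
  if (length(x) < 5)
    stop("need at least 5 positions for a density profile; ",
         "use a histogram instead")
  h <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  dens <- vapply(grid, function(g) {
    mean(dnorm(g, x, h) + dnorm(g, -x, h) + dnorm(g, 200 - x, h))
  }, numeric(1))
  data.frame(position = grid, density = dens)
}

## Scholz-Stephens k-sample Anderson-Darling statistic (midrank version
## for ties) and its standardisation.
.adStatistic <- function(samples) {
  k <- length(samples)
  n <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  z <- sort(unique(pooled))
  L <- length(z)
  lj <- as.vector(table(factor(pooled, levels = z)))
  Bj <- cumsum(lj) - lj / 2
  inner <- 0
  for (i in seq_len(k)) {
    fij <- as.vector(table(factor(samples[[i]], levels = z)))
    Mij <- cumsum(fij) - fij / 2
    denom <- Bj * (N - Bj) - N * lj / 4
    ok <- denom > 0
    inner <- inner + (1 / n[i]) *
      sum((lj[ok] / N) * (N * Mij[ok] - n[i] * Bj[ok])^2 / denom[ok])
  }
  (N - 1) / N * inner
}

.adVariance <- function(n) {
  k <- length(n); N <- sum(n)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  ## g = sum_{i=1}^{N-2} (1/(N-i)) * sum_{j=i+1}^{N-1} 1/j
  cumh <- cumsum(1 / seq_len(N - 1))
  i <- seq_len(N - 2)
  g <- sum((1 / (N - i)) * (cumh[N - 1] - cumh[i]))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H -
    8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
}

## p-value for the standardised statistic via the published critical-value
## standardisation: quantiles t_m(alpha) = b0 + b1/sqrt(m) + b2/m at five
## levels, interpolated/extrapolated on the logit scale by a quadratic.
.adPValue <- function(tObs, m) {
  alpha <- c(0.25, 0.10, 0.05, 0.025, 0.01)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  fit <- stats::lm(log(alpha / (1 - alpha)) ~ tm + I(tm^2))
  lp <- sum(stats::coef(fit) * c(1, tObs, tObs^2))
  stats::plogis(lp)
}

#' Anderson-Darling k-sample test
#'
#' The k-sample Anderson-Darling rank test (midrank version, so ties are
#' handled), comparing the overall shape of two or more position samples
#' without assuming any distributional form. The asymptotic p-value uses
#' the published standardisation of the statistic; `method =
#' "permutation"` instead estimates p by Monte-Carlo permutation of the
#' pooled sample, which serves as a distribution-free reference.
#'
#' @param groups List of k >= 2 numeric samples, each with n >= 2.
#' @param method `"asymptotic"` or `"permutation"`.
#' @param nPermutations Number of label permutations (permutation method).
#' @return A [StatResult] with the statistic `A2`, the standardised
#'   statistic `T` and the sample sizes. Degenerate pooled data (all
#'   values identical) give a flagged `NA` p.
#' @export
#' @examples
#' set.seed(1)
#' adKSample(list(rnorm(30), rnorm(30, 0.2)))
adKSample <- function(groups, method = c("asymptotic", "permutation"),
                      nPermutations = 10000L) {
  method <- match.arg(method)
  stopifnot(length(groups) >= 2)
  groups <- lapply(groups, as.numeric)
  n <- lengths(groups)
  if (any(n < 2)) stop("each sample needs at least 2 observations")
  pooled <- unlist(groups, use.names = FALSE)
  k <- length(groups); N <- sum(n)
  if (length(unique(pooled)) == 1)
    return(.statResult("Anderson-Darling k-sample test",
                       c(A2 = NA_real_), c(k = k, N = N), NA_real_,
                       note = "degenerate: pooled sample is constant"))
  a2 <- .adStatistic(groups)
  sigma <- sqrt(.adVariance(n))
  tObs <- (a2 - (k - 1)) / sigma
  if (method == "asymptotic") {
    p <- .adPValue(tObs, m = k - 1)
  } else {
    labels <- rep(seq_len(k), n)
    count <- 0L
    for (b in seq_len(nPermutations)) {
      perm <- sample(labels)
      a2p <- .adStatistic(split(pooled, perm))
      if (a2p >= a2 - 1e-12) count <- count + 1L
    }
    p <- (count + 1) / (nPermutations + 1)
  }
  .statResult("Anderson-Darling k-sample test",
              c(A2 = a2, T = tObs),
              c(k = k, N = N, sigma = sigma), p,
              note = if (method == "permutation")
                paste0("permutation p, ", nPermutations, " permutations")
              else "")
}
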