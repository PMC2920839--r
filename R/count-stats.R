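#' Summarise per-cell focus counts
#'
#' @param counts Integer vector of per-cell focus counts (n >= 1).
#' @param genotype,stage,marker Labels carried into the summary.
#' @return A [CountSummary] with the mean, the sample standard deviation
#'   (n - 1 denominator; `NA` for a single cell) and the cell count.
#' @export
#' @examples
#' summarizeFocusCounts(c(1, 2, 3, 4))
summarizeFocusCounts <- function(counts, genotype = "", stage = "",
                                 marker = "") {
  stopifnot(length(counts) >= 1)
  countSummary(mean(counts),
               if (length(counts) > 1) sd(counts) else NA_real_,
               length(counts), genotype = genotype, stage = stage,
               marker = marker)
}

.roundFold <- function(x, rounding) {
  switch(rounding,
         "one-decimal" = round(x, 1),
         "nearest-integer" = round(x),
         "nearest-ten" = round(x / 10) * 10,
         "none" = x,
         stop("unknown rounding convention: ", rounding))
}

#' Fold change between two count summaries
#'
#' @param a,b [CountSummary] objects or plain means (numerator,
#'   denominator).
#' @param rounding Printing convention: `"one-decimal"` (default),
#'   `"nearest-integer"`, `"nearest-ten"` or `"none"`.
#' @return A [FoldChange].
#' @export
#' @examples
#' ratio(foldChange(131.0, 18.2))  # 7.2
foldChange <- function(a, b, rounding = "one-decimal") {
  ma <- if (is(a, "CountSummary")) a@mean else as.numeric(a)
  mb <- if (is(b, "CountSummary")) b@mean else as.numeric(b)
  if (mb <= 0) stop("denominator mean must be positive")
  raw <- ma / mb
  new("FoldChange", numerator = ma, denominator = mb, raw = raw,
      ratio = .roundFold(raw, rounding), rounding = rounding)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with the two-sided p defined by the
#' probability-mass method: the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one. One-sided alternatives use the hypergeometric tail directly.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (referring to
#'   the `[1,1]` cell).
#' @return A [StatResult] carrying the sample odds ratio. A zero margin is
#'   degenerate and returns p = 1 flagged.
#' @export
#' @examples
#' pValue(fisherExact2x2(matrix(c(2, 0, 0, 2), 2)))  # 1/3
fisherExact2x2 <- function(table, alternative = "two.sided") {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  m <- sum(tab[1, ])          # row-1 total
  n <- sum(tab[2, ])          # row-2 total
  kk <- sum(tab[, 1])         # column-1 total
  x <- tab[1, 1]
  orEst <- unname((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  if (m == 0 || n == 0 || kk == 0 || sum(tab[, 2]) == 0)
    return(.statResult("Fisher's exact test", c(x = x),
                       c(m = m, n = n, k = kk), 1,
                       alternative = alternative,
                       estimate = c(oddsRatio = orEst),
                       note = "degenerate: a margin is zero"))
  support <- max(0, kk - n):min(kk, m)
  probs <- dhyper(support, m, n, kk)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= dhyper(x, m, n, kk) *
                                      (1 + 1e-7)]),
              greater = phyper(x - 1, m, n, kk, lower.tail = FALSE),
              less = phyper(x, m, n, kk),
              stop("unknown alternative: ", alternative))
  .statResult("Fisher's exact test", c(x = x), c(m = m, n = n, k = kk),
              min(p, 1), alternative = alternative,
              estimate = c(oddsRatio = orEst))
}

#' Likelihood-ratio (G) test of independence
#'
#' `G = 2 * sum(O * log(O / E))` over cells with positive observed counts,
#' with expected counts from the independence model, compared to a
#' chi-squared law with `(r - 1)(c - 1)` degrees of freedom. The Williams
#' small-sample correction is available but off by default.
#'
#' @param table r x c matrix of non-negative integer counts with positive
#'   margins.
#' @param williams Apply the Williams correction.
#' @return A [StatResult] with statistic `G`.
#' @export
#' @examples
#' statValue(gTest(matrix(c(10, 20, 20, 10), 2, byrow = TRUE)))
gTest <- function(table, williams = FALSE) {
  tab <- as.matrix(table)
  stopifnot(all(tab >= 0))
  r <- rowSums(tab); cl <- colSums(tab); N <- sum(tab)
  if (any(r == 0) || any(cl == 0))
    stop("zero expected count (empty row or column); pool categories")
  E <- outer(r, cl) / N
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  note <- ""
  if (williams) {
    q <- 1 + ((N * sum(1 / r) - 1) * (N * sum(1 / cl) - 1)) / (6 * N * df)
    G <- G / q
    note <- sprintf("Williams correction q = %.5f", q)
  }
  .statResult("G test of independence", c(G = G), c(df = df),
              pchisq(G, df, lower.tail = FALSE), note = note)
}

## Exact two-sided Mann-Whitney p under the permutation distribution of
## the rank sum, ties included, via a generating-function count over
## doubled midranks (integers). Equivalent to enumerating all
## choose(n1+n2, n1) splits.
.mwExactP <- function(ranks2, n1, obsR2) {
  N <- length(ranks2)
  maxSum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  minSum <- sum(sort(ranks2)[seq_len(n1)])
  ## counts[s + 1, offset + 1]: number of size-s subsets with doubled-rank
  ## sum equal to offset + minimal achievable, tracked densely from 0
  counts <- matrix(0, nrow = n1 + 1, ncol = maxSum + 1)
  counts[1, 1] <- 1
  for (r in ranks2) {
    smax <- n1
    for (s in smax:1) {
      nz <- which(counts[s, ] > 0)
      if (!length(nz)) next
      tgt <- nz + r
      keep <- tgt <= maxSum + 1
      counts[s + 1, tgt[keep]] <- counts[s + 1, tgt[keep]] +
        counts[s, nz[keep]]
    }
  }
  sums <- which(counts[n1 + 1, ] > 0) - 1
  ways <- counts[n1 + 1, sums + 1]
  mu <- n1 * (N + 1)                       # doubled-rank expectation
  dev <- abs(sums - mu)
  obsDev <- abs(obsR2 - mu)
  sum(ways[dev >= obsDev - 1e-9]) / sum(ways)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test on two samples of focus counts, without assuming
#' normality. For `n1 * n2 <= 400` (unless overridden) the p-value is
#' exact under the tie-aware permutation distribution of the rank sum
#' (equivalent to enumerating every split of the pooled sample); larger
#' samples use the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b Numeric samples (n >= 1 each).
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   decides by `n1 * n2 <= 400`.
#' @return A [StatResult] with statistic `U` (for sample `a`).
#' @export
#' @examples
#' pValue(mannWhitney(c(1, 2, 3), c(10, 11, 12)))  # exact 0.1
mannWhitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  if (is.null(exact)) exact <- (n1 * n2 <= 400)
  pooled <- c(a, b)
  rk <- rank(pooled)
  R1 <- sum(rk[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (exact) {
    p <- .mwExactP(as.integer(round(2 * rk)), n1, as.integer(round(2 * R1)))
    note <- "exact (tie-aware permutation distribution)"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tieCorr)
    mu <- n1 * n2 / 2
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    note <- "normal approximation with tie and continuity correction"
  }
  .statResult("Mann-Whitney test", c(U = U), c(n1 = n1, n2 = n2), p,
              note = note)
}

#' Distribution of focus multiplicities over bivalents
#'
#' Tallies bivalents carrying 0, 1, 2 or 3+ foci of the given marker
#' (zero-focus bivalent rows included, so achiasmate-like fractions are
#' computable).
#'
#' @param dataset A [FocusTable].
#' @param marker Marker label.
#' @param rerank Re-rank bivalents by length (only affects grouping of
#'   unranked input).
#' @return A list with `counts` (named integer vector over classes `"0"`,
#'   `"1"`, `"2"`, `"3+"`), `fractions` (summing to 1) and `n` bivalents.
#' @export
focusNumberDistribution <- function(dataset, marker = "MLH1",
                                    rerank = TRUE) {
  d <- dataset@data
  cells <- groupIntoMeiocytes(FocusTable(d[d$marker == marker, ,
                                           drop = FALSE]))
  k <- unlist(lapply(cells, function(m)
    vapply(m@bivalents, function(b) length(b@positions), integer(1))))
  cls <- cut(k, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  counts <- table(cls)
  list(counts = setNames(as.integer(counts), names(counts)),
       fractions = as.numeric(counts) / length(k), n = length(k))
}

#' Compare two event rates
#'
#' Two proportions, their fold ratio and a two-sided Fisher's exact test
#' on the underlying 2x2 table. For report parity the fold is computed on
#' the one-decimal-rounded percentages (the precision at which rates are
#' printed) and then rounded per convention.
#'
#' @param eventsA,nA,eventsB,nB Event and trial counts (events <= n).
#' @param rounding Fold rounding convention (see [foldChange()]).
#' @return A list with `rateA`, `rateB` (percent), `fold` (`Inf` sentinel
#'   when the denominator rate is zero) and `fisher` (a [StatResult]).
#' @export
#' @examples
#' rateComparison(10, 154, 1, 116)$fold  # 6.5% vs 0.9%: 7.2
rateComparison <- function(eventsA, nA, eventsB, nB,
                           rounding = "one-decimal") {
  stopifnot(eventsA <= nA, eventsB <= nB)
  rA <- eventsA / nA; rB <- eventsB / nB
  pA <- round(100 * rA, 1); pB <- round(100 * rB, 1)
  fold <- if (pB == 0) Inf else .roundFold(pA / pB, rounding)
  fisher <- fisherExact2x2(matrix(c(eventsA, nA - eventsA,
                                    eventsB, nB - eventsB),
                                  nrow = 2, byrow = TRUE))
  list(rateA = 100 * rA, rateB = 100 * rB, fold = fold, fisher = fisher)
}

#' Reconstruct counts from printed percentages
#'
#' Published contingency tables are often given as percentages with a
#' total N. This guard reconstructs integer counts by rounding
#' `percent * N / 100` and verifies that the reconstruction reproduces
#' every printed percentage at the printed precision; reconstructions
#' failing the check are flagged (attribute `ok`), never silently used.
#'
#' @param percents Printed percentages.
#' @param n Total count.
#' @param digits Printed precision (decimal places).
#' @return Integer counts with attribute `ok` (logical per entry); a
#'   warning is raised if any entry fails.
#' @export
#' @examples
#' reconstructCounts(c(32.5, 56.0, 11.5), 416)
reconstructCounts <- function(percents, n, digits = 1) {
  counts <- as.integer(round(percents * n / 100))
  back <- round(100 * counts / n, digits)
  ok <- back == round(percents, digits)
  if (any(!ok))
    warning("reconstruction failed for ", sum(!ok), " entr(ies): ",
            paste0(percents[!ok], "% of ", n, " -> ", counts[!ok],
                   " -> ", back[!ok], "%", collapse = "; "))
  structure(counts, ok = ok)
}
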