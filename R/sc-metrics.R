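#' Rank bivalents by SC length
#'
#' Assigns size ranks 1..k by descending SC length within a cell; ties are
#' broken by input order (stable sort), so re-running is idempotent. Cells
#' with fewer than 19 bivalents are ranked over the bivalents present.
#'
#' @param cell A [Meiocyte] with at least one bivalent.
#' @return The meiocyte with ranks assigned.
#' @export
#' @examples
#' m <- Meiocyte("c1", bivalents = list(Bivalent(NA, 5), Bivalent(NA, 9),
#'                                      Bivalent(NA, 7)))
#' vapply(rankBivalents(m)@bivalents, function(b) b@rank, integer(1))
rankBivalents <- function(cell) {
  stopifnot(is(cell, "Meiocyte"), length(cell@bivalents) >= 1)
  lens <- vapply(cell@bivalents, function(b) b@scLength, numeric(1))
  ord <- order(-lens)                       # stable: ties keep input order
  ranks <- integer(length(lens))
  ranks[ord] <- seq_along(ord)
  cell@bivalents <- mapply(function(b, r) { b@rank <- r; b },
                           cell@bivalents, as.integer(ranks),
                           SIMPLIFY = FALSE)
  cell
}

#' Total autosomal SC length of a cell
#'
#' @param cell A [Meiocyte].
#' @return Sum of SC lengths in micrometres (0 with a warning for an empty
#'   cell).
#' @export
totalAutosomalSC <- function(cell) {
  stopifnot(is(cell, "Meiocyte"))
  if (!length(cell@bivalents)) {
    warning("meiocyte has no bivalents; total SC length is 0")
    return(0)
  }
  sum(vapply(cell@bivalents, function(b) b@scLength, numeric(1)))
}

#' Percent of total SC length
#'
#' The reporting convention for SC-length tables: the mean SC length per
#' chromosome divided by the average total SC length per cell, multiplied
#' by 100.
#'
#' @param meanLength Mean SC length of a chromosome (um).
#' @param meanTotal Mean total autosomal SC length per cell (um).
#' @return Percentage (not rounded).
#' @export
#' @examples
#' percentOfTotalSC(12.8, 171.6)
percentOfTotalSC <- function(meanLength, meanTotal) {
  100 * meanLength / meanTotal
}

.bivalentFrame <- function(dataset, rerank = TRUE) {
  ## one row per bivalent: cell, genotype, rank, length
  cells <- groupIntoMeiocytes(dataset)
  if (rerank) cells <- lapply(cells, rankBivalents)
  do.call(rbind, lapply(cells, function(m) {
    data.frame(cell_id = m@cellId, genotype = m@genotype,
               rank = vapply(m@bivalents, function(b) b@rank, integer(1)),
               length = vapply(m@bivalents, function(b) b@scLength,
                               numeric(1)),
               nFoci = vapply(m@bivalents,
                              function(b) length(b@positions), integer(1)),
               nBivalents = length(m@bivalents),
               stringsAsFactors = FALSE)
  }))
}

#' Size-group summary of SC lengths
#'
#' Reproduces the standard SC-length table: per (genotype, size group)
#' mean and SD over chromosomes, the number of chromosomes, and the
#' percent of total SC ([percentOfTotalSC()], using the mean total over
#' complete 19-bivalent cells). Cells with incomplete bivalent sets are
#' excluded from the per-cell total (which needs all 19) but retained in
#' the per-group means.
#'
#' @param dataset A [FocusTable] of pachytene cells.
#' @param scheme A [SizeGroupScheme].
#' @param rerank Re-rank bivalents by measured length (default) rather
#'   than trusting stored ranks.
#' @return An [SCLengthSummary].
#' @export
scLengthSummary <- function(dataset, scheme = sizeGroupScheme(),
                            rerank = TRUE) {
  b <- .bivalentFrame(dataset, rerank = rerank)
  b$group <- groupOfRank(scheme, b$rank)
  out <- list(); meanTotal <- c(); nComplete <- c()
  for (g in unique(b$genotype)) {
    bg <- b[b$genotype == g, , drop = FALSE]
    complete <- bg[bg$nBivalents == 19L, , drop = FALSE]
    if (!nrow(complete)) {
      warning("genotype ", g, " has no complete 19-bivalent cell; ",
              "per-cell totals use the bivalents present")
      complete <- bg
    }
    totals <- tapply(complete$length, complete$cell_id, sum)
    meanTotal[g] <- mean(totals)
    nComplete[g] <- length(totals)
    for (lab in scheme@labels) {
      x <- bg$length[bg$group == lab]
      if (!length(x)) {
        warning("group ", lab, " has no chromosomes for genotype ", g,
                "; omitted")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, group = lab, meanLength = mean(x),
        sdLength = if (length(x) > 1) sd(x) else NA_real_,
        nChromosomes = length(x),
        percentOfTotal = percentOfTotalSC(mean(x), meanTotal[g]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  new("SCLengthSummary", table = tab,
      meanTotal = meanTotal, nCompleteCells = nComplete)
}

#' Compare SC lengths between two datasets
#'
#' Per size group, a two-sided two-sample t test on per-chromosome SC
#' lengths (Welch by default), plus a whole-genotype t test on per-cell
#' total SC lengths over complete cells.
#'
#' @param a,b [FocusTable] datasets (one genotype each).
#' @param scheme A [SizeGroupScheme].
#' @param pooledVar Use the pooled-variance t test instead of Welch.
#' @return A list with `groups` (named list of [StatResult], one per
#'   group) and `total` (a [StatResult] for per-cell totals). Groups with
#'   fewer than 2 observations on either side get an undefined flagged
#'   result.
#' @export
compareGroupLengths <- function(a, b, scheme = sizeGroupScheme(),
                                pooledVar = FALSE) {
  fa <- .bivalentFrame(a); fb <- .bivalentFrame(b)
  fa$group <- groupOfRank(scheme, fa$rank)
  fb$group <- groupOfRank(scheme, fb$rank)
  asRes <- function(ht, n1, n2) {
    .statResult(method = ht$method,
                statistic = c(t = unname(ht$statistic)),
                parameter = c(df = unname(ht$parameter), n1 = n1, n2 = n2),
                p.value = ht$p.value, alternative = "two.sided")
  }
  groups <- setNames(lapply(scheme@labels, function(lab) {
    xa <- fa$length[fa$group == lab]
    xb <- fb$length[fb$group == lab]
    if (length(xa) < 2 || length(xb) < 2)
      return(.statResult("Two-sample t test", c(t = NA_real_),
                         c(n1 = length(xa), n2 = length(xb)), NA_real_,
                         note = "fewer than 2 observations in a group"))
    asRes(stats::t.test(xa, xb, var.equal = pooledVar),
          length(xa), length(xb))
  }), scheme@labels)
  ta <- tapply(fa$length[fa$nBivalents == 19], fa$cell_id[fa$nBivalents == 19],
               sum)
  tb <- tapply(fb$length[fb$nBivalents == 19], fb$cell_id[fb$nBivalents == 19],
               sum)
  total <- if (length(ta) >= 2 && length(tb) >= 2)
    asRes(stats::t.test(ta, tb, var.equal = pooledVar), length(ta),
          length(tb))
  else .statResult("Two-sample t test", c(t = NA_real_),
                   c(n1 = length(ta), n2 = length(tb)), NA_real_,
                   note = "fewer than 2 complete cells")
  list(groups = groups, total = total)
}
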