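#' @import methods
#' @importFrom stats dgamma pgamma rgamma runif rnorm rpois rnbinom sd
#'   pchisq dhyper phyper uniroot optim setNames dnorm quantile format.pval
#' @importFrom utils read.table write.table head
NULL

## Prophase-I substage labels accepted throughout the package (closed enum).
.STAGES <- c("early-leptonema", "late-leptonema", "early-zygonema",
             "late-zygonema", "pachynema", "diplonema")

#' Prophase I substage labels
#'
#' The closed set of substage labels accepted in the `stage` column of a
#' [FocusTable]. Unknown labels are rejected at read time.
#'
#' @return Character vector of the six recognised substage labels.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() .STAGES

.FOCUS_COLUMNS <- c("cell_id", "genotype", "stage", "chromosome_rank",
                    "sc_length_um", "focus_position_frac", "marker")

#' Table of immunofluorescent focus measurements
#'
#' The pipeline's universal input: one row per detected focus, or one row
#' with an empty `focus_position_frac` for a bivalent on which no focus was
#' detected (zero-focus bivalents are first-class so achiasmate and
#' obligate-crossover statistics stay computable). Positions are stored as
#' fractions of SC length in `[0, 1]` measured from the centromeric end
#' (mouse autosomes are telocentric, so 0 is the centromere); reporting
#' layers convert to percent of SC length.
#'
#' @slot data A `data.frame` with columns `cell_id`, `genotype`, `stage`,
#'   `chromosome_rank` (integer 1-19 or `NA` for unranked),
#'   `sc_length_um` (positive), `focus_position_frac` (fraction in
#'   `[0, 1]`, `NA` on zero-focus rows) and `marker`.
#' @export
setClass("FocusTable", representation(data = "data.frame"))

.validateFocusRows <- function(d) {
  ## returns a character vector of row-level problems, "" if none
  msg <- character(nrow(d))
  bad_stage <- !(d$stage %in% .STAGES)
  msg[bad_stage] <- paste0("unknown stage label '", d$stage[bad_stage], "'")
  bad_len <- !is.finite(d$sc_length_um) | d$sc_length_um <= 0
  msg[bad_len & !nzchar(msg)] <- "sc_length_um must be positive"
  pos <- d$focus_position_frac
  bad_pos <- !is.na(pos) & (pos < 0 | pos > 1)
  msg[bad_pos & !nzchar(msg)] <-
    paste0("focus_position_frac ", pos[bad_pos & !nzchar(msg)],
           " outside [0, 1]")
  bad_rank <- !is.na(d$chromosome_rank) &
    (d$chromosome_rank < 1 | d$chromosome_rank > 19 |
       d$chromosome_rank != round(d$chromosome_rank))
  msg[bad_rank & !nzchar(msg)] <- "chromosome_rank must be in 1..19 or NA"
  msg
}

setValidity("FocusTable", function(object) {
  d <- object@data
  missing <- setdiff(.FOCUS_COLUMNS, names(d))
  if (length(missing))
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  msg <- .validateFocusRows(d)
  bad <- which(nzchar(msg))
  if (length(bad))
    return(paste0("row ", bad[1], ": ", msg[bad[1]]))
  ## within one cell, a rank identifies at most one bivalent (one SC length)
  ranked <- d[!is.na(d$chromosome_rank), , drop = FALSE]
  if (nrow(ranked)) {
    key <- paste(ranked$cell_id, ranked$chromosome_rank)
    n_len <- tapply(ranked$sc_length_um, key, function(x) length(unique(x)))
    if (any(n_len > 1))
      return(paste0("cell/rank '", names(n_len)[which(n_len > 1)[1]],
                    "' carries conflicting sc_length_um values"))
  }
  TRUE
})

#' @describeIn FocusTable Construct a validated focus table from a
#'   data.frame carrying the documented columns.
#' @param data A data.frame with the documented columns.
#' @export
FocusTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("cell_id", "genotype", "stage", "marker"))
    if (col %in% names(data)) data[[col]] <- as.character(data[[col]])
  if ("chromosome_rank" %in% names(data))
    data$chromosome_rank <- as.integer(data$chromosome_rank)
  for (col in c("sc_length_um", "focus_position_frac"))
    if (col %in% names(data)) data[[col]] <- as.numeric(data[[col]])
  rownames(data) <- NULL
  new("FocusTable", data = data[, intersect(.FOCUS_COLUMNS, names(data)),
                                drop = FALSE])
}

setMethod("show", "FocusTable", function(object) {
  d <- object@data
  cat("FocusTable with", nrow(d), "rows (",
      sum(!is.na(d$focus_position_frac)), "foci,",
      sum(is.na(d$focus_position_frac)), "zero-focus bivalent rows )\n")
  cat("  genotypes:", paste(unique(d$genotype), collapse = ", "), "\n")
  cat("  stages:   ", paste(unique(d$stage), collapse = ", "), "\n")
  cat("  markers:  ", paste(unique(d$marker), collapse = ", "), "\n")
  cat("  cells:    ", length(unique(d$cell_id)), "\n")
})

#' One synapsed chromosome pair
#'
#' @slot rank Integer size rank (1 = largest SC, 19 = smallest), `NA` if
#'   unranked.
#' @slot scLength SC length in micrometres.
#' @slot positions Sorted focus positions as fractions of SC length in
#'   `[0, 1]` from the centromeric end; length 0 for an achiasmate-like
#'   bivalent with no detected focus.
#' @export
setClass("Bivalent", representation(rank = "integer", scLength = "numeric",
                                    positions = "numeric"))

setValidity("Bivalent", function(object) {
  if (length(object@scLength) != 1L || !is.finite(object@scLength) ||
      object@scLength <= 0)
    return("scLength must be a single positive number")
  p <- object@positions
  if (length(p) && (any(p < 0 | p > 1)))
    return("positions must lie in [0, 1]")
  if (is.unsorted(p)) return("positions must be sorted ascending")
  TRUE
})

#' @describeIn Bivalent Constructor; positions are sorted for you.
#' @param rank,scLength,positions See slots.
#' @export
Bivalent <- function(rank = NA_integer_, scLength, positions = numeric(0)) {
  new("Bivalent", rank = as.integer(rank), scLength = as.numeric(scLength),
      positions = sort(as.numeric(positions)))
}

#' Pairs of foci closer than the optical resolution gap
#'
#' Adjacent focus pairs separated by less than `gap` (default 0.005 of SC
#' length, about the resolution limit of light microscopy) are flagged, not
#' merged: they are indistinguishable from a single focus in real images,
#' and downstream interval counts should be interpreted accordingly.
#'
#' @param bivalent A [Bivalent].
#' @param gap Minimum resolvable separation, as a fraction of SC length.
#' @return Integer indices `i` such that positions `i` and `i + 1` are
#'   closer than `gap`.
#' @export
closePairs <- function(bivalent, gap = 0.005) {
  p <- bivalent@positions
  if (length(p) < 2) return(integer(0))
  which(diff(p) < gap)
}

#' One spread meiotic nucleus
#'
#' @slot cellId Opaque cell identifier.
#' @slot genotype,stage Labels.
#' @slot bivalents List of [Bivalent] objects (at most 19 autosomal).
#' @export
setClass("Meiocyte", representation(cellId = "character",
                                    genotype = "character",
                                    stage = "character",
                                    bivalents = "list"))

setValidity("Meiocyte", function(object) {
  if (length(object@bivalents) > 19)
    return("at most 19 autosomal bivalents per meiocyte")
  if (!all(vapply(object@bivalents, is, TRUE, class2 = "Bivalent")))
    return("bivalents must be a list of Bivalent objects")
  r <- vapply(object@bivalents, function(b) b@rank, integer(1))
  r <- r[!is.na(r)]
  if (anyDuplicated(r)) return("assigned ranks must not repeat")
  if (length(r) && (any(r < 1 | r > 19)))
    return("ranks must be a subset of 1..19")
  TRUE
})

#' @describeIn Meiocyte Constructor.
#' @param cellId,genotype,stage,bivalents See slots.
#' @export
Meiocyte <- function(cellId, genotype = "", stage = "pachynema",
                     bivalents = list()) {
  new("Meiocyte", cellId = as.character(cellId),
      genotype = as.character(genotype), stage = as.character(stage),
      bivalents = bivalents)
}

setMethod("show", "Meiocyte", function(object) {
  k <- vapply(object@bivalents, function(b) length(b@positions), integer(1))
  cat("Meiocyte", object@cellId, "(", object@genotype, ",", object@stage,
      "):", length(object@bivalents), "bivalents,", sum(k), "foci\n")
})

#' Size-rank grouping scheme
#'
#' Bivalents rank-ordered by SC length from largest (1) to smallest (19)
#' are divided into groups of similarly sized chromosomes. The default
#' grouping is 1-2, 3-5, 6-11, 12-16, 17-19.
#'
#' @slot lo,hi Inclusive rank bounds per group.
#' @slot labels Group labels, e.g. `"1-2"`.
#' @export
setClass("SizeGroupScheme", representation(lo = "integer", hi = "integer",
                                           labels = "character"))

setValidity("SizeGroupScheme", function(object) {
  lo <- object@lo; hi <- object@hi
  if (length(lo) != length(hi) || length(lo) != length(object@labels))
    return("lo, hi and labels must have equal length")
  if (any(lo > hi)) return("each interval needs lo <= hi")
  if (is.unsorted(lo, strictly = TRUE)) return("intervals must be ordered")
  covered <- unlist(mapply(seq, lo, hi, SIMPLIFY = FALSE))
  if (anyDuplicated(covered)) return("intervals must be disjoint")
  if (!setequal(covered, 1:19)) return("intervals must jointly cover 1..19")
  TRUE
})

#' @describeIn SizeGroupScheme Constructor; defaults to the standard
#'   five-group scheme.
#' @param lo,hi Integer vectors of inclusive rank bounds.
#' @export
sizeGroupScheme <- function(lo = c(1L, 3L, 6L, 12L, 17L),
                            hi = c(2L, 5L, 11L, 16L, 19L)) {
  labels <- ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi))
  new("SizeGroupScheme", lo = as.integer(lo), hi = as.integer(hi),
      labels = labels)
}

#' @describeIn SizeGroupScheme Map ranks to group labels (`NA` rank maps to
#'   `NA`).
#' @param scheme A `SizeGroupScheme`.
#' @param ranks Integer ranks.
#' @export
groupOfRank <- function(scheme, ranks) {
  idx <- findInterval(ranks, scheme@lo)
  out <- scheme@labels[idx]
  out[is.na(ranks)] <- NA_character_
  out
}

#' Named regions on the percent-SC axis
#'
#' Default regions: proximal `[0, 15]` (the centromere-proximal ~15% where
#' crossover foci are rare), central `[40, 75]` and distal `[80, 95]`.
#' Region membership uses closed intervals after rounding positions to
#' 0.1%, so fractions match one-decimal printed percentages exactly.
#'
#' @slot regions Named list of numeric `c(lo, hi)` with
#'   `0 <= lo < hi <= 100`.
#' @export
setClass("RegionSpec", representation(regions = "list"))

setValidity("RegionSpec", function(object) {
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    if (length(r) != 2 || r[1] < 0 || r[2] > 100 || r[1] >= r[2])
      return(paste0("region '", nm, "' must satisfy 0 <= lo < hi <= 100"))
  }
  TRUE
})

#' @describeIn RegionSpec Constructor with the default three regions.
#' @param regions Named list of `c(lo, hi)` percent intervals.
#' @export
regionSpec <- function(regions = list(proximal = c(0, 15),
                                      central = c(40, 75),
                                      distal = c(80, 95))) {
  new("RegionSpec", regions = regions)
}

#' Fitted gamma interference model
#'
#' Inter-focus distances are modelled as gamma with shape `shape` and mean
#' `meanSpacing` (rate `shape/meanSpacing`); shape 1 corresponds to no
#' interference (exponential spacing) and larger shapes to more even
#' spacing. When a truncation `window` and finite `span` are set, the fit
#' maximises the likelihood of the observable-distance model (see
#' [fitTruncatedGammaShape]).
#'
#' @slot shape Shape parameter estimate (`Inf` sentinel for degenerate
#'   all-equal data).
#' @slot meanSpacing Mean spacing estimate, in `unit`.
#' @slot unit `"percent"` (of SC length) or `"um"`.
#' @slot window Observable-distance window `c(lo, hi)`; `c(0, Inf)` means
#'   untruncated.
#' @slot span Finite SC span used in the observability weight; `Inf`
#'   disables the weight.
#' @slot nIntervals Number of distances fitted.
#' @slot logLik Log-likelihood at the optimum (of the model actually
#'   fitted).
#' @slot converged Logical; `FALSE` flags a fit that fell back to the
#'   naive estimate.
#' @slot method `"mle"` or `"mle-truncated"`.
#' @export
setClass("GammaInterferenceModel",
         representation(shape = "numeric", meanSpacing = "numeric",
                        unit = "character", window = "numeric",
                        span = "numeric", nIntervals = "integer",
                        logLik = "numeric", converged = "logical",
                        method = "character"))

setMethod("show", "GammaInterferenceModel", function(object) {
  cat("GammaInterferenceModel (", object@method, ")\n", sep = "")
  cat(sprintf("  shape: %.3f   mean spacing: %.2f %s   n = %d\n",
              object@shape, object@meanSpacing,
              if (object@unit == "percent") "% SC" else "um",
              object@nIntervals))
  if (is.finite(object@window[2]) || object@window[1] > 0)
    cat(sprintf("  window: [%.2f, %.2f], span %.1f\n", object@window[1],
                object@window[2], object@span))
  cat(sprintf("  logLik: %.3f   converged: %s\n", object@logLik,
              object@converged))
})

#' @describeIn GammaInterferenceModel Shape-parameter accessor.
#' @param object A `GammaInterferenceModel`.
#' @export
shapeEstimate <- function(object) object@shape

#' @describeIn GammaInterferenceModel Mean-spacing accessor.
#' @export
meanSpacing <- function(object) object@meanSpacing

#' Set of adjacent inter-focus distances
#'
#' @slot distances Adjacent-pair distances, in `unit`.
#' @slot unit `"percent"` or `"um"`.
#' @slot group Size-group label per distance.
#' @slot sourceSC Source-bivalent SC span in the same unit (100 for
#'   percent units).
#' @slot cellId Source cell per distance.
#' @export
setClass("DistanceSet", representation(distances = "numeric",
                                       unit = "character",
                                       group = "character",
                                       sourceSC = "numeric",
                                       cellId = "character"))

setValidity("DistanceSet", function(object) {
  if (any(object@distances <= 0)) return("distances must be positive")
  if (any(object@distances > object@sourceSC + 1e-9))
    return("distances must not exceed the source SC span")
  TRUE
})

setMethod("show", "DistanceSet", function(object) {
  cat("DistanceSet:", length(object@distances), "distances (",
      if (object@unit == "percent") "% SC" else "um", ")\n")
  if (length(object@distances))
    cat(sprintf("  mean %.2f  sd %.2f  groups: %s\n",
                mean(object@distances), sd(object@distances),
                paste(unique(object@group), collapse = ", ")))
})

#' @describeIn DistanceSet Distance accessor.
#' @param object A `DistanceSet`.
#' @export
distances <- function(object) object@distances

#' Uniform container for a named test statistic
#'
#' @slot method Test name.
#' @slot statistic Named statistic value.
#' @slot parameter Named degrees of freedom or sample sizes.
#' @slot p.value P-value in `[0, 1]` (`NA` when flagged undefined).
#' @slot alternative Sidedness.
#' @slot estimate Named auxiliary estimates (e.g. an odds ratio).
#' @slot note Diagnostic note ("" if none).
#' @export
setClass("StatResult", representation(method = "character",
                                      statistic = "numeric",
                                      parameter = "numeric",
                                      p.value = "numeric",
                                      alternative = "character",
                                      estimate = "numeric",
                                      note = "character"))

setValidity("StatResult", function(object) {
  p <- object@p.value
  if (length(p) == 1 && !is.na(p) && (p < 0 || p > 1))
    return("p.value must lie in [0, 1]")
  TRUE
})

.statResult <- function(method, statistic, parameter = numeric(0),
                        p.value = NA_real_, alternative = "two.sided",
                        estimate = numeric(0), note = "") {
  new("StatResult", method = method, statistic = statistic,
      parameter = parameter, p.value = as.numeric(p.value),
      alternative = alternative, estimate = estimate, note = note)
}

setMethod("show", "StatResult", function(object) {
  cat(object@method, "\n")
  if (length(object@statistic))
    cat(" ", paste(names(object@statistic), "=",
                   signif(object@statistic, 5), collapse = ", "))
  if (length(object@parameter))
    cat(", ", paste(names(object@parameter), "=",
                    signif(object@parameter, 5), collapse = ", "))
  cat(", p =", format.pval(object@p.value, digits = 4), "(",
      object@alternative, ")\n")
  if (length(object@estimate))
    cat(" ", paste(names(object@estimate), "=", signif(object@estimate, 5),
                   collapse = ", "), "\n")
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @describeIn StatResult P-value accessor.
#' @param object A `StatResult`.
#' @export
pValue <- function(object) object@p.value

#' @describeIn StatResult Statistic accessor (named numeric).
#' @export
statValue <- function(object) object@statistic

#' Summary of per-cell focus counts
#'
#' @slot genotype,stage,marker Labels.
#' @slot mean,sd Mean and sample standard deviation of foci per cell.
#' @slot n Number of cells.
#' @export
setClass("CountSummary", representation(genotype = "character",
                                        stage = "character",
                                        marker = "character",
                                        mean = "numeric", sd = "numeric",
                                        n = "integer"))

setValidity("CountSummary", function(object) {
  if (object@n < 1) return("n must be >= 1")
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' @describeIn CountSummary Constructor from a published or computed
#'   mean/sd/n triple.
#' @param mean,sd,n,genotype,stage,marker See slots.
#' @export
countSummary <- function(mean, sd, n, genotype = "", stage = "",
                         marker = "") {
  new("CountSummary", genotype = genotype, stage = stage, marker = marker,
      mean = as.numeric(mean), sd = as.numeric(sd), n = as.integer(n))
}

setMethod("show", "CountSummary", function(object) {
  cat(sprintf("CountSummary %s %s %s: %.1f +/- %.1f foci/cell (n = %d)\n",
              object@genotype, object@marker, object@stage, object@mean,
              object@sd, object@n))
})

#' Fold change between two means or rates
#'
#' @slot numerator,denominator The two means.
#' @slot raw Unrounded ratio.
#' @slot ratio Ratio rounded per `rounding`.
#' @slot rounding `"one-decimal"`, `"nearest-integer"`, `"nearest-ten"` or
#'   `"none"`.
#' @export
setClass("FoldChange", representation(numerator = "numeric",
                                      denominator = "numeric",
                                      raw = "numeric", ratio = "numeric",
                                      rounding = "character"))

setMethod("show", "FoldChange", function(object) {
  cat(sprintf("FoldChange: %.4g / %.4g = %.4g (%s -> %g)\n",
              object@numerator, object@denominator, object@raw,
              object@rounding, object@ratio))
})

#' @describeIn FoldChange Rounded-ratio accessor.
#' @param object A `FoldChange`.
#' @export
ratio <- function(object) object@ratio

#' Generative description of one simulated genotype
#'
#' Defaults are set by [wildTypeParams()] and [trip13ModParams()]; see
#' those constructors for the study conditions they encode.
#'
#' @slot genotype,stage,marker Labels written into the simulated table.
#' @slot scLengthMean,scLengthSd Per-rank SC length law (micrometres,
#'   length 19, rank 1 = largest).
#' @slot shape Gamma shape of the crossover spacing law (1 = no
#'   interference).
#' @slot meanSpacing Mean inter-crossover spacing as a fraction of SC
#'   length.
#' @slot detectionEff Per-focus detection probability.
#' @slot proximalWindow Centromere-proximal window (fraction of SC).
#' @slot proximalRetention Probability that a crossover in the proximal
#'   window is retained.
#' @slot obligate Enforce at least one focus per bivalent by bounded
#'   resampling (at most 100 retries).
#' @slot nCells Number of meiocytes to simulate.
#' @slot seed RNG seed used by [simulateDataset()].
#' @export
setClass("SimulationParams",
         representation(genotype = "character", stage = "character",
                        marker = "character", scLengthMean = "numeric",
                        scLengthSd = "numeric", shape = "numeric",
                        meanSpacing = "numeric", detectionEff = "numeric",
                        proximalWindow = "numeric",
                        proximalRetention = "numeric", obligate = "logical",
                        nCells = "integer", seed = "integer"))

setValidity("SimulationParams", function(object) {
  if (length(object@scLengthMean) != 19 || length(object@scLengthSd) != 19)
    return("scLengthMean and scLengthSd must have length 19")
  if (any(object@scLengthMean <= 0)) return("scLengthMean must be positive")
  if (object@shape <= 0) return("shape must be > 0")
  if (object@meanSpacing <= 0) return("meanSpacing must be > 0")
  for (nm in c("detectionEff", "proximalRetention")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) return(paste(nm, "must lie in [0, 1]"))
  }
  if (object@proximalWindow < 0 || object@proximalWindow > 1)
    return("proximalWindow must lie in [0, 1]")
  if (object@nCells < 1) return("nCells must be >= 1")
  TRUE
})

#' @describeIn SimulationParams General constructor.
#' @param genotype,stage,marker,scLengthMean,scLengthSd,shape,meanSpacing
#'   See slots.
#' @param detectionEff,proximalWindow,proximalRetention,obligate,nCells,seed
#'   See slots.
#' @export
simulationParams <- function(genotype, scLengthMean, scLengthSd, shape,
                             meanSpacing, detectionEff = 1,
                             proximalWindow = 0.15, proximalRetention = 0.25,
                             obligate = TRUE, nCells = 32L, seed = 1L,
                             stage = "pachynema", marker = "MLH1") {
  new("SimulationParams", genotype = genotype, stage = stage,
      marker = marker, scLengthMean = as.numeric(scLengthMean),
      scLengthSd = as.numeric(scLengthSd), shape = as.numeric(shape),
      meanSpacing = as.numeric(meanSpacing),
      detectionEff = as.numeric(detectionEff),
      proximalWindow = as.numeric(proximalWindow),
      proximalRetention = as.numeric(proximalRetention),
      obligate = isTRUE(obligate), nCells = as.integer(nCells),
      seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams for", object@genotype, "(", object@stage, ",",
      object@marker, ")\n")
  cat(sprintf("  shape %.2f, mean spacing %.3f SC, detection %.2f\n",
              object@shape, object@meanSpacing, object@detectionEff))
  cat(sprintf("  proximal window %.2f (retention %.2f), obligate %s\n",
              object@proximalWindow, object@proximalRetention,
              object@obligate))
  cat(sprintf("  %d cells, seed %d\n", object@nCells, object@seed))
})

#' Per-stage focus-count model
#'
#' Matches a published mean and standard deviation of foci per cell with an
#' overdispersed (negative binomial) or Poisson count law; see
#' [simulateStageCounts()].
#'
#' @slot genotype,stage,marker Labels.
#' @slot mean,sd Target foci-per-cell mean and SD.
#' @slot nCells Default number of cells to draw.
#' @export
setClass("CountModel", representation(genotype = "character",
                                      stage = "character",
                                      marker = "character",
                                      mean = "numeric", sd = "numeric",
                                      nCells = "integer"))

setValidity("CountModel", function(object) {
  if (object@mean < 0 || object@sd < 0) return("mean and sd must be >= 0")
  TRUE
})

#' @describeIn CountModel Constructor.
#' @param genotype,stage,marker,mean,sd,nCells See slots.
#' @export
countModel <- function(mean, sd, genotype = "", stage = "", marker = "",
                       nCells = 200L) {
  new("CountModel", genotype = genotype, stage = stage, marker = marker,
      mean = as.numeric(mean), sd = as.numeric(sd),
      nCells = as.integer(nCells))
}

#' Table-shaped SC length summary
#'
#' @slot table Per (genotype, group) rows: mean, SD, N chromosomes and
#'   percent of total SC.
#' @slot meanTotal Named per-genotype mean total autosomal SC length over
#'   complete cells.
#' @slot nCompleteCells Named per-genotype count of cells with all 19
#'   bivalents.
#' @export
setClass("SCLengthSummary", representation(table = "data.frame",
                                           meanTotal = "numeric",
                                           nCompleteCells = "numeric"))

setMethod("show", "SCLengthSummary", function(object) {
  cat("SCLengthSummary (mean total per cell:",
      paste(names(object@meanTotal), round(object@meanTotal, 1),
            collapse = ", "), "um )\n")
  print(object@table, digits = 3, row.names = FALSE)
})

#' @describeIn SCLengthSummary Summary-table accessor.
#' @param object An `SCLengthSummary`.
#' @export
summaryTable <- function(object) object@table

#' Stratified crossover-focus positions
#'
#' One row per MLH1 focus on a one- or two-focus bivalent: position in
#' percent of SC from the centromere, size group, focus-multiplicity class
#' and genotype. Three-focus bivalents are rare and omitted (their count is
#' kept in `droppedThreeFocus`).
#'
#' @slot data A data.frame with columns `position`, `group`, `focusClass`,
#'   `genotype`, `cellId`, `rank`.
#' @slot droppedThreeFocus Number of bivalents dropped for carrying 3 or
#'   more foci.
#' @export
setClass("PositionTable", representation(data = "data.frame",
                                         droppedThreeFocus = "integer"))

setValidity("PositionTable", function(object) {
  d <- object@data
  if (nrow(d) && (any(d$position < 0 | d$position > 100)))
    return("positions must lie in [0, 100]")
  if (nrow(d) && !all(d$focusClass %in% c(1L, 2L)))
    return("focusClass must be 1 or 2")
  TRUE
})

setMethod("show", "PositionTable", function(object) {
  d <- object@data
  cat("PositionTable:", nrow(d), "focus positions (% SC);",
      object@droppedThreeFocus, "bivalents with 3+ foci dropped\n")
  if (nrow(d)) print(table(d$genotype, d$focusClass))
})

#' @describeIn PositionTable Position-data accessor.
#' @param object A `PositionTable`.
#' @export
positionData <- function(object) object@data

#' @describeIn FocusTable Accessor for the underlying data.frame.
#' @param object A `FocusTable`.
#' @export
focusData <- function(object) object@data

#' @describeIn FocusTable Number of focus rows (zero-focus rows excluded).
#' @export
nFoci <- function(object) sum(!is.na(object@data$focus_position_frac))
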