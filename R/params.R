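## Per-rank SC-length laws: group means/SDs expanded to ranks 1..19.
.SC_GROUP_RANKS <- list(1:2, 3:5, 6:11, 12:16, 17:19)

.expandRanks <- function(groupValues) {
  out <- numeric(19)
  for (i in seq_along(.SC_GROUP_RANKS)) out[.SC_GROUP_RANKS[[i]]] <-
      groupValues[i]
  out
}

#' Default wild-type simulation parameters
#'
#' Encodes the study conditions of normal mouse pachytene spermatocytes:
#' per-rank SC length laws taken from the published size-group means and
#' SDs (group means 12.8, 11.1, 9.5, 7.7, 5.8 um with SDs 1.7, 1.2, 1.1,
#' 0.9, 1.3, applied to every rank in the group, giving a mean total
#' autosomal SC length of 171.8 um), interference shape 10.9 (the
#' corrected all-chromosome estimate for wild type), an obligate
#' crossover, centromere-proximal suppression over the first 15% of the SC
#' with retention 0.25 (reproducing the ~4% of foci observed in the
#' proximal region), full detection, and a mean spacing of 0.88 SC
#' fractions, calibrated once so that the mean observable inter-focus
#' distance is about 60.8% of SC length.
#'
#' @param nCells Number of cells (default 32, the wild-type sample size).
#' @param seed RNG seed.
#' @return A [SimulationParams].
#' @export
wildTypeParams <- function(nCells = 32L, seed = 101L) {
  simulationParams(
    genotype = "wild-type",
    scLengthMean = .expandRanks(c(12.8, 11.1, 9.5, 7.7, 5.8)),
    scLengthSd = .expandRanks(c(1.7, 1.2, 1.1, 0.9, 1.3)),
    shape = 10.9, meanSpacing = 0.88, detectionEff = 1,
    proximalWindow = 0.15, proximalRetention = 0.25, obligate = TRUE,
    nCells = nCells, seed = seed)
}

#' Default Trip13-hypomorph simulation parameters
#'
#' Encodes the mutant study conditions: shorter SCs (group means 11.0,
#' 9.5, 8.1, 6.8, 5.2 um; SDs 1.0, 0.7, 0.7, 0.6, 1.0; mean total 148.7
#' um), weaker interference (shape 9.2), no obligate-crossover enforcement
#' (the mutant shows achiasmate bivalents), and a mean spacing of 0.82 SC
#' fractions calibrated so that the mean observable inter-focus distance
#' is about 56.8% of SC length.
#'
#' @param nCells Number of cells (default 20, the mutant sample size).
#' @param seed RNG seed.
#' @return A [SimulationParams].
#' @export
trip13ModParams <- function(nCells = 20L, seed = 202L) {
  simulationParams(
    genotype = "Trip13-mod",
    scLengthMean = .expandRanks(c(11.0, 9.5, 8.1, 6.8, 5.2)),
    scLengthSd = .expandRanks(c(1.0, 0.7, 0.7, 0.6, 1.0)),
    shape = 9.2, meanSpacing = 0.82, detectionEff = 1,
    proximalWindow = 0.15, proximalRetention = 0.25, obligate = FALSE,
    nCells = nCells, seed = seed)
}

#' Published per-stage focus-count models
#'
#' The early recombination focus counts (mean +/- SD of foci per cell) for
#' RPA, RAD51/DMC1 (an anti-RAD51 antibody cross-reacting with DMC1) and
#' DMC1 across prophase substages and genotypes, as a data.frame. Use
#' [countModelFor()] to pull one row as a [CountModel].
#'
#' @return A data.frame with columns `marker`, `stage`, `genotype`,
#'   `mean`, `sd`.
#' @export
#' @examples
#' head(stageCountModels())
stageCountModels <- function() {
  rbind(
    ## RPA counts were measured at leptonema; filed under late-leptonema
    ## because the stage enum splits leptonema into early/late
    data.frame(marker = "RPA", stage = "late-leptonema",
               genotype = c("wild-type", "Trip13-mod", "Trip13-sev"),
               mean = c(27.6, 52.1, 70.2), sd = c(22.0, 20.9, 26.9)),
    data.frame(marker = "RAD51/DMC1",
               stage = rep(c("early-leptonema", "late-leptonema",
                             "early-zygonema", "late-zygonema",
                             "pachynema", "diplonema"), each = 3),
               genotype = rep(c("wild-type", "Trip13-mod", "Trip13-sev"),
                              6),
               mean = c(130.7, 82.3, 33.3, 179.3, 146.9, 99.5,
                        219.7, 189.9, 144.5, 133.3, 156.3, 136.9,
                        18.2, 131.0, 99.0, 6.0, 13.0, NA),
               sd = c(60.4, 52.0, 43.3, 45.3, 50.4, 35.5,
                      49.1, 36.4, 22.7, 43.7, 34.8, 21.6,
                      7.0, 14.5, 42.6, 6.2, 8.9, NA)),
    data.frame(marker = "DMC1",
               stage = rep(c("early-leptonema", "late-leptonema",
                             "early-zygonema", "late-zygonema",
                             "pachynema"), each = 2),
               genotype = rep(c("wild-type", "Trip13-sev"), 5),
               mean = c(33.7, 45.5, 147.8, 147.8, 141.8, 169.7,
                        77.2, 166.0, 0.4, 147.8),
               sd = c(17.0, 22.2, 50.7, 38.1, 31.1, 21.9,
                      27.0, 19.2, 0.7, 23.5)))
}

#' @describeIn stageCountModels Look up one (marker, stage, genotype)
#'   combination as a [CountModel].
#' @param marker,stage,genotype Labels matching a row of the table.
#' @param nCells Number of cells the model should draw by default.
#' @export
countModelFor <- function(marker, stage, genotype, nCells = 200L) {
  d <- stageCountModels()
  row <- d[d$marker == marker & d$stage == stage & d$genotype == genotype, ]
  if (nrow(row) != 1 || is.na(row$mean))
    stop("no count model for ", marker, " / ", stage, " / ", genotype)
  countModel(row$mean, row$sd, genotype = genotype, stage = stage,
             marker = marker, nCells = nCells)
}
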