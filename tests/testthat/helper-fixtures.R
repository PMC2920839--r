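## Small in-code fixtures shared across test files.

## A hand-written focus frame: two cells, ranked bivalents, one zero-focus
## bivalent and one multi-focus bivalent with out-of-order positions.
makeFocusFrame <- function() {
  data.frame(
    cell_id = c("c1", "c1", "c1", "c1", "c2", "c2"),
    genotype = "wild-type",
    stage = "pachynema",
    chromosome_rank = c(1L, 1L, 2L, 3L, 1L, 2L),
    sc_length_um = c(12.5, 12.5, 11.0, 9.25, 13.0, 10.5),
    focus_position_frac = c(0.81, 0.20, 0.55, NA, 0.33, 0.9),
    marker = "MLH1",
    stringsAsFactors = FALSE)
}

## A focus frame built from an explicit list of per-bivalent positions:
## bivalents[[cell]][[i]] = list(rank, len, positions)
frameFromBivalents <- function(bivalents, genotype = "g",
                               stage = "pachynema", marker = "MLH1") {
  rows <- list()
  for (cid in names(bivalents)) {
    for (b in bivalents[[cid]]) {
      pos <- b$positions
      if (!length(pos)) pos <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid, genotype = genotype, stage = stage,
        chromosome_rank = b$rank, sc_length_um = b$len,
        focus_position_frac = pos, marker = marker,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Minimal simulation parameters for interference recovery runs: unit-free
## SC laws, no thinning, no proximal suppression, no obligate enforcement.
recoveryParams <- function(shape, meanSpacing = 0.5, nCells = 16L,
                           seed = 1L) {
  simulationParams(genotype = "sim", scLengthMean = rep(10, 19),
                   scLengthSd = rep(0.5, 19), shape = shape,
                   meanSpacing = meanSpacing, detectionEff = 1,
                   proximalWindow = 0, proximalRetention = 1,
                   obligate = FALSE, nCells = nCells, seed = seed)
}

## PositionTable built directly from a vector of percent positions.
positionTableFrom <- function(positions, group = "1-2", focusClass = 2L,
                              genotype = "g") {
  new("PositionTable",
      data = data.frame(position = positions, group = group,
                        focusClass = as.integer(focusClass),
                        genotype = genotype,
                        cellId = "c", rank = 1L,
                        stringsAsFactors = FALSE),
      droppedThreeFocus = 0L)
}
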