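#' Read a focus table from delimited text
#'
#' The file must carry a header row with the documented columns
#' `cell_id, genotype, stage, chromosome_rank, sc_length_um,
#' focus_position_frac, marker`. Comma or tab delimitation is
#' auto-detected from the header line; the decimal separator is always the
#' point. Empty `focus_position_frac` fields mark zero-focus bivalent rows
#' and empty `chromosome_rank` fields mark unranked bivalents.
#'
#' @param path Path to a CSV/TSV file.
#' @param strict If `TRUE` (default) any row violating an invariant aborts
#'   with a validation error citing the row; if `FALSE` offending rows are
#'   dropped and their count reported via a message.
#' @return A validated [FocusTable].
#' @export
#' @examples
#' tab <- simulateDataset(wildTypeParams(nCells = 1))
#' f <- tempfile(fileext = ".csv")
#' writeFocusTable(tab, f)
#' identical(focusData(readFocusTable(f)), focusData(tab))
readFocusTable <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  d <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                  colClasses = "character", check.names = TRUE,
                  na.strings = c("NA", ""), stringsAsFactors = FALSE)
  missing <- setdiff(.FOCUS_COLUMNS, names(d))
  if (length(missing))
    stop("focus table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  d <- d[, .FOCUS_COLUMNS, drop = FALSE]
  suppressWarnings({
    d$chromosome_rank <- as.integer(d$chromosome_rank)
    d$sc_length_um <- as.numeric(d$sc_length_um)
    d$focus_position_frac <- as.numeric(d$focus_position_frac)
  })
  d$cell_id <- as.character(d$cell_id)
  d$genotype <- as.character(d$genotype)
  d$stage <- as.character(d$stage)
  d$marker <- as.character(d$marker)
  msg <- .validateFocusRows(d)
  bad <- which(nzchar(msg))
  if (length(bad)) {
    if (strict)
      stop("focus table validation error at row ", bad[1], ": ", msg[bad[1]])
    message(length(bad), " invalid row(s) dropped on lenient read")
    d <- d[-bad, , drop = FALSE]
    rownames(d) <- NULL
  }
  FocusTable(d)
}

#' Write a focus table as delimited text
#'
#' Writes comma-separated text with the fixed documented header. Numbers
#' are serialised with 17 significant digits so that a read/write
#' round-trip reproduces the table exactly; zero-focus rows get an empty
#' `focus_position_frac` field.
#'
#' @param table A [FocusTable].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFocusTable <- function(table, path) {
  stopifnot(is(table, "FocusTable"))
  d <- table@data
  num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(cell_id = d$cell_id, genotype = d$genotype,
                    stage = d$stage,
                    chromosome_rank = ifelse(is.na(d$chromosome_rank), "",
                                             as.character(d$chromosome_rank)),
                    sc_length_um = num(d$sc_length_um),
                    focus_position_frac = num(d$focus_position_frac),
                    marker = d$marker, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Group focus rows into in-memory meiocytes
#'
#' Rows are grouped by `cell_id`; within a cell, rows sharing a
#' `chromosome_rank` (or, for unranked rows, an SC length) describe one
#' bivalent whose focus positions are collected and sorted. Zero-focus rows
#' yield bivalents with empty position vectors.
#'
#' @param table A [FocusTable].
#' @return A list of [Meiocyte] objects, in order of first appearance of
#'   each cell.
#' @export
groupIntoMeiocytes <- function(table) {
  stopifnot(is(table, "FocusTable"))
  d <- table@data
  cells <- unique(d$cell_id)
  lapply(cells, function(cid) {
    dc <- d[d$cell_id == cid, , drop = FALSE]
    key <- ifelse(is.na(dc$chromosome_rank),
                  paste0("L", format(dc$sc_length_um, digits = 15)),
                  paste0("R", dc$chromosome_rank))
    bivs <- lapply(unique(key), function(k) {
      db <- dc[key == k, , drop = FALSE]
      if (length(unique(db$sc_length_um)) > 1)
        stop("consistency error: cell ", cid, " rank ",
             db$chromosome_rank[1], " has conflicting sc_length_um")
      Bivalent(rank = db$chromosome_rank[1],
               scLength = db$sc_length_um[1],
               positions = db$focus_position_frac[
                 !is.na(db$focus_position_frac)])
    })
    Meiocyte(cellId = cid, genotype = dc$genotype[1], stage = dc$stage[1],
             bivalents = bivs)
  })
}

#' Load run configuration from a YAML file
#'
#' A light wrapper turning a structured text configuration into the
#' package's parameter objects. Recognised top-level fields: `seed`,
#' `size_groups` (list of `[lo, hi]` rank pairs), `regions` (named
#' `[lo, hi]` percent intervals), `truncation_window` (`[lo, hi]` in % SC)
#' and `genotypes`, a named list whose entries carry the
#' [simulationParams()] fields (`sc_length_mean`, `sc_length_sd`, `shape`,
#' `mean_spacing`, `detection_efficiency`, `proximal_window`,
#' `proximal_retention`, `obligate`, `n_cells`, `seed`).
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `params` (named list of
#'   [SimulationParams]), `scheme`, `regions`, `window` and `seed`; absent
#'   fields fall back to package defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  scheme <- if (!is.null(cfg$size_groups)) {
    lo <- vapply(cfg$size_groups, function(x) as.integer(x[[1]]), 1L)
    hi <- vapply(cfg$size_groups, function(x) as.integer(x[[2]]), 1L)
    sizeGroupScheme(lo, hi)
  } else sizeGroupScheme()
  regions <- if (!is.null(cfg$regions)) {
    regionSpec(lapply(cfg$regions, function(x) as.numeric(unlist(x))))
  } else regionSpec()
  window <- if (!is.null(cfg$truncation_window))
    as.numeric(unlist(cfg$truncation_window)) else NULL
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  params <- list()
  for (g in names(cfg$genotypes)) {
    gc <- cfg$genotypes[[g]]
    params[[g]] <- simulationParams(
      genotype = g,
      scLengthMean = as.numeric(unlist(gc$sc_length_mean)),
      scLengthSd = as.numeric(unlist(gc$sc_length_sd)),
      shape = gc$shape, meanSpacing = gc$mean_spacing,
      detectionEff = gc$detection_efficiency %||% 1,
      proximalWindow = gc$proximal_window %||% 0.15,
      proximalRetention = gc$proximal_retention %||% 0.25,
      obligate = gc$obligate %||% TRUE,
      nCells = gc$n_cells %||% 32L,
      seed = gc$seed %||% seed)
  }
  list(params = params, scheme = scheme, regions = regions,
       window = window, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
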