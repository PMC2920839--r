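#' Sample a stationary gamma renewal process
#'
#' Draws one realisation of the equilibrium (stationary) renewal process
#' with i.i.d. gamma inter-event gaps on the interval `[0, L]`. The first
#' event offset follows the equilibrium forward-recurrence distribution
#' with density `(1 - F(x)) / meanSpacing`, sampled exactly as a uniform
#' fraction of a length-biased gap (gamma with shape `shape + 1`); all
#' later gaps are gamma with shape `shape` and mean `meanSpacing`. The
#' expected event count is exactly `L / meanSpacing`, and event counts on
#' disjoint equal subintervals have equal means (stationarity). Shape 1
#' reduces to a homogeneous Poisson process.
#'
#' Uses the global R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param L Interval length (> 0).
#' @param shape Gamma shape of the gap law (> 0); larger values give more
#'   even spacing.
#' @param meanSpacing Mean gap (> 0), same unit as `L`.
#' @return Sorted event positions in `[0, L]` (possibly empty).
#' @export
#' @examples
#' set.seed(1)
#' mean(replicate(2000, length(sampleStationaryGammaRenewal(100, 1, 50))))
sampleStationaryGammaRenewal <- function(L, shape, meanSpacing) {
  if (!is.finite(L) || L <= 0) stop("L must be positive")
  if (!is.finite(shape) || shape <= 0) stop("shape must be positive")
  if (!is.finite(meanSpacing) || meanSpacing <= 0)
    stop("meanSpacing must be positive")
  scale <- meanSpacing / shape
  pos <- runif(1) * rgamma(1, shape + 1, scale = scale)
  if (pos > L) return(numeric(0))
  events <- pos
  repeat {
    remaining <- L - events[length(events)]
    m <- max(8L, ceiling(remaining / meanSpacing +
                           4 * sqrt(remaining / (meanSpacing * shape)) + 4))
    gaps <- rgamma(m, shape, scale = scale)
    cs <- events[length(events)] + cumsum(gaps)
    keep <- cs <= L
    events <- c(events, cs[keep])
    if (!all(keep)) break
  }
  events
}

#' Simulate one bivalent
#'
#' SC length is drawn from the rank's normal law (resampled until
#' positive); crossover positions come from a stationary gamma renewal
#' process on the unit SC. Each focus in the centromere-proximal window is
#' retained with probability `proximalRetention` (modelling crossover
#' suppression near the centromere), then each survivor is retained with
#' the detection efficiency. With `obligate = TRUE`, a bivalent ending up
#' focus-free is resampled (at most 100 retries) before being accepted as
#' zero-focus with a warning, emulating the obligate crossover.
#'
#' @param params A [SimulationParams].
#' @param rank Chromosome size rank, 1-19.
#' @return A [Bivalent].
#' @export
simulateBivalent <- function(params, rank) {
  stopifnot(is(params, "SimulationParams"), rank >= 1, rank <= 19)
  repeat {
    len <- rnorm(1, params@scLengthMean[rank], params@scLengthSd[rank])
    if (len > 0) break
  }
  tries <- if (params@obligate) 100L else 1L
  pos <- numeric(0)
  for (i in seq_len(tries)) {
    pos <- sampleStationaryGammaRenewal(1, params@shape, params@meanSpacing)
    if (length(pos)) {
      inProx <- pos <= params@proximalWindow
      pos <- pos[!inProx | runif(length(pos)) < params@proximalRetention]
    }
    if (length(pos) && params@detectionEff < 1)
      pos <- pos[runif(length(pos)) < params@detectionEff]
    if (length(pos) || !params@obligate) break
  }
  if (params@obligate && !length(pos))
    warning("obligate crossover not achieved within 100 retries; ",
            "zero-focus bivalent emitted")
  Bivalent(rank = rank, scLength = len, positions = pos)
}

#' Simulate a full focus-table dataset
#'
#' Generates `nCells` meiocytes of 19 autosomal bivalents each from a
#' [SimulationParams] description. The generator is seeded from
#' `params@seed`, so an identical parameter object always yields an
#' identical table.
#'
#' @param params A [SimulationParams].
#' @return A validated [FocusTable]; zero-focus bivalents appear as rows
#'   with `NA` positions.
#' @export
#' @examples
#' tab <- simulateDataset(wildTypeParams(nCells = 2))
#' tab
simulateDataset <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  set.seed(params@seed)
  rows <- vector("list", params@nCells * 19L)
  idx <- 0L
  for (i in seq_len(params@nCells)) {
    cid <- sprintf("%s_cell%03d", params@genotype, i)
    for (r in 1:19) {
      b <- simulateBivalent(params, r)
      k <- length(b@positions)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        cell_id = cid, genotype = params@genotype, stage = params@stage,
        chromosome_rank = r, sc_length_um = b@scLength,
        focus_position_frac = if (k) b@positions else NA_real_,
        marker = params@marker, stringsAsFactors = FALSE)
    }
  }
  FocusTable(do.call(rbind, rows))
}

#' Draw per-cell focus counts from a stage model
#'
#' Counts are negative-binomial when the target variance exceeds the mean
#' (size chosen so the law matches the target mean and SD), Poisson when
#' the variance is at most the mean, and degenerate at `round(mean)` when
#' `sd = 0`.
#'
#' @param model A [CountModel] (e.g. from [stageCountModels()]).
#' @param nCells Number of cells to draw; defaults to the model's.
#' @return Integer vector of non-negative per-cell focus counts.
#' @export
#' @examples
#' set.seed(1)
#' mean(simulateStageCounts(countModel(18.2, 7.0), nCells = 500))
simulateStageCounts <- function(model, nCells = model@nCells) {
  stopifnot(is(model, "CountModel"))
  m <- model@mean
  v <- model@sd^2
  if (model@sd == 0) return(rep(as.integer(round(m)), nCells))
  if (m == 0) return(integer(nCells))
  if (v <= m) return(rpois(nCells, m))
  size <- m^2 / (v - m)
  rnbinom(nCells, size = size, mu = m)
}
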