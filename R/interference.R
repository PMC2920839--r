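#' Extract adjacent inter-focus distances
#'
#' Every bivalent with two or more foci contributes all adjacent-pair
#' gaps (a 3-focus bivalent contributes 2 distances). Distances are
#' expressed as percent of the source bivalent's SC length or in
#' micrometres. Size ranks 17-19 are excluded by default: the smallest
#' chromosomes rarely carry more than a single crossover focus.
#'
#' @param dataset A [FocusTable].
#' @param unit `"percent"` (of SC length) or `"um"`.
#' @param scheme [SizeGroupScheme] used to label each distance's group.
#' @param excludeRanks Ranks dropped from the analysis (`NULL` keeps all).
#' @param marker Marker label to select (default `"MLH1"`).
#' @param rerank Re-rank bivalents by measured SC length (default).
#' @return A [DistanceSet].
#' @export
interfocusDistances <- function(dataset, unit = c("percent", "um"),
                                scheme = sizeGroupScheme(),
                                excludeRanks = 17:19, marker = "MLH1",
                                rerank = TRUE) {
  unit <- match.arg(unit)
  stopifnot(is(dataset, "FocusTable"))
  d <- dataset@data
  sub <- FocusTable(d[d$marker == marker, , drop = FALSE])
  cells <- groupIntoMeiocytes(sub)
  if (rerank) cells <- lapply(cells, rankBivalents)
  dist <- numeric(0); grp <- character(0); src <- numeric(0)
  cid <- character(0)
  for (m in cells) {
    for (b in m@bivalents) {
      if (length(b@positions) < 2) next
      if (!is.null(excludeRanks) && !is.na(b@rank) &&
          b@rank %in% excludeRanks) next
      gaps <- diff(b@positions)
      if (unit == "percent") {
        gaps <- gaps * 100
        span <- 100
      } else {
        if (is.na(b@scLength)) stop("sc_length required for um units")
        gaps <- gaps * b@scLength
        span <- b@scLength
      }
      dist <- c(dist, gaps)
      grp <- c(grp, rep(groupOfRank(scheme, b@rank), length(gaps)))
      src <- c(src, rep(span, length(gaps)))
      cid <- c(cid, rep(m@cellId, length(gaps)))
    }
  }
  new("DistanceSet", distances = dist, unit = unit, group = grp,
      sourceSC = src, cellId = cid)
}

#' Reference gamma density and cumulative curves
#'
#' The gamma law with mean `meanSpacing` and shape `shape` (rate
#' `shape / meanSpacing`); shape 1 is the exponential expected with no
#' interference, larger shapes concentrate the density around the mean.
#'
#' @param shape,meanSpacing Positive gamma parameters.
#' @param grid Positions at which to evaluate; non-positive points are
#'   dropped with a warning.
#' @return A data.frame with columns `x`, `density`, `cumulative`.
#' @export
#' @examples
#' gammaCurve(1, 10, c(0, 10))  # exponential: density 0.1 at 0
gammaCurve <- function(shape, meanSpacing, grid) {
  if (shape <= 0 || meanSpacing <= 0)
    stop("shape and meanSpacing must be positive")
  if (any(grid < 0)) {
    warning(sum(grid < 0), " negative grid point(s) dropped")
    grid <- grid[grid >= 0]
  }
  scale <- meanSpacing / shape
  data.frame(x = grid, density = dgamma(grid, shape, scale = scale),
             cumulative = pgamma(grid, shape, scale = scale))
}

## Solve the untruncated gamma shape MLE condition
##   log(a) - digamma(a) = log(mean(x)) - mean(log(x))
.gammaShapeMLE <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) return(Inf)
  f <- function(a) log(a) - digamma(a) - s
  lo <- 1e-4; hi <- 1
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Naive (untruncated) gamma shape fit
#'
#' Maximum-likelihood fit of the gamma interference model ignoring any
#' detection window: the shape solves
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))` and the
#' mean spacing is the arithmetic mean. Degenerate all-equal data give an
#' infinite-shape sentinel with a warning.
#'
#' @param distances A [DistanceSet] or a positive numeric vector (treated
#'   as percent of SC).
#' @param minIntervals Minimum number of distances required (default 10).
#' @return A [GammaInterferenceModel].
#' @export
fitGammaShape <- function(distances, minIntervals = 10L) {
  ds <- if (is(distances, "DistanceSet")) distances else
    new("DistanceSet", distances = as.numeric(distances), unit = "percent",
        group = rep(NA_character_, length(distances)),
        sourceSC = rep(Inf, length(distances)),
        cellId = rep(NA_character_, length(distances)))
  x <- ds@distances
  if (length(x) < minIntervals)
    stop("need at least ", minIntervals, " distances")
  if (any(x <= 0)) stop("all distances must be positive")
  a <- .gammaShapeMLE(x)
  if (!is.finite(a)) {
    warning("zero log-variance: degenerate data, shape reported as Inf")
    return(new("GammaInterferenceModel", shape = Inf, meanSpacing = mean(x),
               unit = ds@unit, window = c(0, Inf), span = Inf,
               nIntervals = length(x), logLik = NA_real_, converged = TRUE,
               method = "mle"))
  }
  mu <- mean(x)
  ll <- sum(dgamma(x, a, scale = mu / a, log = TRUE))
  new("GammaInterferenceModel", shape = a, meanSpacing = mu, unit = ds@unit,
      window = c(0, Inf), span = Inf, nIntervals = length(x), logLik = ll,
      converged = TRUE, method = "mle")
}

## Log normalising constant of the observable-distance model:
##   integral over [lo, min(hi, L)] of f(u) * w(u) du, with w(u) = (L - u)
##   when L is finite (the number of placements of a gap of length u on an
##   SC of span L) and w(u) = 1 otherwise. Closed form via gamma CDFs:
##   integral u f(u) du = a * scale * [F_{a+1}(hi) - F_{a+1}(lo)].
.truncNormaliser <- function(a, mu, lo, hi, span) {
  scale <- mu / a
  hi <- pmin(hi, span)
  p0 <- pgamma(hi, a, scale = scale) - pgamma(lo, a, scale = scale)
  if (all(!is.finite(span))) return(p0)
  p1 <- pgamma(hi, a + 1, scale = scale) - pgamma(lo, a + 1, scale = scale)
  span * p0 - a * scale * p1
}

#' Truncation-corrected gamma shape fit
#'
#' Corrects the gamma interference fit for the fact that the gamma law
#' assumes arbitrarily small and large inter-focus distances can occur and
#' be seen, whereas the detectable range is limited by the resolution of
#' light microscopy (lower window bound, default 2% of SC length) and by
#' the finite length of the SC. Finite length enters twice: distances
#' beyond the span cannot occur (upper truncation, default the 99th
#' percentile of the source spans) and a gap of length `u` has only
#' `span - u` possible placements, so observable gaps are length-biased.
#' The fitted density is therefore
#' `f(u) * (span - u) / Z` on the window, with `f` the gamma density and
#' `Z` the matching normaliser (closed form via gamma CDFs; the
#' `(span - u)` data factor is parameter-free and drops out of the
#' optimisation). Optimisation is quasi-Newton on
#' `(log shape, log mean)` started from the naive fit; non-convergence is
#' flagged and the naive estimates are carried.
#'
#' With `window = c(0, Inf)` and `span = Inf` the fit reduces to
#' [fitGammaShape()].
#'
#' @param distances A [DistanceSet] or positive numeric vector (percent of
#'   SC).
#' @param window `c(lo, hi)` observable window in the distance unit;
#'   `NULL` for the defaults above.
#' @param span Finite SC span for the observability weight; `NULL` takes
#'   the per-distance source span from the `DistanceSet` (100 for percent
#'   units), `Inf` disables the weight.
#' @param minIntervals Minimum number of distances required.
#' @return A [GammaInterferenceModel] with `method = "mle-truncated"`.
#' @export
fitTruncatedGammaShape <- function(distances, window = NULL, span = NULL,
                                   minIntervals = 10L) {
  ds <- if (is(distances, "DistanceSet")) distances else
    new("DistanceSet", distances = as.numeric(distances), unit = "percent",
        group = rep(NA_character_, length(distances)),
        ## plain numeric input is percent of SC: span 100 unless given
        sourceSC = rep_len(if (is.null(span)) 100 else as.numeric(span),
                           length(distances)),
        cellId = rep(NA_character_, length(distances)))
  x <- ds@distances
  if (length(x) < minIntervals)
    stop("need at least ", minIntervals, " distances")
  if (any(x <= 0)) stop("all distances must be positive")
  if (is.null(span)) span <- ds@sourceSC
  span <- rep_len(as.numeric(span), length(x))
  if (is.null(window)) {
    lo <- if (ds@unit == "percent") 2 else 0.02 * stats::median(span)
    hi <- unname(quantile(span, 0.99))
    window <- c(lo, hi)
  }
  if (any(x < window[1] - 1e-9) || any(x > pmin(window[2], span) + 1e-9))
    stop("distances outside the truncation window")
  naive <- fitGammaShape(x, minIntervals = minIntervals)
  if (!is.finite(naive@shape)) return(naive)
  nll <- function(p) {
    a <- exp(p[1]); mu <- exp(p[2])
    Z <- .truncNormaliser(a, mu, window[1], window[2], span)
    if (any(!is.finite(Z)) || any(Z <= 0)) return(1e10)
    -sum(dgamma(x, a, scale = mu / a, log = TRUE)) + sum(log(Z))
  }
  start <- c(log(naive@shape), log(naive@meanSpacing))
  opt <- tryCatch(
    optim(start, nll, method = "Nelder-Mead",
          control = list(maxit = 5000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value)) {
    warning("truncated fit did not converge; carrying the naive fit")
    return(new("GammaInterferenceModel", shape = naive@shape,
               meanSpacing = naive@meanSpacing, unit = ds@unit,
               window = window, span = unname(stats::median(span)),
               nIntervals = length(x), logLik = naive@logLik,
               converged = FALSE, method = "mle-truncated"))
  }
  new("GammaInterferenceModel", shape = exp(opt$par[1]),
      meanSpacing = exp(opt$par[2]), unit = ds@unit, window = window,
      span = unname(stats::median(span)), nIntervals = length(x),
      logLik = -opt$value, converged = TRUE, method = "mle-truncated")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test on inter-focus distances, as used for
#' cumulative-distribution comparisons between genotypes.
#'
#' @param a,b [DistanceSet] objects or numeric vectors.
#' @return A [StatResult] with statistic `D`; fewer than 2 observations on
#'   either side gives an undefined flagged result.
#' @export
ksTwoSample <- function(a, b) {
  xa <- if (is(a, "DistanceSet")) a@distances else as.numeric(a)
  xb <- if (is(b, "DistanceSet")) b@distances else as.numeric(b)
  if (length(xa) < 2 || length(xb) < 2)
    return(.statResult("Two-sample Kolmogorov-Smirnov test",
                       c(D = NA_real_),
                       c(n1 = length(xa), n2 = length(xb)), NA_real_,
                       note = "fewer than 2 observations in a sample"))
  ht <- suppressWarnings(stats::ks.test(xa, xb, alternative = "two.sided"))
  .statResult("Two-sample Kolmogorov-Smirnov test",
              c(D = unname(ht$statistic)),
              c(n1 = length(xa), n2 = length(xb)), ht$p.value)
}

#' Interference report across genotypes and size groups
#'
#' For each genotype and size group (plus an all-chromosomes row pooling
#' every group), reports the interval count and the truncation-corrected
#' shape estimate, together with the mean +/- SD inter-focus distance and
#' the window used.
#'
#' @param datasets Named list of [FocusTable] datasets (names are genotype
#'   labels).
#' @param scheme A [SizeGroupScheme].
#' @param window Truncation window passed to [fitTruncatedGammaShape()]
#'   (`NULL` for defaults).
#' @param unit Distance unit.
#' @param excludeRanks Ranks excluded from the distance extraction.
#' @param minIntervals Groups with fewer intervals are reported with `NA`
#'   shape.
#' @return A data.frame with one row per genotype x group.
#' @export
interferenceReport <- function(datasets, scheme = sizeGroupScheme(),
                               window = NULL, unit = "percent",
                               excludeRanks = 17:19, minIntervals = 10L) {
  out <- list()
  for (g in names(datasets)) {
    ds <- interfocusDistances(datasets[[g]], unit = unit, scheme = scheme,
                              excludeRanks = excludeRanks)
    pieces <- c(list(`all chromosomes` = seq_along(ds@distances)),
                setNames(lapply(scheme@labels,
                                function(l) which(ds@group == l)),
                         scheme@labels))
    for (nm in names(pieces)) {
      idx <- pieces[[nm]]
      if (nm %in% scheme@labels &&
          all(scheme@lo[match(nm, scheme@labels)]:
                scheme@hi[match(nm, scheme@labels)] %in% excludeRanks))
        next
      x <- ds@distances[idx]
      fit <- if (length(x) >= minIntervals) {
        sub <- new("DistanceSet", distances = x, unit = ds@unit,
                   group = ds@group[idx], sourceSC = ds@sourceSC[idx],
                   cellId = ds@cellId[idx])
        fitTruncatedGammaShape(sub, window = window)
      } else NULL
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, group = nm, nIntervals = length(x),
        shapeCorrected = if (is.null(fit)) NA_real_ else fit@shape,
        meanDistance = if (length(x)) mean(x) else NA_real_,
        sdDistance = if (length(x) > 1) sd(x) else NA_real_,
        windowLo = if (is.null(fit)) NA_real_ else fit@window[1],
        windowHi = if (is.null(fit)) NA_real_ else fit@window[2],
        converged = if (is.null(fit)) NA else fit@converged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
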