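#' Interpolate an irregular series onto a uniform day grid
#'
#' The discrete Fourier transform requires uniform sampling, so each
#' feature's irregular (roughly weekly-to-fortnightly) series is linearly
#' interpolated onto a regular grid spanning the observed range. No
#' extrapolation beyond the first and last observations; missing interior
#' values are interpolated across.
#'
#' @param values observed values (may contain NA).
#' @param day_offsets observation times in days (strictly increasing).
#' @param grid_days grid spacing in days.
#' @return list: \code{day} (grid offsets) and \code{value}.
#' @export
regularizeSeries <- function(values, day_offsets, grid_days = 7) {
  ok <- !is.na(values)
  if (sum(ok) < 8)
    stop("need at least 8 observed time points, have ", sum(ok))
  if (any(diff(day_offsets) <= 0))
    stop("day_offsets must be strictly increasing")
  grid <- seq(min(day_offsets[ok]), max(day_offsets[ok]), by = grid_days)
  out <- stats::approx(day_offsets[ok], values[ok], xout = grid,
                       method = "linear", rule = 1)
  list(day = grid, value = out$y)
}

#' Fourier reconstruction from the largest-amplitude components
#'
#' Mean-centres the series, takes the discrete Fourier transform, keeps the
#' \code{n_components} non-DC frequencies of largest amplitude (with their
#' conjugate pairs, so the inverse transform is real) and restores the mean.
#' Discarding the remaining components removes noise and minor fluctuations
#' while preserving the dominant seasonal frequencies.
#'
#' @param x uniform numeric series.
#' @param n_components number of non-DC frequencies to retain (>= 1, at
#'   most \code{floor(length(x)/2)}).
#' @return list: \code{reconstructed}, \code{spectrum} (data.frame:
#'   freq_index = cycles per record, amplitude, retained).
#' @export
fourierReconstruct <- function(x, n_components = 3) {
  n <- length(x)
  nfreq <- n %/% 2
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > nfreq)
    stop("n_components (", n_components, ") exceeds available frequencies (",
         nfreq, ")")
  mu <- mean(x)
  f <- stats::fft(x - mu)
  amp <- Mod(f[2:(nfreq + 1)])              # frequencies 1..nfreq
  keep <- order(amp, decreasing = TRUE)[seq_len(n_components)]
  mask <- rep(0, n)
  mask[keep + 1L] <- 1                      # positive frequencies
  mask[n - keep + 1L] <- 1                  # conjugate pairs
  rec <- Re(stats::fft(f * mask, inverse = TRUE)) / n + mu
  list(reconstructed = rec,
       spectrum = data.frame(freq_index = seq_len(nfreq),
                             amplitude = 2 * amp / n,
                             retained = seq_len(nfreq) %in% keep))
}

# interior local maxima with topographic prominence: for each peak the
# reference is the higher of the lowest points separating it from higher
# terrain on either side (or the boundary minimum)
.peakProminence <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), prominence = numeric()))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  idx <- idx[x[idx] > x[idx - 1L]]          # exclude flat-left plateaus
  prom <- vapply(idx, function(i) {
    left <- x[1:i]
    higher <- which(left > x[i])
    lmin <- if (length(higher)) min(left[max(higher):i]) else min(left)
    right <- x[i:n]
    higher <- which(right > x[i])
    rmin <- if (length(higher)) min(right[1:min(higher)]) else min(right)
    x[i] - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Count oscillations per annual cycle
#'
#' Counts local maxima of a reconstructed signal within each calendar-year
#' window, keeping only peaks whose prominence reaches
#' \code{prominence_frac} of the signal range (the amplitude criterion for
#' a peak/trough to count as an oscillation). The consensus oscillation
#' signal is the modal per-year count, ties broken toward the smaller
#' count; consensus 1 marks an annual oscillator.
#'
#' @param reconstructed numeric series on a uniform grid.
#' @param grid_dates \code{Date} vector parallel to the series.
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   signal range.
#' @param min_year_days calendar years covered by fewer grid days are not
#'   scored.
#' @return list: \code{years}, \code{counts} (per year), \code{peak_day}
#'   (day-of-year of the highest qualifying peak per year, NA when none),
#'   \code{consensus}.
#' @export
countAnnualOscillations <- function(reconstructed, grid_dates,
                                    prominence_frac = 0.1,
                                    min_year_days = 182) {
  stopifnot(length(reconstructed) == length(grid_dates))
  yr <- as.POSIXlt(grid_dates)$year + 1900L
  span <- vapply(split(grid_dates, yr), function(d)
    as.numeric(max(d) - min(d)), numeric(1))
  years <- as.integer(names(span)[span >= min_year_days])
  rng <- diff(range(reconstructed))
  if (rng < 1e-12) {
    counts <- setNames(rep(0L, length(years)), years)
    return(list(years = years, counts = counts,
                peak_day = setNames(rep(NA_real_, length(years)), years),
                consensus = 0L))
  }
  pk <- .peakProminence(reconstructed)
  pk <- pk[pk$prominence >= prominence_frac * rng, , drop = FALSE]
  pyr <- yr[pk$index]
  counts <- setNames(integer(length(years)), years)
  peak_day <- setNames(rep(NA_real_, length(years)), years)
  for (y in years) {
    sel <- which(pyr == y)
    counts[as.character(y)] <- length(sel)
    if (length(sel)) {
      best <- sel[which.max(reconstructed[pk$index[sel]])]
      peak_day[as.character(y)] <- .dayOfYear(grid_dates[pk$index[best]])
    }
  }
  consensus <- .modalCount(counts)
  list(years = years, counts = counts, peak_day = peak_day,
       consensus = consensus)
}

# modal value; ties broken toward the smaller count (conservative)
.modalCount <- function(counts) {
  if (!length(counts)) return(0L)
  tab <- table(counts)
  as.integer(names(tab)[tab == max(tab)][1])
}

#' Phase-rectified signal averaging
#'
#' Averages signal windows centred on phase-defined anchor points (here,
#' increase events: samples exceeding their predecessor), which removes
#' phase variability and reveals periodic structure in the mean curve.
#'
#' @param x uniform numeric series.
#' @param half_window window half-width in samples; only anchors with a
#'   full window inside the series are used.
#' @return numeric vector of length \code{2 * half_window + 1}.
#' @export
prsa <- function(x, half_window) {
  n <- length(x)
  if (n <= 2 * half_window) stop("series shorter than the PRSA window")
  anchors <- which(diff(x) > 0) + 1L
  anchors <- anchors[anchors > half_window & anchors + half_window <= n]
  if (!length(anchors))
    stop("no increase anchors found: series is aperiodic/flat")
  win <- vapply(anchors, function(a) x[(a - half_window):(a + half_window)],
                numeric(2 * half_window + 1))
  rowMeans(win)
}

#' Oscillation profiles for every feature of a time series experiment
#'
#' Runs the full oscillation-signal workflow per feature: interpolation of
#' the relative-abundance series onto a uniform day grid, Fourier
#' reconstruction from the largest-amplitude components, and per-year peak
#' counting, yielding the consensus oscillation signal and per-year peak
#' timing for every feature.
#'
#' @param se a \linkS4class{SeasonalExperiment} (the \code{relabund} assay
#'   is analysed), or a numeric matrix of abundances (features x samples)
#'   if \code{dates} is given.
#' @param dates sample dates, required when \code{se} is a bare matrix.
#' @param feature_class optional class labels for a bare matrix.
#' @param grid_days interpolation grid spacing (days).
#' @param n_components non-DC Fourier components retained.
#' @param prominence_frac peak prominence threshold as a fraction of each
#'   signal's range.
#' @return an \linkS4class{OscillationSet}.
#' @export
oscillationProfiles <- function(se, dates = NULL, feature_class = NULL,
                                grid_days = 7, n_components = 3,
                                prominence_frac = 0.1) {
  if (is(se, "SeasonalExperiment")) {
    m <- relAbundance(se)
    dates <- sampleDates(se)
    feature_class <- featureClass(se)
  } else {
    m <- as.matrix(se)
    if (is.null(dates)) stop("dates required for a matrix input")
    dates <- as.Date(dates)
    if (is.null(feature_class))
      feature_class <- rep(NA_character_, nrow(m))
  }
  day <- as.numeric(dates - dates[1])
  grid <- regularizeSeries(m[1, ], day, grid_days)$day
  grid_dates <- dates[1] + grid
  ng <- length(grid)
  nfeat <- nrow(m)

  gsig <- matrix(NA_real_, nfeat, ng, dimnames = list(rownames(m), NULL))
  rsig <- gsig
  yr <- as.POSIXlt(grid_dates)$year + 1900L
  span <- vapply(split(grid_dates, yr), function(d)
    as.numeric(max(d) - min(d)), numeric(1))
  years <- as.integer(names(span)[span >= 182])
  pcounts <- matrix(NA_integer_, nfeat, length(years),
                    dimnames = list(rownames(m), years))
  pdays <- matrix(NA_real_, nfeat, length(years),
                  dimnames = list(rownames(m), years))
  consensus <- integer(nfeat)
  amplitude <- numeric(nfeat)

  for (i in seq_len(nfeat)) {
    g <- regularizeSeries(m[i, ], day, grid_days)
    rec <- fourierReconstruct(g$value, n_components)$reconstructed
    gsig[i, ] <- g$value
    rsig[i, ] <- rec
    cnt <- countAnnualOscillations(rec, grid_dates, prominence_frac)
    pcounts[i, ] <- cnt$counts
    pdays[i, ] <- cnt$peak_day
    consensus[i] <- cnt$consensus
    amplitude[i] <- diff(range(rec)) / 2
  }
  methods::new("OscillationSet",
               gridSignal = gsig, reconstructed = rsig, gridDay = grid,
               gridDate = grid_dates, years = years, peakCounts = pcounts,
               peakDays = pdays, consensus = consensus,
               amplitude = amplitude,
               featureClass = as.character(feature_class),
               nComponents = as.integer(n_components))
}

#' @rdname OscillationSet
#' @export
setMethod("consensusOscillation", "OscillationSet", function(x)
  setNames(x@consensus, rownames(x@gridSignal)))

#' @rdname OscillationSet
#' @export
setMethod("annualOscillators", "OscillationSet", function(x)
  rownames(x@gridSignal)[x@consensus == 1L])

#' @rdname OscillationSet
#' @export
setMethod("peakDays", "OscillationSet", function(x) x@peakDays)

#' @rdname OscillationSet
#' @export
setMethod("peakCounts", "OscillationSet", function(x) x@peakCounts)

#' @rdname OscillationSet
#' @export
setMethod("reconstructedSignals", "OscillationSet", function(x)
  x@reconstructed)

#' @rdname OscillationSet
#' @export
setMethod("featureClass", "OscillationSet", function(x)
  setNames(x@featureClass, rownames(x@gridSignal)))

setMethod("show", "OscillationSet", function(object) {
  n <- nrow(object@gridSignal)
  cat("OscillationSet:", n, "features on a",
      round(diff(object@gridDay[1:2])), "day grid of",
      length(object@gridDay), "points\n")
  cat("  years scored:", paste(object@years, collapse = ", "), "\n")
  cat("  components retained:", object@nComponents, "\n")
  tab <- table(object@consensus)
  cat("  consensus oscillation signals:",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  cat("  annual oscillators:", sum(object@consensus == 1L),
      sprintf("(%.1f%%)\n", 100 * mean(object@consensus == 1L)))
})
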