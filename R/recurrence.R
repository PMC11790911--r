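#' Fraction of features peaking within a fixed circular window each year
#'
#' A feature is window-consistent when some circular arc of
#' \code{window_days} days contains all of its yearly peak day-of-year
#' values — circular so that winter-peaking features straddling Jan 1 are
#' handled correctly. Features with fewer than 2 yearly peaks are excluded
#' and reported.
#'
#' @param peaks matrix of peak day-of-year values, features x years (NA
#'   allowed).
#' @param window_days arc length in days.
#' @param period cycle length in days.
#' @return list: \code{fraction}, \code{consistent} (named logical over
#'   evaluated features), \code{excluded} (feature IDs with < 2 peaks).
#' @export
peakWindowFraction <- function(peaks, window_days = 30, period = 365) {
  peaks <- as.matrix(peaks)
  nyr <- rowSums(!is.na(peaks))
  excluded <- rownames(peaks)[nyr < 2]
  eval_ids <- rownames(peaks)[nyr >= 2]
  if (!length(eval_ids)) stop("no features with >= 2 yearly peaks")
  consistent <- vapply(eval_ids, function(f) {
    d <- sort(peaks[f, ][!is.na(peaks[f, ])]) %% period
    gaps <- diff(c(d, d[1] + period))
    (period - max(gaps)) <= window_days
  }, logical(1))
  list(fraction = mean(consistent), consistent = consistent,
       excluded = excluded)
}

#' Fraction of features keeping the same oscillation order every year
#'
#' Evaluates features with a peak in every year. Within each year, features
#' are ranked by peak day (ties broken by feature ID); a feature is
#' order-consistent when its rank is identical across all years.
#'
#' @param peaks matrix of peak day-of-year values, features x years.
#' @return list: \code{fraction}, \code{consistent} (named logical),
#'   \code{ranks} (matrix of within-year ranks).
#' @export
orderConsistencyFraction <- function(peaks) {
  peaks <- as.matrix(peaks)
  full <- rowSums(is.na(peaks)) == 0
  peaks <- peaks[full, , drop = FALSE]
  if (nrow(peaks) < 2)
    stop("need >= 2 features with peaks in every year")
  if (ncol(peaks) < 2) stop("need >= 2 years of peaks")
  tie_break <- rank(rownames(peaks))
  ranks <- apply(peaks, 2, function(col)
    rank(col + tie_break * 1e-9, ties.method = "first"))
  consistent <- apply(ranks, 1, function(r) all(r == r[1]))
  list(fraction = mean(consistent),
       consistent = setNames(consistent, rownames(peaks)),
       ranks = ranks)
}
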