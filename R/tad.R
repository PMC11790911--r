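#' 80% truncated average depth
#'
#' Sorts the per-position depths of a target, discards the lowest and
#' highest \code{floor(n * 0.1)} positions (for the default 10%/90%
#' bounds) and returns the mean of the remaining central positions. The
#' truncation makes the average robust to uneven coverage at target ends
#' and to spuriously recruited read stacks.
#'
#' @param depths nonnegative per-position depth vector.
#' @param lower,upper truncation quantile bounds; the default (0.10, 0.90)
#'   gives TAD80. \code{lower = 0, upper = 1} recovers the plain mean.
#' @return the truncated mean depth.
#' @export
tad80 <- function(depths, lower = 0.10, upper = 0.90) {
  if (length(depths) == 0) stop("empty depth vector")
  if (any(depths < 0)) stop("depths must be nonnegative")
  if (lower < 0 || upper > 1 || lower >= upper)
    stop("need 0 <= lower < upper <= 1")
  n <- length(depths)
  s <- sort(depths)
  # guard the boundary count against floating-point drift (10 * 0.1 etc.)
  drop_low <- floor(n * lower + 1e-9)
  drop_high <- floor(n * (1 - upper) + 1e-9)
  mean(s[(drop_low + 1):(n - drop_high)])
}

#' Read per-position coverage from a BedGraph file
#'
#' Imports 0-based half-open (chrom, start, end, depth) intervals and
#' expands them to one depth value per position for each target sequence.
#'
#' @param path BedGraph file path.
#' @return named list of per-position depth vectors, one per target.
#' @examples
#' bg <- system.file("extdata", "synthetic_coverage.bedgraph",
#'                   package = "seasonwheel")
#' tad80FromBedGraph(bg)
#' @export
readBedGraphCoverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sq <- as.character(GenomicRanges::seqnames(gr))
  lapply(split(seq_along(gr), sq), function(idx) {
    g <- gr[idx]
    ord <- order(GenomicRanges::start(g))
    rep(g$score[ord], GenomicRanges::width(g)[ord])
  })
}

#' TAD80 per target from a BedGraph file
#'
#' @param path BedGraph file path.
#' @param lower,upper truncation bounds passed to \code{\link{tad80}}.
#' @return data.frame: target_id, length, tad80.
#' @export
tad80FromBedGraph <- function(path, lower = 0.10, upper = 0.90) {
  cov <- readBedGraphCoverage(path)
  data.frame(target_id = names(cov),
             length = vapply(cov, length, integer(1)),
             tad80 = vapply(cov, tad80, numeric(1),
                            lower = lower, upper = upper),
             row.names = NULL)
}

#' Module-level transcription summary
#'
#' Averages the TAD80 values of all functions assigned to each module (the
#' mean of transcription at module level) and expresses each module mean as
#' a proportion of the summed module means.
#'
#' @param tad named numeric vector of TAD80 values per function, or the
#'   data.frame from \code{\link{tad80FromBedGraph}}.
#' @param modules named factor/character of module assignments covering
#'   the evaluated functions; modules without evaluated functions are
#'   reported NA.
#' @return data.frame: module, n_functions, mean_tad80, proportion.
#' @export
moduleTranscriptionSummary <- function(tad, modules) {
  if (is.data.frame(tad)) tad <- setNames(tad$tad80, tad$target_id)
  mods <- if (is.factor(modules)) levels(modules) else
    levels(factor(modules))
  means <- vapply(mods, function(m) {
    f <- intersect(names(modules)[modules == m], names(tad))
    if (!length(f)) return(NA_real_)
    mean(tad[f])
  }, numeric(1))
  tot <- sum(means, na.rm = TRUE)
  data.frame(module = mods,
             n_functions = vapply(mods, function(m)
               length(intersect(names(modules)[modules == m], names(tad))),
               integer(1)),
             mean_tad80 = unname(means),
             proportion = unname(means) / tot,
             row.names = NULL)
}
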