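# vegan::rrarefy warns whenever a table has no singleton count; depth
# validity is checked by the callers, so muffle that advisory only
.rrarefy <- function(x, sample) {
  withCallingHandlers(
    vegan::rrarefy(x, sample),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Rarefy a count table
#'
#' Subsamples each sample (column) to a fixed depth without replacement.
#'
#' @param m count matrix, features x samples.
#' @param depth target depth; must not exceed any column sum.
#' @param seed optional RNG seed.
#' @return matrix of the same shape; every column sums exactly to
#'   \code{depth}.
#' @export
rarefyCounts <- function(m, depth, seed = NULL) {
  m <- as.matrix(m)
  cs <- colSums(m)
  low <- which(cs < depth)
  if (length(low))
    stop("depth ", depth, " exceeds the total count of sample(s): ",
         paste(colnames(m)[low] %||% low, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  t(.rrarefy(t(m), depth))
}

#' Alpha diversity under iterated rarefaction
#'
#' Rarefies the count table to the minimum sample depth and recomputes
#' Richness (R), Shannon diversity (H', nats) and Pielou evenness
#' (E = H'/ln R) over repeated draws; reports the per-sample mean and SD of
#' each metric. Evenness is undefined (NA) when a rarefied sample retains
#' fewer than two features.
#'
#' @param m count matrix, features x samples.
#' @param iterations number of rarefaction draws.
#' @param seed RNG seed.
#' @param depth rarefaction depth; defaults to the minimum column sum.
#' @return data.frame, one row per sample: richness/shannon/evenness mean
#'   and sd, plus the depth used.
#' @export
alphaIterated <- function(m, iterations = 100, seed = 1, depth = NULL) {
  m <- as.matrix(m)
  # fix the row order fed to the RNG so results are exactly invariant to
  # the caller's feature ordering
  if (!is.null(rownames(m))) m <- m[order(rownames(m)), , drop = FALSE]
  if (is.null(depth)) depth <- min(colSums(m))
  set.seed(seed)
  acc <- array(NA_real_, dim = c(ncol(m), 3, iterations))
  for (it in seq_len(iterations)) {
    r <- t(.rrarefy(t(m), depth))
    R <- colSums(r > 0)
    H <- vegan::diversity(t(r), index = "shannon")
    E <- ifelse(R > 1, H / log(R), NA_real_)
    acc[, , it] <- cbind(R, H, E)
  }
  stat <- function(j, f) apply(acc[, j, , drop = FALSE], 1, f, na.rm = TRUE)
  out <- data.frame(
    sample_id = colnames(m),
    richness_mean = stat(1, mean), richness_sd = stat(1, stats::sd),
    shannon_mean = stat(2, mean), shannon_sd = stat(2, stats::sd),
    evenness_mean = stat(3, mean), evenness_sd = stat(3, stats::sd),
    depth = depth)
  out$evenness_mean[is.nan(out$evenness_mean)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity on Hellinger-transformed profiles
#'
#' Each sample is converted to proportions and square-rooted (Hellinger
#' transform) before Bray-Curtis dissimilarities are computed between all
#' sample pairs.
#'
#' @param m count or relative-abundance matrix, features x samples.
#' @return symmetric dissimilarity matrix with zero diagonal, values in
#'   [0, 1].
#' @export
brayCurtisHellinger <- function(m) {
  m <- as.matrix(m)
  cs <- colSums(m)
  if (any(cs == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[cs == 0] %||% which(cs == 0), collapse = ", "))
  h <- vegan::decostand(t(m), method = "hellinger")
  as.matrix(vegan::vegdist(h, method = "bray"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Best-of-\code{n_starts} NMDS (Kruskal stress-1) in \code{k} dimensions,
#' with the final configuration rotated to its principal axes so that
#' repeated runs under the same seed are reproducible.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension.
#' @param n_starts random starts.
#' @param seed RNG seed.
#' @return list with \code{coordinates} (samples x k matrix) and
#'   \code{stress}.
#' @export
nmdsOrdination <- function(d, k = 2, n_starts = 50, seed = 1) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts,
                        trymax = n_starts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  coords <- vegan::scores(fit, display = "sites")
  rownames(coords) <- rownames(d)
  list(coordinates = coords, stress = fit$stress)
}

#' Convex hull area per sample group
#'
#' Area of the convex hull of each group's points in a 2-D ordination,
#' used as an inter-annual cohesion measure when groups are calendar
#' months pooled across years. Groups with fewer than 3 distinct points
#' get area 0 with a warning.
#'
#' @param coords samples x 2 coordinate matrix.
#' @param groups group label per sample (e.g. month names).
#' @return named numeric vector of hull areas.
#' @export
convexHullArea <- function(coords, groups) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) == length(groups))
  vapply(split(seq_along(groups), groups), function(idx) {
    p <- unique(coords[idx, , drop = FALSE])
    if (nrow(p) < 3) {
      warning("group with < 3 distinct points: hull area set to 0")
      return(0)
    }
    h <- grDevices::chull(p)
    x <- p[h, 1]; y <- p[h, 2]
    # shoelace formula
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
}
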