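#' Pairwise Pearson correlation of oscillation signals
#'
#' Correlates every pair of feature signals (rows), returning the
#' correlation, the two-sided p value from the t statistic with n - 2
#' degrees of freedom, and Benjamini-Hochberg adjusted q values computed
#' once over all unordered pairs. Zero-variance signals get NA throughout.
#'
#' @param signals matrix, features x time points (e.g.
#'   \code{reconstructedSignals()} of an \linkS4class{OscillationSet}).
#' @return list of symmetric matrices \code{r}, \code{p}, \code{q}.
#' @export
pairwiseOscillationCorrelation <- function(signals) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 2) stop("need >= 2 features")
  n <- ncol(signals)
  sdv <- apply(signals, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(signals)))
  r[sdv == 0, ] <- NA; r[, sdv == 0] <- NA
  diag(r) <- ifelse(sdv == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  up <- upper.tri(p)
  q <- p
  q[up] <- stats::p.adjust(p[up], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(r = r, p = p, q = q)
}

#' Build the co-oscillation network
#'
#' Edges connect feature pairs with r strictly above \code{r_min} and
#' BH-adjusted q below \code{alpha} — significant positive correlations
#' only, which avoids the topology distortion negative edges introduce.
#' Edge weights are the correlation coefficients; nodes left without any
#' edge are dropped.
#'
#' @param cors list from \code{\link{pairwiseOscillationCorrelation}}.
#' @param feature_class optional named feature classes stored as the node
#'   \code{kind} attribute.
#' @param r_min correlation threshold (exclusive).
#' @param alpha adjusted-p threshold (exclusive).
#' @return a \linkS4class{CoOscNetwork}.
#' @export
buildNetwork <- function(cors, feature_class = NULL, r_min = 0.7,
                         alpha = 0.05) {
  r <- cors$r; q <- cors$q
  stopifnot(identical(dim(r), dim(q)))
  adj <- !is.na(r) & !is.na(q) & r > r_min & q < alpha
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$r <- r[cbind(el[, 1], el[, 2])]
  igraph::E(g)$q <- q[cbind(el[, 1], el[, 2])]
  igraph::E(g)$weight <- igraph::E(g)$r
  if (!is.null(feature_class))
    igraph::V(g)$kind <- unname(feature_class[igraph::V(g)$name])
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  methods::new("CoOscNetwork", graph = g, rMin = r_min, alpha = alpha,
               modules = factor())
}

#' Detect modules by the Louvain algorithm
#'
#' Louvain community detection is order-dependent, so it is run
#' \code{n_runs} times under distinct sub-seeds of \code{seed} and the
#' partition with the highest modularity is kept. Modules are relabelled
#' M1, M2, ... by decreasing size (ties by earliest member peak day when
#' \code{peak_day} is supplied, else by node name).
#'
#' @param net a \linkS4class{CoOscNetwork}.
#' @param seed master RNG seed.
#' @param resolution Louvain resolution parameter.
#' @param n_runs independent Louvain restarts.
#' @param peak_day optional named vector of feature peak day-of-year used
#'   to order equally sized modules phenologically.
#' @return the network with its \code{modules} slot filled and a
#'   \code{module} node attribute set.
#' @export
detectModules <- function(net, seed = 1, resolution = 1.0, n_runs = 20,
                          peak_day = NULL) {
  stopifnot(is(net, "CoOscNetwork"))
  g <- net@graph
  if (igraph::vcount(g) == 0) stop("empty network: no nodes to cluster")
  best <- NULL; best_mod <- -Inf
  for (i in seq_len(n_runs)) {
    set.seed(seed * 1000L + i)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    mod <- igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight)
    if (mod > best_mod) { best <- cl; best_mod <- mod }
  }
  memb <- igraph::membership(best)
  sizes <- table(memb)
  first_peak <- vapply(names(sizes), function(m) {
    nodes <- names(memb)[memb == m]
    if (is.null(peak_day)) return(NA_real_)
    suppressWarnings(min(peak_day[nodes], na.rm = TRUE))
  }, numeric(1))
  ord <- order(-as.integer(sizes), first_peak, names(sizes))
  relabel <- setNames(sprintf("M%d", seq_along(ord)), names(sizes)[ord])
  modules <- factor(unname(relabel[as.character(memb)]),
                    levels = sprintf("M%d", seq_along(ord)))
  names(modules) <- names(memb)
  igraph::V(g)$module <- as.character(modules)
  methods::initialize(net, graph = g, modules = modules)
}

#' @rdname CoOscNetwork
#' @export
setMethod("networkGraph", "CoOscNetwork", function(x) x@graph)

#' @rdname CoOscNetwork
#' @export
setMethod("moduleAssignment", "CoOscNetwork", function(x) x@modules)

#' @rdname CoOscNetwork
#' @param min_nodes modules smaller than this are omitted from
#'   \code{moduleSizes}.
#' @export
setMethod("moduleSizes", "CoOscNetwork", function(x) {
  if (!length(x@modules)) stop("run detectModules() first")
  table(x@modules)
})

setMethod("show", "CoOscNetwork", function(object) {
  g <- object@graph
  cat("CoOscNetwork:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      sprintf("edges (r > %.2f, q < %.2f)\n", object@rMin, object@alpha))
  if (length(object@modules)) {
    tab <- table(object@modules)
    cat("  modules:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  } else cat("  modules: not yet detected\n")
})

#' Summed module abundance profiles over time
#'
#' For each module and feature class, sums the relative abundances of the
#' module's member features at every time point, giving the temporal
#' dynamics of module prokaryotic ASVs, microeukaryotic ASVs and
#' functional clusters.
#'
#' @param relabund relative-abundance matrix, features x samples.
#' @param modules named factor of module assignments (e.g.
#'   \code{moduleAssignment()}); features absent from \code{relabund} are
#'   ignored.
#' @param feature_class named character of feature classes.
#' @return data.frame: module, feature_class, sample_id, abundance.
#' @export
moduleProfiles <- function(relabund, modules, feature_class) {
  feats <- intersect(names(modules), rownames(relabund))
  out <- list()
  for (m in levels(factor(modules))) {
    for (cl in unique(feature_class[feats])) {
      sel <- feats[modules[feats] == m & feature_class[feats] == cl]
      prof <- if (length(sel))
        colSums(relabund[sel, , drop = FALSE]) else
        setNames(rep(0, ncol(relabund)), colnames(relabund))
      out[[length(out) + 1L]] <- data.frame(
        module = m, feature_class = cl,
        sample_id = colnames(relabund), abundance = unname(prof))
    }
  }
  do.call(rbind, out)
}

#' Correlate module profiles with environmental covariates
#'
#' Pearson correlation of each (module, feature class) abundance profile
#' against each environmental covariate, pairwise-complete on missing
#' covariate values, with one Benjamini-Hochberg correction over the full
#' grid. Pairs with fewer than \code{min_pairs} complete observations are
#' reported NA.
#'
#' @param profiles data.frame from \code{\link{moduleProfiles}}.
#' @param env data.frame of covariates, rows aligned to samples in
#'   timeline order.
#' @param min_pairs minimum complete pairs for a correlation.
#' @param alpha significance threshold on q.
#' @return data.frame: module, feature_class, covariate, n, r, p, q,
#'   significant.
#' @export
moduleEnvCorrelations <- function(profiles, env, min_pairs = 3,
                                  alpha = 0.05) {
  samples <- unique(profiles$sample_id)
  stopifnot(nrow(env) == length(samples))
  rows <- list()
  for (key in split(profiles,
                    list(profiles$module, profiles$feature_class),
                    drop = TRUE)) {
    prof <- key$abundance[match(samples, key$sample_id)]
    for (cv in colnames(env)) {
      x <- env[[cv]]
      ok <- !is.na(prof) & !is.na(x)
      if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0 ||
          stats::sd(prof[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = key$module[1], feature_class = key$feature_class[1],
          covariate = cv, n = sum(ok), r = NA_real_, p = NA_real_)
        next
      }
      ct <- stats::cor.test(prof[ok], x[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        module = key$module[1], feature_class = key$feature_class[1],
        covariate = cv, n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < alpha
  out
}

#' Module robustness to depth and monthly subsampling
#'
#' Checks that module composition is not an artefact of uneven sequencing
#' depth or sampling frequency: rarefies the count table to its minimum
#' sample depth over repeated draws (mode \code{"depth"}), optionally
#' keeping a single sample per calendar month first (mode
#' \code{"monthly"}), and recomputes per-module component richness and
#' Shannon diversity of retained members each time.
#'
#' @param counts count matrix, features x samples.
#' @param modules named factor of module assignments.
#' @param dates sample dates (needed for mode \code{"monthly"}).
#' @param mode \code{"depth"} or \code{"monthly"}.
#' @param iterations rarefaction draws.
#' @param seed RNG seed.
#' @return data.frame per module: mean/sd of retained-member richness and
#'   Shannon diversity, and the mean fraction of members retained.
#' @export
moduleRobustnessSubsample <- function(counts, modules, dates = NULL,
                                      mode = c("depth", "monthly"),
                                      iterations = 20, seed = 1) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (mode == "monthly") {
    if (is.null(dates)) stop("dates required for monthly mode")
    key <- format(as.Date(dates), "%Y-%m")
    keep <- !duplicated(key)           # first sample of each month
    counts <- counts[, keep, drop = FALSE]
  }
  feats <- intersect(names(modules), rownames(counts))
  counts <- counts[feats, , drop = FALSE]
  depth <- min(colSums(counts))
  set.seed(seed)
  mods <- levels(factor(modules[feats]))
  acc <- array(NA_real_, c(length(mods), 3, iterations),
               dimnames = list(mods, c("richness", "shannon", "retained"),
                               NULL))
  for (it in seq_len(iterations)) {
    r <- t(.rrarefy(t(counts), depth))
    tot <- rowSums(r)
    for (m in mods) {
      sel <- feats[modules[feats] == m]
      v <- tot[sel]
      pres <- v > 0
      p <- v[pres] / sum(v)
      acc[m, , it] <- c(sum(pres),
                        -sum(p * log(p)),
                        mean(pres))
    }
  }
  data.frame(
    module = mods,
    richness_mean = apply(acc[, 1, , drop = FALSE], 1, mean),
    richness_sd = apply(acc[, 1, , drop = FALSE], 1, stats::sd),
    shannon_mean = apply(acc[, 2, , drop = FALSE], 1, mean),
    shannon_sd = apply(acc[, 2, , drop = FALSE], 1, stats::sd),
    retained_fraction = apply(acc[, 3, , drop = FALSE], 1, mean),
    mode = mode, depth = depth, row.names = NULL)
}

#' Write a network as an edge list and GraphML
#'
#' @param net a \linkS4class{CoOscNetwork}.
#' @param edge_path TSV path (source, target, r, q).
#' @param graphml_path optional GraphML path with node kind/module
#'   attributes.
#' @export
writeNetwork <- function(net, edge_path, graphml_path = NULL) {
  g <- net@graph
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   r = igraph::E(g)$r, q = igraph::E(g)$q)
  data.table::fwrite(df, edge_path, sep = "\t", quote = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(edge_path)
}
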