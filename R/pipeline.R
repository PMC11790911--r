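#' Oscillation-to-modules recovery pipeline
#'
#' Runs the full co-oscillation workflow on a (typically synthetic)
#' community: functional-cluster abundances are summed from member gene
#' clusters, ASV and function series are Fourier-reconstructed, annual
#' oscillators (consensus oscillation signal 1) are correlated pairwise,
#' the significant positive correlations form the network, and Louvain
#' partitions it into modules. When ground truth is supplied the detected
#' partition is scored against the planted cohorts by the adjusted Rand
#' index.
#'
#' @param sim list from \code{\link{simulateSeasonalCommunity}}, or a
#'   compatible list with elements \code{se}, \code{function_map},
#'   \code{ground_truth}.
#' @param r_min,alpha network edge thresholds.
#' @param n_components,grid_days,prominence_frac oscillation parameters.
#' @param min_nodes modules smaller than this are not reported.
#' @param seed RNG seed for Louvain restarts.
#' @return list: \code{oscillation} (OscillationSet), \code{network}
#'   (CoOscNetwork with modules), \code{n_modules} (count of modules with
#'   >= min_nodes nodes), \code{module_sizes}, \code{ari} (NA without
#'   ground truth), \code{assignment} (named module per node).
#' @export
recoverModules <- function(sim, r_min = 0.7, alpha = 0.05,
                           n_components = 3, grid_days = 7,
                           prominence_frac = 0.1, min_nodes = 5,
                           seed = 1) {
  se <- sim$se
  relab <- relAbundance(se)
  cls <- setNames(featureClass(se), rownames(se))

  # function nodes: summed member gene-cluster relative abundances
  gene_relab <- relab[cls[rownames(relab)] == "gene_cluster", , drop = FALSE]
  fun_tab <- functionAbundanceTable(gene_relab, sim$function_map)
  asv <- relab[cls[rownames(relab)] %in% c("prok_asv", "euk_asv"), ,
               drop = FALSE]
  node_tab <- rbind(asv, fun_tab)
  node_cls <- c(cls[rownames(asv)],
                setNames(rep("function", nrow(fun_tab)), rownames(fun_tab)))

  osc <- oscillationProfiles(node_tab, dates = sampleDates(se),
                             feature_class = node_cls[rownames(node_tab)],
                             grid_days = grid_days,
                             n_components = n_components,
                             prominence_frac = prominence_frac)
  keep <- annualOscillators(osc)
  if (length(keep) < 2) stop("fewer than 2 annual oscillators")
  sig <- reconstructedSignals(osc)[keep, , drop = FALSE]
  cors <- pairwiseOscillationCorrelation(sig)
  net <- buildNetwork(cors, feature_class = node_cls, r_min = r_min,
                      alpha = alpha)
  pk <- rowMeans(peakDays(osc), na.rm = TRUE)
  net <- detectModules(net, seed = seed, peak_day = pk)

  assignment <- moduleAssignment(net)
  sizes <- table(assignment)
  big <- names(sizes)[sizes >= min_nodes]

  ari <- NA_real_
  if (!is.null(sim$ground_truth)) {
    truth <- c(setNames(sim$ground_truth$cohort, sim$ground_truth$feature_id))
    if (!is.null(sim$function_classes))
      truth <- c(truth, setNames(sim$function_classes$cohort,
                                 sim$function_classes$function_id))
    nodes <- names(assignment)[!is.na(truth[names(assignment)])]
    if (length(nodes) >= 2)
      ari <- adjustedRandIndex(as.character(assignment[nodes]),
                               truth[nodes])
  }
  list(oscillation = osc, network = net, n_modules = length(big),
       module_sizes = sizes, ari = ari, assignment = assignment)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index computed from the contingency table
#' of the two labellings; 1 for identical partitions, ~0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- choose2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
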