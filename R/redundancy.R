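#' Aggregate gene-cluster abundances into functional clusters
#'
#' A functional cluster's abundance at each sample is the sum of its member
#' gene clusters. Gene clusters absent from the map are reported via the
#' \code{"unmapped"} attribute.
#'
#' @param gene_table matrix of gene-cluster abundances, features x samples.
#' @param map data.frame with columns \code{gene_id}, \code{function_id}
#'   (each gene cluster mapping to exactly one function).
#' @return matrix of function abundances, functions x samples.
#' @export
functionAbundanceTable <- function(gene_table, map) {
  if (is.null(map) || nrow(map) == 0) stop("empty function map")
  if (anyDuplicated(map$gene_id))
    stop("gene cluster(s) mapped to more than one function: ",
         paste(unique(map$gene_id[duplicated(map$gene_id)]), collapse = ", "))
  present <- map$gene_id %in% rownames(gene_table)
  map <- map[present, , drop = FALSE]
  if (nrow(map) == 0) stop("no mapped gene clusters found in the table")
  sub <- gene_table[map$gene_id, , drop = FALSE]
  out <- rowsum(sub, group = map$function_id)
  attr(out, "unmapped") <- setdiff(rownames(gene_table), map$gene_id)
  out
}

#' Fraction of multi-gene-cluster functions per module
#'
#' The proportion of functions in each module comprising two or more gene
#' clusters — a proxy for functional redundancy.
#'
#' @param map data.frame (gene_id, function_id).
#' @param modules named factor/character of module assignments for
#'   function IDs; functions without an assignment are pooled under
#'   \code{"(unassigned)"}.
#' @return data.frame: module, n_functions, n_multi, multi_fraction.
#' @export
multiClusterFraction <- function(map, modules = NULL) {
  members <- table(map$function_id)
  fids <- names(members)
  mod <- if (is.null(modules)) rep("all", length(fids)) else {
    m <- as.character(modules[fids])
    m[is.na(m)] <- "(unassigned)"
    m
  }
  out <- do.call(rbind, lapply(split(seq_along(fids), mod), function(idx) {
    data.frame(n_functions = length(idx),
               n_multi = sum(members[idx] >= 2))
  }))
  out <- data.frame(module = rownames(out), out, row.names = NULL)
  out$multi_fraction <- out$n_multi / out$n_functions
  out
}

#' Diversity-abundance coupling of a function's gene clusters
#'
#' At each time point, the Shannon diversity of the member gene clusters is
#' computed on their within-function composition (members renormalised to
#' sum 1); the function's relative abundance is then regressed on that
#' diversity by ordinary least squares. A significant positive slope means
#' the function's dynamics are driven by the concurrent growth of multiple,
#' metabolically overlapping members rather than a single dominant one.
#' Time points where the function is absent are excluded (diversity is
#' undefined at zero).
#'
#' @param function_series numeric vector, the function's relative abundance
#'   over samples.
#' @param member_matrix matrix of member gene-cluster abundances, members x
#'   samples (>= 2 members).
#' @param alpha significance level on the two-sided slope p value.
#' @param min_points minimum usable time points.
#' @return list: slope, p, flag (slope > 0 and p < alpha), n, diversity.
#' @export
diversityAbundanceAssociation <- function(function_series, member_matrix,
                                          alpha = 0.05, min_points = 8) {
  member_matrix <- as.matrix(member_matrix)
  if (nrow(member_matrix) < 2) stop("function needs >= 2 member gene clusters")
  tot <- colSums(member_matrix)
  ok <- tot > 0 & !is.na(function_series)
  if (sum(ok) < min_points)
    stop("need >= ", min_points, " time points with nonzero abundance, have ",
         sum(ok))
  p_comp <- sweep(member_matrix[, ok, drop = FALSE], 2, tot[ok], "/")
  H <- apply(p_comp, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  y <- function_series[ok]
  if (stats::sd(H) == 0)
    return(list(slope = 0, p = NA_real_, flag = FALSE, n = sum(ok),
                diversity = H))
  fit <- stats::lm(y ~ H)
  co <- summary(fit)$coefficients
  slope <- co["H", "Estimate"]
  pval <- co["H", "Pr(>|t|)"]
  list(slope = slope, p = pval, flag = slope > 0 && pval < alpha,
       n = sum(ok), diversity = H)
}

#' Cross-year dominance consistency of a function's gene clusters
#'
#' For each year, locates the time point where the function reaches its
#' peak abundance and identifies the dominant member there (largest member
#' value; exact ties resolved to the lexicographically smallest ID and
#' flagged). The function is \code{"same"} when one member dominates every
#' scored year, \code{"different"} otherwise. Years where the function is
#' entirely absent are skipped and noted.
#'
#' @param member_matrix member gene-cluster abundances, members x samples.
#' @param year_index year label per sample (>= 2 distinct years required).
#' @return list: status ("same"/"different"), dominant (named by year),
#'   tie (logical), skipped_years.
#' @export
dominanceConsistency <- function(member_matrix, year_index) {
  member_matrix <- as.matrix(member_matrix)
  years <- unique(year_index)
  if (length(years) < 2) stop("need >= 2 years")
  fun <- colSums(member_matrix)
  dominant <- character(); tie <- FALSE; skipped <- c()
  for (y in years) {
    sel <- which(year_index == y)
    if (all(fun[sel] == 0)) { skipped <- c(skipped, y); next }
    peak <- sel[which.max(fun[sel])]
    v <- member_matrix[, peak]
    top <- which(v == max(v))
    if (length(top) > 1) {
      tie <- TRUE
      top <- top[order(rownames(member_matrix)[top])[1]]
    }
    dominant[as.character(y)] <- rownames(member_matrix)[top]
  }
  if (!length(dominant)) stop("function absent in every year")
  list(status = if (length(unique(dominant)) == 1L) "same" else "different",
       dominant = dominant, tie = tie, skipped_years = skipped)
}

#' Per-module redundancy report
#'
#' Combines the three gene-cluster-within-function analyses for every
#' module: the fraction of multi-cluster functions, the fraction of tested
#' multi-cluster functions with a significant positive diversity-abundance
#' slope, and the fraction of multi-cluster functions dominated by the same
#' gene cluster at each year's peak.
#'
#' @param gene_relabund relative-abundance matrix of gene clusters.
#' @param map data.frame (gene_id, function_id).
#' @param modules named module assignment for function IDs (optional).
#' @param year_index year label per sample.
#' @param alpha significance level for the regression flag.
#' @return list: \code{summary} (per-module fractions) and \code{detail}
#'   (per-function slope/p/flag/dominance).
#' @export
redundancyReport <- function(gene_relabund, map, modules = NULL,
                             year_index, alpha = 0.05) {
  fun_tab <- functionAbundanceTable(gene_relabund, map)
  mcf <- multiClusterFraction(map, modules)
  members <- split(map$gene_id, map$function_id)
  detail <- list()
  for (f in names(members)) {
    mem <- intersect(members[[f]], rownames(gene_relabund))
    if (length(mem) < 2) next
    mm <- gene_relabund[mem, , drop = FALSE]
    assoc <- tryCatch(
      diversityAbundanceAssociation(fun_tab[f, ], mm, alpha = alpha),
      error = function(e) list(slope = NA_real_, p = NA_real_, flag = NA,
                               n = NA_integer_))
    dom <- tryCatch(dominanceConsistency(mm, year_index),
                    error = function(e) list(status = NA_character_,
                                             tie = NA))
    detail[[f]] <- data.frame(
      function_id = f, n_members = length(mem),
      slope = assoc$slope, p = assoc$p, coupling_flag = assoc$flag,
      dominance = dom$status, tie = dom$tie)
  }
  detail <- do.call(rbind, c(detail, list(make.row.names = FALSE)))
  mod_of <- function(fid) {
    if (is.null(modules)) rep("all", length(fid))
    else {
      m <- as.character(modules[fid]); m[is.na(m)] <- "(unassigned)"; m
    }
  }
  detail$module <- mod_of(detail$function_id)
  agg <- do.call(rbind, lapply(split(detail, detail$module), function(d) {
    data.frame(
      module = d$module[1],
      coupling_fraction = mean(d$coupling_flag[!is.na(d$coupling_flag)]),
      same_dominant_fraction = mean(d$dominance == "same", na.rm = TRUE),
      n_multi_tested = sum(!is.na(d$coupling_flag)))
  }))
  summary <- merge(mcf, agg, by = "module", all.x = TRUE)
  list(summary = summary, detail = detail)
}
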