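#' Construct a SeasonalExperiment
#'
#' @param counts numeric matrix of nonnegative abundances, features x samples,
#'   with feature IDs as rownames and sample IDs as colnames.
#' @param dates sample collection dates (\code{Date} or ISO-8601 strings),
#'   one per column of \code{counts}. Samples are reordered chronologically.
#' @param feature_class character, one of \code{"prok_asv"}, \code{"euk_asv"},
#'   \code{"gene_cluster"}, \code{"function"}; recycled if length 1.
#' @param env optional data.frame of environmental covariates, one row per
#'   sample (reordered with the samples). Missing values are kept as NA.
#' @param taxonomy optional character vector of taxonomy strings per feature.
#'
#' @return a \linkS4class{SeasonalExperiment} with assays \code{counts} and
#'   \code{relabund} (per-sample relative abundances).
#' @export
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("asv", 1:3), paste0("s", 1:4)))
#' se <- SeasonalExperiment(m, as.Date("2016-01-01") + c(0, 14, 28, 42),
#'                          feature_class = "prok_asv")
#' featureClass(se)
SeasonalExperiment <- function(counts, dates, feature_class = "prok_asv",
                               env = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have feature IDs as rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample IDs as colnames")
  dates <- as.Date(dates)
  if (length(dates) != ncol(counts))
    stop("one date per sample required")
  ord <- order(dates)
  counts <- counts[, ord, drop = FALSE]
  dates <- dates[ord]
  if (length(feature_class) == 1L)
    feature_class <- rep(feature_class, nrow(counts))
  cd <- S4Vectors::DataFrame(
    date = dates,
    day_of_year = .dayOfYear(dates),
    year_index = .yearIndex(dates),
    row.names = colnames(counts)
  )
  env_names <- character()
  if (!is.null(env)) {
    env <- as.data.frame(env)[ord, , drop = FALSE]
    env_names <- colnames(env)
    for (nm in env_names) cd[[nm]] <- env[[nm]]
  }
  rd <- S4Vectors::DataFrame(feature_class = feature_class,
                             row.names = rownames(counts))
  if (!is.null(taxonomy)) rd$taxonomy <- taxonomy
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts,
                  relabund = .closeColumns(counts)),
    rowData = rd, colData = cd
  )
  out <- methods::new("SeasonalExperiment", se)
  S4Vectors::metadata(out)$env_covariates <- env_names
  out
}

# day-of-year on the actual calendar (leap-aware), Jan 1 = 1
.dayOfYear <- function(dates) as.POSIXlt(dates)$yday + 1L

.yearIndex <- function(dates) {
  yr <- as.POSIXlt(dates)$year
  as.integer(yr - min(yr) + 1L)
}

.closeColumns <- function(m) {
  cs <- colSums(m)
  if (any(cs == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  sweep(m, 2, cs, "/")
}

#' @rdname SeasonalExperiment
#' @export
setMethod("featureClass", "SeasonalExperiment", function(x)
  SummarizedExperiment::rowData(x)$feature_class)

#' @rdname SeasonalExperiment
#' @export
setMethod("sampleDates", "SeasonalExperiment", function(x)
  as.Date(SummarizedExperiment::colData(x)$date))

#' @rdname SeasonalExperiment
#' @export
setMethod("dayOfYear", "SeasonalExperiment", function(x)
  SummarizedExperiment::colData(x)$day_of_year)

#' @rdname SeasonalExperiment
#' @export
setMethod("yearIndex", "SeasonalExperiment", function(x)
  SummarizedExperiment::colData(x)$year_index)

#' @rdname SeasonalExperiment
#' @export
setMethod("envCovariates", "SeasonalExperiment", function(x) {
  nms <- S4Vectors::metadata(x)$env_covariates
  if (is.null(nms)) {
    core <- c("date", "day_of_year", "year_index")
    nms <- setdiff(colnames(SummarizedExperiment::colData(x)), core)
  }
  as.data.frame(SummarizedExperiment::colData(x)[, nms, drop = FALSE])
})

#' Counts and relative-abundance accessors
#'
#' @param x a \code{SeasonalExperiment}.
#' @return numeric matrix, features x samples.
#' @export
seasonCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname seasonCounts
#' @export
relAbundance <- function(x) {
  if ("relabund" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "relabund")
  else
    .closeColumns(SummarizedExperiment::assay(x, "counts"))
}

setMethod("show", "SeasonalExperiment", function(object) {
  cl <- table(featureClass(object))
  d <- sampleDates(object)
  cat("SeasonalExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  features:", paste(sprintf("%s (%d)", names(cl), cl),
                           collapse = ", "), "\n")
  if (length(d))
    cat("  timeline:", format(min(d)), "to", format(max(d)),
        sprintf("(%d days, %d calendar years)\n",
                as.integer(max(d) - min(d)),
                length(unique(as.POSIXlt(d)$year))))
  env <- S4Vectors::metadata(object)$env_covariates
  if (length(env)) cat("  environment:", paste(env, collapse = ", "), "\n")
})
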