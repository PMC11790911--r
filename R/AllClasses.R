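#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.FEATURE_CLASSES <- c("prok_asv", "euk_asv", "gene_cluster", "function")

.ENV_COVARIATES <- c("temperature", "salinity", "oxygen", "chlorophyll",
                     "PAR", "MLD")

#' SeasonalExperiment: a feature-by-sample time series container
#'
#' Extends \linkS4class{SummarizedExperiment} for multi-year microbiome time
#' series. Rows are features (prokaryotic/microeukaryotic ASVs, gene clusters
#' or functional clusters, recorded in \code{rowData()$feature_class});
#' columns are samples ordered by collection date. \code{colData()} carries
#' the sample timeline (\code{date}, derived \code{day_of_year} and
#' \code{year_index}) plus any environmental covariates (temperature,
#' salinity, oxygen saturation, chlorophyll, PAR, mixed layer depth).
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @export
setClass("SeasonalExperiment", contains = "SummarizedExperiment")

setValidity("SeasonalExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"date" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'date' column")
  else {
    d <- as.Date(cd$date)
    if (anyNA(d)) msg <- c(msg, "colData 'date' contains unparseable values")
    else if (ncol(object) > 1L && any(diff(as.numeric(d)) <= 0))
      msg <- c(msg, "sample dates must be strictly increasing")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"feature_class" %in% colnames(rd))
    msg <- c(msg, "rowData must contain a 'feature_class' column")
  else if (!all(rd$feature_class %in% .FEATURE_CLASSES))
    msg <- c(msg, sprintf("feature_class values must be one of: %s",
                          paste(.FEATURE_CLASSES, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature IDs (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample IDs (colnames) must be present and unique")
  for (an in SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, an)
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("assay '%s' contains negative values", an))
  }
  if (length(msg)) msg else TRUE
})

#' OscillationSet: per-feature oscillation signals
#'
#' Holds, for a set of features, the abundance series interpolated onto a
#' uniform day grid, the Fourier reconstruction from a limited number of
#' components, and the derived oscillation signals: per-year peak counts,
#' the consensus count (the modal per-year count, ties broken toward the
#' smaller count), per-year peak day-of-year, and the reconstruction
#' amplitude. A feature with consensus 1 — a single peak and trough per
#' annual cycle — is an annual oscillator.
#'
#' @slot gridSignal matrix, features x grid points: interpolated series.
#' @slot reconstructed matrix, features x grid points: limited-component
#'   Fourier reconstruction.
#' @slot gridDay numeric, day offset of each grid point from the first sample.
#' @slot gridDate Date vector parallel to \code{gridDay}.
#' @slot years integer, the calendar years over which peaks were counted.
#' @slot peakCounts integer matrix, features x years.
#' @slot peakDays numeric matrix, features x years: day-of-year of the
#'   highest peak in each year (NA when no peak).
#' @slot consensus integer, consensus oscillation signal per feature.
#' @slot amplitude numeric, half peak-to-trough range of the reconstruction.
#' @slot featureClass character, feature class per feature.
#' @slot nComponents integer(1), number of non-DC components retained.
#' @export
setClass("OscillationSet",
  representation(
    gridSignal    = "matrix",
    reconstructed = "matrix",
    gridDay       = "numeric",
    gridDate      = "Date",
    years         = "integer",
    peakCounts    = "matrix",
    peakDays      = "matrix",
    consensus     = "integer",
    amplitude     = "numeric",
    featureClass  = "character",
    nComponents   = "integer"
  )
)

setValidity("OscillationSet", function(object) {
  msg <- character()
  n <- nrow(object@gridSignal)
  g <- ncol(object@gridSignal)
  if (!identical(dim(object@reconstructed), c(n, g)))
    msg <- c(msg, "gridSignal and reconstructed must have identical dimensions")
  if (length(object@gridDay) != g)
    msg <- c(msg, "gridDay length must equal the number of grid points")
  if (nrow(object@peakCounts) != n || nrow(object@peakDays) != n)
    msg <- c(msg, "peak matrices must have one row per feature")
  if (ncol(object@peakCounts) != length(object@years))
    msg <- c(msg, "peakCounts must have one column per year")
  if (length(object@consensus) != n || length(object@amplitude) != n ||
      length(object@featureClass) != n)
    msg <- c(msg, "per-feature vectors must match the number of features")
  if (any(object@peakCounts < 0, na.rm = TRUE))
    msg <- c(msg, "peak counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' CoOscNetwork: filtered co-oscillation correlation network
#'
#' An undirected graph whose nodes are annually oscillating features (ASVs
#' and functional clusters) and whose edges are significant positive Pearson
#' correlations between oscillation signals (r above a threshold, BH-adjusted
#' p below alpha), with a Louvain module partition once
#' \code{\link{detectModules}} has been run.
#'
#' @slot graph an \code{igraph} object; edge attributes \code{r} and \code{q},
#'   node attributes \code{kind} (feature class) and, after module detection,
#'   \code{module}.
#' @slot rMin numeric(1), correlation threshold used for edges.
#' @slot alpha numeric(1), adjusted-p threshold used for edges.
#' @slot modules factor, module assignment named by node (length 0 before
#'   detection).
#' @export
setClass("CoOscNetwork",
  representation(graph = "ANY", rMin = "numeric", alpha = "numeric",
                 modules = "factor")
)

setValidity("CoOscNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph))
    msg <- c(msg, "graph slot must contain an igraph object")
  else {
    if (igraph::is_directed(object@graph))
      msg <- c(msg, "network must be undirected")
    if (igraph::any_loop(object@graph))
      msg <- c(msg, "network must not contain self-loops")
    nm <- length(object@modules)
    if (nm && nm != igraph::vcount(object@graph))
      msg <- c(msg, "module assignment must cover every node")
  }
  if (length(msg)) msg else TRUE
})
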