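#' Read a feature-by-sample abundance table
#'
#' Expects tab-separated text with feature IDs in the first column and a
#' header row of sample IDs. Values must be nonnegative; \code{NA} encodes
#' missing.
#'
#' @param path file path.
#' @param class_label feature class assigned to every row (one of
#'   \code{"prok_asv"}, \code{"euk_asv"}, \code{"gene_cluster"},
#'   \code{"function"}).
#' @return numeric matrix with feature rownames and sample colnames, plus a
#'   \code{"feature_class"} attribute.
#' @export
readFeatureTable <- function(path, class_label = "prok_asv") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!class_label %in% .FEATURE_CLASSES)
    stop("unknown class_label: ", class_label)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2) stop("no features in ", path)
  ids <- as.character(dt[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(dt[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))) &
                                         !is.na(r) & r != "NA")))
    stop("non-numeric value(s) at row(s): ", paste(bad, collapse = ", "))
  }
  neg <- which(apply(m, 1, function(r) any(r < 0, na.rm = TRUE)))
  if (length(neg))
    stop("negative value(s) at row(s): ", paste(neg, collapse = ", "))
  rownames(m) <- ids
  attr(m, "feature_class") <- class_label
  m
}

#' Write a feature table as TSV
#'
#' Features as rows, samples as columns; missing values written as
#' \code{NA}. \code{readFeatureTable} round-trips the result.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header of the feature-ID column.
#' @export
writeFeatureTable <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_column
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read sample metadata into a timeline
#'
#' Requires \code{sample_id} and ISO-8601 \code{date} columns; any other
#' columns are treated as environmental covariates and kept (missing cells
#' stay \code{NA}). Rows are sorted by date; day-of-year (leap-aware,
#' Jan 1 = 1) and a year index are derived.
#'
#' @param path file path.
#' @return data.frame sorted by date with columns sample_id, date,
#'   day_of_year, year_index and any covariates.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- setdiff(c("sample_id", "date"), colnames(df))
  if (length(need))
    stop("missing required column(s): ", paste(need, collapse = ", "))
  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable date value(s): ",
         paste(df$date[is.na(d)], collapse = ", "))
  df$date <- d
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  covar <- setdiff(colnames(df), c("sample_id", "date"))
  out <- data.frame(sample_id = df$sample_id, date = df$date,
                    day_of_year = .dayOfYear(df$date),
                    year_index = .yearIndex(df$date))
  for (nm in covar) out[[nm]] <- df[[nm]]
  out
}

#' Convert counts to relative abundances
#'
#' Optionally divides each sample by a scale factor first (e.g. the
#' estimated number of prokaryotic genomes per sample) before closing each
#' column to sum 1. Idempotent: applying it twice equals applying it once.
#'
#' @param m numeric matrix, features x samples.
#' @param scale_factors optional per-sample divisors (> 0).
#' @return matrix whose columns each sum to 1.
#' @export
toRelativeAbundance <- function(m, scale_factors = NULL) {
  m <- as.matrix(m)
  if (!is.null(scale_factors)) {
    if (length(scale_factors) != ncol(m))
      stop("one scale factor per sample required")
    if (any(scale_factors <= 0)) stop("scale factors must be > 0")
    m <- sweep(m, 2, scale_factors, "/")
  }
  cs <- colSums(m, na.rm = TRUE)
  zero <- which(cs == 0)
  if (length(zero))
    stop("all-zero sample(s): ",
         paste(colnames(m)[zero] %||% zero, collapse = ", "))
  sweep(m, 2, cs, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prevalence filter for count tables
#'
#' Retains features observed with more than \code{min_count} counts in more
#' than \code{min_samples} samples (strict inequalities; the defaults keep
#' features with >3 counts in >3 samples).
#'
#' @param m count matrix, features x samples.
#' @param min_count count threshold (exclusive).
#' @param min_samples sample-number threshold (exclusive).
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
filterPrevalence <- function(m, min_count = 3, min_samples = 3) {
  keep <- rowSums(m > min_count, na.rm = TRUE) > min_samples
  if (!any(keep)) warning("no features pass the prevalence filter")
  m[keep, , drop = FALSE]
}
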