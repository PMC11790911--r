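#' Specification of a planted seasonal cohort
#'
#' A cohort is a set of features (prokaryotic ASVs, microeukaryotic ASVs and
#' gene clusters) whose latent abundance follows a shared von-Mises-shaped
#' annual pulse centred on \code{peak_day}. The five default cohorts emulate
#' a seasonal succession of co-oscillating community states.
#'
#' @param name cohort label.
#' @param n_asv_prok,n_asv_euk,n_gene feature counts (>= 0).
#' @param peak_day day-of-year of the abundance maximum, in [1, 365].
#' @param width_days approximate full width at half maximum of the annual
#'   pulse, in days (> 0).
#' @param amplitude_range min/max of the per-feature latent amplitude,
#'   drawn uniformly.
#' @param peaks_per_year number of pulses per annual cycle (1 = annual,
#'   2 = semiannual).
#' @return a \code{cohort_spec} list.
#' @export
cohortSpec <- function(name, n_asv_prok = 6L, n_asv_euk = 3L, n_gene = 8L,
                       peak_day = 180, width_days = 90,
                       amplitude_range = c(0.5, 2), peaks_per_year = 1L) {
  if (any(c(n_asv_prok, n_asv_euk, n_gene) < 0))
    stop("cohort feature counts must be >= 0 (cohort '", name, "')")
  if (peak_day < 1 || peak_day > 365)
    stop("peak_day must be in [1, 365] (cohort '", name, "')")
  if (width_days <= 0)
    stop("width_days must be > 0 (cohort '", name, "')")
  if (peaks_per_year < 1)
    stop("peaks_per_year must be >= 1 (cohort '", name, "')")
  structure(list(name = as.character(name),
                 n_asv_prok = as.integer(n_asv_prok),
                 n_asv_euk = as.integer(n_asv_euk),
                 n_gene = as.integer(n_gene),
                 peak_day = peak_day, width_days = width_days,
                 amplitude_range = amplitude_range,
                 peaks_per_year = as.integer(peaks_per_year)),
            class = "cohort_spec")
}

#' Default seasonal cohorts
#'
#' Five cohorts peaking in early polar night (day 330), late polar night
#' (60), spring (135), summer (200) and autumn (270), mirroring a polar
#' annual succession. The minimum circular separation between peak days is
#' 60 days, which keeps cross-cohort pulse correlations far below the 0.7
#' network edge threshold.
#'
#' @export
defaultCohorts <- function() {
  peaks <- c(M1 = 330, M2 = 60, M3 = 135, M4 = 200, M5 = 270)
  lapply(names(peaks), function(nm) cohortSpec(nm, peak_day = peaks[[nm]]))
}

#' Specification of a synthetic seasonal community
#'
#' @param n_years number of simulated annual cycles (>= 1).
#' @param interval_days mean sampling spacing in days.
#' @param jitter_days half-width of the uniform timing noise, in days; must
#'   be < interval_days / 2 so that sampling dates stay strictly increasing.
#' @param cohorts list of \code{\link{cohortSpec}} objects.
#' @param n_arrhythmic number of non-seasonal (random-walk) features.
#' @param noise_dispersion negative-binomial overdispersion of the counts
#'   (variance = mu + dispersion * mu^2); 0 gives deterministic rounded
#'   counts.
#' @param library_size expected total counts per sample.
#' @param start_date first sampling date (anchors calendar years).
#' @param seed RNG seed fixing all randomness end-to-end.
#' @return a \code{synthetic_spec} list.
#' @export
syntheticSpec <- function(n_years = 4L, interval_days = 14, jitter_days = 3,
                          cohorts = defaultCohorts(), n_arrhythmic = 15L,
                          noise_dispersion = 0.1, library_size = 1e5,
                          start_date = "2016-01-01", seed = 1L) {
  if (n_years < 1) stop("invalid spec: n_years must be >= 1")
  if (interval_days <= 0) stop("invalid spec: interval_days must be > 0")
  if (jitter_days < 0 || jitter_days >= interval_days / 2)
    stop("invalid spec: jitter_days must be in [0, interval_days/2)")
  if (n_arrhythmic < 0) stop("invalid spec: n_arrhythmic must be >= 0")
  if (noise_dispersion < 0) stop("invalid spec: noise_dispersion must be >= 0")
  if (!all(vapply(cohorts, inherits, logical(1), "cohort_spec")))
    stop("invalid spec: cohorts must be a list of cohortSpec objects")
  structure(list(n_years = as.integer(n_years),
                 interval_days = interval_days, jitter_days = jitter_days,
                 cohorts = cohorts, n_arrhythmic = as.integer(n_arrhythmic),
                 noise_dispersion = noise_dispersion,
                 library_size = library_size,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate an irregular multi-year sampling timeline
#'
#' Samples are placed every \code{interval_days} over \code{n_years} x 365
#' days, each displaced by an integer jitter drawn uniformly from
#' [-jitter_days, jitter_days] (endpoints pinned inside the span). Dates are
#' strictly increasing.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return data.frame with columns sample_id, date, day_offset, day_of_year,
#'   year_index.
#' @export
generateTimeline <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  span <- spec$n_years * 365
  base <- seq(0, span, by = spec$interval_days)
  set.seed(spec$seed + 101L)
  jit <- if (spec$jitter_days > 0)
    sample(-spec$jitter_days:spec$jitter_days, length(base), replace = TRUE)
  else rep(0L, length(base))
  off <- pmin(pmax(base + jit, 0), span)
  off[1] <- 0
  stopifnot(all(diff(off) > 0))
  dates <- spec$start_date + off
  data.frame(sample_id = sprintf("S%03d", seq_along(off)),
             date = dates, day_offset = off,
             day_of_year = .dayOfYear(dates),
             year_index = .yearIndex(dates))
}

#' Default environmental phase parameters
#'
#' Sinusoidal annual cycles for the six covariates of a high-latitude
#' Atlantic-water site: temperature (degC), salinity (PSU), oxygen
#' saturation (%), chlorophyll (ug/L), PAR (umol photons m-2 s-1, clipped
#' at 0 during polar night) and mixed layer depth (m, anti-phase to
#' temperature by construction).
#'
#' @export
defaultEnvironmentPhases <- function() {
  list(
    temperature = list(peak_day = 240, amplitude = 2.5, baseline = 4.5, lag = 0),
    salinity    = list(peak_day = 60,  amplitude = 0.15, baseline = 35.0, lag = 0),
    oxygen      = list(peak_day = 120, amplitude = 8,   baseline = 95,  lag = 0),
    chlorophyll = list(peak_day = 160, amplitude = 1.2, baseline = 1.25, lag = 0),
    PAR         = list(peak_day = 172, amplitude = 350, baseline = 120, lag = 0),
    MLD         = list(peak_day = 57,  amplitude = 120, baseline = 150, lag = 0)
  )
}

#' Generate seasonally phased environmental covariates
#'
#' Each covariate is baseline + amplitude * cos(2 pi (doy - peak_day - lag)
#' / 365). PAR and chlorophyll are clipped at 0, which produces the polar
#' night window of zero irradiance; the default MLD peak day is anti-phase
#' to temperature, so cor(temperature, MLD) < 0 by construction.
#'
#' @param timeline data.frame from \code{\link{generateTimeline}}.
#' @param phases named list of lists with elements peak_day, amplitude,
#'   baseline, lag; names must be covariates from
#'   \code{\link{defaultEnvironmentPhases}}.
#' @return data.frame, one row per sample, one column per covariate.
#' @export
generateEnvironment <- function(timeline, phases = defaultEnvironmentPhases()) {
  if (nrow(timeline) == 0) stop("timeline is empty")
  unknown <- setdiff(names(phases), .ENV_COVARIATES)
  if (length(unknown))
    stop("unknown covariate key(s): ", paste(unknown, collapse = ", "))
  doy <- timeline$day_of_year
  out <- lapply(names(phases), function(nm) {
    p <- phases[[nm]]
    v <- p$baseline + p$amplitude *
      cos(2 * pi * (doy - p$peak_day - p$lag) / 365)
    if (nm %in% c("PAR", "chlorophyll")) v <- pmax(v, 0)
    v
  })
  names(out) <- names(phases)
  as.data.frame(out, row.names = timeline$sample_id)
}

# von Mises concentration giving a pulse of approximately the requested
# full width at half maximum (in days) on a 365-day cycle
.pulseKappa <- function(width_days) {
  log(2) / (1 - cos(pi * width_days / 365))
}

# unit-peak annual pulse: exp(kappa (cos(2 pi k (t - mu)/365) - 1))
.annualPulse <- function(day_offset, peak_day, width_days, peaks_per_year = 1) {
  kap <- .pulseKappa(width_days)
  exp(kap * (cos(2 * pi * peaks_per_year * (day_offset - peak_day) / 365) - 1))
}

# smoothed, exponentiated Gaussian random walk: positive, autocorrelated,
# non-seasonal
.arrhythmicSeries <- function(n, sd = 0.12) {
  w <- cumsum(stats::rnorm(n, sd = sd))
  s <- as.numeric(stats::filter(w, rep(1 / 3, 3), sides = 2))
  s[1] <- w[1]; s[n] <- w[n]
  v <- exp(s - mean(s))
  v / mean(v)
}

#' Generate a synthetic seasonal community
#'
#' Cohort features get a von-Mises-shaped annual pulse centred on the
#' cohort's peak day with a per-feature (optionally per-year) amplitude;
#' arrhythmic features are smoothed, exponentiated Gaussian random walks.
#' Latent abundances are closed to proportions per sample and counts drawn
#' with negative-binomial overdispersion at the configured library size
#' (deterministic rounding when \code{noise_dispersion} is 0).
#'
#' @param timeline data.frame from \code{\link{generateTimeline}}.
#' @param spec a \code{\link{syntheticSpec}}.
#' @param feature_params optional data.frame overriding the per-feature
#'   latent parameters (as produced by the internal builder); used by
#'   \code{\link{simulateSeasonalCommunity}} to plant redundancy structure.
#' @param env optional environment table attached to the result's colData.
#' @return list with elements \code{se} (a
#'   \linkS4class{SeasonalExperiment}) and \code{ground_truth} (data.frame:
#'   feature_id, feature_class, cohort, planted_oscillations, peak_day).
#' @export
generateCommunity <- function(timeline, spec, feature_params = NULL,
                              env = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(feature_params))
    feature_params <- .defaultFeatureParams(spec)
  if (nrow(feature_params) == 0) stop("zero total features")
  n_years <- spec$n_years
  t <- timeline$day_offset
  set.seed(spec$seed + 202L)

  latent <- matrix(0, nrow(feature_params), length(t),
                   dimnames = list(feature_params$feature_id,
                                   timeline$sample_id))
  for (i in seq_len(nrow(feature_params))) {
    fp <- feature_params[i, ]
    if (fp$type == "pulse") {
      amps <- fp$amp_schedule[[1]]
      if (length(amps) == 1L) amps <- rep(amps, n_years)
      amp_t <- amps[pmin(timeline$year_index, length(amps))]
      latent[i, ] <- amp_t *
        .annualPulse(t, fp$peak_day, fp$width_days, fp$peaks_per_year) +
        fp$baseline
    } else {
      latent[i, ] <- fp$amp_schedule[[1]][1] * .arrhythmicSeries(length(t))
    }
  }

  prop <- .closeColumns(latent)
  mu <- prop * spec$library_size
  if (spec$noise_dispersion == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / spec$noise_dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu))
  }
  # guard against an (improbable) all-zero sample after count draws
  zero <- colSums(counts) == 0
  if (any(zero)) counts[1, zero] <- 1

  se <- SeasonalExperiment(counts, timeline$date,
                           feature_class = feature_params$feature_class,
                           env = env)
  gt <- data.frame(feature_id = feature_params$feature_id,
                   feature_class = feature_params$feature_class,
                   cohort = feature_params$cohort,
                   planted_oscillations = ifelse(
                     feature_params$type == "pulse",
                     feature_params$peaks_per_year, NA_integer_),
                   peak_day = feature_params$peak_day)
  list(se = se, ground_truth = gt)
}

# one row per feature: latent-model parameters; amp_schedule is a list
# column of per-year amplitude vectors (length 1 = constant across years)
.defaultFeatureParams <- function(spec) {
  set.seed(spec$seed + 303L)
  rows <- list()
  for (co in spec$cohorts) {
    for (cl in c("prok_asv", "euk_asv", "gene_cluster")) {
      n <- switch(cl, prok_asv = co$n_asv_prok, euk_asv = co$n_asv_euk,
                  gene_cluster = co$n_gene)
      if (n == 0) next
      pre <- switch(cl, prok_asv = "pro", euk_asv = "euk",
                    gene_cluster = "gc")
      amp <- stats::runif(n, co$amplitude_range[1], co$amplitude_range[2])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s_%s_%02d", pre, co$name, seq_len(n)),
        feature_class = cl, cohort = co$name, type = "pulse",
        peak_day = co$peak_day, width_days = co$width_days,
        peaks_per_year = co$peaks_per_year, baseline = 0,
        amp_schedule = I(as.list(amp)))
    }
  }
  if (spec$n_arrhythmic > 0) {
    cls <- rep(c("prok_asv", "euk_asv", "gene_cluster"),
               length.out = spec$n_arrhythmic)
    amp <- stats::runif(spec$n_arrhythmic, 0.5, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = sprintf("arr_%02d", seq_len(spec$n_arrhythmic)),
      feature_class = cls, cohort = NA_character_, type = "walk",
      peak_day = NA_real_, width_days = NA_real_, peaks_per_year = NA_integer_,
      baseline = 0, amp_schedule = I(as.list(amp)))
  }
  do.call(rbind, rows)
}

#' Redundancy configuration for the synthetic function map
#'
#' @param multi_fraction fraction of functions comprising >= 2 gene
#'   clusters, in [0, 1].
#' @param switching_fraction fraction of the multi-cluster functions whose
#'   dominant member switches between years, in [0, 1]; the remainder are
#'   multi-covarying (members grow concurrently).
#' @param members_per_multi gene clusters per multi-cluster function.
#' @export
redundancyConfig <- function(multi_fraction = 0.5, switching_fraction = 0.5,
                             members_per_multi = 3L) {
  if (multi_fraction < 0 || multi_fraction > 1)
    stop("multi_fraction must be in [0, 1]")
  if (switching_fraction < 0 || switching_fraction > 1)
    stop("switching_fraction must be in [0, 1]")
  if (members_per_multi < 2) stop("members_per_multi must be >= 2")
  list(multi_fraction = multi_fraction,
       switching_fraction = switching_fraction,
       members_per_multi = as.integer(members_per_multi))
}

#' Generate a gene-cluster to function map with planted redundancy classes
#'
#' Functions are assembled from the supplied gene-cluster IDs in order:
#' multi-cluster functions take \code{members_per_multi} consecutive IDs,
#' single-cluster functions take one. Each gene cluster maps to at most one
#' function; leftover IDs remain unmapped (reported via the
#' \code{"unmapped"} attribute). Annotation sources cycle through CAZy,
#' KEGG, PFAM (the priority order used when grouping gene clusters into
#' functional clusters).
#'
#' @param gene_ids unique gene-cluster IDs.
#' @param config a \code{\link{redundancyConfig}}.
#' @param n_functions number of functions to create; default packs as many
#'   as the IDs allow at the configured multi fraction.
#' @param prefix function ID prefix.
#' @return data.frame (gene_id, function_id, source) with attribute
#'   \code{"classes"}: data.frame (function_id, redundancy_class) where
#'   redundancy_class is single, multi-covarying or multi-switching.
#' @export
generateFunctionMap <- function(gene_ids, config = redundancyConfig(),
                                n_functions = NULL, prefix = "F") {
  if (anyDuplicated(gene_ids)) stop("gene feature IDs must be unique")
  m <- config$members_per_multi
  if (is.null(n_functions)) {
    # largest n with round(mf*n)*m + (n - round(mf*n)) <= length(gene_ids)
    n_functions <- 0L
    while (TRUE) {
      nm <- round(config$multi_fraction * (n_functions + 1L))
      need <- nm * m + (n_functions + 1L - nm)
      if (need > length(gene_ids)) break
      n_functions <- n_functions + 1L
    }
  }
  if (n_functions < 1) stop("not enough gene clusters for one function")
  n_multi <- round(config$multi_fraction * n_functions)
  n_switch <- round(config$switching_fraction * n_multi)
  sizes <- c(rep(m, n_multi), rep(1L, n_functions - n_multi))
  if (sum(sizes) > length(gene_ids))
    stop("not enough gene clusters: need ", sum(sizes), ", have ",
         length(gene_ids))
  classes <- c(rep("multi-switching", n_switch),
               rep("multi-covarying", n_multi - n_switch),
               rep("single", n_functions - n_multi))
  fid <- sprintf("%s%03d", prefix, seq_len(n_functions))
  src <- rep(c("CAZy", "KEGG", "PFAM"), length.out = n_functions)
  map <- data.frame(
    gene_id = gene_ids[seq_len(sum(sizes))],
    function_id = rep(fid, times = sizes),
    source = rep(src, times = sizes))
  attr(map, "classes") <- data.frame(function_id = fid,
                                     redundancy_class = classes)
  attr(map, "unmapped") <- setdiff(gene_ids, map$gene_id)
  map
}

#' Simulate a complete seasonal community with planted redundancy structure
#'
#' End-to-end generator: timeline, environment, community counts and a
#' gene-cluster to function map whose redundancy classes are realised in
#' the latent series. Members of multi-covarying functions share the cohort
#' pulse but one member keeps a year-round baseline, so within-function
#' Shannon diversity rises with function abundance; members of
#' multi-switching functions get rotating per-year amplitude schedules, so
#' a different member dominates each year.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param redundancy a \code{\link{redundancyConfig}}; the map is planted
#'   per cohort so that every function's members share one seasonal pulse.
#' @return list: \code{se} (SeasonalExperiment of ASVs and gene clusters,
#'   environment in colData), \code{timeline}, \code{environment},
#'   \code{function_map} (with \code{"classes"} attribute),
#'   \code{ground_truth}.
#' @export
simulateSeasonalCommunity <- function(spec = syntheticSpec(),
                                      redundancy = redundancyConfig()) {
  tl <- generateTimeline(spec)
  env <- generateEnvironment(tl)
  fp <- .defaultFeatureParams(spec)

  maps <- list(); cls <- list()
  for (co in spec$cohorts) {
    gid <- fp$feature_id[fp$feature_class == "gene_cluster" &
                           !is.na(fp$cohort) & fp$cohort == co$name]
    if (length(gid) == 0) next
    map <- generateFunctionMap(gid, redundancy,
                               prefix = paste0("F", co$name, "_"))
    maps[[co$name]] <- map
    cls[[co$name]] <- attr(map, "classes")
  }
  function_map <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
  classes <- do.call(rbind, c(cls, list(make.row.names = FALSE)))
  attr(function_map, "classes") <- classes

  # realise redundancy classes in the latent parameters of member genes
  for (f in classes$function_id) {
    members <- function_map$gene_id[function_map$function_id == f]
    rc <- classes$redundancy_class[classes$function_id == f]
    idx <- match(members, fp$feature_id)
    if (rc == "multi-covarying") {
      # anchor member persists year-round; the rest pulse with the cohort,
      # so member evenness (and Shannon diversity) peaks with abundance
      base_amp <- mean(unlist(fp$amp_schedule[idx]))
      fp$amp_schedule[idx] <- as.list(rep(base_amp, length(idx)))
      fp$baseline[idx[1]] <- 0.35 * base_amp
      fp$amp_schedule[[idx[1]]] <- 0.65 * base_amp
    } else if (rc == "multi-switching") {
      base_amp <- mean(unlist(fp$amp_schedule[idx]))
      for (k in seq_along(idx)) {
        sched <- rep(0.15 * base_amp, spec$n_years)
        dominant_years <- which((seq_len(spec$n_years) - 1L) %%
                                  length(idx) == (k - 1L))
        sched[dominant_years] <- 2 * base_amp
        fp$amp_schedule[[idx[k]]] <- sched
      }
    }
  }

  com <- generateCommunity(tl, spec, feature_params = fp, env = env)
  gt <- com$ground_truth
  fcls <- classes
  fcls$cohort <- sub("^F(.*)_[0-9]+$", "\\1", fcls$function_id)
  list(se = com$se, timeline = tl, environment = env,
       function_map = function_map, function_classes = fcls,
       ground_truth = gt)
}
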