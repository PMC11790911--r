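test_that("timeline spacing, span and determinism follow the spec", {
  spec <- syntheticSpec(n_years = 4, interval_days = 14, jitter_days = 0,
                        seed = 1)
  tl <- generateTimeline(spec)
  expect_equal(nrow(tl), 105)                       # 1460/14 + 1
  expect_true(all(diff(tl$day_offset) == 14))
  expect_equal(max(tl$day_offset), 1456)

  specj <- syntheticSpec(jitter_days = 3, seed = 1)
  expect_identical(generateTimeline(specj), generateTimeline(specj))
  tj <- generateTimeline(specj)
  expect_true(all(diff(tj$day_offset) > 0))
  expect_true(all(abs(diff(tj$day_offset) - 14) <= 6))

  one <- generateTimeline(syntheticSpec(n_years = 1, seed = 2))
  expect_true(all(format(one$date, "%Y") == "2016"))
})

test_that("invalid synthetic specs fail naming the offending field", {
  expect_error(syntheticSpec(n_years = 0), "n_years")
  expect_error(syntheticSpec(jitter_days = 7, interval_days = 14),
               "jitter_days")
  expect_error(syntheticSpec(noise_dispersion = -1), "noise_dispersion")
  expect_error(cohortSpec("X", peak_day = 400), "peak_day")
  expect_error(cohortSpec("X", width_days = 0), "width_days")
})

test_that("environment covariates are seasonally phased as constructed", {
  tl <- generateTimeline(syntheticSpec(seed = 1))
  env <- generateEnvironment(tl)
  expect_equal(nrow(env), nrow(tl))
  # MLD anti-phase to temperature
  expect_lt(cor(env$temperature, env$MLD), 0)
  # polar-night PAR clipped to zero
  winter <- tl$day_of_year < 40 | tl$day_of_year > 325
  expect_true(any(env$PAR[winter] == 0))
  expect_equal(min(env$PAR), 0)
  # zero amplitude gives a constant series at baseline
  ph <- defaultEnvironmentPhases()
  ph$temperature$amplitude <- 0
  env0 <- generateEnvironment(tl, ph)
  expect_true(all(env0$temperature == ph$temperature$baseline))
  # unknown covariate key
  expect_error(generateEnvironment(tl, list(sunspots = ph$temperature)),
               "unknown covariate")
})

test_that("community tables are closed, deterministic and complete", {
  spec <- syntheticSpec(seed = 3)
  tl <- generateTimeline(spec)
  com <- generateCommunity(tl, spec)
  ra <- relAbundance(com$se)
  expect_true(all(abs(colSums(ra) - 1) < 1e-9))
  com2 <- generateCommunity(tl, spec)
  expect_identical(seasonCounts(com$se), seasonCounts(com2$se))
  # every generated feature appears exactly once in the ground truth
  expect_setequal(com$ground_truth$feature_id, rownames(com$se))
  expect_false(anyDuplicated(com$ground_truth$feature_id) > 0)
})

test_that("noiseless cohort features peak at the planted day every year", {
  co <- list(cohortSpec("A", n_asv_prok = 1, n_asv_euk = 0, n_gene = 0,
                        peak_day = 150))
  spec <- syntheticSpec(cohorts = co, n_arrhythmic = 3,
                        noise_dispersion = 0, jitter_days = 0, seed = 1)
  tl <- generateTimeline(spec)
  com <- generateCommunity(tl, spec)
  x <- relAbundance(com$se)["pro_A_01", ]
  # the pulse is flat near its maximum, so compositional closure against
  # the co-simulated features can move the argmax one sample past the
  # nearest grid point: bound = 1.5 sampling intervals in offset space
  for (y in 1:4) {
    sel <- which(tl$year_index == y)
    pk <- tl$day_offset[sel[which.max(x[sel])]]
    expect_lte(abs(pk - (150 + 365 * (y - 1))), 1.5 * spec$interval_days)
  }
})

test_that("function maps plant the configured redundancy structure", {
  ids <- sprintf("g%02d", 1:25)
  map <- generateFunctionMap(ids, redundancyConfig(multi_fraction = 0.5),
                             n_functions = 10)
  members <- table(map$function_id)
  expect_equal(length(members), 10)
  expect_equal(sum(members >= 2), 5)
  expect_true(all(table(map$gene_id) == 1))

  all_single <- generateFunctionMap(ids, redundancyConfig(multi_fraction = 0),
                                    n_functions = 10)
  expect_true(all(table(all_single$function_id) == 1))

  expect_error(redundancyConfig(multi_fraction = 1.5), "multi_fraction")

  # map round-trips through the TSV writer/reader unchanged
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(map, f, sep = "\t", quote = FALSE)
  back <- as.data.frame(data.table::fread(f, sep = "\t"))
  expect_equal(back, as.data.frame(map)[names(back)], ignore_attr = TRUE)
})

test_that("the end-to-end simulator is seed-deterministic", {
  a <- simulateSeasonalCommunity(syntheticSpec(seed = 7))
  b <- simulateSeasonalCommunity(syntheticSpec(seed = 7))
  expect_identical(seasonCounts(a$se), seasonCounts(b$se))
  expect_identical(a$function_map, b$function_map)
  c <- simulateSeasonalCommunity(syntheticSpec(seed = 8))
  expect_false(identical(seasonCounts(a$se), seasonCounts(c$se)))
})
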