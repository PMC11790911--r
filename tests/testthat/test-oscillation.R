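test_that("regularisation interpolates linearly without extrapolating", {
  days <- seq(0, 140, by = 14)
  const <- regularizeSeries(rep(3, length(days)), days, grid_days = 7)
  expect_true(all(const$value == 3))
  expect_equal(range(const$day), c(0, 140))

  two <- regularizeSeries(c(0, 14, 0, 14, 0, 14, 0, 14),
                          c(0, 14, 28, 42, 56, 70, 84, 98), grid_days = 7)
  expect_equal(two$value[two$day == 7], 7)          # midpoint linearity
  expect_equal(two$value[1], 0)                     # endpoints preserved
  expect_equal(two$value[length(two$value)], 14)

  expect_error(regularizeSeries(1:5, c(0, 7, 14, 21, 28)), "8")
  # interior missing values are interpolated across
  v <- c(0, 2, NA, 6, 8, 10, 12, 14, 16)
  g <- regularizeSeries(v, seq(0, 112, by = 14), grid_days = 14)
  expect_equal(g$value[3], 4)
})

test_that("Fourier reconstruction keeps the dominant components exactly", {
  t <- 0:99
  x <- 2 + 3 * cos(2 * pi * 4 * t / 100)
  rec <- fourierReconstruct(x, 1)
  expect_equal(rec$reconstructed, x, tolerance = 1e-9)
  expect_equal(rec$spectrum$freq_index[rec$spectrum$retained], 4)
  expect_equal(rec$spectrum$amplitude[4], 3, tolerance = 1e-9)

  const <- fourierReconstruct(rep(5, 64), 1)
  expect_equal(const$reconstructed, rep(5, 64), tolerance = 1e-12)

  expect_error(fourierReconstruct(x, 51), "exceeds")
})

test_that("discarded energy obeys Parseval and shrinks with components", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.7), 128)) + sin(2 * pi * (1:128) / 32)
  energy <- function(v) sum((v - mean(v))^2)
  errs <- sapply(1:10, function(k) {
    rec <- fourierReconstruct(x, k)$reconstructed
    expect_equal(energy(x), energy(rec) + sum((x - rec)^2),
                 tolerance = 1e-9 * energy(x))
    sum((x - rec)^2)
  })
  expect_true(all(diff(errs) <= 1e-9))              # nonincreasing error
})

test_that("annual oscillation counts match planted sinusoid frequencies", {
  gd <- grid_dates(4)
  t <- as.numeric(gd - gd[1])
  annual <- sin(2 * pi * t / 365)
  c1 <- countAnnualOscillations(annual, gd)
  expect_true(all(c1$counts == 1))
  expect_equal(c1$consensus, 1L)

  semi <- sin(4 * pi * t / 365)
  c2 <- countAnnualOscillations(semi, gd)
  expect_equal(c2$consensus, 2L)

  flat <- countAnnualOscillations(rep(2, length(t)), gd)
  expect_equal(flat$consensus, 0L)
  expect_true(all(flat$counts == 0))
})

test_that("consensus is the modal count with ties toward fewer peaks", {
  # internal helper exercised through full profiles: build a signal with
  # per-year counts 1,1,2,2 -> consensus must be 1
  expect_equal(seasonwheel:::.modalCount(c(1, 1, 2, 2)), 1L)
  expect_equal(seasonwheel:::.modalCount(c(2, 2, 1, 2)), 2L)
  expect_equal(seasonwheel:::.modalCount(integer(0)), 0L)
})

test_that("peak prominence filters shallow ripples", {
  t <- seq(0, 1459, by = 7)
  x <- cos(2 * pi * t / 365) + 0.04 * cos(2 * pi * t / 36.5)
  gd <- as.Date("2016-01-01") + t
  cnt <- countAnnualOscillations(x, gd, prominence_frac = 0.1)
  expect_equal(cnt$consensus, 1L)                   # ripples < 10% of range
  cnt2 <- countAnnualOscillations(x, gd, prominence_frac = 0.01)
  expect_gt(cnt2$consensus, 1L)                     # now ripples count
})

test_that("PRSA reproduces slope and period of structured signals", {
  expect_error(prsa(rep(1, 50), 5), "anchors")

  line <- 0.5 * (1:100)
  p <- prsa(line, 10)
  expect_equal(diff(p), rep(0.5, 20), tolerance = 1e-12)

  x <- sin(2 * pi * (1:400) / 50)
  pp <- prsa(x, 100)
  # periodic with the source period: shifted curve matches itself
  expect_gt(cor(pp[1:(201 - 50)], pp[51:201]), 0.99)
})

test_that("whole-experiment profiles classify planted pulses perfectly", {
  spec <- syntheticSpec(noise_dispersion = 0, seed = 2)
  com <- generateCommunity(generateTimeline(spec), spec)
  osc <- oscillationProfiles(com$se)
  gt <- com$ground_truth
  pulses <- gt$feature_id[!is.na(gt$planted_oscillations)]
  expect_true(all(consensusOscillation(osc)[pulses] == 1))
  expect_setequal(annualOscillators(osc)[annualOscillators(osc) %in% pulses],
                  pulses)
  # per-year peak days sit near the planted peak day
  pd <- peakDays(osc)[pulses, ]
  planted <- gt$peak_day[match(pulses, gt$feature_id)]
  err <- abs(pd - planted)
  expect_true(all(pmin(err, 365 - err) <= 21, na.rm = TRUE))
  # processing order does not matter
  osc_rev <- oscillationProfiles(
    relAbundance(com$se)[rev(rownames(com$se)), ],
    dates = sampleDates(com$se))
  expect_equal(consensusOscillation(osc_rev)[pulses],
               consensusOscillation(osc)[pulses])
})
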