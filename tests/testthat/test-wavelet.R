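params_fast <- waveletParams(n_permutations = 199)

test_that("period grid is geometric, spans 2-12 and contains 12 exactly", {
  p <- waveletParams()
  months <- .mon(37)
  s <- EntitySeries("e", "DOM", "1m", months, 100 + sin(1:37))
  d <- suppressWarnings(cwtMorlet(s, p))
  per <- wavePeriods(d)
  expect_true(12 %in% per)
  expect_gte(min(per), 2)
  expect_lte(max(per), 12)
  expect_equal(diff(log2(per)), rep(1 / 20, length(per) - 1))
})

test_that("transform matches the direct-summation oracle", {
  set.seed(42)
  months <- .mon(37)
  v <- pmax(100 + rnorm(37, 0, 20), 0)
  s <- EntitySeries("e", "DOM", "1m", months, v)
  d <- suppressWarnings(cwtMorlet(s, waveletParams()))
  xs <- (v - mean(v)) / sd(v)
  Wo <- oracleCwt(xs, wavePeriods(d))
  expect_lt(max(abs(Mod(Wo)^2 - wavePower(d))) / max(wavePower(d)), 1e-9)
})

test_that("pure cosines recover their period; constants are rejected", {
  months <- .mon(37)
  for (per in c(6, 12)) {
    v <- 100 + 50 * cos(2 * pi * (0:36) / per)
    d <- suppressWarnings(cwtMorlet(EntitySeries("e", "DOM", "1m", months, v)))
    expect_lte(abs(log2(dominantPeriod(d) / per)), 1 / 20 + 1e-9)
  }
  expect_error(cwtMorlet(EntitySeries("e", "DOM", "1m", months,
                                      rep(5, 37))), "constant")
})

test_that("permutation p-values are bounded and saturate at zero power", {
  months <- .mon(37)
  set.seed(1)
  s <- EntitySeries("e", "DOM", "1m", months, pmax(100 + rnorm(37, 0, 10), 0))
  d <- cwtMorlet(s, params_fast)
  d@coefficients[1, 1] <- 0 + 0i
  d2 <- permutationSignificance(s, params_fast, decomp = d, seed = 1)
  expect_equal(d2@pvalues[1, 1], 1)
  expect_true(all(d2@pvalues >= 1 / 200 & d2@pvalues <= 1))
})

test_that("a strong 12-month cosine is significant at the dominant period", {
  months <- .mon(37)
  set.seed(2)
  v <- pmax(100 + 50 * cos(2 * pi * (0:36) / 12) + rnorm(37, 0, 5), 0)
  s <- EntitySeries("e", "DOM", "1m", months, v)
  p <- waveletParams()  # 1000 permutations
  d <- permutationSignificance(s, p, seed = 3)
  j <- which.max(medianPower(d))
  expect_lte(medianPValues(d)[j], 0.01)
})

test_that("classification applies the RSD gate and the 12-month band", {
  months <- .mon(37)
  set.seed(4)
  base_sig <- 50 * cos(2 * pi * (0:36) / 12) + rnorm(37, 0, 5)
  s_hi <- EntitySeries("e", "DOM", "1m", months, pmax(100 + base_sig, 0))
  cl <- classifySeasonality(s_hi, params_fast, seed = 5)
  expect_true(cl@passedRSD)
  expect_true(cl@isSeasonal)
  expect_equal(cl@season, "summer_stratified")

  # same signal on an inflated baseline: RSD ~ 10%, gate fails
  s_lo <- EntitySeries("e", "DOM", "1m", months, pmax(360 + base_sig, 0))
  cl2 <- classifySeasonality(s_lo, params_fast, seed = 5)
  expect_false(cl2@passedRSD)
  expect_false(cl2@isSeasonal)
  expect_true(is.na(cl2@peakMonth))
})

test_that("wavelet power is invariant to positive affine transforms", {
  months <- .mon(37)
  set.seed(6)
  v <- pmax(100 + rnorm(37, 0, 15), 0)
  d1 <- suppressWarnings(cwtMorlet(EntitySeries("e", "DOM", "1m", months, v)))
  d2 <- suppressWarnings(cwtMorlet(EntitySeries("e", "DOM", "1m", months,
                                                3 * v + 7)))
  expect_equal(wavePower(d1), wavePower(d2), tolerance = 1e-12)
  # the RSD gate is not invariant
  expect_false(isTRUE(all.equal(seriesRSD(v), seriesRSD(3 * v + 7))))
})

test_that("total power approximates series variance (Parseval)", {
  n <- 256
  months <- .mon(n, "2000-01-01")
  v <- 100 + 30 * cos(2 * pi * (0:(n - 1)) / 8)
  p <- waveletParams()
  d <- cwtMorlet(EntitySeries("e", "DOM", "1m", months, v), p)
  scales <- wavePeriods(d) / (4 * pi / (6 + sqrt(38)))
  tot <- (1 / 20) / (0.776 * n) * sum(sweep(wavePower(d), 1, scales, "/"))
  expect_equal(tot, 1, tolerance = 0.1)  # standardized variance is 1
})

test_that("12-month band reconstruction preserves phase and shape", {
  months <- .mon(37)
  cal <- as.POSIXlt(months)$mon + 1
  phase <- which(cal == 7)[1] - 1
  v <- 100 + 50 * cos(2 * pi * (0:36 - phase) / 12)
  d <- suppressWarnings(cwtMorlet(EntitySeries("e", "DOM", "1m", months, v)))
  rp <- reconstructBand(d, band = 12)
  expect_equal(rp$peak_month, 7L)
  expect_gt(cor(rp$reconstruction, v), 0.95)
  expect_error(reconstructBand(d, band = 100), "outside")
})

test_that("partial-year signals score lower median power than full ones", {
  wins <- 0
  for (seed in 1:10) {
    spec_full <- cohortSpec(1, fraction_seasonal = 1, amplitude = 40,
                            baseline = 100, noise_sd = 10, seed = seed)
    spec_part <- cohortSpec(1, fraction_seasonal = 1, amplitude = 40,
                            baseline = 100, noise_sd = 10, seed = seed,
                            partial_year_flags = TRUE)
    mp <- function(sp) {
      d <- suppressWarnings(cwtMorlet(generateEntitySeries(sp, 1)))
      max(medianPower(d))
    }
    if (mp(spec_full) > mp(spec_part)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("months map onto the hydrographic seasons", {
  expect_equal(seasonOfMonth(2), "winter_mixed")
  expect_equal(seasonOfMonth(7), "summer_stratified")
  expect_equal(seasonOfMonth(4), "spring_transition")
  expect_equal(seasonOfMonth(11), "fall_transition")
  custom <- defaultSeasonMap()
  custom[4] <- "winter_mixed"
  expect_equal(seasonOfMonth(4, custom), "winter_mixed")
  expect_error(seasonOfMonth(13), "1..12")
})

test_that("white noise is rarely classified seasonal (light calibration)", {
  months <- .mon(37)
  hits <- 0
  for (r in 1:30) {
    set.seed(100 + r)
    v <- pmax(1000 + rnorm(37, 0, 300), 0)
    cl <- classifySeasonality(EntitySeries("w", "DOM", "1m", months, v),
                              params_fast, seed = 500 + r)
    hits <- hits + cl@isSeasonal
  }
  expect_lte(hits / 30, 0.1)
})
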