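test_that("gaussian shape screen scores clean, flat and multimodal peaks", {
  t <- seq(0, 20, length.out = 11)
  y <- 5 + 50 * exp(-(t - 10)^2 / (2 * 3^2))
  res <- gaussianShapeScreen(t, y)
  expect_equal(res$correlation, 1, tolerance = 1e-6)
  expect_true(res$pass)

  flat <- gaussianShapeScreen(t, rep(7, 11))
  expect_false(flat$pass)
  expect_true(is.na(flat$correlation))

  expect_error(gaussianShapeScreen(1:4, c(1, 2, 3, 2)), "at least 5")
  expect_error(gaussianShapeScreen(t, y - 100), ">= 0")
})

test_that("gaussian fit of a two-peaked profile matches the grid oracle", {
  t <- seq(0, 20, length.out = 21)
  y <- 100 * exp(-(t - 6)^2 / (2 * 2^2)) + 80 * exp(-(t - 14)^2 / (2 * 2^2))
  res <- gaussianShapeScreen(t, y)
  r_oracle <- oracleGaussianBestCor(t, y)
  expect_equal(res$correlation, r_oracle, tolerance = 1e-3)
})

test_that("width filter is strict at the boundary", {
  ft <- toyFeatureTable(matrix(100, 6, 3),
                        peak_width = c(14.9, 15.0, 5, 5, 16, 3))
  res <- filterByWidth(ft)
  expect_setequal(keptIds(res), c("F01", "F03", "F04", "F06"))
  expect_equal(res$report@nOut, 4L)

  ft5 <- toyFeatureTable(matrix(100, 4, 3), peak_width = 5)
  expect_equal(filterByWidth(ft5)$report@nOut, 4L)

  ftNA <- toyFeatureTable(matrix(100, 2, 3), peak_width = c(5, NA))
  expect_error(filterByWidth(ftNA), "missing")
})

test_that("annotation filter removes isotopologues and adducts", {
  ft <- toyFeatureTable(matrix(100, 10, 3),
                        isotope = c(rep(TRUE, 2), rep(FALSE, 8)),
                        adduct = c(rep(FALSE, 9), TRUE))
  res <- filterByAnnotation(ft)
  expect_equal(res$report@nOut, 7L)
  expect_false(any(featureInfo(res$table)$isotope_flag |
                     featureInfo(res$table)$adduct_flag))
})

test_that("blank filter removes blank-dominated features in any configuration", {
  set.seed(11)
  S <- matrix(runif(40, 50, 500), 10, 4)
  B <- matrix(0, 10, 2)
  B[1, ] <- rowMeans(S)[1] * 2  # d < 0 for F01
  ft <- toyFeatureTable(S, B)
  for (tq in c(0.1, 0.25, 0.5))
    for (cuts in list(c(0.2, 0.4, 0.6, 0.8), c(0.5), c(0.25, 0.5, 0.75)))
      expect_false("F01" %in% keptIds(filterByBlank(ft, cuts, tq)))

  # all blanks zero, all samples positive: everything kept
  res <- filterByBlank(toyFeatureTable(S, matrix(0, 10, 2)))
  expect_equal(res$report@nOut, 10L)
})

test_that("blank filter reproduces the worked 10-feature hand computation", {
  ft <- workedBlankFixture()
  # independent hand computation of bins, thresholds and decisions
  X <- intensityMatrix(ft)
  L <- log10(X + 1)
  m_all <- rowMeans(L)
  d <- rowMeans(L[, 1:4]) - rowMeans(L[, 5:6])
  cuts <- quantile(m_all, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  bin <- findInterval(m_all, cuts) + 1
  kept_oracle <- logical(10)
  for (b in unique(bin)) {
    ib <- bin == b
    neg <- d[ib & d < 0]
    Tb <- if (length(neg)) quantile(neg, 0.25, type = 7, names = FALSE) else 0
    kept_oracle[ib] <- d[ib] > abs(Tb)
  }
  res <- filterByBlank(ft)
  expect_identical(keptIds(res), rownames(X)[kept_oracle])
  # frozen expected set (verified by hand: F07 has d = +0.082 but falls to
  # the bin-1 threshold |T| = 0.312 set by F10)
  expect_identical(keptIds(res), c("F01", "F03", "F05", "F06", "F09"))
})

test_that("blank filter decisions are scale-invariant (pseudocount 0)", {
  set.seed(4)
  S <- matrix(runif(48, 10, 1000), 12, 4)
  B <- matrix(runif(24, 1, 800), 12, 2)
  ft1 <- toyFeatureTable(S, B)
  ft2 <- toyFeatureTable(S * 37.5, B * 37.5)
  expect_identical(keptIds(filterByBlank(ft1, pseudocount = 0)),
                   keptIds(filterByBlank(ft2, pseudocount = 0)))
})

test_that("detection filter is strict and ignores blanks and pools", {
  S <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0),   # 50% exactly -> removed
             c(1, 1, 1, 1, 1, 1, 1, 1),   # all -> kept
             c(1, 1, 1, 1, 1, 0, 0, 0))   # 5/8 -> kept
  ft <- toyFeatureTable(S * 100, B = matrix(0, 3, 2))
  res <- filterByDetection(ft)
  expect_setequal(keptIds(res), c("F02", "F03"))
})

test_that("RT consistency filter is strict at 5 s", {
  ft <- toyFeatureTable(matrix(100, 7, 3),
                        median_rt_range = c(4.9, 5.0, 0, 6, 2, 5.1, 1))
  res <- filterByRTRange(ft)
  expect_setequal(keptIds(res), c("F01", "F03", "F05", "F07"))
})

test_that("pool RSD uses the first pool per batch and spares undetected", {
  S <- matrix(100, 3, 4)
  # 5 batches, two pools each; second pool of each batch is a decoy that
  # must not enter the RSD
  P <- matrix(0, 3, 10)
  first <- seq(1, 10, by = 2)
  P[1, first] <- c(100, 100, 100, 100, 150)  # RSD 20.33% -> removed
  P[2, first] <- 200                          # RSD 0 -> kept
  P[1, -first] <- 1e6
  P[2, -first] <- 1e6
  # feature 3 absent from every pool -> kept unconditionally
  ft <- toyFeatureTable(S, P = P,
                        pool_batches = rep(paste0("B", 1:5), each = 2))
  res <- filterByPoolRSD(ft)
  expect_setequal(keptIds(res), c("F02", "F03"))
  rsd1 <- 100 * sd(c(100, 100, 100, 100, 150)) / mean(c(100, 100, 100, 100, 150))
  expect_equal(rsd1, 20.32789, tolerance = 1e-5)
})

test_that("cascade stage counts reconcile and remove true contaminants", {
  spec <- cohortSpec(n_entities = 40, fraction_seasonal = 0.5, seed = 9)
  ft <- generateFeatureTable(spec, blank_contaminant_fraction = 0.25)
  out <- runFilterCascade(ft)
  reps <- out$reports
  for (i in seq_len(length(reps) - 1))
    expect_equal(reps[[i]]@nOut, reps[[i + 1]]@nIn)
  expect_equal(reps[[length(reps)]]@nOut,
               nrow(featureInfo(out$table)))
  gt <- S4Vectors::metadata(ft)$ground_truth
  contaminants <- gt$feature_id[gt$contaminant]
  blank_dec <- reps$blank@decisions
  expect_true(all(!blank_dec$kept[blank_dec$feature_id %in% contaminants]))
})
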