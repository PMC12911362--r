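# shared fixtures and independent oracles

.mon <- function(n = 37, start = "2016-07-01") {
  seq(as.Date(start), by = "month", length.out = n)
}

# minimal feature table with explicit intensities
toyFeatureTable <- function(S, B = NULL, P = NULL,
                            peak_width = 5, median_rt_range = 1,
                            isotope = FALSE, adduct = FALSE,
                            pool_batches = NULL) {
  X <- S
  inj <- data.frame(injection_id = paste0("s", seq_len(ncol(S))),
                    kind = "sample", batch = "B1",
                    stringsAsFactors = FALSE)
  if (!is.null(B)) {
    X <- cbind(X, B)
    inj <- rbind(inj, data.frame(injection_id = paste0("b", seq_len(ncol(B))),
                                 kind = "process_blank", batch = "B1"))
  }
  if (!is.null(P)) {
    X <- cbind(X, P)
    bt <- if (is.null(pool_batches)) paste0("B", seq_len(ncol(P)))
          else pool_batches
    inj <- rbind(inj, data.frame(injection_id = paste0("p", seq_len(ncol(P))),
                                 kind = "pool", batch = bt))
  }
  n <- nrow(X)
  feats <- data.frame(
    feature_id = sprintf("F%02d", seq_len(n)), mz = seq_len(n) + 100,
    rt = seq_len(n) * 10,
    peak_width = rep_len(peak_width, n),
    median_rt_range = rep_len(median_rt_range, n),
    isotope_flag = rep_len(isotope, n), adduct_flag = rep_len(adduct, n),
    stringsAsFactors = FALSE)
  FeatureTable(X, feats, inj)
}

keptIds <- function(res) featureInfo(res$table)$feature_id

# O(N^2) direct-summation evaluation of the frequency-domain Morlet
# transform definition (no fft calls): independent oracle for cwtMorlet
oracleCwt <- function(xs, periods, omega0 = 6, dt = 1) {
  n <- length(xs)
  npad <- 2^ceiling(log2(n))
  xp <- c(xs, rep(0, npad - n))
  k <- 0:(npad - 1)
  xhat <- vapply(k, function(kk)
    sum(xp * exp(-2i * pi * kk * (0:(npad - 1)) / npad)), 0 + 0i)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  W <- matrix(0 + 0i, length(periods), n)
  for (j in seq_along(periods)) {
    s <- periods[j] / ff
    dg <- ifelse(omega > 0,
                 sqrt(2 * pi * s / dt) * pi^(-0.25) *
                   exp(-(s * omega - omega0)^2 / 2), 0)
    for (tt in seq_len(n))
      W[j, tt] <- sum(xhat * dg * exp(2i * pi * k * (tt - 1) / npad)) / npad
  }
  W
}

# dense grid-search oracle for the best single-Gaussian profile fit:
# maximises the correlation between observed and fitted (equivalently,
# minimises SSE with analytic height/offset)
oracleGaussianBestCor <- function(time, y, n_mu = 300, n_sg = 200) {
  rng <- diff(range(time))
  best <- -Inf
  for (mu in seq(min(time), max(time), length.out = n_mu)) {
    for (sg in exp(seq(log(rng * 0.01), log(rng), length.out = n_sg))) {
      g <- exp(-(time - mu)^2 / (2 * sg^2))
      if (sd(g) < 1e-12) next
      co <- coef(lm.fit(cbind(1, g), y))
      r <- suppressWarnings(cor(y, co[1] + co[2] * g))
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}

# hand-computable worked fixture for the blank filter
workedBlankFixture <- function() {
  path <- system.file("extdata", "blank_filter_worked_example.tsv",
                      package = "DOMwave")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -1])
  rownames(X) <- tab$feature_id
  inj <- data.frame(
    injection_id = colnames(X),
    kind = c(rep("sample", 4), rep("process_blank", 2)), batch = "B1",
    stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = tab$feature_id, mz = 1:10, rt = 1:10,
                      peak_width = 5, median_rt_range = 1,
                      isotope_flag = FALSE, adduct_flag = FALSE,
                      stringsAsFactors = FALSE)
  FeatureTable(X, feats, inj)
}
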