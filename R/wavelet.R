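#' @include AllClasses.R timeseries.R
NULL

# Morlet reconstruction constants (omega0 = 6)
.C_DELTA <- 0.776
.PSI0 <- pi^(-0.25)

.nextPow2 <- function(n) 2^ceiling(log2(n))

.morletFourierFactor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

# geometric period grid anchored at upper_period so the 12-month bin is exact
.morletPeriods <- function(params) {
  n_steps <- floor(log2(params@upperPeriod / params@lowerPeriod) *
                     params@suboctaves)
  params@upperPeriod * 2^(-(n_steps:0) / params@suboctaves)
}

# frequency-domain Morlet daughters, one row per scale (Torrence & Compo)
.morletDaughters <- function(npad, periods, omega0, dt) {
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  scales <- periods / .morletFourierFactor(omega0)
  D <- matrix(0, length(scales), npad)
  pos <- omega > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    D[j, pos] <- sqrt(2 * pi * s / dt) * .PSI0 *
      exp(-(s * omega[pos] - omega0)^2 / 2)
  }
  D
}

.standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("constant series: cannot standardize for wavelet analysis")
  list(x = (x - mean(x)) / s, mean = mean(x), sd = s)
}

# complex CWT coefficients of one standardized series, period x time
.cwtCoefficients <- function(xs, periods, omega0, dt) {
  n <- length(xs)
  npad <- .nextPow2(n)
  xhat <- stats::fft(c(xs, rep(0, npad - n)))
  D <- .morletDaughters(npad, periods, omega0, dt)
  W <- matrix(0 + 0i, length(periods), n)
  for (j in seq_along(periods))
    W[j, ] <- stats::fft(xhat * D[j, ], inverse = TRUE)[seq_len(n)] / npad
  W
}

#' Morlet continuous wavelet transform of an entity series
#'
#' Decomposes a monthly series into period x time wavelet power following
#' Torrence & Compo: the series is standardized to zero mean and unit
#' variance, zero-padded to the next power of two, and convolved in the
#' frequency domain with Morlet daughters (omega0 = 6 by default) on a
#' geometric period grid from \code{lower_period} to \code{upper_period}
#' months at \code{2^(1/suboctaves)} spacing. Power is |W|^2. Edge effects
#' are retained (no cone-of-influence masking) so per-period medians use
#' all time points; set \code{coi_mask = TRUE} to mask the cone of
#' influence with NA before the medians.
#'
#' @param series an \linkS4class{EntitySeries} (uniform monthly grid; a
#'   warning is given below 2 x upper_period points).
#' @param params a \linkS4class{WaveletParams}.
#' @param coi_mask mask the cone of influence (default FALSE).
#' @return a \linkS4class{WaveletDecomposition} (p-values empty until
#'   \code{\link{permutationSignificance}}).
#' @export
cwtMorlet <- function(series, params = waveletParams(), coi_mask = FALSE) {
  x <- seriesValues(series)
  n <- length(x)
  if (n < 2 * params@upperPeriod)
    warning(sprintf("series has %d points; >= %g recommended for periods up to %g months",
                    n, 2 * params@upperPeriod, params@upperPeriod))
  st <- .standardize(x)
  periods <- .morletPeriods(params)
  W <- .cwtCoefficients(st$x, periods, params@omega0, params@dt)
  P <- Mod(W)^2
  if (coi_mask) {
    # e-folding time sqrt(2)*s from each edge
    scales <- periods / .morletFourierFactor(params@omega0)
    tt <- seq_len(n) - 1
    for (j in seq_along(scales)) {
      coi <- sqrt(2) * scales[j]
      P[j, pmin(tt, n - 1 - tt) < coi] <- NA_real_
    }
  }
  new("WaveletDecomposition", periods = periods, times = seq_len(n) - 1,
      coefficients = W, power = P,
      pvalues = matrix(numeric(0), 0, 0),
      medianPower = apply(P, 1, stats::median, na.rm = TRUE),
      medianP = rep(NA_real_, length(periods)),
      seriesMean = st$mean, seriesSD = st$sd,
      months = seriesMonths(series), params = params)
}

#' White-noise permutation significance for a wavelet decomposition
#'
#' Simulates \code{n_permutations} standardized Gaussian white-noise series
#' of the same length, computes their wavelet power, and assigns each
#' (period, time) cell the p-value
#' \code{(1 + #simulated >= observed) / (1 + n_permutations)}.
#'
#' @param series the \linkS4class{EntitySeries} analysed.
#' @param params a \linkS4class{WaveletParams}.
#' @param decomp optional precomputed \linkS4class{WaveletDecomposition}
#'   for the series (recomputed when NULL).
#' @param seed optional RNG seed for the permutations.
#' @return the decomposition with \code{pvalues} and \code{medianP} filled.
#' @export
permutationSignificance <- function(series, params = waveletParams(),
                                    decomp = NULL, seed = NULL) {
  if (is.null(decomp)) decomp <- cwtMorlet(series, params)
  obs <- Mod(decomp@coefficients)^2
  n <- ncol(obs)
  periods <- decomp@periods
  npad <- .nextPow2(n)
  m <- params@nPermutations
  runPerms <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m)
    Z <- scale(Z)  # per-column standardization, matching the observed series
    Zhat <- stats::mvfft(rbind(Z, matrix(0, npad - n, m)))
    D <- .morletDaughters(npad, periods, params@omega0, params@dt)
    counts <- matrix(0, length(periods), n)
    for (j in seq_along(periods)) {
      Wj <- stats::mvfft(Zhat * D[j, ], inverse = TRUE)[seq_len(n), ,
                                                        drop = FALSE] / npad
      counts[j, ] <- rowSums(Mod(Wj)^2 >= obs[j, ])
    }
    counts
  }
  counts <- if (is.null(seed)) runPerms() else .withSeed(seed, runPerms())
  decomp@pvalues <- (1 + counts) / (1 + m)
  decomp@medianP <- apply(decomp@pvalues, 1, stats::median)
  decomp
}

# Is this period inside the 12-month band? One suboctave step on either
# side of 12: the scale grid oversamples the Morlet's intrinsic period
# resolution (about sqrt(2)/omega0 ~ 24% of the period, i.e. ~7 suboctave
# steps at omega0 = 6, suboctaves = 20), so the bins adjacent to 12 months
# are statistically indistinguishable from a 12-month response.
.inTwelveBand <- function(period, params, band = 12) {
  abs(log2(period / band)) <= 1 / params@suboctaves + 1e-9
}

#' Band-limited wavelet reconstruction and peak month
#'
#' Inverts the transform restricted to the period bins within half a
#' suboctave step of \code{band} months (Torrence & Compo reconstruction,
#' C_delta = 0.776, psi0(0) = pi^(-1/4)), rescaled to the original series
#' units. The peak month is the calendar month maximizing the
#' climatological mean (average over years) of the reconstruction;
#' \code{peak_method = "global_max"} uses the single global maximum
#' instead.
#'
#' @param decomp a \linkS4class{WaveletDecomposition}.
#' @param band band centre in months (default 12).
#' @param peak_method "climatology" (default) or "global_max".
#' @return list with \code{reconstruction} (numeric, original units) and
#'   \code{peak_month} (integer 1-12).
#' @export
reconstructBand <- function(decomp, band = 12,
                            peak_method = c("climatology", "global_max")) {
  peak_method <- match.arg(peak_method)
  params <- decomp@params
  sel <- which(.inTwelveBand(decomp@periods, params, band))
  if (!length(sel))
    stop(sprintf("band %g months is outside the period grid", band))
  scales <- decomp@periods[sel] / .morletFourierFactor(params@omega0)
  dj <- 1 / params@suboctaves
  contrib <- Re(decomp@coefficients[sel, , drop = FALSE]) / sqrt(scales)
  rec_std <- dj * sqrt(params@dt) / (.C_DELTA * .PSI0) * colSums(contrib)
  rec <- decomp@seriesMean + decomp@seriesSD * rec_std
  cal <- as.POSIXlt(decomp@months)$mon + 1L
  peak_month <- if (peak_method == "climatology") {
    clim <- tapply(rec, cal, mean)
    as.integer(names(clim)[which.max(clim)])
  } else cal[which.max(rec)]
  list(reconstruction = rec, peak_month = peak_month)
}

#' Full wavelet reconstruction over all analysed periods
#'
#' @param decomp a \linkS4class{WaveletDecomposition}.
#' @return numeric reconstruction in original series units.
#' @export
reconstructAll <- function(decomp) {
  params <- decomp@params
  scales <- decomp@periods / .morletFourierFactor(params@omega0)
  dj <- 1 / params@suboctaves
  rec_std <- dj * sqrt(params@dt) / (.C_DELTA * .PSI0) *
    colSums(Re(decomp@coefficients) / sqrt(scales))
  decomp@seriesMean + decomp@seriesSD * rec_std
}

#' Map a calendar month to a hydrographic season
#'
#' Default map for the seasonally oligotrophic North Atlantic: Jan-Mar
#' winter mixed, Apr spring transition, May-Oct summer stratified, Nov-Dec
#' fall transition. Fully configurable via \code{season_map}.
#'
#' @param month integer 1-12.
#' @param season_map character vector of length 12 (January first).
#' @return season label.
#' @export
seasonOfMonth <- function(month, season_map = defaultSeasonMap()) {
  if (any(month < 1 | month > 12)) stop("month must be in 1..12")
  if (length(season_map) != 12) stop("season_map must have length 12")
  season_map[month]
}

#' @describeIn seasonOfMonth the default month-to-season map
#' @export
defaultSeasonMap <- function() {
  c(rep("winter_mixed", 3), "spring_transition",
    rep("summer_stratified", 6), rep("fall_transition", 2))
}

#' Classify the seasonality of one entity series
#'
#' Runs the full per-series pipeline: RSD gate (series RSD must exceed
#' \code{rsd_threshold}), Morlet decomposition, white-noise permutation
#' significance, dominant-period assignment (highest per-period median
#' power), and - when the series is significant with a 12-month dominant
#' period - 12-month band reconstruction, peak month and season
#' assignment.
#'
#' @param series an \linkS4class{EntitySeries}.
#' @param params a \linkS4class{WaveletParams}.
#' @param seed optional permutation seed.
#' @param season_map month-to-season map (see \code{\link{seasonOfMonth}}).
#' @return a \linkS4class{SeasonalityCall}.
#' @export
classifySeasonality <- function(series, params = waveletParams(),
                                seed = NULL,
                                season_map = defaultSeasonMap()) {
  rsd <- seriesRSD(series)
  passed_rsd <- rsd > params@rsdThreshold
  decomp <- cwtMorlet(series, params)
  decomp <- permutationSignificance(series, params, decomp, seed)
  j <- which.max(decomp@medianPower)
  dom <- decomp@periods[j]
  significant <- passed_rsd && decomp@medianP[j] <= params@alpha
  seasonal <- significant && .inTwelveBand(dom, params)
  peak <- NA_integer_
  season <- NA_character_
  if (seasonal) {
    rp <- reconstructBand(decomp, band = 12)
    peak <- rp$peak_month
    season <- seasonOfMonth(peak, season_map)
  }
  new("SeasonalityCall", entityId = series@entityId,
      entityKind = series@entityKind, depth = series@depth,
      passedRSD = passed_rsd, significant = significant,
      dominantPeriod = dom, dominantMedianPower = decomp@medianPower[j],
      peakMonth = peak, season = season, isSeasonal = seasonal)
}

#' Classify a list of entity series
#'
#' @param series_list list of \linkS4class{EntitySeries}.
#' @param params a \linkS4class{WaveletParams}.
#' @param seed base seed; each series receives a derived sub-seed.
#' @param season_map month-to-season map.
#' @return data.frame of calls (one row per series), as
#'   \code{\link{seasonalityCallTable}}.
#' @export
classifyCohort <- function(series_list, params = waveletParams(),
                           seed = NULL, season_map = defaultSeasonMap()) {
  calls <- lapply(seq_along(series_list), function(i)
    classifySeasonality(series_list[[i]], params,
                        seed = if (is.null(seed)) NULL
                               else .subSeed(seed, i),
                        season_map = season_map))
  seasonalityCallTable(calls)
}
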