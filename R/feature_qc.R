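#' @include AllClasses.R
NULL

#' Gaussian peak-shape screen
#'
#' Fits a four-parameter Gaussian (location, scale, height, offset) to an
#' extracted chromatographic peak profile by nonlinear least squares and
#' scores the fit with the Pearson correlation between fitted and observed
#' intensities. A peak passes when the correlation exceeds 0.6 and the
#' correlation-test p-value is below 0.075.
#'
#' @param time,intensity numeric vectors (>= 5 points, intensity >= 0).
#' @param min_correlation correlation threshold (default 0.6).
#' @param max_p p-value threshold (default 0.075).
#' @return list with \code{pass}, \code{correlation}, \code{p_value} and the
#'   \code{fitted} profile.
#' @export
gaussianShapeScreen <- function(time, intensity, min_correlation = 0.6,
                                max_p = 0.075) {
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length")
  if (length(time) < 5) stop("profile must have at least 5 points")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (stats::sd(intensity) == 0)
    return(list(pass = FALSE, correlation = NA_real_, p_value = NA_real_,
                fitted = rep(mean(intensity), length(time))))
  # profiled least squares: height and offset are linear given (location,
  # scale), so scan (mu, sigma) coarsely and refine with bounded L-BFGS-B;
  # the scan keeps the refinement out of local optima on multimodal
  # profiles, the sigma bound [1%, 100% of the time range] excludes the
  # degenerate flat-Gaussian limit
  rng <- diff(range(time))
  profSSE <- function(par) {
    g <- exp(-(time - par[1])^2 / (2 * exp(par[2])^2))
    if (stats::sd(g) < 1e-12) return(sum((intensity - mean(intensity))^2))
    co <- stats::coef(stats::lm.fit(cbind(1, g), intensity))
    sum((intensity - co[1] - co[2] * g)^2)
  }
  best <- list(sse = Inf, mu = time[which.max(intensity)], sg = rng / 6)
  for (mu in seq(min(time), max(time), length.out = 25)) {
    for (sg in rng * c(0.02, 0.03, 0.05, 0.08, 0.12, 0.18, 0.25, 0.4,
                       0.6, 1)) {
      sse <- profSSE(c(mu, log(sg)))
      if (sse < best$sse) best <- list(sse = sse, mu = mu, sg = sg)
    }
  }
  opt <- stats::optim(c(best$mu, log(best$sg)), profSSE,
                      method = "L-BFGS-B",
                      lower = c(min(time), log(rng * 0.01)),
                      upper = c(max(time), log(rng)))
  g <- exp(-(time - opt$par[1])^2 / (2 * exp(opt$par[2])^2))
  co <- stats::coef(stats::lm.fit(cbind(1, g), intensity))
  yhat <- co[1] + co[2] * g
  if (stats::sd(yhat) == 0)
    return(list(pass = FALSE, correlation = NA_real_, p_value = NA_real_,
                fitted = yhat))
  ct <- suppressWarnings(stats::cor.test(intensity, yhat))
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(pass = isTRUE(r > min_correlation && p < max_p),
       correlation = r, p_value = p, fitted = yhat)
}

.subsetFeatures <- function(table, kept, stage, reason) {
  ids <- featureInfo(table)$feature_id
  rep_ <- .filterReport(stage, ids, kept,
                        ifelse(kept, "kept", reason))
  list(table = table[kept, ], report = rep_)
}

#' Peak-width filter
#'
#' Keeps features whose chromatographic peak width is strictly below
#' \code{max_width} seconds.
#'
#' @param table a \linkS4class{FeatureTable} with \code{peak_width} in its
#'   feature metadata.
#' @param max_width seconds (default 15).
#' @return list(table, report).
#' @export
filterByWidth <- function(table, max_width = 15) {
  w <- featureInfo(table)$peak_width
  if (is.null(w) || anyNA(w))
    stop("peak_width missing for features: ",
         paste(featureInfo(table)$feature_id[is.null(w) | is.na(w)],
               collapse = ", "))
  .subsetFeatures(table, w < max_width, "width",
                  sprintf("peak_width >= %g s", max_width))
}

#' Isotopologue/adduct annotation filter
#'
#' Removes features flagged as isotopologues or adducts by upstream
#' annotation.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @return list(table, report).
#' @export
filterByAnnotation <- function(table) {
  fi <- featureInfo(table)
  kept <- !(fi$isotope_flag | fi$adduct_flag)
  .subsetFeatures(table, kept, "annotation", "isotopologue or adduct")
}

#' Data-adaptive blank filter
#'
#' For each feature, the mean log abundance over all sample and blank
#' injections (\code{m_all}) and the difference \code{d} between the mean
#' log abundance of samples and of blanks are computed
#' (log10(intensity + pseudocount)). Features are binned into five bins by
#' the 20/40/60/80th quantiles of \code{m_all} (left-closed: a feature
#' exactly at a cut goes to the upper bin). Within each bin the threshold T
#' is the \code{threshold_quartile} percentile of the negative differences;
#' features are kept when \code{d > |T|}. A bin with no negative difference
#' uses T = 0, keeping features with \code{d > 0}.
#'
#' @param table a \linkS4class{FeatureTable} with >= 1 sample and >= 1
#'   process blank injection.
#' @param quantile_cuts probabilities defining the abundance bins.
#' @param threshold_quartile percentile (as a probability) of the negative
#'   differences used as the bin threshold (default 0.25).
#' @param pseudocount added before log10 (default 1; use 0 on strictly
#'   positive tables for exact scale invariance).
#' @return list(table, report).
#' @export
filterByBlank <- function(table, quantile_cuts = c(0.2, 0.4, 0.6, 0.8),
                          threshold_quartile = 0.25, pseudocount = 1) {
  inj <- injectionInfo(table)
  s_idx <- which(inj$kind == "sample")
  b_idx <- which(inj$kind == "process_blank")
  if (length(s_idx) < 1 || length(b_idx) < 1)
    stop("blank filter needs at least one sample and one blank injection")
  L <- log10(intensityMatrix(table) + pseudocount)
  m_all <- rowMeans(L[, c(s_idx, b_idx), drop = FALSE])
  d <- rowMeans(L[, s_idx, drop = FALSE]) - rowMeans(L[, b_idx, drop = FALSE])
  cuts <- stats::quantile(m_all, quantile_cuts, type = 7, names = FALSE)
  bin <- findInterval(m_all, cuts) + 1L
  kept <- logical(length(d))
  for (b in unique(bin)) {
    in_bin <- bin == b
    neg <- d[in_bin & d < 0]
    Tb <- if (length(neg)) stats::quantile(neg, threshold_quartile, type = 7,
                                           names = FALSE) else 0
    kept[in_bin] <- d[in_bin] > abs(Tb)
  }
  .subsetFeatures(table, kept, "blank",
                  "sample-minus-blank log difference below bin threshold")
}

#' Detection-frequency filter
#'
#' Keeps features detected (intensity > 0) in strictly more than
#' \code{min_fraction} of sample injections; blanks and pools are excluded
#' from the denominator.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param min_fraction proportion (default 0.5).
#' @return list(table, report).
#' @export
filterByDetection <- function(table, min_fraction = 0.5) {
  inj <- injectionInfo(table)
  s_idx <- which(inj$kind == "sample")
  if (!length(s_idx)) stop("no sample injections")
  frac <- rowMeans(intensityMatrix(table)[, s_idx, drop = FALSE] > 0)
  .subsetFeatures(table, frac > min_fraction, "detection",
                  sprintf("detected in <= %g%% of samples",
                          100 * min_fraction))
}

#' Retention-time consistency filter
#'
#' Keeps features whose grouped peaks have a range in median retention
#' times strictly below \code{max_range} seconds.
#'
#' @param table a \linkS4class{FeatureTable} with \code{median_rt_range}.
#' @param max_range seconds (default 5).
#' @return list(table, report).
#' @export
filterByRTRange <- function(table, max_range = 5) {
  r <- featureInfo(table)$median_rt_range
  if (is.null(r) || anyNA(r))
    stop("median_rt_range missing for features: ",
         paste(featureInfo(table)$feature_id[is.na(r)], collapse = ", "))
  .subsetFeatures(table, r < max_range, "rt_range",
                  sprintf("median RT range >= %g s", max_range))
}

#' Pooled-QC relative standard deviation filter
#'
#' For each feature detected in any pool injection, the relative standard
#' deviation (100 * sd/mean, sample sd) is computed across the first pool
#' injection of each batch; the feature is kept when RSD < \code{max_rsd}.
#' Features absent from every pool pass unconditionally. If no pool
#' injections exist the stage is skipped with a warning recorded in the
#' report.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param max_rsd percent (default 20).
#' @return list(table, report).
#' @export
filterByPoolRSD <- function(table, max_rsd = 20) {
  inj <- injectionInfo(table)
  pool_idx <- which(inj$kind == "pool")
  ids <- featureInfo(table)$feature_id
  if (!length(pool_idx)) {
    warning("no pool injections; pool RSD stage skipped")
    return(list(table = table,
                report = .filterReport("pool_rsd", ids,
                                       rep(TRUE, length(ids)),
                                       "stage skipped: no pools")))
  }
  # first pool injection (column order) of each batch
  first_per_batch <- pool_idx[!duplicated(inj$batch[pool_idx])]
  if (length(first_per_batch) < 2)
    stop("pool RSD filter needs pools in at least 2 batches")
  X <- intensityMatrix(table)
  detected <- rowSums(X[, pool_idx, drop = FALSE] > 0) > 0
  P <- X[, first_per_batch, drop = FALSE]
  rsd <- 100 * apply(P, 1, stats::sd) / rowMeans(P)
  kept <- !detected | (rsd < max_rsd)
  kept[is.na(kept)] <- FALSE
  .subsetFeatures(table, kept, "pool_rsd",
                  sprintf("pool RSD >= %g%%", max_rsd))
}

#' Run the full QC filter cascade
#'
#' Applies, in order: annotation filter, width filter, blank filter,
#' retention-time consistency filter, detection-frequency filter and
#' pooled-QC RSD filter, with the defaults used for the time-series
#' analysis. Per-stage thresholds can be overridden through the arguments.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param max_width,max_rsd,max_range,min_fraction stage thresholds.
#' @param quantile_cuts,threshold_quartile,pseudocount blank-filter
#'   parameters.
#' @return list with \code{table} (the filtered \linkS4class{FeatureTable})
#'   and \code{reports} (a list of \linkS4class{FilterReport}s).
#' @export
runFilterCascade <- function(table, max_width = 15,
                             quantile_cuts = c(0.2, 0.4, 0.6, 0.8),
                             threshold_quartile = 0.25, pseudocount = 1,
                             max_range = 5, min_fraction = 0.5,
                             max_rsd = 20) {
  reports <- list()
  st <- filterByAnnotation(table)
  reports$annotation <- st$report
  st <- filterByWidth(st$table, max_width)
  reports$width <- st$report
  st <- filterByBlank(st$table, quantile_cuts, threshold_quartile,
                      pseudocount)
  reports$blank <- st$report
  st <- filterByRTRange(st$table, max_range)
  reports$rt_range <- st$report
  st <- filterByDetection(st$table, min_fraction)
  reports$detection <- st$report
  st <- filterByPoolRSD(st$table, max_rsd)
  reports$pool_rsd <- st$report
  list(table = st$table, reports = reports)
}

#' Per-batch median centering (optional utility)
#'
#' Divides each feature's intensities within a batch by the batch median of
#' its detected sample intensities and rescales by the overall median, a
#' light-weight alternative when upstream batch correction has not been
#' applied. Off by default in the cascade: tables are normally assumed
#' batch-corrected upstream.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @return a batch-centred \linkS4class{FeatureTable}.
#' @export
medianCenterBatches <- function(table) {
  X <- intensityMatrix(table)
  inj <- injectionInfo(table)
  for (i in seq_len(nrow(X))) {
    det <- X[i, ] > 0 & inj$kind == "sample"
    if (!any(det)) next
    overall <- stats::median(X[i, det])
    for (b in unique(inj$batch)) {
      in_b <- inj$batch == b
      med_b <- stats::median(X[i, det & in_b])
      if (!is.na(med_b) && med_b > 0)
        X[i, in_b] <- X[i, in_b] / med_b * overall
    }
  }
  FeatureTable(X, featureInfo(table), injectionInfo(table),
               metadata = metadata(table))
}
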