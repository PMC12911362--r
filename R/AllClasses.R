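#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.VALID_KINDS <- c("sample", "process_blank", "pool")
.SEASONS <- c("winter_mixed", "spring_transition", "summer_stratified",
              "fall_transition")

#' FeatureTable: an untargeted LC-MS feature table
#'
#' A \linkS4class{SummarizedExperiment} holding one intensity assay
#' (features x injections; 0 means not detected), feature metadata as
#' \code{rowData} (\code{mz}, \code{rt}, \code{peak_width},
#' \code{median_rt_range}, \code{isotope_flag}, \code{adduct_flag}) and
#' injection metadata as \code{colData} (\code{kind} one of
#' \code{sample}/\code{process_blank}/\code{pool}, \code{batch},
#' \code{depth}, \code{event_date}).
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else if (any(assay(object, "intensity") < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  cd <- colData(object)
  if (!all(c("kind", "batch") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'kind' and 'batch'")
  else {
    if (!all(cd$kind %in% .VALID_KINDS))
      msg <- c(msg, sprintf("injection kind must be one of %s",
                            paste(.VALID_KINDS, collapse = ", ")))
    if (any(!nzchar(as.character(cd$batch))))
      msg <- c(msg, "batch labels must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param intensities numeric matrix, features x injections, non-negative.
#' @param features data.frame of feature metadata, one row per feature
#'   (columns \code{feature_id}, \code{mz}, \code{rt}, \code{peak_width},
#'   \code{median_rt_range}, \code{isotope_flag}, \code{adduct_flag};
#'   extra columns are kept).
#' @param injections data.frame of injection metadata, one row per injection
#'   (columns \code{injection_id}, \code{kind}, \code{batch}, optional
#'   \code{depth}, \code{event_date}).
#' @param metadata optional list stored in the object metadata (e.g. the
#'   synthetic ground truth).
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(intensities, features, injections, metadata = list()) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features))
    stop("feature metadata rows must match intensity matrix rows")
  if (ncol(intensities) != nrow(injections))
    stop("injection metadata rows must match intensity matrix columns")
  if ("feature_id" %in% colnames(features))
    rownames(intensities) <- features$feature_id
  if ("injection_id" %in% colnames(injections))
    colnames(intensities) <- injections$injection_id
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = DataFrame(features, row.names = rownames(intensities)),
    colData = DataFrame(injections, row.names = colnames(intensities)),
    metadata = metadata)
  new("FeatureTable", se)
}

#' @describeIn FeatureTable intensity assay accessor
#' @param x a FeatureTable
#' @export
intensityMatrix <- function(x) assay(x, "intensity")

#' @describeIn FeatureTable injection metadata as a data.frame
#' @export
injectionInfo <- function(x) as.data.frame(colData(x))

#' @describeIn FeatureTable feature metadata as a data.frame
#' @export
featureInfo <- function(x) as.data.frame(rowData(x))

#' EntitySeries: one entity's monthly time series at one depth
#'
#' Values of a DOM molecule (intensity, arbitrary units) or an ASV
#' (relative abundance) on a uniform calendar-month grid.
#'
#' @slot entityId character identifier.
#' @slot entityKind "DOM" or "ASV".
#' @slot depth depth label.
#' @slot months Date vector (first of month), strictly increasing by 1 month.
#' @slot values non-negative numeric vector.
#' @slot observedMask logical: TRUE where the grid month was directly
#'   observed, FALSE where it was interpolated.
#' @export
setClass("EntitySeries", representation(
  entityId = "character", entityKind = "character", depth = "character",
  months = "Date", values = "numeric", observedMask = "logical"))

setValidity("EntitySeries", function(object) {
  msg <- character()
  n <- length(object@months)
  if (length(object@values) != n || length(object@observedMask) != n)
    msg <- c(msg, "months, values and observedMask must have equal length")
  if (n > 1) {
    steps <- diff(.monthIndex(object@months))
    if (any(steps != 1L))
      msg <- c(msg, "months must increase with a step of exactly 1 month")
  }
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "values must be >= 0")
  if (!object@entityKind %in% c("DOM", "ASV"))
    msg <- c(msg, "entityKind must be 'DOM' or 'ASV'")
  if (length(msg)) msg else TRUE
})

#' Construct an EntitySeries
#'
#' @param entity_id,entity_kind,depth identifiers (kind one of "DOM","ASV").
#' @param months Date vector of consecutive calendar months.
#' @param values numeric vector of the same length.
#' @param observed_mask logical; defaults to all observed.
#' @return An \linkS4class{EntitySeries}.
#' @export
EntitySeries <- function(entity_id, entity_kind = "DOM", depth = "1m",
                         months, values,
                         observed_mask = rep(TRUE, length(values))) {
  new("EntitySeries", entityId = as.character(entity_id),
      entityKind = entity_kind, depth = as.character(depth),
      months = as.Date(months), values = as.numeric(values),
      observedMask = observed_mask)
}

#' @describeIn EntitySeries series values
#' @param x an EntitySeries
#' @export
seriesValues <- function(x) x@values

#' @describeIn EntitySeries grid months
#' @export
seriesMonths <- function(x) x@months

setMethod("length", "EntitySeries", function(x) length(x@values))

setMethod("show", "EntitySeries", function(object) {
  cat(sprintf("EntitySeries %s (%s) at %s: %d months %s..%s\n",
              object@entityId, object@entityKind, object@depth,
              length(object@values), format(min(object@months), "%Y-%m"),
              format(max(object@months), "%Y-%m")))
})

#' WaveletParams: parameters for the Morlet wavelet analysis
#'
#' @slot lowerPeriod,upperPeriod analysed period range in months (default
#'   2-12).
#' @slot suboctaves voices per octave on the geometric period grid
#'   (default 20).
#' @slot omega0 Morlet nondimensional angular frequency (default 6).
#' @slot dt sampling interval in months (default 1).
#' @slot nPermutations white-noise permutations for significance
#'   (default 1000).
#' @slot alpha significance level on the median p-value (default 0.01).
#' @slot rsdThreshold relative standard deviation gate in percent
#'   (default 25).
#' @export
setClass("WaveletParams", representation(
  lowerPeriod = "numeric", upperPeriod = "numeric", suboctaves = "numeric",
  omega0 = "numeric", dt = "numeric", nPermutations = "numeric",
  alpha = "numeric", rsdThreshold = "numeric"))

setValidity("WaveletParams", function(object) {
  msg <- character()
  if (!(object@lowerPeriod >= 2 && object@lowerPeriod < object@upperPeriod))
    msg <- c(msg, "need 2 <= lowerPeriod < upperPeriod")
  if (object@nPermutations < 100)
    msg <- c(msg, "nPermutations must be >= 100")
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0,1)")
  if (object@suboctaves < 1) msg <- c(msg, "suboctaves must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct WaveletParams
#'
#' @param lower_period,upper_period period range in months.
#' @param suboctaves voices per octave.
#' @param omega0 Morlet angular frequency.
#' @param dt sampling step (months).
#' @param n_permutations permutation count for the white-noise null.
#' @param alpha significance level on the median p-value.
#' @param rsd_threshold RSD gate in percent.
#' @return A \linkS4class{WaveletParams}.
#' @export
waveletParams <- function(lower_period = 2, upper_period = 12,
                          suboctaves = 20, omega0 = 6, dt = 1,
                          n_permutations = 1000, alpha = 0.01,
                          rsd_threshold = 25) {
  new("WaveletParams", lowerPeriod = lower_period, upperPeriod = upper_period,
      suboctaves = suboctaves, omega0 = omega0, dt = dt,
      nPermutations = n_permutations, alpha = alpha,
      rsdThreshold = rsd_threshold)
}

#' WaveletDecomposition: Morlet power, coefficients and p-values
#'
#' @slot periods analysed periods (months), geometric grid.
#' @slot times month indices of the series.
#' @slot coefficients complex wavelet coefficients, period x time.
#' @slot power |W|^2, period x time.
#' @slot pvalues permutation p-values, period x time (empty until
#'   \code{permutationSignificance} is run).
#' @slot medianPower per-period median of power over time.
#' @slot medianP per-period median p-value over time.
#' @slot seriesMean,seriesSD mean/sd used for standardization.
#' @slot months the series' calendar months.
#' @slot params the \linkS4class{WaveletParams} used.
#' @export
setClass("WaveletDecomposition", representation(
  periods = "numeric", times = "numeric", coefficients = "matrix",
  power = "matrix", pvalues = "matrix", medianPower = "numeric",
  medianP = "numeric", seriesMean = "numeric", seriesSD = "numeric",
  months = "Date", params = "WaveletParams"))

setMethod("show", "WaveletDecomposition", function(object) {
  cat(sprintf(
    "WaveletDecomposition: %d periods (%.2f-%.2f months) x %d time points\n",
    length(object@periods), min(object@periods), max(object@periods),
    length(object@times)))
  cat(sprintf("  dominant period %.2f months (median power %.3f)%s\n",
              dominantPeriod(object),
              max(object@medianPower),
              if (length(object@pvalues)) "" else " [no p-values yet]"))
})

#' @describeIn WaveletDecomposition analysed periods (months)
#' @param x a WaveletDecomposition
#' @export
wavePeriods <- function(x) x@periods

#' @describeIn WaveletDecomposition wavelet power matrix (period x time)
#' @export
wavePower <- function(x) x@power

#' @describeIn WaveletDecomposition per-period median power over time
#' @export
medianPower <- function(x) x@medianPower

#' @describeIn WaveletDecomposition per-period median permutation p-value
#' @export
medianPValues <- function(x) x@medianP

#' @describeIn WaveletDecomposition the period with highest median power
#' @export
dominantPeriod <- function(x) x@periods[which.max(x@medianPower)]

#' SeasonalityCall: the per-entity seasonality classification
#'
#' @slot entityId,entityKind,depth identifiers.
#' @slot passedRSD TRUE if series RSD exceeded the threshold.
#' @slot significant TRUE if the median p-value at the dominant period is
#'   at most alpha and the RSD gate passed.
#' @slot dominantPeriod months.
#' @slot dominantMedianPower unitless.
#' @slot peakMonth calendar month 1-12 of the reconstructed 12-month
#'   maximum, NA unless seasonal.
#' @slot season hydrographic season label, NA unless seasonal.
#' @slot isSeasonal TRUE if significant and the dominant period is the
#'   12-month band.
#' @export
setClass("SeasonalityCall", representation(
  entityId = "character", entityKind = "character", depth = "character",
  passedRSD = "logical", significant = "logical", dominantPeriod = "numeric",
  dominantMedianPower = "numeric", peakMonth = "integer", season = "character",
  isSeasonal = "logical"))

setMethod("show", "SeasonalityCall", function(object) {
  cat(sprintf(
    "SeasonalityCall %s at %s: %sseasonal (dominant %.2f mo, median power %.3f%s)\n",
    object@entityId, object@depth, if (object@isSeasonal) "" else "not ",
    object@dominantPeriod, object@dominantMedianPower,
    if (object@isSeasonal) sprintf(", peak month %d [%s]",
                                   object@peakMonth, object@season) else ""))
})

#' Bind SeasonalityCall objects into a data.frame
#'
#' @param calls list of \linkS4class{SeasonalityCall} objects.
#' @return data.frame with one row per call.
#' @export
seasonalityCallTable <- function(calls) {
  if (is(calls, "SeasonalityCall")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(cc) data.frame(
    entity_id = cc@entityId, entity_kind = cc@entityKind, depth = cc@depth,
    passed_rsd = cc@passedRSD, significant = cc@significant,
    dominant_period = cc@dominantPeriod,
    dominant_median_power = cc@dominantMedianPower,
    peak_month = cc@peakMonth, season = cc@season,
    is_seasonal = cc@isSeasonal, stringsAsFactors = FALSE)))
}

#' FilterReport: bookkeeping for one QC filter stage
#'
#' @slot stage stage name.
#' @slot nIn,nOut feature counts before/after.
#' @slot decisions data.frame (feature_id, kept, reason) covering all input
#'   features.
#' @export
setClass("FilterReport", representation(
  stage = "character", nIn = "integer", nOut = "integer",
  decisions = "data.frame"))

setValidity("FilterReport", function(object) {
  msg <- character()
  if (object@nOut > object@nIn) msg <- c(msg, "nOut must be <= nIn")
  if (nrow(object@decisions) != object@nIn)
    msg <- c(msg, "decisions must cover all input features")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport [%s]: %d -> %d features (%d removed)\n",
              object@stage, object@nIn, object@nOut,
              object@nIn - object@nOut))
})

.filterReport <- function(stage, feature_ids, kept, reason) {
  new("FilterReport", stage = stage, nIn = length(feature_ids),
      nOut = sum(kept),
      decisions = data.frame(feature_id = feature_ids, kept = kept,
                             reason = reason, stringsAsFactors = FALSE))
}

# month index = whole months since 1970-01
.monthIndex <- function(dates) {
  lt <- as.POSIXlt(dates)
  (lt$year - 70L) * 12L + lt$mon
}

.monthFromIndex <- function(idx) {
  as.Date(sprintf("%d-%02d-01", 1970L + idx %/% 12L, idx %% 12L + 1L))
}
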