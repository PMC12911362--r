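#' @include AllClasses.R
NULL

#' Average replicate observations within calendar months
#'
#' Dates are mapped to their calendar month (regardless of day) and each
#' month's representative value is the arithmetic mean of its observations
#' (multiple samples per month arise mainly from July diel campaigns).
#'
#' @param dates Date vector.
#' @param values numeric vector of the same length.
#' @return data.frame with \code{month} (Date, first of month) and
#'   \code{value}, one row per observed month, ordered by month.
#' @export
collapseReplicates <- function(dates, values) {
  if (length(dates) != length(values) || !length(dates))
    stop("dates and values must be non-empty and of equal length")
  idx <- .monthIndex(as.Date(dates))
  agg <- tapply(values, idx, mean)
  data.frame(month = .monthFromIndex(as.integer(names(agg))),
             value = as.numeric(agg))
}

#' Build a uniform monthly-grid series by linear interpolation
#'
#' Interior gaps between observed months are filled by linear
#' interpolation; observed months keep their exact values. Leading and
#' trailing unobserved months are never extrapolated: the series is
#' trimmed to the observed span (intersected with [start, end]).
#'
#' @param monthly data.frame with \code{month} (Date) and \code{value}
#'   (e.g. from \code{collapseReplicates}); >= 2 observed months.
#' @param start,end grid limits ("YYYY-MM" or Date); default the observed
#'   span.
#' @param entity_id,entity_kind,depth series identifiers.
#' @return an \linkS4class{EntitySeries}; \code{observed_mask} records
#'   which grid months were directly observed.
#' @export
toMonthlyGrid <- function(monthly, start = NULL, end = NULL,
                          entity_id = "entity", entity_kind = "DOM",
                          depth = "1m") {
  if (nrow(monthly) < 2)
    stop("cannot interpolate from a single observation")
  obs_idx <- .monthIndex(as.Date(monthly$month))
  o <- order(obs_idx)
  obs_idx <- obs_idx[o]
  vals <- monthly$value[o]
  if (anyDuplicated(obs_idx)) stop("duplicate observed months")
  lo <- if (is.null(start)) min(obs_idx)
        else max(.monthIndex(as.Date(paste0(start, "-01"))), min(obs_idx))
  hi <- if (is.null(end)) max(obs_idx)
        else min(.monthIndex(as.Date(paste0(end, "-01"))), max(obs_idx))
  lo <- max(lo, min(obs_idx))  # no extrapolation
  hi <- min(hi, max(obs_idx))
  grid <- lo:hi
  yi <- stats::approx(obs_idx, vals, xout = grid, method = "linear")$y
  EntitySeries(entity_id, entity_kind, depth, .monthFromIndex(grid), yi,
               observed_mask = grid %in% obs_idx)
}

#' Relative standard deviation of a series
#'
#' 100 * sd / mean over the grid values (sample sd). Used as the gate for
#' which environmental variability is assumed to exceed analytical
#' variability (threshold 25 percent).
#'
#' @param series an \linkS4class{EntitySeries} or numeric vector.
#' @return RSD in percent.
#' @export
seriesRSD <- function(series) {
  v <- if (is(series, "EntitySeries")) seriesValues(series) else series
  m <- mean(v)
  if (m <= 0) stop("RSD undefined: series mean must be > 0")
  100 * stats::sd(v) / m
}

#' Long-format observations to a list of EntitySeries
#'
#' Convenience wrapper: splits a long table (entity, depth, date, value)
#' into per-(entity, depth) series via \code{collapseReplicates} and
#' \code{toMonthlyGrid}.
#'
#' @param df data.frame with columns \code{entity_id}, \code{depth},
#'   \code{date}, \code{value} and optionally \code{entity_kind}.
#' @param start,end optional grid limits.
#' @return list of \linkS4class{EntitySeries}.
#' @export
buildSeriesFromLong <- function(df, start = NULL, end = NULL) {
  keys <- interaction(df$entity_id, df$depth, drop = TRUE)
  lapply(split(df, keys), function(g) {
    monthly <- collapseReplicates(g$date, g$value)
    toMonthlyGrid(monthly, start, end, entity_id = g$entity_id[1],
                  entity_kind = if ("entity_kind" %in% names(g))
                    g$entity_kind[1] else "DOM",
                  depth = g$depth[1])
  })
}
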