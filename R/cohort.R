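#' @include AllClasses.R
NULL

#' Exact depth-set intersections of seasonal entities (upset table)
#'
#' Assigns each seasonal entity to the exact set of depths at which it is
#' seasonal and counts entities per non-empty depth subset (15 rows for 4
#' depths) and per entity kind, plus per-depth totals.
#'
#' @param calls data.frame of seasonality calls (from
#'   \code{\link{classifyCohort}} or \code{\link{seasonalityCallTable}}):
#'   columns \code{entity_id}, \code{entity_kind}, \code{depth},
#'   \code{is_seasonal}.
#' @param depths depth universe; defaults to the depths present in calls.
#' @return list with \code{subsets} (data.frame: one row per non-empty
#'   depth subset with counts per kind) and \code{per_depth_totals}
#'   (data.frame of seasonal counts per depth and kind).
#' @export
depthIntersections <- function(calls, depths = NULL) {
  if (anyDuplicated(calls[, c("entity_id", "entity_kind", "depth")]))
    stop("duplicate (entity, depth) calls")
  if (is.null(depths)) depths <- sort(unique(calls$depth))
  kinds <- sort(unique(calls$entity_kind))
  seas <- calls[calls$is_seasonal, , drop = FALSE]

  # all non-empty subsets, ordered by size then membership
  n_d <- length(depths)
  subset_masks <- lapply(seq_len(2^n_d - 1),
                         function(b) as.logical(bitwAnd(b, 2^(seq_len(n_d) - 1))))
  subset_masks <- subset_masks[order(vapply(subset_masks, sum, 0L))]
  subset_key <- vapply(subset_masks,
                       function(m) paste(depths[m], collapse = "+"), "")

  counts <- matrix(0L, length(subset_masks), length(kinds),
                   dimnames = list(subset_key, kinds))
  if (nrow(seas)) {
    keys <- interaction(seas$entity_id, seas$entity_kind, drop = TRUE)
    for (g in split(seas, keys)) {
      key <- paste(depths[depths %in% g$depth], collapse = "+")
      counts[key, g$entity_kind[1]] <- counts[key, g$entity_kind[1]] + 1L
    }
  }
  subsets <- data.frame(depth_set = subset_key,
                        n_depths = vapply(subset_masks, sum, 0L),
                        counts, check.names = FALSE,
                        stringsAsFactors = FALSE, row.names = NULL)
  totals <- expand.grid(depth = depths, entity_kind = kinds,
                        stringsAsFactors = FALSE)
  totals$n_seasonal <- mapply(function(d, k)
    sum(seas$depth == d & seas$entity_kind == k), totals$depth,
    totals$entity_kind)
  list(subsets = subsets, per_depth_totals = totals)
}

#' Tally peak seasons of seasonal entities
#'
#' Counts seasonal entities by (depth, season, entity kind) with
#' percentages within each depth and kind.
#'
#' @param calls data.frame of seasonality calls.
#' @return data.frame with \code{depth}, \code{entity_kind},
#'   \code{season}, \code{n} and \code{pct} (within depth and kind).
#' @export
peakSeasonTally <- function(calls) {
  seas <- calls[calls$is_seasonal & !is.na(calls$season), , drop = FALSE]
  if (!nrow(seas))
    return(data.frame(depth = character(), entity_kind = character(),
                      season = character(), n = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(depth = seas$depth,
                             entity_kind = seas$entity_kind,
                             season = seas$season),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  tab <- tab[tab$n > 0 | TRUE, ]
  grp_tot <- stats::ave(tab$n, tab$depth, tab$entity_kind, FUN = sum)
  tab$pct <- ifelse(grp_tot > 0, 100 * tab$n / grp_tot, NA_real_)
  tab[order(tab$depth, tab$entity_kind, tab$season), , drop = FALSE]
}

# two-sided asymptotic two-sample Kolmogorov p-value
.ksAsymptoticP <- function(D, n_a, n_b) {
  n_eff <- n_a * n_b / (n_a + n_b)
  t <- sqrt(n_eff) * D
  if (t == 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Compare two median-power distributions (two-sample Kolmogorov-Smirnov)
#'
#' D is the supremum distance between the two empirical cumulative
#' distribution functions, evaluated over the pooled sample points (exact
#' under ties). The p-value is the asymptotic Kolmogorov distribution for
#' large samples, or the exact null distribution (\code{stats::psmirnov})
#' when both samples have fewer than 30 tie-free observations.
#'
#' @param powers_a,powers_b numeric vectors (>= 5 each), e.g. dominant
#'   median powers of two entity cohorts.
#' @return list with \code{D}, \code{p_value}, \code{n_a}, \code{n_b},
#'   \code{ecdf_a}, \code{ecdf_b}.
#' @export
compareMedianPower <- function(powers_a, powers_b) {
  n_a <- length(powers_a)
  n_b <- length(powers_b)
  if (n_a < 5 || n_b < 5) stop("need at least 5 values per cohort")
  Fa <- stats::ecdf(powers_a)
  Fb <- stats::ecdf(powers_b)
  pooled <- sort(unique(c(powers_a, powers_b)))
  D <- max(abs(Fa(pooled) - Fb(pooled)))
  has_ties <- anyDuplicated(c(powers_a, powers_b)) > 0
  p <- if (n_a < 30 && n_b < 30 && !has_ties)
    stats::psmirnov(D, sizes = c(n_a, n_b), two.sided = TRUE,
                    lower.tail = FALSE)
  else .ksAsymptoticP(D, n_a, n_b)
  list(D = D, p_value = p, n_a = n_a, n_b = n_b, ecdf_a = Fa, ecdf_b = Fb)
}
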