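#' @include AllClasses.R
NULL

#' E-value filter for contig-level KO annotations
#'
#' Keeps non-SCMG records with HMM e-value at most \code{threshold}
#' (default 1e-10); single-copy marker gene (SCMG) records are kept if and
#' only if their precomputed score-threshold pass flag (\code{scmg_pass})
#' is TRUE, regardless of e-value.
#'
#' @param records data.frame of contig KO records (columns \code{is_scmg},
#'   \code{evalue}, \code{scmg_pass}).
#' @param threshold e-value cutoff for non-SCMG records.
#' @return the filtered data.frame.
#' @export
filterByEvalue <- function(records, threshold = 1e-10) {
  scmg <- records$is_scmg
  if (anyNA(records$evalue[!scmg]))
    stop("evalue missing for non-SCMG records")
  keep <- ifelse(scmg, records$scmg_pass %in% TRUE,
                 records$evalue <= threshold)
  records[keep, , drop = FALSE]
}

# round half-up
.roundHalfUp <- function(x) floor(x + 0.5)

#' SCMG-based sample richness
#'
#' Counts, per single-copy marker gene KO, the number of contigs carrying
#' it in the sample; richness S is the median of these counts across the
#' SCMG KOs present, rounded half-up to an integer. SCMGs are assumed to
#' occur once per genome, so each SCMG contig count estimates the number
#' of community members.
#'
#' @param records contig KO records for one sample (post e-value filter).
#' @param method "median" (default), "mean" or "sum" across SCMG KOs.
#' @return integer richness S.
#' @export
scmgRichness <- function(records, method = c("median", "mean", "sum")) {
  method <- match.arg(method)
  scmg <- records[records$is_scmg %in% TRUE, , drop = FALSE]
  if (!nrow(scmg)) stop("no SCMG records in sample")
  counts <- tapply(scmg$contig_id, scmg$ko_id,
                   function(x) length(unique(x)))
  val <- switch(method, median = stats::median(counts),
                mean = mean(counts), sum = sum(counts))
  as.integer(.roundHalfUp(val))
}

#' Contribution evenness (CE)
#'
#' Functional-redundancy metric for one (sample, KO) pair. Contributions
#' (contig RPKM) are normalized to shares p over the positive contributors;
#' the effective contributor number is the Hill number of order \code{q}
#' (q = 1: exp of Shannon entropy), and
#' \code{CE = (D_q - 1) / (S - 1)} with S the SCMG-estimated richness.
#' CE = 0 when a single member carries the gene, CE = 1 when all S members
#' contribute equally. CE is defined as 1 when S = 1, and clipped to [0,1]
#' with a warning when the effective number exceeds S.
#'
#' @param contributions non-negative RPKM contributions, at least one
#'   positive.
#' @param S richness (>= 1).
#' @param q Hill order (default 1).
#' @return CE in [0,1].
#' @export
contributionEvenness <- function(contributions, S, q = 1) {
  if (any(contributions < 0)) stop("contributions must be >= 0")
  pos <- contributions[contributions > 0]
  if (!length(pos)) stop("all contributions are zero")
  if (S < 1) stop("S must be >= 1")
  p <- pos / sum(pos)
  D <- if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
  if (S == 1) return(1)
  ce <- (D - 1) / (S - 1)
  if (D > S + 1e-9) {
    warning("effective contributor number exceeds SCMG richness; CE clipped")
    ce <- min(ce, 1)
  }
  .snapUnit(max(0, min(1, ce)))
}

#' Contribution evenness for every (sample, KO) pair in a table
#'
#' Computes per-sample SCMG richness and, for each target KO, the CE of
#' its contig-level RPKM contributions (each contig is one community
#' member's gene copy; contigs are not aggregated by taxon here).
#'
#' @param records contig KO records (post e-value filter).
#' @param ko_ids target KO ids; defaults to all non-SCMG KOs present.
#' @param q Hill order.
#' @param richness_method passed to \code{\link{scmgRichness}}.
#' @return data.frame with \code{sample_id}, \code{ko_id}, \code{CE},
#'   \code{S}, \code{n_contributors}, \code{total_rpkm}, and the sample's
#'   \code{season} when present.
#' @export
ceTable <- function(records, ko_ids = NULL, q = 1,
                    richness_method = "median") {
  if (is.null(ko_ids))
    ko_ids <- sort(unique(records$ko_id[!(records$is_scmg %in% TRUE)]))
  out <- list()
  for (g in split(records, records$sample_id)) {
    S <- scmgRichness(g, richness_method)
    for (ko in ko_ids) {
      rows <- g[g$ko_id == ko & !(g$is_scmg %in% TRUE), , drop = FALSE]
      if (!nrow(rows) || sum(rows$rpkm) == 0) next
      contrib <- tapply(rows$rpkm, rows$contig_id, sum)
      out[[length(out) + 1]] <- data.frame(
        sample_id = g$sample_id[1], ko_id = ko,
        CE = contributionEvenness(as.numeric(contrib), S, q),
        S = S, n_contributors = sum(contrib > 0),
        total_rpkm = sum(contrib),
        season = if ("season" %in% names(g)) g$season[1] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Core-gene presence across samples
#'
#' A KO is present in a sample when at least one passing contig carries
#' it; KOs present in strictly more than \code{min_fraction} of samples
#' are flagged as core genes.
#'
#' @param records contig KO records across >= 2 samples (post e-value
#'   filter).
#' @param min_fraction core cutoff (default 0.85).
#' @return data.frame with \code{ko_id}, \code{present_fraction},
#'   \code{is_core}.
#' @export
coreGenePresence <- function(records, min_fraction = 0.85) {
  samples <- unique(records$sample_id)
  if (length(samples) < 2) stop("need at least 2 samples")
  kos <- sort(unique(records$ko_id[!(records$is_scmg %in% TRUE)]))
  frac <- vapply(kos, function(ko)
    length(unique(records$sample_id[records$ko_id == ko &
                                      !(records$is_scmg %in% TRUE)])) /
      length(samples), 0)
  data.frame(ko_id = kos, present_fraction = frac,
             is_core = frac > min_fraction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Functional taxonomy: relative taxonomic contributions per KO
#'
#' Per sample and KO, each taxonomic group's contribution is its summed
#' RPKM divided by the total annotated RPKM for that KO in the sample
#' (records labelled "unannotated" are excluded from numerator and
#' denominator). Per-taxon totals across the KO set (for pie scaling) and
#' the display set of taxa present in >= 2 samples are also returned.
#'
#' @param records contig KO records (post e-value filter).
#' @param ko_set KO ids to aggregate (default all non-SCMG KOs present).
#' @return list with \code{contributions} (sample, taxon, ko,
#'   relative_contribution), \code{taxon_totals} (sample, taxon, total
#'   relative contribution across the KO set) and \code{display_taxa}.
#' @export
functionalTaxonomy <- function(records, ko_set = NULL) {
  if (is.null(ko_set))
    ko_set <- sort(unique(records$ko_id[!(records$is_scmg %in% TRUE)]))
  ann <- records[!(records$is_scmg %in% TRUE) &
                   records$ko_id %in% ko_set &
                   !is.na(records$taxon) &
                   records$taxon != "unannotated", , drop = FALSE]
  out <- list()
  for (g in split(ann, interaction(ann$sample_id, ann$ko_id, drop = TRUE))) {
    tot <- sum(g$rpkm)
    if (tot == 0) next
    by_tax <- tapply(g$rpkm, g$taxon, sum)
    out[[length(out) + 1]] <- data.frame(
      sample_id = g$sample_id[1], taxon = names(by_tax),
      ko_id = g$ko_id[1], relative_contribution = as.numeric(by_tax) / tot,
      stringsAsFactors = FALSE)
  }
  contributions <- do.call(rbind, out)
  rownames(contributions) <- NULL
  taxon_totals <- if (!is.null(contributions)) {
    agg <- stats::aggregate(relative_contribution ~ sample_id + taxon,
                            contributions, sum)
    names(agg)[3] <- "total_relative_contribution"
    agg
  } else NULL
  display_taxa <- if (!is.null(contributions)) {
    n_samp <- tapply(contributions$sample_id, contributions$taxon,
                     function(x) length(unique(x)))
    sort(names(n_samp)[n_samp >= 2])
  } else character()
  list(contributions = contributions, taxon_totals = taxon_totals,
       display_taxa = display_taxa)
}

#' Wilcoxon rank-sum comparisons of CE groups
#'
#' Compares CE values between two groups (e.g. succinate vs trehalose
#' KOs, or summer stratified vs winter mixed samples per KO) with a
#' two-sided Wilcoxon rank-sum test and flags significance at a
#' configurable threshold (0.01 for metabolite-level, 0.1 for
#' season-level comparisons).
#'
#' @param values numeric CE values.
#' @param groups two-level grouping factor/character.
#' @param p_threshold significance flag threshold.
#' @return list with \code{statistic}, \code{p_value}, \code{significant},
#'   \code{n} per group.
#' @export
ceWilcoxon <- function(values, groups, p_threshold = 0.01) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group")
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied; p = 1")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                significant = FALSE, n = c(length(a), length(b))))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value <= p_threshold,
       n = c(length(a), length(b)))
}

#' Group tests over a CE table
#'
#' \code{grouping = "metabolite"} pools CE values by metabolite (via
#' \code{ko_map}) and runs one test; \code{grouping = "season"} tests,
#' per KO, summer-stratified against winter-mixed samples.
#'
#' @param ce data.frame from \code{\link{ceTable}}.
#' @param grouping "metabolite" or "season".
#' @param ko_map named character vector mapping KO id to metabolite
#'   (required for metabolite grouping).
#' @param p_threshold significance threshold (default 0.01 for
#'   metabolite, 0.1 for season).
#' @param seasons the two season labels compared (season grouping).
#' @return data.frame with one row per comparison.
#' @export
ceGroupTests <- function(ce, grouping = c("metabolite", "season"),
                         ko_map = NULL, p_threshold = NULL,
                         seasons = c("summer_stratified", "winter_mixed")) {
  grouping <- match.arg(grouping)
  if (grouping == "metabolite") {
    if (is.null(ko_map)) stop("ko_map required for metabolite grouping")
    if (is.null(p_threshold)) p_threshold <- 0.01
    grp <- ko_map[ce$ko_id]
    keep <- !is.na(grp)
    res <- ceWilcoxon(ce$CE[keep], grp[keep], p_threshold)
    data.frame(comparison = paste(sort(unique(grp[keep])), collapse = " vs "),
               statistic = res$statistic, p_value = res$p_value,
               significant = res$significant, stringsAsFactors = FALSE)
  } else {
    if (is.null(p_threshold)) p_threshold <- 0.1
    out <- list()
    for (ko in sort(unique(ce$ko_id))) {
      sub <- ce[ce$ko_id == ko & ce$season %in% seasons, , drop = FALSE]
      if (length(unique(sub$season)) != 2 ||
          min(table(sub$season)) < 3) next
      res <- tryCatch(ceWilcoxon(sub$CE, sub$season, p_threshold),
                      warning = function(w)
                        list(statistic = NA_real_, p_value = 1,
                             significant = FALSE))
      out[[length(out) + 1]] <- data.frame(
        comparison = ko, statistic = res$statistic,
        p_value = res$p_value, significant = res$significant,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
}
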