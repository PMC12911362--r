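#' @include AllClasses.R
NULL

# run expr under a temporary RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-entity/per-depth sub-seed, kept inside 32-bit range
.subSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

#' SyntheticCohortSpec: design of a synthetic DOM/ASV time-series cohort
#'
#' Emulates a multi-depth, bimonthly three-year sampling design: a monthly
#' calendar grid from \code{start_month} to \code{end_month} (default
#' 2016-07 to 2019-07, 37 points) at four fixed depths. Entities are a
#' mixture of seasonal sinusoids (period \code{period_months}, calendar
#' maximum at \code{peak_month}), partial-year sinusoids present in only one
#' of the years, and white-noise-only series.
#'
#' @slot nEntities number of entities.
#' @slot depths depth labels.
#' @slot startMonth,endMonth Date, first of month.
#' @slot fractionSeasonal proportion of entities with a periodic signal.
#' @slot periodMonths true period for seasonal entities (2-12 months).
#' @slot peakMonth calendar month (1-12) of the sinusoid maximum.
#' @slot amplitude,baseline,noiseSD intensity units.
#' @slot partialYearFlags per-entity logical: periodic signal restricted to
#'   a single 12-month window.
#' @slot noiseKind "gaussian" (default) or "t" (heavier-tailed, df 3).
#' @slot seed RNG seed.
#' @export
setClass("SyntheticCohortSpec", representation(
  nEntities = "integer", depths = "character", startMonth = "Date",
  endMonth = "Date", fractionSeasonal = "numeric", periodMonths = "numeric",
  peakMonth = "integer", amplitude = "numeric", baseline = "numeric",
  noiseSD = "numeric", partialYearFlags = "logical", noiseKind = "character",
  seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  msg <- character()
  if (object@nEntities < 1) msg <- c(msg, "n_entities must be >= 1")
  if (object@fractionSeasonal < 0 || object@fractionSeasonal > 1)
    msg <- c(msg, "fraction_seasonal must be in [0,1]")
  if (object@noiseSD < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@periodMonths < 2 || object@periodMonths > 12)
    msg <- c(msg, "period_months must be in [2,12]")
  if (object@peakMonth < 1 || object@peakMonth > 12)
    msg <- c(msg, "peak_month must be in 1..12")
  if (object@endMonth <= object@startMonth)
    msg <- c(msg, "end_month must be after start_month")
  if (length(object@partialYearFlags) != object@nEntities)
    msg <- c(msg, "partial_year_flags must have length n_entities")
  if (!object@noiseKind %in% c("gaussian", "t"))
    msg <- c(msg, "noise_kind must be 'gaussian' or 't'")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticCohortSpec
#'
#' @param n_entities entity count.
#' @param depths depth labels (default the four BATS-style depths).
#' @param start_month,end_month grid limits, "YYYY-MM" or Date.
#' @param fraction_seasonal proportion of seasonal entities; the first
#'   \code{round(fraction_seasonal * n_entities)} entities are seasonal.
#' @param period_months,peak_month,amplitude,baseline,noise_sd signal
#'   parameters (see class docs).
#' @param partial_year_flags per-entity logical (recycled if length 1).
#' @param noise_kind "gaussian" or "t".
#' @param seed RNG seed.
#' @return a validated \linkS4class{SyntheticCohortSpec}.
#' @export
cohortSpec <- function(n_entities = 100,
                       depths = c("1m", "40m", "120m", "200m"),
                       start_month = "2016-07", end_month = "2019-07",
                       fraction_seasonal = 0.5, period_months = 12,
                       peak_month = 7, amplitude = 50, baseline = 100,
                       noise_sd = 10, partial_year_flags = FALSE,
                       noise_kind = "gaussian", seed = 1L) {
  if (length(partial_year_flags) == 1)
    partial_year_flags <- rep(partial_year_flags, n_entities)
  new("SyntheticCohortSpec", nEntities = as.integer(n_entities),
      depths = depths,
      startMonth = as.Date(paste0(start_month, "-01")),
      endMonth = as.Date(paste0(end_month, "-01")),
      fractionSeasonal = fraction_seasonal, periodMonths = period_months,
      peakMonth = as.integer(peak_month), amplitude = amplitude,
      baseline = baseline, noiseSD = noise_sd,
      partialYearFlags = partial_year_flags, noiseKind = noise_kind,
      seed = as.integer(seed))
}

#' @describeIn cohortSpec the calendar-month grid of a cohort spec
#' @param spec a SyntheticCohortSpec
#' @export
cohortMonths <- function(spec) {
  seq(spec@startMonth, spec@endMonth, by = "month")
}

.isSeasonalEntity <- function(spec, entity_index) {
  entity_index <= round(spec@fractionSeasonal * spec@nEntities)
}

#' Generate one synthetic entity series
#'
#' Seasonal entities follow
#' \code{baseline + amplitude * cos(2*pi*(t - phase)/period) + noise}, with
#' the phase anchored so the sinusoid maximum falls on calendar month
#' \code{peak_month}; non-seasonal entities are baseline + noise. Entities
#' flagged partial-year carry the sinusoid only within one 12-month window
#' (a seeded choice among the whole years of the grid). Values are floored
#' at zero (intensity 0 = not detected).
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}.
#' @param entity_index 1-based entity index.
#' @param depth depth label (defaults to the first depth of the spec).
#' @param entity_kind "DOM" or "ASV".
#' @return an \linkS4class{EntitySeries} with one value per grid month.
#' @export
generateEntitySeries <- function(spec, entity_index, depth = spec@depths[1],
                                 entity_kind = "DOM") {
  validObject(spec)
  if (entity_index > spec@nEntities || entity_index < 1)
    stop("entity_index must be in 1..n_entities")
  months <- cohortMonths(spec)
  n <- length(months)
  tt <- seq_len(n) - 1
  depth_idx <- match(depth, spec@depths)
  if (is.na(depth_idx)) stop("unknown depth label: ", depth)
  .withSeed(.subSeed(spec@seed, entity_index, depth_idx), {
    sig <- rep(0, n)
    if (.isSeasonalEntity(spec, entity_index)) {
      cal_month <- as.POSIXlt(months)$mon + 1L
      phase <- which(cal_month == spec@peakMonth)[1] - 1
      sig <- spec@amplitude * cos(2 * pi * (tt - phase) / spec@periodMonths)
      if (spec@partialYearFlags[entity_index]) {
        n_years <- max(1L, n %/% 12L)
        yr <- sample.int(n_years, 1)
        window <- tt >= (yr - 1) * 12 & tt < yr * 12
        sig[!window] <- 0
      }
    }
    noise <- if (spec@noiseSD == 0) rep(0, n)
             else if (spec@noiseKind == "t")
               spec@noiseSD * stats::rt(n, df = 3) / sqrt(3)
             else stats::rnorm(n, 0, spec@noiseSD)
    vals <- pmax(spec@baseline + sig + noise, 0)
    EntitySeries(paste0("E", entity_index), entity_kind, depth, months, vals)
  })
}

#' Generate a synthetic LC-MS feature table
#'
#' Builds a \linkS4class{FeatureTable} emulating the sampling and injection
#' design: bimonthly sampling events on the cohort grid, one sample
#' injection per depth per event, one process blank per event, events
#' assigned to \code{n_batches} contiguous batches, and two pool injections
#' per batch. Feature intensities at sample injections follow each entity's
#' synthetic series at the injection's depth and month. A seeded subset of
#' features (\code{blank_contaminant_fraction}) is constructed as blank
#' contaminants whose blank intensities are each at least the feature's
#' mean sample intensity, guaranteeing blank mean >= sample mean. The
#' ground truth (entity class, contaminant flag) is stored in
#' \code{metadata(x)$ground_truth}.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}.
#' @param blank_contaminant_fraction fraction of features flagged as blank
#'   contaminants, in [0,1].
#' @param n_batches number of injection batches (default 5).
#' @return a \linkS4class{FeatureTable}.
#' @export
generateFeatureTable <- function(spec, blank_contaminant_fraction = 0,
                                 n_batches = 5) {
  validObject(spec)
  if (blank_contaminant_fraction < 0 || blank_contaminant_fraction > 1)
    stop("blank_contaminant_fraction must be in [0,1]")
  months <- cohortMonths(spec)
  event_idx <- seq(1, length(months), by = 2)  # bimonthly events
  events <- months[event_idx]
  n_ev <- length(events)
  batch_of_event <- paste0("B", ceiling(seq_len(n_ev) / ceiling(n_ev / n_batches)))

  inj <- do.call(rbind, lapply(seq_len(n_ev), function(e) {
    rbind(
      data.frame(injection_id = sprintf("S_%s_%s", format(events[e], "%Y%m"),
                                        spec@depths),
                 kind = "sample", batch = batch_of_event[e],
                 depth = spec@depths, event_date = events[e],
                 stringsAsFactors = FALSE),
      data.frame(injection_id = sprintf("BL_%s", format(events[e], "%Y%m")),
                 kind = "process_blank", batch = batch_of_event[e],
                 depth = NA_character_, event_date = events[e],
                 stringsAsFactors = FALSE))
  }))
  for (b in unique(batch_of_event)) {
    inj <- rbind(inj, data.frame(
      injection_id = sprintf("POOL_%s_%d", b, 1:2),
      kind = "pool", batch = b, depth = NA_character_,
      event_date = as.Date(NA), stringsAsFactors = FALSE))
  }

  n_feat <- spec@nEntities
  n_seasonal <- round(spec@fractionSeasonal * n_feat)
  classes <- ifelse(seq_len(n_feat) <= n_seasonal,
                    ifelse(spec@partialYearFlags[seq_len(n_feat)],
                           "partial", "seasonal"),
                    "noise")

  X <- matrix(0, n_feat, nrow(inj))
  is_sample <- inj$kind == "sample"
  for (i in seq_len(n_feat)) {
    for (d in spec@depths) {
      cols <- which(is_sample & inj$depth == d)
      ser <- generateEntitySeries(spec, i, d)
      X[i, cols] <- seriesValues(ser)[match(inj$event_date[cols], months)]
    }
  }

  .withSeed(.subSeed(spec@seed, 999983), {
    contaminant <- rep(FALSE, n_feat)
    k <- round(blank_contaminant_fraction * n_feat)
    if (k > 0) contaminant[sample.int(n_feat, k)] <- TRUE
    blank_cols <- which(inj$kind == "process_blank")
    pool_cols <- which(inj$kind == "pool")
    sample_mean <- rowMeans(X[, is_sample, drop = FALSE])
    for (i in which(contaminant))
      X[i, blank_cols] <- sample_mean[i] * stats::runif(length(blank_cols), 1, 1.5)
    for (i in seq_len(n_feat))
      X[i, pool_cols] <- pmax(sample_mean[i] *
        (1 + stats::rnorm(length(pool_cols), 0, 0.02)), 0)

    feats <- data.frame(
      feature_id = sprintf("F%04d", seq_len(n_feat)),
      mz = sort(stats::runif(n_feat, 100, 1000)),
      rt = stats::runif(n_feat, 60, 540),
      peak_width = stats::runif(n_feat, 3, 14),
      median_rt_range = stats::runif(n_feat, 0, 4.5),
      isotope_flag = FALSE, adduct_flag = FALSE, stringsAsFactors = FALSE)

    gt <- data.frame(feature_id = feats$feature_id, class = classes,
                     contaminant = contaminant,
                     period = ifelse(classes == "noise", NA_real_,
                                     spec@periodMonths),
                     peak_month = ifelse(classes == "noise", NA_integer_,
                                         spec@peakMonth),
                     stringsAsFactors = FALSE)
    FeatureTable(X, feats, inj, metadata = list(ground_truth = gt))
  })
}

#' SyntheticCommunitySpec: design of a synthetic metagenome KO table
#'
#' Emulates contig-level KO annotation tables: per sample, \code{S_true}
#' taxa each carry exactly one contig per single-copy marker gene (SCMG),
#' and each target KO is carried by \code{ceiling(carrier_fraction *
#' S_true)} taxa with relative contributions drawn from a symmetric
#' Dirichlet with concentration \code{contribution_skew}
#' (\code{Inf} = exactly equal shares).
#'
#' @slot nSamples sample count.
#' @slot STrue taxa per sample.
#' @slot scmgIds the 10 SCMG KO identifiers.
#' @slot koIds target KO identifiers.
#' @slot carrierFraction fraction of taxa carrying each target KO, (0,1].
#' @slot contributionSkew Dirichlet concentration (Inf = equal shares).
#' @slot seasonLabels per-sample season labels.
#' @slot rpkmScale abundance scale.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticCommunitySpec", representation(
  nSamples = "integer", STrue = "integer", scmgIds = "character",
  koIds = "character", carrierFraction = "numeric",
  contributionSkew = "numeric", seasonLabels = "character",
  rpkmScale = "numeric", seed = "integer"))

setValidity("SyntheticCommunitySpec", function(object) {
  msg <- character()
  if (object@STrue < 1) msg <- c(msg, "S_true must be >= 1")
  if (object@carrierFraction <= 0 || object@carrierFraction > 1)
    msg <- c(msg, "carrier_fraction must be in (0,1]")
  if (object@nSamples < 1) msg <- c(msg, "n_samples must be >= 1")
  if (length(object@seasonLabels) != object@nSamples)
    msg <- c(msg, "season_labels must have length n_samples")
  if (length(msg)) msg else TRUE
})

# the 10 SCMG KOs searched in the metagenomes
.DEFAULT_SCMGS <- c("K01409", "K01869", "K01873", "K01875", "K01883",
                    "K01887", "K01889", "K03106", "K03110", "K06942")

#' Construct a SyntheticCommunitySpec
#'
#' @param n_samples,S_true,scmg_ids,ko_ids,carrier_fraction,contribution_skew
#'   see class docs.
#' @param season_labels per-sample seasons (recycled if length 1).
#' @param rpkm_scale abundance units.
#' @param seed RNG seed.
#' @return a validated \linkS4class{SyntheticCommunitySpec}.
#' @export
communitySpec <- function(n_samples = 4, S_true = 10,
                          scmg_ids = .DEFAULT_SCMGS,
                          ko_ids = c("K00135", "K13057"),
                          carrier_fraction = 1, contribution_skew = Inf,
                          season_labels = "summer_stratified",
                          rpkm_scale = 100, seed = 1L) {
  if (length(season_labels) == 1)
    season_labels <- rep(season_labels, n_samples)
  new("SyntheticCommunitySpec", nSamples = as.integer(n_samples),
      STrue = as.integer(S_true), scmgIds = scmg_ids, koIds = ko_ids,
      carrierFraction = carrier_fraction,
      contributionSkew = contribution_skew, seasonLabels = season_labels,
      rpkmScale = rpkm_scale, seed = as.integer(seed))
}

#' Generate a synthetic contig-level KO table
#'
#' Returns a data.frame with one row per contig annotation (columns
#' \code{sample_id}, \code{contig_id}, \code{ko_id}, \code{rpkm},
#' \code{taxon}, \code{is_scmg}, \code{scmg_pass}, \code{evalue},
#' \code{season}, \code{role}). Every taxon carries exactly one contig per
#' SCMG KO. The ground-truth contribution evenness per (sample, KO),
#' computed from the drawn carrier shares with S = \code{S_true}, is
#' attached as \code{attr(x, "ground_truth")}.
#'
#' @param spec a \linkS4class{SyntheticCommunitySpec}.
#' @param ko_roles optional named character vector mapping target KO ids to
#'   a role label (e.g. "product"/"reactant"); default "none".
#' @return data.frame of contig records with a ground-truth attribute.
#' @export
generateKOTable <- function(spec, ko_roles = NULL) {
  validObject(spec)
  .withSeed(spec@seed, {
    recs <- list()
    gt <- list()
    for (s in seq_len(spec@nSamples)) {
      sid <- sprintf("M%02d", s)
      taxa <- sprintf("Clade%02d", seq_len(spec@STrue))
      # one contig per taxon per SCMG, score-threshold pass flag set
      for (ko in spec@scmgIds) {
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = sid,
          contig_id = sprintf("%s_%s_%s", sid, taxa, ko),
          ko_id = ko,
          rpkm = spec@rpkmScale * exp(stats::rnorm(spec@STrue, 0, 0.3)),
          taxon = taxa, is_scmg = TRUE, scmg_pass = TRUE,
          evalue = NA_real_, season = spec@seasonLabels[s],
          role = "none", stringsAsFactors = FALSE)
      }
      n_car <- ceiling(spec@carrierFraction * spec@STrue)
      for (ko in spec@koIds) {
        carriers <- sort(sample.int(spec@STrue, n_car))
        shares <- if (is.infinite(spec@contributionSkew)) rep(1 / n_car, n_car)
                  else {
                    g <- stats::rgamma(n_car, shape = spec@contributionSkew)
                    g / sum(g)
                  }
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = sid,
          contig_id = sprintf("%s_%s_%s", sid, taxa[carriers], ko),
          ko_id = ko, rpkm = spec@rpkmScale * shares,
          taxon = taxa[carriers], is_scmg = FALSE, scmg_pass = NA,
          evalue = 10^stats::runif(n_car, -30, -11),
          season = spec@seasonLabels[s],
          role = if (!is.null(ko_roles) && ko %in% names(ko_roles))
                   ko_roles[[ko]] else "none",
          stringsAsFactors = FALSE)
        gt[[length(gt) + 1]] <- data.frame(
          sample_id = sid, ko_id = ko,
          CE_true = .ceFromShares(shares, spec@STrue),
          n_carriers = n_car, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "ground_truth") <- do.call(rbind, gt)
    out
  })
}

# independent-of-pipeline CE from raw shares (used for ground truth)
.ceFromShares <- function(shares, S) {
  p <- shares[shares > 0] / sum(shares)
  D <- exp(-sum(p * log(p)))
  if (S == 1) return(1)
  .snapUnit(max(0, min(1, (D - 1) / (S - 1))))
}

# exp/log round-trips miss the CE endpoints by ~1e-16; snap them
.snapUnit <- function(x, tol = 1e-12) {
  if (abs(x) < tol) 0 else if (abs(x - 1) < tol) 1 else x
}

#' Write a feature table and its ground truth to plain-text files
#'
#' Writes \code{intensities.tsv}, \code{features.tsv}, \code{injections.tsv}
#' and, when present, a \code{ground_truth.yaml} sidecar.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeFeatureTable <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(intensityMatrix(x), file.path(dir, "intensities.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(featureInfo(x), file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(injectionInfo(x), file.path(dir, "injections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- metadata(x)$ground_truth
  if (!is.null(gt) && requireNamespace("yaml", quietly = TRUE))
    writeLines(yaml::as.yaml(as.list(gt)), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Read a feature table written by \code{writeFeatureTable}
#'
#' @param dir directory containing the TSV files.
#' @return a \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(dir) {
  X <- as.matrix(utils::read.table(file.path(dir, "intensities.tsv"),
                                   sep = "\t", header = TRUE, row.names = 1,
                                   check.names = FALSE))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  inj <- utils::read.table(file.path(dir, "injections.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  inj$event_date <- as.Date(inj$event_date)
  md <- list()
  gt_path <- file.path(dir, "ground_truth.yaml")
  if (file.exists(gt_path) && requireNamespace("yaml", quietly = TRUE))
    md$ground_truth <- as.data.frame(yaml::read_yaml(gt_path),
                                     stringsAsFactors = FALSE)
  FeatureTable(X, feats, inj, metadata = md)
}
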