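mkRecords <- function(sample_id, ko_id, rpkm, taxon = "CladeA",
                      is_scmg = FALSE, scmg_pass = NA, evalue = 1e-12,
                      season = "summer_stratified") {
  n <- max(lengths(list(ko_id, rpkm, taxon)))
  data.frame(sample_id = sample_id,
             contig_id = paste0(sample_id, "_c", seq_len(n)),
             ko_id = rep_len(ko_id, n), rpkm = rep_len(rpkm, n),
             taxon = rep_len(taxon, n), is_scmg = rep_len(is_scmg, n),
             scmg_pass = rep_len(scmg_pass, n),
             evalue = rep_len(evalue, n), season = season, role = "none",
             stringsAsFactors = FALSE)
}

test_that("e-value filter honours the cutoff and the SCMG pass flag", {
  r <- rbind(
    mkRecords("s1", "K00001", 1, evalue = 1e-12),
    mkRecords("s1", "K00002", 1, evalue = 1e-9),
    mkRecords("s1", "K00003", 1, evalue = 1e-10),  # boundary: kept (<=)
    mkRecords("s1", "K01409", 1, is_scmg = TRUE, scmg_pass = FALSE,
              evalue = NA),
    mkRecords("s1", "K01869", 1, is_scmg = TRUE, scmg_pass = TRUE,
              evalue = NA))
  out <- filterByEvalue(r)
  expect_setequal(out$ko_id, c("K00001", "K00003", "K01869"))

  toy <- rbind(mkRecords("s1", paste0("K0000", 1:5), 1,
                         evalue = c(1e-12, 1e-11, 1e-10, 1e-9, 1e-8)),
               mkRecords("s1", paste0("K0001", 1:4), 1,
                         evalue = c(1e-15, 1e-5, 1e-3, 1)))
  expect_equal(nrow(filterByEvalue(toy)), 4)
})

test_that("SCMG richness is the rounded median of per-marker contig counts", {
  scmgs <- c("K01409", "K01869", "K01873", "K01875", "K01883",
             "K01887", "K01889", "K03106", "K03110", "K06942")
  even <- do.call(rbind, lapply(scmgs, function(k) {
    r <- mkRecords("s1", k, rep(1, 50), is_scmg = TRUE, scmg_pass = TRUE,
                   evalue = NA)
    r$contig_id <- paste0(k, "_c", 1:50)
    r
  }))
  expect_equal(scmgRichness(even), 50L)

  counts <- c(48, 49, 50, 50, 50, 50, 50, 51, 52, 60)
  mixed <- do.call(rbind, lapply(seq_along(scmgs), function(i) {
    r <- mkRecords("s1", scmgs[i], rep(1, counts[i]), is_scmg = TRUE,
                   scmg_pass = TRUE, evalue = NA)
    r$contig_id <- paste0(scmgs[i], "_c", seq_len(counts[i]))
    r
  }))
  expect_equal(scmgRichness(mixed), 50L)
  expect_equal(scmgRichness(mixed, method = "sum"), sum(counts))

  single <- mkRecords("s1", "K01409", rep(1, 30), is_scmg = TRUE,
                      scmg_pass = TRUE, evalue = NA)
  single$contig_id <- paste0("c", 1:30)
  expect_equal(scmgRichness(single), 30L)

  expect_error(scmgRichness(mkRecords("s1", "K00001", 1)), "no SCMG")
  # invariant to duplicating non-SCMG records
  expect_equal(scmgRichness(rbind(mixed, mkRecords("s1", "K00001",
                                                   rep(1, 100)))), 50L)
})

test_that("contribution evenness hits its endpoints and closed forms", {
  expect_equal(contributionEvenness(c(5, 0, 0), S = 10), 0)
  expect_equal(contributionEvenness(rep(3, 10), S = 10), 1)
  expect_equal(contributionEvenness(c(1, 1), S = 4), 1 / 3)
  expect_equal(contributionEvenness(7, S = 1), 1)
  # scale invariance
  set.seed(5)
  v <- runif(8)
  expect_equal(contributionEvenness(v * 1e4, S = 12),
               contributionEvenness(v, S = 12))
  expect_error(contributionEvenness(c(0, 0), S = 5), "zero")
  expect_warning(ce <- contributionEvenness(rep(1, 10), S = 5), "clipped")
  expect_equal(ce, 1)
})

test_that("CE is Schur-concave under Robin Hood transfers", {
  set.seed(6)
  for (i in 1:100) {
    v <- sort(rgamma(6, 1), decreasing = TRUE) + 1e-6
    eps <- runif(1, 0, (v[1] - v[6]) / 2)
    w <- v
    w[1] <- w[1] - eps
    w[6] <- w[6] + eps
    expect_gte(contributionEvenness(w, S = 10) + 1e-12,
               contributionEvenness(v, S = 10))
  }
})

test_that("pipeline CE recovers the generator's ground truth", {
  spec <- communitySpec(n_samples = 6, S_true = 25, carrier_fraction = 0.4,
                        contribution_skew = 0.5, seed = 11)
  ko <- generateKOTable(spec)
  gt <- attr(ko, "ground_truth")
  ce <- ceTable(filterByEvalue(ko))
  merged <- merge(ce, gt, by = c("sample_id", "ko_id"))
  expect_equal(nrow(merged), nrow(gt))
  expect_equal(merged$CE, merged$CE_true, tolerance = 1e-12)
  expect_true(all(merged$S == 25))
})

test_that("core genes require strictly >85% sample presence", {
  all28 <- do.call(rbind, lapply(1:28, function(i) rbind(
    mkRecords(paste0("s", i), "K00244", 1),
    if (i <= 24) mkRecords(paste0("s", i), "K13057", 1))))
  core <- coreGenePresence(all28)
  expect_true(core$is_core[core$ko_id == "K00244"])
  expect_equal(core$present_fraction[core$ko_id == "K13057"], 24 / 28)
  expect_true(core$is_core[core$ko_id == "K13057"])  # 0.857 > 0.85

  exact <- do.call(rbind, lapply(1:20, function(i) rbind(
    mkRecords(paste0("s", i), "K00001", 1),
    if (i <= 17) mkRecords(paste0("s", i), "K00002", 1))))
  core2 <- coreGenePresence(exact)
  expect_equal(core2$present_fraction[core2$ko_id == "K00002"], 0.85)
  expect_false(core2$is_core[core2$ko_id == "K00002"])
})

test_that("functional taxonomy aggregates RPKM shares by taxon", {
  r <- rbind(mkRecords("s1", "K00135", c(30, 70), taxon = c("Alpha", "Gamma")),
             mkRecords("s2", "K00135", 10, taxon = "Alpha"),
             mkRecords("s2", "K13057", c(5, 5), taxon = c("Alpha",
                                                          "unannotated")))
  ftx <- functionalTaxonomy(r)
  c1 <- ftx$contributions
  expect_equal(c1$relative_contribution[c1$sample_id == "s1" &
                                          c1$taxon == "Alpha"], 0.3)
  expect_equal(c1$relative_contribution[c1$sample_id == "s1" &
                                          c1$taxon == "Gamma"], 0.7)
  # single annotated taxon takes share 1; unannotated excluded
  expect_equal(c1$relative_contribution[c1$sample_id == "s2" &
                                          c1$ko_id == "K13057"], 1)
  expect_equal(ftx$display_taxa, "Alpha")  # present in two samples

  # seeded synthetic table vs brute-force group-by
  spec <- communitySpec(n_samples = 4, S_true = 12, carrier_fraction = 0.5,
                        contribution_skew = 1, seed = 13)
  ko <- filterByEvalue(generateKOTable(spec))
  ftx2 <- functionalTaxonomy(ko)
  tgt <- ko[!ko$is_scmg, ]
  for (r_i in sample(nrow(ftx2$contributions), 10)) {
    row <- ftx2$contributions[r_i, ]
    sub <- tgt[tgt$sample_id == row$sample_id & tgt$ko_id == row$ko_id, ]
    expect_equal(row$relative_contribution,
                 sum(sub$rpkm[sub$taxon == row$taxon]) / sum(sub$rpkm))
  }
})

test_that("rank-sum comparisons match exact enumeration and detect shifts", {
  two <- function(a, b) c(rep("A", length(a)), rep("B", length(b)))
  expect_warning(res <- ceWilcoxon(rep(0.5, 10),
                                   two(1:5, 1:5)), "tied")
  expect_equal(res$p_value, 1)

  a <- seq(0.01, 0.10, by = 0.01)
  b <- seq(0.51, 0.60, by = 0.01)
  res2 <- ceWilcoxon(c(a, b), two(a, b), p_threshold = 0.01)
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res2$significant)

  # power at n = 12/group for a 0.2 CE shift
  set.seed(17)
  hits <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    g1 <- pmin(pmax(rnorm(12, 0.3, 0.1), 0), 1)
    g2 <- pmin(pmax(rnorm(12, 0.5, 0.1), 0), 1)
    if (ceWilcoxon(c(g1, g2), two(g1, g2),
                   p_threshold = 0.05)$significant) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.8)
})

test_that("group tests run per metabolite and per season", {
  spec <- communitySpec(n_samples = 12, S_true = 20, carrier_fraction = 0.8,
                        contribution_skew = 5,
                        ko_ids = c("K00135", "K00244", "K13057"),
                        season_labels = rep(c("summer_stratified",
                                              "winter_mixed"), 6),
                        seed = 19)
  ce <- ceTable(filterByEvalue(generateKOTable(spec)))
  ko_map <- c(K00135 = "succinate", K00244 = "succinate",
              K13057 = "trehalose")
  met <- ceGroupTests(ce, "metabolite", ko_map = ko_map)
  expect_equal(met$comparison, "succinate vs trehalose")
  expect_true(met$p_value >= 0 && met$p_value <= 1)

  seas <- ceGroupTests(ce, "season")
  expect_equal(sort(seas$comparison), c("K00135", "K00244", "K13057"))
  expect_true(all(seas$p_value >= 0 & seas$p_value <= 1))
})
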