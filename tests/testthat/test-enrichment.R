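# Fisher 2x2, category enrichment, combo-score interval enrichment, Wilcoxon.

test_that("fisher_exact_2x2 matches enumeration oracles and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), list(odds_ratio = 1, p_two_tailed = 1))
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p_two_tailed, 1 / 3)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p_two_tailed, 34 / 70, tolerance = 1e-12)
  expect_identical(fisher_exact_2x2(3, 0, 1, 3)$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(0, 2, 3, 0)$odds_ratio, 0)
  expect_true(is.na(fisher_exact_2x2(0, 3, 0, 3)$odds_ratio))
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")

  # exhaustive check against the independent choose() enumeration oracle and
  # fisher.test for all tables with margins <= 9
  for (m1 in 0:9) for (m2 in 0:9) {
    if (m1 + m2 == 0) next
    for (k in 0:(m1 + m2)) for (a in max(0, k - m2):min(k, m1)) {
      b <- m1 - a; c <- k - a; d <- m2 - c
      got <- fisher_exact_2x2(a, b, c, d)$p_two_tailed
      expect_equal(got, fisher_enumerate(a, b, c, d), tolerance = 1e-12)
      expect_equal(got,
                   fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                   tolerance = 1e-9)
    }
  }

  # random larger tables with margins <= 30
  set.seed(4)
  for (i in 1:200) {
    m1 <- sample(0:30, 1); m2 <- sample(0:30, 1)
    if (m1 + m2 == 0) next
    k <- sample(0:(m1 + m2), 1)
    a_range <- max(0, k - m2):min(k, m1)
    a <- a_range[sample.int(length(a_range), 1)]
    b <- m1 - a; c <- k - a; d <- m2 - c
    expect_equal(fisher_exact_2x2(a, b, c, d)$p_two_tailed,
                 fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("swapping the 2x2 columns inverts the odds ratio, p unchanged", {
  set.seed(5)
  for (i in 1:25) {
    t4 <- sample(0:15, 4, replace = TRUE)
    if (sum(t4) == 0) next
    f1 <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])
    f2 <- fisher_exact_2x2(t4[2], t4[1], t4[4], t4[3])
    expect_equal(f1$p_two_tailed, f2$p_two_tailed, tolerance = 1e-12)
    if (!is.na(f1$odds_ratio) && is.finite(f1$odds_ratio) && f1$odds_ratio > 0)
      expect_equal(f2$odds_ratio, 1 / f1$odds_ratio, tolerance = 1e-12)
  }
})

test_that("probe category enrichment flags constructed extremes, not nulls", {
  set.seed(6)
  n_bg <- 4000
  cats <- sample(names(sim_config()$category_freqs), n_bg, replace = TRUE,
                 prob = sim_config()$category_freqs)
  ann <- toy_manifest("chr1", seq_len(n_bg) * 100,
                      probe_id = sprintf("cg%05d", seq_len(n_bg)))
  ann$region_category <- cats

  # all-TSS200 signature against a ~10% TSS200 background
  tss <- ann$probe_id[ann$region_category == "TSS200"][1:60]
  enr <- probe_category_enrichment(tss, ann)
  expect_identical(enr$direction[enr$feature == "TSS200"], "enriched")
  expect_identical(enr$direction[enr$feature == "Body"], "depleted")
  expect_gt(enr$tier[enr$feature == "TSS200"], 0)
  # 2x2 construction consistency: a+b is the signature, a+c the category
  expect_true(all(enr$a + enr$b == 60))
  expect_equal(enr$a + enr$c,
               as.integer(table(factor(ann$region_category,
                                       levels = enr$feature))[enr$feature]))

  # uniformly drawn signatures should essentially never earn tiers
  tiers <- vapply(1:20, function(s) {
    set.seed(s)
    sig <- sample(ann$probe_id, 60)
    sum(probe_category_enrichment(sig, ann)$tier > 0)
  }, numeric(1))
  expect_lte(mean(tiers > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / 20))

  expect_error(probe_category_enrichment(character(0), ann), "empty signature")
})

test_that("DMR feature enrichment applies the strict >50% overlap rule", {
  dm <- data.frame(chrom = "chr1", start = c(1000L, 3000L),
                   end = c(2000L, 4000L), n_cpgs = 5L,
                   mean_delta_beta = 0.15, direction = "hyper",
                   fisher_p = 1e-6, fisher_q = 1e-6, stouffer_p = 1e-6,
                   probe_ids = "x", stringsAsFactors = FALSE)
  extent <- c(chr1 = 100000)
  # covers 60% of DMR 1 and exactly 50% of DMR 2
  feats <- list(TSS1500 = GenomicRanges::GRanges("chr1",
                  IRanges::IRanges(start = c(1001, 3001), end = c(1600, 3500))))
  hit <- episignr:::overlap_fraction(episignr:::dmr_granges(dm), feats$TSS1500)
  expect_equal(hit, c(0.6, 0.5))
  enr <- dmr_feature_enrichment(dm, feats, extent, n_draws = 200, seed = 1)
  expect_identical(enr$a, 1L)   # only the 60% DMR is a hit

  # saturation: a category covering the whole genome gives OR ~ 1
  full <- list(Body = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000)))
  enr_full <- dmr_feature_enrichment(dm, full, extent, n_draws = 200, seed = 1)
  expect_equal(enr_full$odds_ratio, 1, tolerance = 1e-9)

  bad <- dm; bad$end[1] <- 200000L
  expect_error(dmr_feature_enrichment(bad, feats, extent), "genome extent")
})

test_that("combo scores are signed enrichment measures with a centered null", {
  extent <- c(chr1 = 1e6)
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1000, 90000, by = 10000),
                                                       width = 500))
  self <- giggle_score(q, q, extent)
  expect_gt(self$odds_ratio, 1)
  expect_gt(self$combo_score, 0)
  expect_identical(self$direction, "enriched")

  # OR of exactly 1 zeroes the combo score
  even <- giggle_score(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1001), width = 100)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(50, 5001), width = 10)),
    extent)
  if (!is.na(even$odds_ratio) && even$odds_ratio == 1)
    expect_equal(even$combo_score, 0)

  # random placement: mean combo score within 3 SE of zero over 20 seeds
  ref <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1, 1e6 - 2000, by = 5000),
                                                         width = 1000))
  scores <- vapply(1:20, function(s) {
    set.seed(s)
    qq <- episignr:::random_intervals(rep(800, 30), extent, 30)
    giggle_score(qq, ref, extent)$combo_score
  }, numeric(1))
  expect_lt(abs(mean(scores)), 3 * sd(scores) / sqrt(20))

  expect_error(giggle_score(q[0], q, extent), "non-empty")
  expect_error(giggle_score(q, q, c(chr1 = 0)), "zero genome extent")
})

test_that("Wilcoxon p-values match rank-split enumeration and the large-n limit", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)),
               wilcoxon_enumerate(c(1, 2), c(3, 4)))
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5)), 1)  # all tied

  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_enumerate(x, y),
                 tolerance = 1e-12)
  }

  # the tie-corrected normal approximation tracks the exact branch at n=20+20
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    exact <- wilcox.test(x, y, exact = TRUE)$p.value
    approx <- wilcoxon_rank_sum(x, y, exact_below = 2)
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("chromatin-state profiles rank planted promoter DMRs correctly", {
  cfg <- sim_config(n_probes = 4000, n_controls = 60, n_signal_regions = 6,
                    n_signal_probes = 120, seed = 30, n_epigenomes = 5)
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  epi <- simulate_epigenomes(cfg, man)
  sheet <- sim$sheet
  mc <- match_controls(sheet[sheet$group == "case", ],
                       sheet[sheet$group == "control", ], ratio = 7)
  ids <- c(mc$case_ids, mc$control_ids)
  st <- probe_stats(sim$beta[, ids], ids %in% mc$case_ids)
  dm <- find_dmrs(st, man)
  expect_gt(nrow(dm), 0)
  prof <- chromatin_state_profile(dm, epi, attr(man, "chrom_lengths"))
  expect_identical(names(prof$medians)[1], "Active TSS")
  expect_identical(names(prof$medians)[length(prof$medians)], "Quiescent")
  # identical distributions compare with adjusted p of 1
  fake <- prof$scores
  pw_same <- wilcoxon_rank_sum(fake$combo_score[fake$state == "Heterochromatin"],
                               fake$combo_score[fake$state == "Heterochromatin"])
  expect_equal(pw_same, 1)
  expect_true(all(prof$pairwise$adj_p >= prof$pairwise$p - 1e-12))
})
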