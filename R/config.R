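#' Pipeline configuration
#'
#' Collects every tunable threshold of the episignature pipeline with its
#' default. Defaults follow the published analysis protocol: arrays with more
#' than 5% failed probes are excluded (strictly greater), controls are drawn
#' at a 7:1 ratio to cases, differentially methylated probes require
#' BH-adjusted q < 0.01 and |delta-beta| > 0.10, the selection funnel keeps
#' the 1000 highest effect-size-by-p-value probes, the 500 best per-probe ROC
#' discriminators, and then prunes probes whose pairwise Pearson correlation
#' exceeds 0.9. DMRs require at least five CpGs with inter-probe gaps of at
#' most 1 kb, a region mean |delta-beta| of at least 0.10 and a BH-adjusted
#' Fisher combined p below 0.01. Interval enrichment counts a region as
#' hitting a feature when more than 50% of its length is covered.
#'
#' @param failure_rate_max Maximum tolerated per-sample probe failure
#'   fraction; samples strictly above are dropped.
#' @param control_ratio Matched controls per case.
#' @param fdr_max BH-adjusted q-value cut-off for DMP calling (strict `<`).
#' @param delta_beta_min Minimum |delta-beta| for DMP calling (strict `>`).
#' @param n_candidates Funnel stage 1 size (effect x p-value ranking).
#' @param n_roc Funnel stage 2 size (per-probe ROC AUC ranking).
#' @param r_max Maximum tolerated pairwise Pearson |r| in the final set.
#' @param dmr_min_cpgs,dmr_max_gap,dmr_p_max,dmr_delta_min DMR criteria:
#'   minimum CpG count, maximum inter-probe gap in bp, BH-adjusted Fisher
#'   combined p cut-off (strict `<`), minimum region mean |delta-beta|
#'   (non-strict `>=`).
#' @param overlap_fraction_min Fraction of a region's length that must be
#'   covered by a feature to count as a hit (strict `>`).
#' @param train_fraction Fraction of each background pool used to train the
#'   MVP classifier.
#' @param rank_p Which p-value feeds the stage-1 score: `"raw"` (default) or
#'   `"adjusted"`.
#' @param svm_cost Soft-margin cost of the linear-kernel SVM.
#' @param seed Integer seed governing all stochastic steps.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(failure_rate_max = 0.05,
                            control_ratio = 7L,
                            fdr_max = 0.01,
                            delta_beta_min = 0.10,
                            n_candidates = 1000L,
                            n_roc = 500L,
                            r_max = 0.9,
                            dmr_min_cpgs = 5L,
                            dmr_max_gap = 1000L,
                            dmr_p_max = 0.01,
                            dmr_delta_min = 0.10,
                            overlap_fraction_min = 0.5,
                            train_fraction = 0.75,
                            rank_p = c("raw", "adjusted"),
                            svm_cost = 1,
                            seed = 1L) {
  rank_p <- match.arg(rank_p)
  stopifnot(failure_rate_max > 0, failure_rate_max < 1,
            control_ratio >= 1, fdr_max > 0, fdr_max < 1,
            delta_beta_min >= 0, delta_beta_min < 1,
            n_candidates >= 1, n_roc >= 1, n_roc <= n_candidates,
            r_max > 0, r_max <= 1,
            dmr_min_cpgs >= 2, dmr_max_gap > 0,
            dmr_p_max > 0, dmr_p_max < 1,
            overlap_fraction_min >= 0, overlap_fraction_min < 1,
            train_fraction > 0, train_fraction < 1, svm_cost > 0)
  structure(list(failure_rate_max = failure_rate_max,
                 control_ratio = as.integer(control_ratio),
                 fdr_max = fdr_max,
                 delta_beta_min = delta_beta_min,
                 n_candidates = as.integer(n_candidates),
                 n_roc = as.integer(n_roc),
                 r_max = r_max,
                 dmr_min_cpgs = as.integer(dmr_min_cpgs),
                 dmr_max_gap = as.integer(dmr_max_gap),
                 dmr_p_max = dmr_p_max,
                 dmr_delta_min = dmr_delta_min,
                 overlap_fraction_min = overlap_fraction_min,
                 train_fraction = train_fraction,
                 rank_p = rank_p,
                 svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Synthetic cohort configuration
#'
#' Parameters of the EPIC-like cohort generator. The defaults define the
#' package's desk-scale study geometry: 20,000 probes on 4 synthetic
#' chromosomes, 8 cases against a 200-sample control pool (from which 56
#' age/sex matched controls are drawn at the 7:1 ratio), two confounder
#' cohorts of 20 samples carrying unrelated signatures, 300 planted signal
#' probes with beta-scale effects between 0.10 and 0.20 (all
#' hypermethylating by default), and logit-scale Gaussian noise with
#' standard deviation 0.15.
#'
#' @param n_probes Total probes (>= 100).
#' @param n_chromosomes Synthetic chromosomes the probes are spread over.
#' @param n_cases,n_controls,n_other_disorders,n_per_other,n_vus Cohort
#'   sizes: cases, control pool, number and size of confounder ("other
#'   disorder") cohorts, and unclassified (VUS) carriers drawn from the case
#'   model with probability `vus_case_fraction`.
#' @param vus_case_fraction Fraction of VUS samples that truly carry the case
#'   signature.
#' @param n_signal_probes Planted differential probes in the case cohort
#'   (region-planted probes count towards this total).
#' @param n_signal_regions Planted differentially methylated regions (probe
#'   clusters receiving one coherent effect).
#' @param delta_beta_range Range of planted |delta-beta| effects.
#' @param fraction_hyper Share of planted effects that increase methylation.
#' @param promoter_bias Sampling-weight multiplier placing signal probes in
#'   promoter categories (TSS200/TSS1500/1stExon/5'UTR).
#' @param noise_sd Logit-scale Gaussian noise standard deviation.
#' @param global_shift Logit-scale background shift applied to all non-signal
#'   probes of case samples (0 disables; negative values emulate slight
#'   global hypomethylation).
#' @param n_cell_types Blood cell types in the mixing model.
#' @param celltype_informative_fraction Fraction of probes on which cell
#'   types differ.
#' @param celltype_sd Logit-scale spread of cell-type profiles at informative
#'   probes.
#' @param celltype_case_shift Relative increase of the first Dirichlet
#'   concentration parameter in cases (cell-composition confounding; 0
#'   disables).
#' @param include_cell_proportions Write the true mixing proportions into the
#'   sample sheet (as `ct_*` columns)?
#' @param category_freqs Named marginal frequencies over the seven
#'   gene-region categories.
#' @param cluster_fraction Fraction of probes placed in CpG-island-like
#'   clusters (5-15 probes, 50-500 bp gaps) rather than isolated (>2 kb
#'   gaps).
#' @param flag_fraction Fraction of probes carrying a QC flag
#'   (sex-chromosome / cross-reactive / SNP-overlap, chosen uniformly).
#' @param det_fail_rate Per-entry detection failure probability (failed
#'   entries are set missing).
#' @param n_epigenomes Synthetic reference epigenomes generated by
#'   [simulate_epigenomes()].
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 20000L,
                       n_chromosomes = 4L,
                       n_cases = 8L,
                       n_controls = 200L,
                       n_other_disorders = 2L,
                       n_per_other = 20L,
                       n_vus = 0L,
                       vus_case_fraction = 0.2,
                       n_signal_probes = 300L,
                       n_signal_regions = 10L,
                       delta_beta_range = c(0.10, 0.20),
                       fraction_hyper = 1.0,
                       promoter_bias = 5,
                       noise_sd = 0.15,
                       global_shift = 0,
                       n_cell_types = 6L,
                       celltype_informative_fraction = 0.10,
                       celltype_sd = 0.8,
                       celltype_case_shift = 0.3,
                       include_cell_proportions = TRUE,
                       category_freqs = c("TSS200" = 0.10, "TSS1500" = 0.12,
                                          "5'UTR" = 0.08, "1stExon" = 0.05,
                                          "Body" = 0.35, "3'UTR" = 0.05,
                                          "IGR" = 0.25),
                       cluster_fraction = 0.6,
                       flag_fraction = 0.05,
                       det_fail_rate = 0,
                       n_epigenomes = 20L,
                       seed = 1L) {
  if (n_probes < 100) stop("n_probes must be at least 100 (selection funnel defaults need headroom)")
  stopifnot(n_chromosomes >= 2, n_cases >= 2, n_controls >= 1,
            fraction_hyper >= 0, fraction_hyper <= 1,
            length(delta_beta_range) == 2,
            delta_beta_range[1] > 0, delta_beta_range[2] < 1,
            delta_beta_range[1] <= delta_beta_range[2],
            noise_sd > 0, promoter_bias > 0,
            n_cell_types >= 2, cluster_fraction >= 0, cluster_fraction <= 1,
            flag_fraction >= 0, flag_fraction < 1,
            det_fail_rate >= 0, det_fail_rate < 1,
            n_epigenomes >= 1,
            vus_case_fraction >= 0, vus_case_fraction <= 1)
  if (!setequal(names(category_freqs), REGION_CATEGORIES))
    stop("category_freqs must be named by the seven region categories")
  category_freqs <- category_freqs[REGION_CATEGORIES] / sum(category_freqs)
  structure(list(n_probes = as.integer(n_probes),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_other_disorders = as.integer(n_other_disorders),
                 n_per_other = as.integer(n_per_other),
                 n_vus = as.integer(n_vus),
                 vus_case_fraction = vus_case_fraction,
                 n_signal_probes = as.integer(n_signal_probes),
                 n_signal_regions = as.integer(n_signal_regions),
                 delta_beta_range = delta_beta_range,
                 fraction_hyper = fraction_hyper,
                 promoter_bias = promoter_bias,
                 noise_sd = noise_sd,
                 global_shift = global_shift,
                 n_cell_types = as.integer(n_cell_types),
                 celltype_informative_fraction = celltype_informative_fraction,
                 celltype_sd = celltype_sd,
                 celltype_case_shift = celltype_case_shift,
                 include_cell_proportions = isTRUE(include_cell_proportions),
                 category_freqs = category_freqs,
                 cluster_fraction = cluster_fraction,
                 flag_fraction = flag_fraction,
                 det_fail_rate = det_fail_rate,
                 n_epigenomes = as.integer(n_epigenomes),
                 seed = as.integer(seed)),
            class = "sim_config")
}
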