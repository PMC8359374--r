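# Feature-category and interval-overlap enrichment: Fisher 2x2 tests for
# gene-region categories, combo-score (log2 OR x -log10 p) interval
# enrichment against reference tracks, and the cross-state comparison.

#' Fisher's exact test on a 2x2 table
#'
#' The odds ratio is the sample odds ratio `(a*d)/(b*c)` (`Inf` when only
#' `b*c` is zero, `NA` when both products vanish); the two-tailed p-value
#' sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (relative tolerance 1e-7).
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = (feature, not
#'   feature) x columns = (query, background).
#' @return List with `odds_ratio` and `p_two_tailed`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("all-zero table")
  or <- if (b * c > 0) (a * d) / (b * c)
  else if (a * d > 0) Inf
  else NA_real_
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_two_tailed = p)
}

star_tier <- function(p, thresholds) sum(p < thresholds)

#' Gene-region enrichment of signature probes
#'
#' For each region category, contrasts the signature probes against the
#' analyzed background by Fisher's exact test. Significance tiers (number of
#' stars) follow the probe-level scale p < 0.01 / 1e-3 / 1e-6 by default; a
#' BH-adjusted q across categories is reported alongside.
#'
#' @param signature_probes Probe ids (must all appear in `ann`).
#' @param ann Probe manifest restricted to the analyzed background.
#' @param tier_thresholds Decreasing p-value thresholds for the star tiers.
#' @return `data.frame` per category: counts a,b,c,d, odds_ratio, p, q, tier,
#'   direction.
#' @export
probe_category_enrichment <- function(signature_probes, ann,
                                      tier_thresholds = c(1e-2, 1e-3, 1e-6)) {
  if (length(signature_probes) == 0L) stop("empty signature")
  if (!all(signature_probes %in% ann$probe_id))
    stop("signature contains probes absent from the annotation")
  sig_cat <- ann$region_category[match(signature_probes, ann$probe_id)]
  bg_tab <- table(factor(ann$region_category, levels = REGION_CATEGORIES))
  cats <- names(bg_tab)[bg_tab > 0]
  n_sig <- length(signature_probes); n_bg <- nrow(ann)
  rows <- lapply(cats, function(cat) {
    a <- sum(sig_cat == cat)
    b <- n_sig - a
    c <- as.integer(bg_tab[[cat]]) - a
    d <- (n_bg - as.integer(bg_tab[[cat]])) - b
    ft <- fisher_exact_2x2(a, b, c, d)
    data.frame(feature = cat, a = a, b = b, c = c, d = d,
               odds_ratio = ft$odds_ratio, p_two_tailed = ft$p_two_tailed,
               direction = enrich_direction(ft$odds_ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_two_tailed)
  out$tier <- vapply(out$p_two_tailed, star_tier, numeric(1),
                     thresholds = sort(tier_thresholds, decreasing = TRUE))
  out
}

enrich_direction <- function(or) {
  if (is.na(or) || or == 1) "none" else if (or > 1) "enriched" else "depleted"
}

# Fraction of each query interval covered by a feature track.
overlap_fraction <- function(query, feats) {
  frac <- numeric(length(query))
  if (length(feats) == 0L) return(frac)
  feats <- GenomicRanges::reduce(feats)
  hits <- GenomicRanges::findOverlaps(query, feats)
  if (length(hits) == 0L) return(frac)
  ov <- GenomicRanges::pintersect(query[S4Vectors::queryHits(hits)],
                                  feats[S4Vectors::subjectHits(hits)])
  w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  frac[as.integer(names(w))] <- as.numeric(w) /
    GenomicRanges::width(query)[as.integer(names(w))]
  frac
}

# Uniform random placement of n intervals with the given lengths on a genome
# described by named chromosome lengths.
random_intervals <- function(lengths, genome_extent, n) {
  len <- sample(lengths, n, replace = TRUE)
  chr_w <- genome_extent / sum(genome_extent)
  chrom <- sample(names(genome_extent), n, replace = TRUE, prob = chr_w)
  max_start <- pmax(genome_extent[chrom] - len, 1)
  start <- floor(runif(n, min = 1, max = max_start + 1))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, width = len))
}

#' Feature enrichment of DMRs by overlap fraction
#'
#' A DMR hits a feature category when strictly more than
#' `min_overlap_fraction` of its length is covered by the category's
#' intervals. The background rate is estimated from `n_draws` random
#' length-matched intervals placed uniformly on the genome (seeded), and the
#' 2x2 of observed vs background hits is Fisher-tested per category. Tiers
#' follow the region-level scale p < 0.05 / 0.01 / 0.001 by default.
#'
#' @param dmrs Output of [find_dmrs()].
#' @param features Named list of `GRanges`, one per category.
#' @param genome_extent Named vector of chromosome lengths (bp).
#' @param min_overlap_fraction Hit threshold (strict `>`).
#' @param n_draws Random background intervals.
#' @param seed Seed for the random placement.
#' @param tier_thresholds Star-tier thresholds.
#' @return `data.frame` per category with counts, odds_ratio, p, q, tier,
#'   direction.
#' @export
dmr_feature_enrichment <- function(dmrs, features, genome_extent,
                                   min_overlap_fraction = 0.5,
                                   n_draws = 1000L, seed = 1L,
                                   tier_thresholds = c(0.05, 0.01, 0.001)) {
  if (nrow(dmrs) == 0L) stop("no DMRs to test")
  gr <- dmr_granges(dmrs)
  if (!all(as.character(GenomicRanges::seqnames(gr)) %in% names(genome_extent)))
    stop("DMRs outside the genome extent")
  if (any(dmrs$end > genome_extent[dmrs$chrom]))
    stop("DMRs outside the genome extent")
  null_gr <- with_seed(seed,
                       random_intervals(GenomicRanges::width(gr), genome_extent, n_draws))
  rows <- lapply(names(features), function(cat) {
    obs_hit <- overlap_fraction(gr, features[[cat]]) > min_overlap_fraction
    null_hit <- overlap_fraction(null_gr, features[[cat]]) > min_overlap_fraction
    a <- sum(obs_hit); b <- length(gr) - a
    c <- sum(null_hit); d <- n_draws - c
    ft <- fisher_exact_2x2(a, b, c, d)
    or <- ft$odds_ratio
    # saturation: identical hit profiles in both columns carry no signal
    if (is.na(or) && ((a == 0 && c == 0) || (b == 0 && d == 0))) or <- 1
    data.frame(feature = cat, a = a, b = b, c = c, d = d,
               odds_ratio = or, p_two_tailed = ft$p_two_tailed,
               direction = enrich_direction(or),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_two_tailed)
  out$tier <- vapply(out$p_two_tailed, star_tier, numeric(1),
                     thresholds = sort(tier_thresholds, decreasing = TRUE))
  out
}

#' Gene-region interval tracks from a probe manifest
#'
#' Builds one interval track per region category by padding each probe
#' position and merging overlapping intervals, so that region-level
#' (overlap-fraction) analyses can be run against a manifest that annotates
#' probes rather than intervals.
#'
#' @param ann Probe manifest (1-based positions).
#' @param pad Bases added on each side of every probe.
#' @return Named list of `GRanges`, one per category present.
#' @export
category_tracks <- function(ann, pad = 100L) {
  lapply(split(ann, ann$region_category), function(sub) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$chrom,
      IRanges::IRanges(start = pmax(sub$position - pad, 1),
                       end = sub$position + pad)))
  })
}

#' Combo-score interval enrichment
#'
#' Scores the enrichment of a query interval set within a reference track by
#' the combo score `sign(ln OR) * |log2 OR| * (-log10 p)`, where the 2x2
#' table is built from overlap counts: `a` = query intervals overlapping the
#' reference, `b` = query intervals not overlapping, `c` = reference
#' intervals not overlapped, and `d` fills the table up to the number of
#' genomic slots, defined as the total genome length divided by the width of
#' the window in which two intervals can touch (mean query length plus mean
#' reference length, the choice that centers the score at zero under uniform
#' random placement), floored at `a + b + c + 1`. Zero cells are offset by
#' 0.5 for the odds ratio only.
#'
#' @param query,reference Non-empty `GRanges`.
#' @param genome_extent Named chromosome lengths (bp).
#' @return List with the 2x2 counts, `odds_ratio`, `p_two_tailed`,
#'   `combo_score`, `direction`.
#' @export
giggle_score <- function(query, reference, genome_extent) {
  if (length(query) == 0L || length(reference) == 0L)
    stop("query and reference must be non-empty")
  total <- sum(genome_extent)
  if (total <= 0) stop("zero genome extent")
  a <- sum(IRanges::overlapsAny(query, reference))
  b <- length(query) - a
  cc <- sum(!IRanges::overlapsAny(reference, query))
  window <- mean(GenomicRanges::width(query)) + mean(GenomicRanges::width(reference))
  n_slots <- max(floor(total / window), a + b + cc + 1)
  d <- n_slots - a - b - cc
  ft <- fisher_exact_2x2(a, b, cc, d)
  or <- ft$odds_ratio
  or_adj <- if (!is.na(or) && is.finite(or) && or > 0 && b * cc > 0 && a * d > 0) or
  else ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  combo <- sign(log(or_adj)) * abs(log2(or_adj)) *
    (-log10(max(ft$p_two_tailed, 1e-300)))
  list(a = a, b = b, c = cc, d = d,
       odds_ratio = or, p_two_tailed = ft$p_two_tailed,
       combo_score = combo, direction = enrich_direction(or_adj))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration (via the null rank-sum distribution) when the combined
#' sample size is below `exact_below` and there are no ties; otherwise the
#' continuity-corrected normal approximation with midranks and tie-corrected
#' variance. A zero-variance comparison (all values tied) returns p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_below Combined-size threshold for the exact branch.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below = 50L) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(x) + length(y) < exact_below && !ties)
    return(wilcox.test(x, y, exact = TRUE)$p.value)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (v <= 0) return(1)
  min(1, 2 * pnorm(-max(abs(u - mu) - 0.5, 0) / sqrt(v)))
}

#' Chromatin-state enrichment profile of DMRs
#'
#' Computes the combo score of the DMR set against every chromatin-state
#' track of every reference epigenome, then compares the per-state score
#' distributions by pairwise two-sided Wilcoxon rank-sum tests with BH
#' adjustment. A state absent from an epigenome is scored 0 and flagged.
#'
#' @param dmrs Output of [find_dmrs()].
#' @param epigenomes List (>= 2) of `GRanges` with a `label` column holding
#'   the state of each segment.
#' @param genome_extent Named chromosome lengths (bp).
#' @param states State vocabulary (default [chromatin_states()]).
#' @return List with `scores` (epigenome x state long table), `medians`
#'   (named per-state median combo score, decreasing), and `pairwise`
#'   (state pairs with raw and BH-adjusted Wilcoxon p).
#' @export
chromatin_state_profile <- function(dmrs, epigenomes, genome_extent,
                                    states = chromatin_states()) {
  if (length(epigenomes) < 2L) stop("need at least 2 epigenomes")
  gr <- dmr_granges(dmrs)
  rows <- list()
  for (e in seq_along(epigenomes)) {
    epi <- epigenomes[[e]]
    lab <- S4Vectors::mcols(epi)$label
    for (st in states) {
      track <- epi[lab == st]
      if (length(track) == 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(epigenome = e, state = st, combo_score = 0,
                     odds_ratio = NA_real_, p_two_tailed = NA_real_,
                     missing = TRUE, stringsAsFactors = FALSE)
      } else {
        g <- giggle_score(gr, track, genome_extent)
        rows[[length(rows) + 1L]] <-
          data.frame(epigenome = e, state = st, combo_score = g$combo_score,
                     odds_ratio = g$odds_ratio, p_two_tailed = g$p_two_tailed,
                     missing = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, rows)
  med <- sort(tapply(scores$combo_score, scores$state, median), decreasing = TRUE)
  prs <- utils::combn(states, 2L)
  pw <- data.frame(state1 = prs[1, ], state2 = prs[2, ],
                   p = apply(prs, 2L, function(pr)
                     wilcoxon_rank_sum(scores$combo_score[scores$state == pr[1]],
                                       scores$combo_score[scores$state == pr[2]])),
                   stringsAsFactors = FALSE)
  pw$adj_p <- bh_adjust(pw$p)
  list(scores = scores, medians = med, pairwise = pw)
}
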