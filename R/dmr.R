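# Differentially methylated region calling: seed-and-extend grouping of
# probes into runs, Fisher / Stouffer p-value combination, and a recovery
# report against planted simulation truth.

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p))` referred to the upper tail of a chi-square with
#' `2k` degrees of freedom.
#'
#' @param p Vector of p-values in (0, 1\].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L) stop("no p-values to combine")
  stopifnot(all(p > 0 & p <= 1))
  x <- -2 * sum(log(p))
  pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Stouffer's method for combining p-values
#'
#' Sums normal quantiles `z_i = qnorm(1 - p_i)` with optional weights:
#' `Z = sum(w z) / sqrt(sum(w^2))`, combined p `= 1 - pnorm(Z)`.
#'
#' @param p Vector of p-values in (0, 1) (0 and 1 are rejected: their normal
#'   quantiles are infinite).
#' @param weights Optional non-negative weights (default equal).
#' @return Combined p-value.
#' @export
stouffer_combine <- function(p, weights = NULL) {
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(p <= 0 | p >= 1)) stop("Stouffer's method requires p strictly in (0,1)")
  w <- weights %||% rep(1, length(p))
  stopifnot(length(w) == length(p), all(w >= 0), any(w > 0))
  z <- qnorm(1 - p)
  pnorm(sum(w * z) / sqrt(sum(w^2)), lower.tail = FALSE)
}

#' Call differentially methylated regions
#'
#' Seed-and-extend DMR calling over probe-level statistics: probes on one
#' chromosome whose consecutive gaps are at most `max_gap` bp form candidate
#' runs; a run is reported as a DMR when it has at least `min_cpgs` probes,
#' its unweighted mean delta-beta satisfies `|mean| >= delta_min`, and its
#' BH-adjusted Fisher-combined p-value (adjustment across all size-eligible
#' candidates) is strictly below `p_max`. Stouffer's combined p is reported
#' alongside. Output intervals are 0-based half-open.
#'
#' @param stats Probe-statistics table (needs probe_id, delta_beta, p_value).
#' @param ann Probe manifest (1-based positions); auto-sorted with a warning
#'   when unsorted.
#' @param min_cpgs,max_gap,delta_min,p_max DMR criteria (see
#'   [pipeline_config()]).
#' @return `data.frame` with one row per DMR: chrom, start, end, n_cpgs,
#'   mean_delta_beta, direction, fisher_p, fisher_q, stouffer_p, probe_ids
#'   (semicolon-joined, in genomic order).
#' @export
find_dmrs <- function(stats, ann, min_cpgs = 5L, max_gap = 1000L,
                      delta_min = 0.10, p_max = 0.01) {
  ann <- ann[ann$probe_id %in% stats$probe_id, ]
  if (nrow(ann) == 0L) stop("stats and annotation share no probes")
  if (is.unsorted(order(ann$chrom, ann$position), strictly = FALSE)) {
    o <- order(ann$chrom, ann$position)
    if (!identical(o, seq_len(nrow(ann)))) {
      warning("annotation not position-sorted; sorting")
      ann <- ann[o, ]
    }
  }
  idx <- match(ann$probe_id, stats$probe_id)
  delta <- stats$delta_beta[idx]
  pval <- stats$p_value[idx]

  # split into runs: new run at chromosome change or gap > max_gap
  new_run <- c(TRUE, ann$chrom[-1] != ann$chrom[-nrow(ann)] |
                 diff(ann$position) > max_gap)
  run_id <- cumsum(new_run)
  keep_runs <- which(tabulate(run_id) >= min_cpgs)
  if (length(keep_runs) == 0L) return(empty_dmr_frame())

  cand <- lapply(keep_runs, function(r) {
    i <- which(run_id == r)
    data.frame(chrom = ann$chrom[i[1]],
               start = as.integer(min(ann$position[i])) - 1L,  # 0-based half-open
               end = as.integer(max(ann$position[i])),
               n_cpgs = length(i),
               mean_delta_beta = mean(delta[i]),
               fisher_p = fisher_combine(pval[i]),
               stouffer_p = stouffer_combine(clip01(pval[i], 1e-15)),
               probe_ids = paste(ann$probe_id[i], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  cand$fisher_p <- pmax(cand$fisher_p, .Machine$double.xmin)  # chi-sq tail underflow
  cand$fisher_q <- bh_adjust(cand$fisher_p)
  out <- cand[abs(cand$mean_delta_beta) >= delta_min & cand$fisher_q < p_max, ]
  if (nrow(out) == 0L) return(empty_dmr_frame())
  out$direction <- ifelse(out$mean_delta_beta > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "n_cpgs", "mean_delta_beta", "direction",
          "fisher_p", "fisher_q", "stouffer_p", "probe_ids")]
}

empty_dmr_frame <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             n_cpgs = integer(0), mean_delta_beta = numeric(0),
             direction = character(0), fisher_p = numeric(0),
             fisher_q = numeric(0), stouffer_p = numeric(0),
             probe_ids = character(0), stringsAsFactors = FALSE)
}

dmr_granges <- function(dmrs) {
  GenomicRanges::GRanges(dmrs$chrom,
                         IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end))
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, `-log10(fisher_p)`, strand `"."`, then
#' n_cpgs, mean_delta_beta, stouffer_p.
#'
#' @param dmrs Output of [find_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  out <- data.frame(dmrs$chrom, dmrs$start, dmrs$end,
                    sprintf("DMR_%03d", seq_len(nrow(dmrs))),
                    round(-log10(pmax(dmrs$fisher_p, 1e-300)), 4), ".",
                    dmrs$n_cpgs, dmrs$mean_delta_beta, dmrs$stouffer_p)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compare called DMRs to planted truth
#'
#' Matches called regions to planted regions by any (>= 1 bp) interval
#' overlap and reports sensitivity (planted regions recovered), precision
#' (called regions overlapping planted ones) and direction accuracy (among
#' matched calls, the share whose hyper/hypo direction equals the planted
#' one).
#'
#' @param dmrs Output of [find_dmrs()].
#' @param truth A `SimulationTruth` (see [simulate_cohort()]) or a
#'   `data.frame` of planted regions with chrom, start, end, direction
#'   (0-based half-open).
#' @return List with sensitivity, precision, direction_accuracy, n_called,
#'   n_planted.
#' @export
dmr_recovery_report <- function(dmrs, truth) {
  planted <- if (is.data.frame(truth)) truth else truth$signal_regions
  n_called <- nrow(dmrs); n_planted <- nrow(planted)
  if (n_planted == 0L) stop("no planted regions in truth")
  if (n_called == 0L)
    return(list(sensitivity = 0, precision = NA_real_,
                direction_accuracy = NA_real_,
                n_called = 0L, n_planted = n_planted))
  gr_called <- dmr_granges(dmrs)
  gr_planted <- GenomicRanges::GRanges(planted$chrom,
                                       IRanges::IRanges(start = planted$start + 1L,
                                                        end = planted$end))
  hits <- GenomicRanges::findOverlaps(gr_called, gr_planted)
  sens <- length(unique(S4Vectors::subjectHits(hits))) / n_planted
  prec <- length(unique(S4Vectors::queryHits(hits))) / n_called
  dir_ok <- NA_real_
  if (length(hits) > 0L && !is.null(planted$direction)) {
    agree <- dmrs$direction[S4Vectors::queryHits(hits)] ==
      planted$direction[S4Vectors::subjectHits(hits)]
    matched <- tapply(agree, S4Vectors::queryHits(hits), any)
    dir_ok <- mean(matched)
  }
  list(sensitivity = sens, precision = prec, direction_accuracy = dir_ok,
       n_called = n_called, n_planted = n_planted)
}
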