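#' Derive a DNA methylation episignature
#'
#' Fits the full discovery pipeline on a beta-value matrix: QC probe
#' filtering, array failure filtering, age/sex matched control selection at
#' the configured ratio, M-value transformation, cell-composition-adjusted
#' per-probe moderated-t differential methylation with BH correction, and the
#' three-stage selection funnel (top `n_candidates` by
#' `|delta_beta| * (-log10 p)`, top `n_roc` by per-probe ROC AUC, then greedy
#' correlation pruning at `r_max`). Per-probe case and control reference
#' medians are stored for concordance scoring, and — when confounder and/or
#' control pools beyond the matched set are available — a linear-kernel SVM
#' with Platt calibration is trained on the signature probes to produce
#' methylation variant pathogenicity (MVP) scores.
#'
#' @param beta Beta matrix (probes x samples), optionally carrying a
#'   `"detection_failure"` attribute.
#' @param sample_sheet Sample sheet covering all columns of `beta`; `group`
#'   must contain `"case"` and `"control"` samples.
#' @param manifest Probe manifest covering all rows of `beta`.
#' @param config A [pipeline_config()].
#' @param cell_reference Optional cell-type reference (cell types x probes)
#'   used to estimate proportions when the sheet carries none.
#' @param fit_classifier Train the MVP classifier (default: yes, whenever a
#'   background pool remains after matching).
#' @return An object of class `"episignature"` with components `probes`
#'   (ordered final signature), `case_median` / `control_median`, `stats`
#'   (the full probe-statistics table), `dmps` (probes passing the DMP
#'   criteria), `funnel` (stage sizes), `training` (matched cohort),
#'   `classifier` (an `"mvp_classifier"` or `NULL`), and `config`.
#' @seealso [predict.episignature()], [plot.episignature()], [save_model()],
#'   [find_dmrs()], [loo_cross_validate()]
#' @examples
#' cfg <- sim_config(n_probes = 2000, n_controls = 60, n_signal_probes = 60,
#'                   n_signal_regions = 4, seed = 7)
#' sim <- simulate_cohort(cfg)
#' fit <- episignature(sim$beta, sim$sheet, sim$manifest,
#'                     config = pipeline_config(n_candidates = 200, n_roc = 100))
#' fit
#' @export
episignature <- function(beta, sample_sheet, manifest,
                         config = pipeline_config(),
                         cell_reference = NULL,
                         fit_classifier = TRUE) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  stopifnot(all(colnames(beta) %in% sample_sheet$sample_id))
  n_total <- nrow(beta)

  beta_f <- filter_probes(beta, manifest)
  if (!is.null(attr(beta_f, "detection_failure")))
    beta_f <- filter_arrays(beta_f, config$failure_rate_max)
  sheet <- sample_sheet[match(colnames(beta_f), sample_sheet$sample_id), ]

  cases <- sheet[sheet$group == "case", ]
  pool <- sheet[sheet$group == "control", ]
  if (nrow(cases) < 2L) stop("need at least 2 case samples")
  matched <- match_controls(cases, pool, ratio = config$control_ratio)
  train_ids <- c(matched$case_ids, matched$control_ids)

  bt <- beta_f[, train_ids, drop = FALSE]
  complete <- rowSums(is.na(bt)) == 0L
  bt <- bt[complete, , drop = FALSE]
  if (nrow(bt) == 0L) stop("no probes with complete training data")
  is_case <- colnames(bt) %in% matched$case_ids

  covars <- training_covariates(bt, sheet, train_ids, cell_reference)
  stats <- probe_stats(bt, is_case, covariates = covars, rank_p = config$rank_p)
  dmps <- call_dmps(stats, config$fdr_max, config$delta_beta_min)

  # The published signature satisfies the DMP criteria and is the funnel
  # output at once, so the funnel ranks within the significant probes; when
  # nothing is significant the ranking falls back to all probes so that
  # downstream null-behaviour analyses stay defined.
  pool <- stats[stats$probe_id %in% dmps, , drop = FALSE]
  if (nrow(pool) < 2L) {
    warning("no probes pass the DMP criteria; ranking all probes")
    pool <- stats
  }
  candidates <- rank_candidates(pool, min(config$n_candidates, nrow(pool)))
  roc <- roc_select(bt, is_case, candidates, config$n_roc)
  stats$auc[match(names(roc$auc), stats$probe_id)] <- as.numeric(roc$auc)
  probes <- prune_correlated(bt, roc$probes, config$r_max)

  case_median <- row_medians(bt[probes, is_case, drop = FALSE])
  control_median <- row_medians(bt[probes, !is_case, drop = FALSE])

  classifier <- NULL
  if (isTRUE(fit_classifier)) {
    tryCatch({
      classifier <- train_mvp(beta_f, sheet, probes,
                              train_fraction = config$train_fraction,
                              seed = config$seed, cost = config$svm_cost)
    }, error = function(e) {
      warning("MVP classifier not trained: ", conditionMessage(e))
    })
  }

  structure(list(probes = probes,
                 case_median = case_median,
                 control_median = control_median,
                 stats = stats,
                 dmps = dmps,
                 funnel = list(total = n_total,
                               filtered = nrow(bt),
                               candidates = length(candidates),
                               roc = length(roc$probes),
                               final = length(probes)),
                 training = matched,
                 classifier = classifier,
                 config = config,
                 call = match.call()),
            class = "episignature")
}

# Cell-proportion covariates for the training samples: sheet columns take
# precedence, then NNLS estimation against a reference, else none. One
# simplex column is dropped to keep the design full rank.
training_covariates <- function(beta_train, sheet, train_ids, cell_reference) {
  ct <- celltype_columns(sheet)
  if (length(ct)) {
    props <- as.matrix(sheet[match(train_ids, sheet$sample_id), ct, drop = FALSE])
  } else if (!is.null(cell_reference)) {
    props <- estimate_cell_proportions(beta_train, cell_reference)
  } else {
    return(NULL)
  }
  props[, -ncol(props), drop = FALSE]
}

#' @export
print.episignature <- function(x, ...) {
  f <- x$funnel
  cat("DNA methylation episignature\n")
  if (!is.null(f))
    cat(sprintf("  funnel: %d probes -> %d analyzed -> %d candidates -> %d ROC -> %d final\n",
                f$total, f$filtered, f$candidates, f$roc, f$final))
  cat(sprintf("  signature probes: %d (%d hypermethylated)\n",
              length(x$probes),
              if (!is.null(x$stats))
                sum(x$stats$delta_beta[match(x$probes, x$stats$probe_id)] > 0)
              else sum(x$case_median > x$control_median)))
  if (!is.null(x$dmps))
    cat(sprintf("  DMPs at q < %g, |delta-beta| > %g: %d\n",
                x$config$fdr_max, x$config$delta_beta_min, length(x$dmps)))
  cat(sprintf("  MVP classifier: %s\n",
              if (is.null(x$classifier)) "none" else "linear SVM, Platt-calibrated"))
  invisible(x)
}

#' @export
summary.episignature <- function(object, ...) {
  sel <- object$stats[match(object$probes, object$stats$probe_id), ]
  out <- list(funnel = object$funnel,
              n_probes = length(object$probes),
              n_hyper = sum(sel$delta_beta > 0),
              n_hypo = sum(sel$delta_beta < 0),
              n_dmps = length(object$dmps),
              delta_beta = summary(sel$delta_beta),
              top = head(sel[order(sel$p_value), ], 10L))
  class(out) <- "summary.episignature"
  out
}

#' @export
print.summary.episignature <- function(x, ...) {
  cat(sprintf("Episignature: %d probes (%d hyper / %d hypo), %d DMPs\n",
              x$n_probes, x$n_hyper, x$n_hypo, x$n_dmps))
  cat("delta-beta distribution over selected probes:\n")
  print(x$delta_beta)
  cat("top probes by p-value:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Probe-level coefficients of a fitted episignature
#'
#' @param object An `"episignature"`.
#' @param all Return statistics for all analyzed probes rather than the
#'   selected signature.
#' @param ... Unused.
#' @return The probe-statistics `data.frame` (selected probes by default).
#' @export
coef.episignature <- function(object, all = FALSE, ...) {
  if (is.null(object$stats)) stop("this model was loaded without probe statistics")
  if (all) object$stats
  else object$stats[match(object$probes, object$stats$probe_id), ]
}

#' Score new samples against a fitted episignature
#'
#' @param object An `"episignature"`.
#' @param newdata Beta matrix (probes x samples) containing all signature
#'   probes.
#' @param type `"score"` for the MVP results table, `"concordance"` for the
#'   per-sample fraction of signature probes closer to the case median.
#' @param ... Unused.
#' @return `data.frame` of per-sample results.
#' @export
predict.episignature <- function(object, newdata,
                                 type = c("score", "concordance"), ...) {
  type <- match.arg(type)
  if (type == "score") {
    if (is.null(object$classifier))
      stop("no MVP classifier attached to this model")
    return(mvp_results(object$classifier, newdata))
  }
  frac <- vapply(colnames(newdata), function(s)
    concordance_fraction(newdata[, s], object$case_median,
                         object$control_median, object$probes)$fraction_case_like,
    numeric(1))
  data.frame(sample_id = colnames(newdata),
             fraction_case_like = as.numeric(frac),
             stringsAsFactors = FALSE)
}

#' MDS plot of samples on the signature probes
#'
#' @param x An `"episignature"`.
#' @param beta Beta matrix of the samples to display.
#' @param groups Optional named group labels for coloring.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the MDS coordinates.
#' @export
plot.episignature <- function(x, beta, groups = NULL, ...) {
  coords <- classical_mds(beta[x$probes, , drop = FALSE], n_dims = 2L)
  if (is.null(groups)) groups <- rep("sample", nrow(coords))
  g <- factor(groups[rownames(coords)] %||% groups)
  plot(coords, col = as.integer(g), pch = 19,
       xlab = "MDS 1", ylab = "MDS 2", ...)
  legend("topright", legend = levels(g), col = seq_along(levels(g)), pch = 19)
  invisible(coords)
}
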