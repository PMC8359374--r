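# The differential-methylation engine: per-probe linear models on M-values,
# empirical-Bayes variance moderation, BH adjustment, and the three-stage
# probe-selection funnel (effect x p ranking -> per-probe ROC -> correlation
# pruning).

#' Per-probe linear models on M-values
#'
#' Fits, for every probe, an ordinary least-squares regression of the M-value
#' on an intercept, a case/control indicator, and optional covariates (cell
#' proportions, batch). One QR decomposition of the shared design is reused
#' across probes.
#'
#' @param m M-value matrix (probes x samples).
#' @param group Logical or factor aligned with the columns of `m`; `TRUE` /
#'   level `"case"` marks cases.
#' @param covariates Optional numeric matrix (samples x covariates). When the
#'   covariates include a full set of simplex proportions the caller should
#'   drop one column; collinear designs are rejected with the offending
#'   columns named.
#' @return List with per-probe `coef` (group coefficient, case minus
#'   control), `sigma2` (residual variance), `df_resid`, and the scalar
#'   `stdev_unscaled` (the group coefficient's standard error for unit
#'   residual SD).
#' @export
fit_linear_models <- function(m, group, covariates = NULL) {
  if (is.factor(group) || is.character(group)) group <- group == "case"
  group <- as.logical(group)
  stopifnot(length(group) == ncol(m))
  if (sum(group) < 2L || sum(!group) < 2L)
    stop("need at least 2 samples per group")
  X <- cbind("(Intercept)" = 1, group = as.numeric(group))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear design; offending column(s): ", paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, t(m))
  coefs <- t(fit$coefficients)
  resid <- t(fit$residuals)
  df_resid <- ncol(m) - qx$rank
  if (df_resid < 1L) stop("no residual degrees of freedom")
  sigma2 <- rowSums(resid^2) / df_resid
  xtx_inv <- chol2inv(qr.R(qx))
  stdev_unscaled <- sqrt(xtx_inv[2L, 2L])
  list(coef = setNames(coefs[, "group"], rownames(m)),
       sigma2 = setNames(sigma2, rownames(m)),
       df_resid = rep(df_resid, nrow(m)),
       stdev_unscaled = stdev_unscaled)
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-probe residual variances toward a prior estimated across all
#' probes and forms moderated t-statistics, following the classic
#' empirical-Bayes formulation: the prior degrees of freedom `d0` and prior
#' variance `s0_sq` are obtained by the method of moments on `log(s_g^2)`,
#' the posterior variance is `(d0*s0_sq + d_g*s_g_sq) / (d0 + d_g)`, and the
#' moderated t has `d0 + d_g` degrees of freedom. When the moment estimator
#' finds no excess spread in the observed log-variances, `d0` is infinite and
#' every posterior variance equals `s0_sq`.
#'
#' @param fit Output of [fit_linear_models()].
#' @param d0_override Force the prior df (0 recovers the ordinary t;
#'   `Inf` a pooled-variance z-like statistic).
#' @return List with `d0`, `s0_sq`, per-probe `s_post_sq`, `t_mod`,
#'   `p_value`, and `df_total`.
#' @export
moderate <- function(fit, d0_override = NULL) {
  s2 <- fit$sigma2
  if (length(s2) < 10L && is.null(d0_override))
    stop("need at least 10 probes to estimate moderation hyperparameters")
  if (all(s2 == 0)) stop("all residual variances are zero")
  dg <- fit$df_resid
  s2f <- pmax(s2, 1e-12)
  if (is.null(d0_override)) {
    mm <- fit_variance_prior(s2f, dg)
    d0 <- mm$d0; s0_sq <- mm$s0_sq
  } else {
    d0 <- d0_override
    # prior variance only matters when it gets weight
    s0_sq <- if (is.finite(d0) && d0 == 0) NA_real_ else exp(mean(log(s2f)))
  }
  if (is.infinite(d0)) {
    s_post <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s_post <- s2
    df_total <- dg
  } else {
    s_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  t_mod <- fit$coef / (sqrt(s_post) * fit$stdev_unscaled)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  list(d0 = d0, s0_sq = s0_sq, s_post_sq = setNames(s_post, names(s2)),
       t_mod = setNames(t_mod, names(s2)),
       p_value = setNames(p, names(s2)),
       df_total = df_total)
}

# Method-of-moments fit of the scaled-F prior on residual variances
# (Smyth 2004): working variable e_g = log s_g^2 - digamma(d_g/2) +
# log(d_g/2) has mean log s0^2 + digamma(d0/2) - log(d0/2) and variance
# trigamma(d_g/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, dg) {
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L)
  rhs <- evar - mean(trigamma(dg / 2))
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values in (0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Per-probe differential methylation statistics
#'
#' Convenience wrapper producing the probe-statistics table used throughout
#' the funnel: beta-scale effect (mean case minus mean control beta),
#' M-value moderated t and p, BH q, and the stage-1 ranking score
#' `|delta_beta| * (-log10 p)`.
#'
#' @param beta Beta matrix (effect sizes are reported on this scale).
#' @param group Case indicator aligned with columns.
#' @param covariates Optional covariate matrix passed to
#'   [fit_linear_models()].
#' @param rank_p Use `"raw"` or `"adjusted"` p in the ranking score.
#' @return `data.frame` with columns probe_id, delta_beta, t_mod, p_value,
#'   q_value, rank_score, auc (filled later by [roc_select()]).
#' @export
probe_stats <- function(beta, group, covariates = NULL, rank_p = "raw") {
  if (is.factor(group) || is.character(group)) group <- group == "case"
  m <- beta_to_m(beta)
  fit <- fit_linear_models(m, group, covariates)
  mod <- moderate(fit)
  # extreme probes can underflow the t tail to 0; floor so BH stays defined
  mod$p_value <- pmax(mod$p_value, .Machine$double.xmin)
  q <- bh_adjust(mod$p_value)
  delta <- rowMeans(beta[, group, drop = FALSE]) -
    rowMeans(beta[, !group, drop = FALSE])
  p_for_rank <- if (identical(rank_p, "adjusted")) q else mod$p_value
  data.frame(probe_id = rownames(beta),
             delta_beta = as.numeric(delta),
             t_mod = as.numeric(mod$t_mod),
             p_value = as.numeric(mod$p_value),
             q_value = as.numeric(q),
             rank_score = abs(delta) * (-log10(pmax(p_for_rank, .Machine$double.xmin))),
             auc = NA_real_,
             stringsAsFactors = FALSE)
}

#' Call differentially methylated probes
#'
#' Probes with `|delta_beta| > delta_min` and `q_value < fdr_max` (both
#' strict, so a probe at exactly 10% difference is excluded).
#'
#' @param stats Probe-statistics table from [probe_stats()].
#' @param fdr_max,delta_min Cut-offs.
#' @return Character vector of significant probe ids (possibly empty).
#' @export
call_dmps <- function(stats, fdr_max = 0.01, delta_min = 0.10) {
  stats$probe_id[abs(stats$delta_beta) > delta_min & stats$q_value < fdr_max]
}

#' Stage 1: rank candidate probes by effect x significance
#'
#' Scores every probe as `|delta_beta| * (-log10 p)` and keeps the top `n`.
#' Ties are broken by smaller p, then probe id.
#'
#' @param stats Probe-statistics table.
#' @param n Candidates to keep (warns and returns all when `n` exceeds the
#'   probe count).
#' @return Character vector of probe ids in rank order.
#' @export
rank_candidates <- function(stats, n = 1000L) {
  if (n > nrow(stats)) {
    warning("n exceeds the number of probes; returning all")
    n <- nrow(stats)
  }
  ord <- order(-stats$rank_score, stats$p_value, stats$probe_id)
  stats$probe_id[ord[seq_len(n)]]
}

#' Per-probe ROC AUC (Mann-Whitney identity)
#'
#' Area under the ROC curve of one probe's values as a score for the case
#' label, computed by the rank-sum identity with midrank tie handling.
#'
#' @param values Numeric vector of probe values.
#' @param is_case Logical vector.
#' @return AUC in \[0,1\]; 0.5 when all values are tied.
#' @export
probe_auc <- function(values, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stage 2: ROC-based probe selection
#'
#' Computes per-probe AUC on the beta scale and keeps the `n` probes with the
#' largest `max(auc, 1 - auc)`, so hypo- and hypermethylated probes compete
#' symmetrically. Ties are broken by probe id.
#'
#' @param beta Beta matrix.
#' @param is_case Logical vector over columns.
#' @param candidates Probe ids from [rank_candidates()].
#' @param n Probes to keep.
#' @return List with `probes` (ids in rank order) and `auc` (named AUCs for
#'   all candidates).
#' @export
roc_select <- function(beta, is_case, candidates, n = 500L) {
  auc <- vapply(candidates, function(p) probe_auc(beta[p, ], is_case), numeric(1))
  disc <- pmax(auc, 1 - auc)
  ord <- order(-disc, candidates)
  n <- min(n, length(candidates))
  list(probes = candidates[ord[seq_len(n)]], auc = setNames(auc, candidates))
}

#' Stage 3: greedy correlation pruning
#'
#' Scans probes in rank order and keeps a probe only if its Pearson
#' correlation with every probe already kept satisfies `|r| <= r_max`.
#' Constant probes (undefined r) are kept with a warning.
#'
#' @param beta Beta matrix over the training samples.
#' @param ranked_probes Probe ids in rank order (from [roc_select()]).
#' @param r_max Correlation threshold.
#' @return Character vector of kept probe ids, order preserved.
#' @export
prune_correlated <- function(beta, ranked_probes, r_max = 0.9) {
  x <- t(beta[ranked_probes, , drop = FALSE])
  const <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant probe(s) treated as uncorrelated: ",
            paste(ranked_probes[const], collapse = ", "))
  suppressWarnings(cmat <- abs(cor(x)))
  cmat[is.na(cmat)] <- 0
  kept <- integer(0)
  for (i in seq_along(ranked_probes)) {
    if (length(kept) == 0L || all(cmat[i, kept] <= r_max)) kept <- c(kept, i)
  }
  ranked_probes[kept]
}
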