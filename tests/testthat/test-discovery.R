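# Differential-methylation engine and selection funnel: OLS against a
# normal-equations oracle, moderation against an independent moment solver
# and limma, BH, DMP calling, ranking, ROC, pruning, and funnel invariants.

test_that("per-probe OLS matches the normal-equations oracle", {
  set.seed(1)
  n <- 8L
  group <- rep(c(TRUE, FALSE), each = 4)
  covar <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "cell"))
  m <- matrix(rnorm(3 * n), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), sprintf("s%d", 1:n)))
  fit <- fit_linear_models(m, group, covar)
  X <- cbind(1, as.numeric(group), covar)
  for (i in 1:3) {
    bhat <- solve(t(X) %*% X, t(X) %*% m[i, ])   # oracle: explicit normal equations
    expect_equal(unname(fit$coef[i]), bhat[2], tolerance = 1e-10)
    res <- m[i, ] - X %*% bhat
    expect_equal(unname(fit$sigma2[i]), sum(res^2) / (n - 3), tolerance = 1e-10)
  }
  expect_equal(fit$stdev_unscaled, sqrt(solve(t(X) %*% X)[2, 2]), tolerance = 1e-12)

  # with no covariates the group coefficient is the difference of means and
  # residual df is n - 2
  f2 <- fit_linear_models(m, group)
  expect_equal(unname(f2$coef),
               rowMeans(m[, group]) - rowMeans(m[, !group]),
               ignore_attr = TRUE)
  expect_identical(unique(f2$df_resid), n - 2L)

  # collinear covariates are reported
  bad <- cbind(covar, cell2 = 2 * covar[, 1])
  expect_error(fit_linear_models(m, group, bad), "cell2|collinear")
  expect_error(fit_linear_models(m, rep(TRUE, n)), "2 samples per group")
})

test_that("moderation hyperparameters match an independent moment solver", {
  set.seed(2)
  n_probe <- 50; dg <- 6
  s2 <- exp(rnorm(n_probe, -1, 0.8))
  fit <- list(coef = rnorm(n_probe), sigma2 = s2,
              df_resid = rep(dg, n_probe), stdev_unscaled = 0.5)
  mod <- moderate(fit)

  # oracle: solve the moment equations with uniroot, independent of the
  # Newton trigamma inversion used by the implementation
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  rhs <- var(e) - trigamma(dg / 2)
  stopifnot(rhs > 0)
  half_d0 <- uniroot(function(x) trigamma(x) - rhs, c(1e-6, 1e6), tol = 1e-12)$root
  d0_oracle <- 2 * half_d0
  s0_oracle <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  expect_equal(mod$d0, d0_oracle, tolerance = 1e-6)
  expect_equal(mod$s0_sq, s0_oracle, tolerance = 1e-6)

  # posterior variance identity
  expect_equal(mod$s_post_sq,
               (mod$d0 * mod$s0_sq + dg * s2) / (mod$d0 + dg),
               ignore_attr = TRUE)
})

test_that("moderated t agrees with limma on a shared fixture", {
  skip_if_not_installed("limma")
  set.seed(3)
  n <- 10; n_probe <- 120
  group <- rep(c(1, 0), each = n / 2)
  m <- matrix(rnorm(n_probe * n, sd = rep(exp(rnorm(n_probe, 0, 0.5)), n)),
              nrow = n_probe,
              dimnames = list(sprintf("p%03d", 1:n_probe), sprintf("s%d", 1:n)))
  m[1:10, group == 1] <- m[1:10, group == 1] + 2

  fit <- fit_linear_models(m, group == 1)
  mod <- moderate(fit)

  design <- cbind(Intercept = 1, group = group)
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(mod$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$t_mod), unname(lfit$t[, "group"]), tolerance = 1e-8)
  expect_equal(unname(mod$p_value), unname(lfit$p.value[, "group"]), tolerance = 1e-8)
})

test_that("moderation limits recover the ordinary t and the pooled z", {
  set.seed(4)
  fit <- list(coef = rnorm(30), sigma2 = exp(rnorm(30)),
              df_resid = rep(5L, 30), stdev_unscaled = 0.4)
  plain_t <- fit$coef / (sqrt(fit$sigma2) * fit$stdev_unscaled)

  m0 <- moderate(fit, d0_override = 0)
  expect_equal(unname(m0$t_mod), plain_t)
  expect_equal(unname(m0$p_value), 2 * pt(-abs(plain_t), 5))

  mi <- moderate(fit, d0_override = Inf)
  expect_true(all(mi$s_post_sq == mi$s0_sq))
  expect_equal(unname(mi$p_value),
               2 * pnorm(-abs(fit$coef / (sqrt(mi$s0_sq) * 0.4))))

  # equal observed variances carry no spread: the prior takes over with
  # infinite df and a common posterior variance (the moment estimator's
  # bias-corrected log-variance mean), so all probes share one variance and
  # the moderated t is proportional to the ordinary t
  fe <- list(coef = rnorm(20), sigma2 = rep(0.3, 20),
             df_resid = rep(6L, 20), stdev_unscaled = 0.4)
  me <- moderate(fe)
  expect_true(is.infinite(me$d0))
  s0_expected <- exp(log(0.3) - digamma(3) + log(3))
  expect_equal(unname(me$s_post_sq), rep(s0_expected, 20), tolerance = 1e-10)
  plain_te <- fe$coef / (sqrt(0.3) * 0.4)
  expect_equal(unname(me$t_mod) / plain_te,
               rep(sqrt(0.3 / s0_expected), 20), tolerance = 1e-10)

  expect_error(moderate(list(coef = 0, sigma2 = rep(0, 20),
                             df_resid = rep(3L, 20), stdev_unscaled = 1)),
               "all residual variances")
})

test_that("BH adjustment is the step-up procedure and permutation-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  set.seed(5)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(diff(bh_adjust(sort(p))) >= 0))  # monotone in sorted order
  expect_true(all(bh_adjust(p) <= 1) && all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "p > 0")
})

test_that("call_dmps applies strict thresholds and controls the null", {
  stats <- toy_stats(c("a", "b", "c"),
                     delta_beta = c(0.10, 0.15, 0.25),
                     p_value = c(1e-9, 1e-9, 0.5))
  # a fails |delta| > 0.10 (exactly at the boundary), c fails the q cut
  expect_identical(call_dmps(stats), "b")

  # null simulation: no planted signal, 20 seeds -> median 0 discoveries
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_probes = 800, n_controls = 60, n_signal_probes = 0,
                      n_signal_regions = 0, seed = 100 + s)
    sim <- simulate_cohort(cfg)
    sheet <- sim$sheet
    mc <- match_controls(sheet[sheet$group == "case", ],
                         sheet[sheet$group == "control", ], ratio = 7)
    ids <- c(mc$case_ids, mc$control_ids)
    st <- probe_stats(sim$beta[, ids], ids %in% mc$case_ids)
    length(call_dmps(st))
  }, numeric(1))
  expect_identical(median(hits), 0)
})

test_that("candidate ranking scores, orders, and breaks ties as documented", {
  stats <- toy_stats(c("A", "B", "Z"),
                     delta_beta = c(0.2, 0.1, 0),
                     p_value = c(1e-4, 1e-6, 1e-20))
  expect_equal(stats$rank_score[1], 0.8)   # 0.2 * 4
  expect_equal(stats$rank_score[2], 0.6)   # 0.1 * 6
  expect_equal(stats$rank_score[3], 0)     # zero effect ranks last
  expect_identical(rank_candidates(stats, 3), c("A", "B", "Z"))

  tie <- toy_stats(c("t1", "t2"), delta_beta = c(0.2, 0.1),
                   p_value = c(1e-3, 1e-6))
  expect_equal(tie$rank_score[1], tie$rank_score[2])  # both 0.6
  expect_identical(rank_candidates(tie, 2), c("t2", "t1"))  # smaller p first

  expect_warning(out <- rank_candidates(stats, 10), "exceeds")
  expect_length(out, 3)
})

test_that("per-probe AUC follows the rank-sum identity and is monotone-invariant", {
  is_case <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(probe_auc(c(0.8, 0.6, 0.7, 0.5), is_case), 0.75)
  expect_equal(probe_auc(c(0.9, 0.8, 0.2, 0.1), is_case), 1.0)
  expect_equal(probe_auc(rep(0.5, 4), is_case), 0.5)
  set.seed(6)
  v <- runif(20); lab <- rep(c(TRUE, FALSE), 10)
  expect_equal(probe_auc(v, lab), probe_auc(qlogis(v), lab))
  expect_equal(probe_auc(v, lab), probe_auc(v^3, lab))
  expect_error(probe_auc(v, rep(FALSE, 20)), "both classes")
})

test_that("roc_select ranks by two-sided discrimination", {
  b <- toy_beta(rbind(hyper = c(0.9, 0.8, 0.2, 0.1),
                      hypo = c(0.1, 0.2, 0.9, 0.8),
                      null = c(0.5, 0.4, 0.45, 0.55)))
  rownames(b) <- c("hyper", "hypo", "null")
  sel <- roc_select(b, c(TRUE, TRUE, FALSE, FALSE), rownames(b), n = 2)
  expect_setequal(sel$probes, c("hyper", "hypo"))
  expect_equal(unname(sel$auc["hyper"]), 1)
  expect_equal(unname(sel$auc["hypo"]), 0)
})

test_that("correlation pruning keeps the greedy rank-order solution", {
  # feasible correlation triple: r(A,B), r(B,C) above the cut, r(A,C) below
  R <- matrix(c(1, 0.91, 0.70,
                0.91, 1, 0.91,
                0.70, 0.91, 1), 3, 3)
  X <- exact_cor_matrix(R)
  beta <- t((X - min(X)) / diff(range(X)))   # affine map into [0,1], r unchanged
  rownames(beta) <- c("A", "B", "C")
  colnames(beta) <- sprintf("s%02d", seq_len(ncol(beta)))
  expect_equal(cor(beta["A", ], beta["B", ]), 0.91, tolerance = 1e-10)
  expect_identical(prune_correlated(beta, c("A", "B", "C"), r_max = 0.9),
                   c("A", "C"))

  dup <- beta[c("A", "A", "C"), ]; rownames(dup) <- c("A", "A2", "C")
  expect_identical(prune_correlated(dup, rownames(dup), 0.9), c("A", "C"))

  ind <- toy_beta(matrix(runif(2 * 50), nrow = 2))
  expect_identical(prune_correlated(ind, rownames(ind), 0.9), rownames(ind))

  konst <- toy_beta(rbind(rep(0.5, 10), runif(10)))
  expect_warning(kept <- prune_correlated(konst, rownames(konst), 0.9),
                 "constant")
  expect_identical(kept, rownames(konst))
})

test_that("the funnel is monotone, decorrelated, sensitive and deterministic", {
  sm <- small_sim(seed = 11)
  cfg <- small_pipeline_config()
  fit <- episignature(sm$sim$beta, sm$sim$sheet, sm$sim$manifest, config = cfg)

  stats <- fit$stats
  cand <- rank_candidates(stats[stats$probe_id %in% fit$dmps, ],
                          min(cfg$n_candidates, length(fit$dmps)))
  expect_true(all(fit$probes %in% cand))
  expect_true(all(cand %in% stats$probe_id))
  expect_lte(length(fit$probes), cfg$n_roc)

  # pairwise decorrelation on the training betas
  ids <- c(fit$training$case_ids, fit$training$control_ids)
  cm <- abs(cor(t(sm$sim$beta[fit$probes, ids])))
  expect_lte(max(cm[upper.tri(cm)]), cfg$r_max)

  # sensitivity at high SNR: selected probes are overwhelmingly planted
  expect_gte(mean(fit$probes %in% sm$sim$truth$signal_probe_ids), 0.9)

  fit2 <- episignature(sm$sim$beta, sm$sim$sheet, sm$sim$manifest, config = cfg)
  expect_identical(fit$probes, fit2$probes)
  expect_equal(mvp_score(fit$classifier, sm$sim$beta[, 1:4]),
               mvp_score(fit2$classifier, sm$sim$beta[, 1:4]))
})
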