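# Shared fixtures: all built in code at test time.

# A small synthetic cohort for fast end-to-end tests.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_probes = 3000, n_controls = 80, n_other_disorders = 2,
                    n_per_other = 12, n_signal_probes = 120,
                    n_signal_regions = 5, seed = seed, ...)
  list(cfg = cfg, sim = simulate_cohort(cfg))
}

small_pipeline_config <- function(...) {
  pipeline_config(n_candidates = 300, n_roc = 150, ...)
}

# Tiny named beta matrix.
toy_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns with exact sample correlation matrix R (zero-mean, so cor() is
# exact): orthonormalize centered noise, then apply chol(R).
exact_cor_matrix <- function(R, n = 40, seed = 99) {
  k <- ncol(R)
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  X <- sweep(X, 2, colMeans(X))
  Q <- qr.Q(qr(X))
  Q %*% chol(R)
}

# Manifest data.frame builder for DMR tests (1-based positions).
toy_manifest <- function(chrom, position, probe_id = NULL,
                         region_category = "Body", flags = "") {
  n <- length(position)
  data.frame(probe_id = probe_id %||% sprintf("cg%03d", seq_len(n)),
             chrom = rep_len(chrom, n), position = position,
             region_category = rep_len(region_category, n),
             flags = rep_len(flags, n), stringsAsFactors = FALSE)
}

toy_stats <- function(probe_id, delta_beta, p_value) {
  data.frame(probe_id = probe_id, delta_beta = delta_beta,
             t_mod = NA_real_, p_value = p_value,
             q_value = p.adjust(p_value, "BH"),
             rank_score = abs(delta_beta) * -log10(p_value),
             auc = NA_real_, stringsAsFactors = FALSE)
}

# Exact two-sided Wilcoxon p by enumerating all rank splits (oracle).
wilcoxon_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  pl <- mean(u_all <= u_obs); pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Independent two-tailed Fisher p oracle: direct hypergeometric enumeration
# with choose(), no dhyper.
fisher_enumerate <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, support) * choose(m2, k - support) / choose(m1 + m2, k)
  p_obs <- choose(m1, a) * choose(m2, c) / choose(m1 + m2, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
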