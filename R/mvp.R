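# Sample-level classification: Ward clustering, classical MDS, the SVM-based
# methylation variant pathogenicity (MVP) score with its 75/25 disorder-aware
# training design, leave-one-out cross-validation, and the per-sample
# concordance statistic.

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering with Ward's variance-minimizing linkage on
#' Euclidean distances over signature-probe betas (`ward.D2`, the linkage
#' whose merge costs are squared Euclidean variance increments).
#'
#' @param beta Beta matrix restricted to the signature probes
#'   (probes x samples).
#' @param k Flat clusters to cut (default 2: case-like vs control-like).
#' @return List with the `hclust` tree and `labels` (named cluster ids).
#' @export
ward_cluster <- function(beta, k = 2L) {
  if (ncol(beta) < k) stop("fewer samples than clusters")
  hc <- hclust(dist(t(beta)), method = "ward.D2")
  list(tree = hc, labels = cutree(hc, k = k))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared pairwise Euclidean distance matrix and
#' eigendecomposes it; when the configuration is intrinsically
#' `n_dims`-dimensional the embedded distances reproduce the originals
#' exactly. Coordinates are defined up to rotation/reflection.
#'
#' @param x Beta matrix (probes x samples) or a `dist` object.
#' @param n_dims Dimensions to return (capped at n-1).
#' @return Matrix samples x dimensions.
#' @export
classical_mds <- function(x, n_dims = 2L) {
  d <- if (inherits(x, "dist")) x else dist(t(x))
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least 2 samples")
  k <- min(n_dims, n - 1L)
  fit <- cmdscale(d, k = k, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))) &&
      sum(pmax(fit$eig, 0)[seq_len(k)]) < sum(abs(fit$eig[fit$eig < 0])))
    warning("negative eigenvalues dominate; distances are strongly non-Euclidean")
  coords <- fit$points
  if (ncol(coords) < n_dims)  # degenerate configurations span fewer dims
    coords <- cbind(coords, matrix(0, nrow = n, ncol = n_dims - ncol(coords)))
  rownames(coords) <- labels(d)
  coords
}

# Sigmoid (Platt-type) calibration: fit p(case | f) = 1 / (1 + exp(A f + B))
# to decision values by Newton iteration with backtracking (the damped update
# of Lin, Lin & Weng 2007). Targets are the raw 0/1 labels, so on cleanly
# separable data the fitted probabilities saturate towards 1 for cases and 0
# for the rest; `smoothed_targets = TRUE` switches to the prior-adjusted
# targets (N+1)/(N+2), 1/(N+2) that temper the saturation.
platt_fit <- function(f, y_case, smoothed_targets = FALSE) {
  prior1 <- sum(y_case); prior0 <- sum(!y_case)
  if (smoothed_targets) {
    t <- ifelse(y_case, (prior1 + 1) / (prior1 + 2), 1 / (prior0 + 2))
  } else {
    t <- as.numeric(y_case)
  }
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fval <- obj(A, B)
  for (it in seq_len(200)) {
    z <- A * f + B
    p <- plogis(-z)                       # P(case)
    d1 <- t - p
    d2 <- p * (1 - p)
    g_A <- sum(f * d1); g_B <- sum(d1)
    h_AA <- sum(f * f * d2) + 1e-12
    h_AB <- sum(f * d2)
    h_BB <- sum(d2) + 1e-12
    det <- h_AA * h_BB - h_AB^2
    dA <- -(h_BB * g_A - h_AB * g_B) / det
    dB <- -(h_AA * g_B - h_AB * g_A) / det
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- obj(newA, newB)
      if (newf < fval + 1e-4 * step * (g_A * dA + g_B * dB)) break
      step <- step / 2
      if (step < 1e-10) break
    }
    A <- A + step * dA; B <- B + step * dB
    if (abs(fval - obj(A, B)) < 1e-10) break
    fval <- obj(A, B)
  }
  list(A = A, B = B)
}

#' Train the MVP classifier
#'
#' Trains a linear-kernel support vector machine to separate case samples
#' from everything else, using the disorder-aware 75/25 design: the training
#' set holds all cases, `train_fraction` of the controls, and
#' `train_fraction` of each confounder ("other disorder") cohort, split
#' stratified by cohort under the given seed; the remainder plus any
#' unclassified (VUS) samples form the test set and are only ever scored.
#' Decision values are mapped to probabilities by a Platt-type sigmoid
#' calibration fitted on the training set; on cleanly separable data the
#' scores saturate (cases near 1, background near 0), matching how
#' methylation variant pathogenicity scores behave in practice. The returned
#' classifier is a plain list of numeric weights, so it serializes exactly.
#'
#' @param beta Beta matrix covering all pools (probes x samples).
#' @param sheet Sample sheet; `group` distinguishes case / control /
#'   other_disorder / vus, and an optional `cohort` column separates
#'   confounder pools.
#' @param signature_probes Probe ids fixed beforehand by the discovery
#'   funnel.
#' @param train_fraction Fraction of each background pool used for training.
#' @param seed Seed for the stratified split.
#' @param cost SVM soft-margin cost.
#' @return Object of class `"mvp_classifier"`: named weights `w`, offset `b`,
#'   Platt coefficients `platt_a`, `platt_b`, plus the training/test ids.
#' @export
train_mvp <- function(beta, sheet, signature_probes, train_fraction = 0.75,
                      seed = 1L, cost = 1) {
  stopifnot(all(signature_probes %in% rownames(beta)))
  sheet <- sheet[order(sheet$sample_id), ]
  case_ids <- sheet$sample_id[sheet$group == "case"]
  vus_ids <- sheet$sample_id[sheet$group == "vus"]
  if (length(case_ids) < 2L) stop("need at least 2 case samples")
  pools <- split(sheet$sample_id[sheet$group %in% c("control", "other_disorder")],
                 interaction(sheet$group[sheet$group %in% c("control", "other_disorder")],
                             if (!is.null(sheet$cohort))
                               sheet$cohort[sheet$group %in% c("control", "other_disorder")]
                             else "", drop = TRUE))
  train_bg <- with_seed(seed, unlist(lapply(pools, function(ids) {
    n_tr <- floor(train_fraction * length(ids))
    if (n_tr < 2L || length(ids) - n_tr < 1L)
      stop("a background pool is too small for the train/test split")
    sort(sample(ids, n_tr))
  }), use.names = FALSE))
  test_bg <- setdiff(unlist(pools, use.names = FALSE), train_bg)
  train_ids <- c(case_ids, sort(train_bg))
  x <- t(beta[signature_probes, train_ids, drop = FALSE])
  y <- factor(ifelse(train_ids %in% case_ids, "case", "rest"),
              levels = c("case", "rest"))
  sv <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(sv$coefs) %*% sv$SV)
  b <- -sv$rho
  f <- drop(x %*% w) + b
  # orient so larger decision values mean more case-like
  if (mean(f[y == "case"]) < mean(f[y != "case"])) {
    w <- -w; b <- -b; f <- -f
  }
  pl <- platt_fit(f, y == "case")
  structure(list(probe_ids = signature_probes,
                 w = setNames(w, signature_probes), b = b,
                 platt_a = pl$A, platt_b = pl$B,
                 cost = cost, train_fraction = train_fraction, seed = seed,
                 train_ids = train_ids,
                 test_ids = sort(c(test_bg, vus_ids))),
            class = "mvp_classifier")
}

#' Score samples with a trained MVP classifier
#'
#' Calibrated probability, in \[0,1\], that a sample carries the episignature
#' the classifier was trained on.
#'
#' @param classifier An `"mvp_classifier"`.
#' @param beta Beta matrix (probes x samples) or a named beta vector for one
#'   sample; must contain every signature probe.
#' @return Named numeric vector of MVP scores.
#' @export
mvp_score <- function(classifier, beta) {
  if (is.null(dim(beta))) beta <- matrix(beta, ncol = 1,
                                         dimnames = list(names(beta), "sample"))
  missing <- setdiff(classifier$probe_ids, rownames(beta))
  if (length(missing))
    stop("missing signature probe(s): ", paste(head(missing, 5), collapse = ", "))
  x <- t(beta[classifier$probe_ids, , drop = FALSE])
  f <- drop(x %*% classifier$w[classifier$probe_ids]) + classifier$b
  p <- plogis(-(classifier$platt_a * f + classifier$platt_b))
  setNames(as.numeric(p), colnames(beta))
}

#' MVP results table
#'
#' Scores every sample and reports the calibrated probability, the reporting
#' label (case-like iff score >= 0.5; no clinical verdict implied) and the
#' sample's training role.
#'
#' @param classifier An `"mvp_classifier"`.
#' @param beta Beta matrix covering the samples to score.
#' @return `data.frame` with sample_id, mvp_score, predicted_class,
#'   training_role.
#' @export
mvp_results <- function(classifier, beta) {
  score <- mvp_score(classifier, beta)
  data.frame(sample_id = colnames(beta),
             mvp_score = as.numeric(score),
             predicted_class = ifelse(score >= 0.5, "case-like", "control-like"),
             training_role = ifelse(colnames(beta) %in% classifier$train_ids,
                                    "train", "test"),
             stringsAsFactors = FALSE)
}

#' Per-sample concordance with the case methylation pattern
#'
#' For each signature probe compares the sample's beta to the case and
#' control reference medians: a probe is case-like when
#' `|B - control_median| - |B - case_median| > 0` (strictly closer to the
#' case median; exact midpoints count as not case-like). Reports the fraction
#' of case-like probes.
#'
#' @param sample_beta Named beta vector for one sample.
#' @param case_median,control_median Named per-probe reference medians.
#' @param probes Probe set to evaluate (defaults to the median names).
#' @return List with `fraction_case_like` and the per-probe differences `a`.
#' @export
concordance_fraction <- function(sample_beta, case_median, control_median,
                                 probes = names(case_median)) {
  if (length(probes) == 0L) stop("empty probe set")
  b <- sample_beta[probes]
  a <- abs(b - control_median[probes]) - abs(b - case_median[probes])
  list(fraction_case_like = mean(a > 0), a = setNames(as.numeric(a), probes))
}

#' Leave-one-out cross-validation of the episignature
#'
#' For each case in turn, re-derives the episignature from the remaining
#' cases (with freshly matched controls), embeds all cases and matched
#' controls by classical MDS on the re-derived signature, and assigns the
#' held-out case to the nearer group centroid in the embedding.
#'
#' @param beta Beta matrix covering cases and the control pool.
#' @param sheet Sample sheet (needs >= 3 cases).
#' @param manifest Probe manifest.
#' @param config A [pipeline_config()].
#' @return `data.frame` with one row per round: held_out, assigned, correct,
#'   signature_size. Rounds whose derivation fails are reported with
#'   `assigned = NA` and skipped.
#' @export
loo_cross_validate <- function(beta, sheet, manifest, config = pipeline_config()) {
  case_ids <- sort(sheet$sample_id[sheet$group == "case"])
  if (length(case_ids) < 3L) stop("leave-one-out needs at least 3 cases")
  rounds <- lapply(case_ids, function(held) {
    sheet_i <- sheet[!(sheet$sample_id == held), ]
    res <- tryCatch({
      fit <- episignature(beta[, colnames(beta) != held, drop = FALSE],
                          sheet_i, manifest, config = config,
                          fit_classifier = FALSE)
      ids <- c(fit$training$case_ids, fit$training$control_ids, held)
      coords <- classical_mds(beta[fit$probes, ids, drop = FALSE], n_dims = 2L)
      cent_case <- colMeans(coords[fit$training$case_ids, , drop = FALSE])
      cent_ctrl <- colMeans(coords[fit$training$control_ids, , drop = FALSE])
      d_case <- sqrt(sum((coords[held, ] - cent_case)^2))
      d_ctrl <- sqrt(sum((coords[held, ] - cent_ctrl)^2))
      assigned <- if (d_case < d_ctrl) "case" else "control"
      data.frame(held_out = held, assigned = assigned,
                 correct = assigned == "case",
                 signature_size = length(fit$probes),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("round for '%s' skipped: %s", held, conditionMessage(e)))
      data.frame(held_out = held, assigned = NA_character_, correct = NA,
                 signature_size = NA_integer_, stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rounds)
}
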