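# Quality filtering, matched-control selection, M-value transformation and
# blood-cell deconvolution: the stage between normalized betas and the
# differential analysis.

#' Remove QC-flagged probes
#'
#' Drops probes flagged as located on sex chromosomes, cross-reactive, or
#' overlapping SNPs, mirroring standard EPIC pre-filtering.
#'
#' @param beta Beta matrix (probes x samples).
#' @param ann Probe manifest covering every probe in `beta`.
#' @return Filtered beta matrix; attribute `"removed_counts"` reports, per
#'   flag, how many removed probes carried it (a probe with several flags is
#'   counted under each).
#' @export
filter_probes <- function(beta, ann) {
  missing <- setdiff(rownames(beta), ann$probe_id)
  if (length(missing))
    stop("probe(s) missing from manifest: ", paste(head(missing, 3), collapse = ", "))
  ann <- ann[match(rownames(beta), ann$probe_id), ]
  flags <- strsplit(ann$flags, ";", fixed = TRUE)
  flagged <- lengths(flags) > 0L
  if (all(flagged)) stop("no probes survive filtering")
  removed_flags <- unlist(flags[flagged])
  counts <- setNames(integer(length(PROBE_FLAGS)), PROBE_FLAGS)
  tab <- table(removed_flags)
  counts[names(tab)] <- as.integer(tab)
  out <- beta[!flagged, , drop = FALSE]
  df <- attr(beta, "detection_failure")
  if (!is.null(df)) attr(out, "detection_failure") <- df[!flagged, , drop = FALSE]
  attr(out, "removed_counts") <- counts
  out
}

#' Drop samples with excessive probe failure
#'
#' Excludes arrays whose detection-failure fraction is strictly greater than
#' `max_failure` (default 5%); a sample failing exactly 5% of probes is
#' retained.
#'
#' @param beta Beta matrix carrying a `"detection_failure"` attribute.
#' @param max_failure Maximum tolerated failure fraction.
#' @return Beta matrix restricted to passing samples; attribute
#'   `"dropped_samples"` lists exclusions.
#' @export
filter_arrays <- function(beta, max_failure = 0.05) {
  df <- attr(beta, "detection_failure")
  if (is.null(df)) stop("filter_arrays requires a detection_failure matrix")
  frac <- colMeans(df)
  drop <- frac > max_failure
  if (all(drop)) stop("all samples exceed the failure threshold")
  out <- beta[, !drop, drop = FALSE]
  attr(out, "detection_failure") <- df[, !drop, drop = FALSE]
  attr(out, "dropped_samples") <- colnames(beta)[drop]
  out
}

#' Select age/sex matched controls
#'
#' For each case (processed in lexicographic `sample_id` order) selects
#' `ratio` controls of identical sex minimizing absolute age difference,
#' sampling without replacement; age ties are broken by lexicographic
#' `sample_id`. The procedure is deterministic and invariant to the row
#' order of the pool.
#'
#' @param cases,pool Sample-sheet `data.frame`s (disjoint sample ids).
#' @param ratio Controls per case (default 7, so 8 cases yield 56 controls).
#' @param seed Unused (the selection is deterministic); kept so callers can
#'   treat matching like the other seeded stages.
#' @return List with `case_ids`, `control_ids`, and `match_table` (per-case
#'   character vectors of matched control ids).
#' @export
match_controls <- function(cases, pool, ratio = 7L, seed = NULL) {
  if (length(intersect(cases$sample_id, pool$sample_id)))
    stop("control pool must be disjoint from cases")
  if (nrow(pool) < ratio * nrow(cases))
    stop("control pool smaller than ratio x cases")
  pool <- pool[order(pool$sample_id), ]
  case_ids <- sort(cases$sample_id)
  taken <- character(0)
  match_table <- list()
  for (cid in case_ids) {
    cs <- cases[cases$sample_id == cid, ]
    avail <- pool[pool$sex == cs$sex & !(pool$sample_id %in% taken), ]
    if (nrow(avail) < ratio)
      stop(sprintf("insufficient same-sex controls for case '%s'", cid))
    ord <- order(abs(avail$age - cs$age), avail$sample_id)
    chosen <- avail$sample_id[ord[seq_len(ratio)]]
    match_table[[cid]] <- chosen
    taken <- c(taken, chosen)
  }
  list(case_ids = case_ids, control_ids = taken, match_table = match_table)
}

#' Beta to M-value conversion
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[epsilon, 1 - epsilon]` so boundary values stay finite. Monotone in beta;
#' [m_to_beta()] inverts it exactly inside the clipping range.
#'
#' @param beta Beta matrix or vector in \[0,1\].
#' @param epsilon Clipping margin.
#' @return M-values with the shape of the input.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  b <- clip01(beta, epsilon)
  m <- log2(b / (1 - b))
  attributes(m) <- attributes(beta)[c("dim", "dimnames", "names")]
  m
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m) {
  b <- 2^m / (1 + 2^m)
  attributes(b) <- attributes(m)[c("dim", "dimnames", "names")]
  b
}

#' Reference-based cell-proportion estimation
#'
#' Projects each sample's beta profile onto reference cell-type profiles by
#' non-negative least squares and renormalizes to the simplex — the standard
#' constrained-projection approach to blood deconvolution.
#'
#' @param beta Beta matrix.
#' @param reference Matrix of reference profiles, cell types x probes
#'   (probe names in columns), covering at least 50 probes present in `beta`.
#' @return Matrix samples x cell types; rows are non-negative and sum to 1.
#' @export
estimate_cell_proportions <- function(beta, reference) {
  shared <- intersect(colnames(reference), rownames(beta))
  if (length(shared) < 50)
    stop("reference must share at least 50 probes with the beta matrix")
  A <- t(reference[, shared, drop = FALSE])   # probes x cell types
  if (qr(A)$rank < ncol(A)) stop("rank-deficient cell-type reference")
  props <- t(vapply(seq_len(ncol(beta)), function(j) {
    fit <- pracma::lsqnonneg(A, beta[shared, j])
    x <- fit$x
    if (sum(x) <= 0) x <- rep(1 / length(x), length(x))
    x / sum(x)
  }, numeric(nrow(reference))))
  dimnames(props) <- list(colnames(beta), rownames(reference))
  props
}

#' PCA-based sample QC
#'
#' Projects samples onto the leading principal components of the M-value
#' matrix and flags samples lying more than `sd_limit` robust standard
#' deviations from the component-wise center. Advisory only — nothing is
#' excluded automatically.
#'
#' @param m M-value matrix (probes x samples), at least 3 samples.
#' @param n_components Components to return.
#' @param sd_limit Flagging distance in component-wise SD units.
#' @return List with `coords` (samples x components), `flagged` (logical),
#'   and `sdev`.
#' @export
pca_qc <- function(m, n_components = 2L, sd_limit = 3) {
  if (ncol(m) < 3L) stop("pca_qc needs at least 3 samples")
  if (all(apply(m, 1L, function(x) diff(range(x)) == 0)))
    stop("constant matrix: no variation across samples")
  k <- min(n_components, ncol(m) - 1L)
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE, rank. = k)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  scale_by <- apply(coords, 2L, function(x) {
    s <- mad(x)                       # robust so one outlier cannot mask itself
    if (s == 0) s <- sd(x)
    if (s == 0) s <- 1
    s
  })
  z <- sweep(sweep(coords, 2L, apply(coords, 2L, median)), 2L, scale_by, "/")
  flagged <- sqrt(rowSums(z^2)) > sd_limit
  list(coords = coords, flagged = flagged, sdev = pc$sdev)
}
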