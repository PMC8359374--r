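# Probe/array filtering, matched controls, M-values, deconvolution, PCA QC.

test_that("filter_probes removes flagged probes and reports counts per reason", {
  b <- toy_beta(matrix(runif(20), nrow = 10))
  ann <- toy_manifest("chr1", seq(100, 1000, by = 100),
                      probe_id = rownames(b))
  ann$flags[2] <- "sex_chromosome"
  ann$flags[5] <- "cross_reactive"
  ann$flags[9] <- "snp_overlap"
  out <- filter_probes(b, ann)
  expect_identical(nrow(out), 7L)
  expect_identical(attr(out, "removed_counts"),
                   c(sex_chromosome = 1L, cross_reactive = 1L, snp_overlap = 1L))

  ann$flags[] <- ""
  clean <- filter_probes(b, ann)
  expect_equal(clean[, ], b[, ])

  ann$flags[] <- "cross_reactive"
  expect_error(filter_probes(b, ann), "no probes survive")

  expect_error(filter_probes(b, ann[-1, ]), "missing from manifest")
})

test_that("filter_arrays drops samples strictly above the failure threshold", {
  b <- toy_beta(matrix(runif(1000), nrow = 100))
  df <- matrix(FALSE, 100, 10, dimnames = dimnames(b))
  df[1:6, 1] <- TRUE   # 6% -> dropped
  df[1:5, 2] <- TRUE   # exactly 5% -> retained
  attr(b, "detection_failure") <- df
  out <- filter_arrays(b, max_failure = 0.05)
  expect_identical(ncol(out), 9L)
  expect_identical(attr(out, "dropped_samples"), "s01")

  df2 <- df; df2[1:10, c(3, 7)] <- TRUE
  attr(b, "detection_failure") <- df2
  expect_identical(ncol(filter_arrays(b)), 7L)

  attr(b, "detection_failure") <- NULL
  expect_error(filter_arrays(b), "detection_failure")
})

test_that("probe and array filtering commute on non-interacting fixtures", {
  b <- toy_beta(matrix(runif(200), nrow = 20))
  ann <- toy_manifest("chr1", seq(100, 2000, by = 100), probe_id = rownames(b))
  ann$flags[c(3, 11)] <- "snp_overlap"
  df <- matrix(FALSE, 20, 10, dimnames = dimnames(b))
  df[, 4] <- TRUE
  attr(b, "detection_failure") <- df
  a_then_p <- filter_probes(filter_arrays(b), ann)
  p_then_a <- filter_arrays(filter_probes(b, ann))
  expect_equal(a_then_p[, ], p_then_a[, ])
})

test_that("match_controls selects same-sex nearest-age controls deterministically", {
  cases <- data.frame(sample_id = sprintf("case_%d", 1:8),
                      group = "case",
                      sex = rep(c("F", "M"), each = 4),
                      age = c(10, 12, 14, 16, 9, 11, 13, 15))
  set.seed(42)
  pool <- data.frame(sample_id = sprintf("ctrl_%03d", 1:120),
                     group = "control",
                     sex = rep(c("F", "M"), 60),
                     age = runif(120, 2, 40))
  m <- match_controls(cases, pool, ratio = 7)
  expect_length(m$control_ids, 56)
  expect_false(anyDuplicated(m$control_ids) > 0)
  for (cid in m$case_ids)
    expect_true(all(pool$sex[match(m$match_table[[cid]], pool$sample_id)] ==
                      cases$sex[cases$sample_id == cid]))

  # invariant to pool row order
  m2 <- match_controls(cases, pool[sample(nrow(pool)), ], ratio = 7)
  expect_identical(m, m2)

  # age ties break lexicographically
  tie_pool <- data.frame(sample_id = c("ctrl_b", "ctrl_a", "ctrl_c"),
                         group = "control", sex = "F", age = c(12, 8, 30))
  one_case <- data.frame(sample_id = "case_x", group = "case", sex = "F", age = 10)
  mt <- match_controls(one_case, tie_pool, ratio = 1)
  expect_identical(mt$control_ids, "ctrl_a")

  # forced solution: exactly ratio same-sex clones per case
  clone_pool <- data.frame(sample_id = sprintf("c%02d", 1:7), group = "control",
                           sex = "F", age = 10)
  mf <- match_controls(one_case, clone_pool, ratio = 7)
  expect_setequal(mf$control_ids, clone_pool$sample_id)

  expect_error(match_controls(cases, pool[1:10, ], ratio = 7), "pool smaller")
})

test_that("beta/M conversion matches log2 odds and round-trips", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(1e-4, 1 - 1e-4, length.out = 101)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("cell deconvolution recovers exact memberships and mixtures", {
  set.seed(3)
  ref <- matrix(runif(3 * 60, 0.05, 0.95), nrow = 3,
                dimnames = list(c("A", "B", "C"), sprintf("cg%02d", 1:60)))
  pure <- toy_beta(t(ref["B", , drop = FALSE]), probes = colnames(ref),
                   samples = "pureB")
  props <- estimate_cell_proportions(pure, ref)
  expect_equal(unname(props["pureB", ]), c(0, 1, 0), tolerance = 1e-8)

  mix <- toy_beta(matrix(0.5 * ref["A", ] + 0.5 * ref["C", ]),
                  probes = colnames(ref), samples = "mixAC")
  pm <- estimate_cell_proportions(mix, ref)
  expect_equal(unname(pm["mixAC", ]), c(0.5, 0, 0.5), tolerance = 1e-6)

  noisy <- toy_beta(matrix(runif(60 * 4), nrow = 60), probes = colnames(ref))
  pn <- estimate_cell_proportions(noisy, ref)
  expect_true(all(pn >= 0))
  expect_equal(unname(rowSums(pn)), rep(1, 4))

  expect_error(estimate_cell_proportions(pure[1:10, , drop = FALSE], ref),
               "at least 50 probes")
})

test_that("pca_qc flags planted outliers and reproduces optimal embeddings", {
  set.seed(8)
  m <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(NULL, sprintf("s%02d", 1:12)))
  m[, 5] <- m[, 4]                 # duplicated sample
  qc <- pca_qc(m)
  expect_equal(qc$coords[5, ], qc$coords[4, ])

  shift_idx <- sample(500, 150)
  m2 <- m; m2[shift_idx, 12] <- m2[shift_idx, 12] + 5
  qc2 <- pca_qc(m2)
  expect_true(qc2$flagged["s12"])

  # Torgerson cross-check: PCA scores reproduce the same pairwise sample
  # distances as classical MDS at the same rank (both are rank-k optimal)
  toy <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, letters[1:5]))
  qc3 <- pca_qc(toy, n_components = 2)
  mds <- cmdscale(dist(t(toy)), k = 2)
  expect_equal(as.matrix(dist(qc3$coords)), as.matrix(dist(mds)),
               tolerance = 1e-9)

  expect_error(pca_qc(m[, 1:2]), "at least 3")
  expect_error(pca_qc(matrix(1, 5, 4)), "constant")
})
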