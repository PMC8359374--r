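# Internal helpers shared across modules.

REGION_CATEGORIES <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR", "IGR")
PROMOTER_CATEGORIES <- c("TSS200", "TSS1500", "1stExon", "5'UTR")
GROUP_LEVELS <- c("case", "control", "vus", "other_disorder")
PROBE_FLAGS <- c("sex_chromosome", "cross_reactive", "snp_overlap")

#' Fifteen-state chromatin vocabulary
#'
#' The chromatin-state labels used by the synthetic epigenome generator and
#' the enrichment profiler, following the 15-state Roadmap Epigenomics
#' segmentation (active TSS through quiescent).
#'
#' @return Character vector of 15 state names.
#' @export
chromatin_states <- function() {
  c("Active TSS", "Flanking Active TSS", "Transcription at 5' and 3'",
    "Strong Transcription", "Weak Transcription", "Genic Enhancers",
    "Enhancers", "ZNF genes & repeats", "Heterochromatin",
    "Bivalent poised TSS", "Flanking Bivalent TSS/Enhancer",
    "Bivalent Enhancer", "Repressed PolyComb", "Weak Repressed PolyComb",
    "Quiescent")
}

# Dirichlet draws via independent gammas; rows sum to 1 exactly.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

# Newton inversion of the trigamma function (used by the empirical-Bayes
# moment estimator). Monotone decreasing on (0, Inf).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(75)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-12) break
  }
  x
}

# Run a block of code under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Names of cell-proportion columns in a sample sheet.
celltype_columns <- function(sheet) grep("^ct_", names(sheet), value = TRUE)

row_medians <- function(x) apply(x, 1L, median)
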