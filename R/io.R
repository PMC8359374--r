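# Readers/writers for the on-disk formats the pipeline touches: beta-value
# TSV, sample sheet TSV, probe manifest TSV, BED4 interval tracks, and the
# JSON model format. All pairs are lossless round trips.

validate_beta <- function(values, detection_failure = NULL) {
  if (is.null(dim(values)) || nrow(values) == 0L) stop("no probes")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix must carry probe (row) and sample (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("beta value outside [0,1] at probe '%s', sample '%s' (%g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  if (!is.null(detection_failure)) {
    if (!identical(dim(detection_failure), dim(values)))
      stop("detection_failure must have the dimensions of the beta matrix")
    detection_failure <- detection_failure != 0
    dimnames(detection_failure) <- dimnames(values)
    attr(values, "detection_failure") <- detection_failure
  }
  na_at <- is.na(values)
  if (any(na_at)) {
    df <- attr(values, "detection_failure")
    if (is.null(df) || any(na_at & !df))
      stop("missing beta values are only allowed where detection_failure marks them")
  }
  values
}

#' Read / write a beta-value matrix
#'
#' Beta matrices are stored as TSV with probe ids in the first column
#' (`probe_id`) and one column per sample. Values must lie in \[0,1\];
#' missing values are only accepted where a detection-failure matrix (same
#' layout, 0/1 entries) marks a failed measurement.
#'
#' @param path TSV file path.
#' @param failures_path Optional path of a 0/1 detection-failure TSV with the
#'   same layout.
#' @return Numeric matrix (probes x samples), with a logical
#'   `"detection_failure"` attribute when failures were supplied.
#' @export
read_beta_matrix <- function(path, failures_path = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no probes")
  if (ncol(tab) < 2L) stop("malformed header: expected probe_id plus sample columns")
  if (names(tab)[1] != "probe_id") stop("malformed header: first column must be 'probe_id'")
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric beta values")
  rownames(values) <- as.character(tab[[1]])
  failures <- NULL
  if (!is.null(failures_path)) {
    ft <- read.delim(failures_path, check.names = FALSE, stringsAsFactors = FALSE)
    failures <- as.matrix(ft[, -1, drop = FALSE]) != 0
    rownames(failures) <- as.character(ft[[1]])
    if (!identical(dimnames(failures), dimnames(values)))
      stop("detection-failure file does not match the beta matrix layout")
  }
  validate_beta(values, failures)
}

#' @rdname read_beta_matrix
#' @param beta Validated beta matrix.
#' @export
write_beta_matrix <- function(beta, path, failures_path = NULL) {
  out <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df <- attr(beta, "detection_failure")
  if (!is.null(failures_path) && !is.null(df)) {
    out <- data.frame(probe_id = rownames(beta), df + 0L, check.names = FALSE)
    write.table(out, failures_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group", "sex", "age")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(sheet$group), GROUP_LEVELS)
  if (length(bad))
    stop(sprintf("unknown group label(s) %s; allowed: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(GROUP_LEVELS, collapse = ", ")))
  if (!all(sheet$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(sheet$age < 0)) stop("age must be non-negative")
  ct <- celltype_columns(sheet)
  if (length(ct)) {
    props <- as.matrix(sheet[, ct, drop = FALSE])
    if (any(props < 0)) stop("cell proportions must be non-negative")
    if (any(abs(rowSums(props) - 1) > 1e-6))
      stop("cell proportions must sum to 1 (tolerance 1e-6)")
  }
  sheet
}

#' Read / write a sample sheet
#'
#' TSV with columns `sample_id`, `group` (one of case, control, vus,
#' other_disorder — optionally suffixed as `other_disorder:<cohort>`),
#' `sex` (F/M), `age` (years), and optional cell-proportion columns named
#' `ct_<celltype>` which must form a simplex per sample.
#'
#' @param path TSV file path.
#' @return A validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  # cohort tags ride along in an optional 'cohort' column
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet Validated sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(ann) {
  need <- c("probe_id", "chrom", "position", "region_category", "flags")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe ids in manifest")
  if (any(ann$position < 0)) stop("manifest positions must be non-negative")
  bad <- setdiff(unique(ann$region_category), REGION_CATEGORIES)
  if (length(bad))
    stop(sprintf("unknown region category %s; allowed: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(REGION_CATEGORIES, collapse = ", ")))
  fl <- setdiff(unlist(strsplit(ann$flags[nzchar(ann$flags)], ";", fixed = TRUE)),
                PROBE_FLAGS)
  if (length(fl)) stop("unknown probe flag(s): ", paste(fl, collapse = ", "))
  ann
}

#' Read / write a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `position` (1-based bp, as in the
#' EPIC manifest), `region_category` (TSS200, TSS1500, 5'UTR, 1stExon, Body,
#' 3'UTR or IGR) and `flags` (semicolon-separated subset of sex_chromosome,
#' cross_reactive, snp_overlap; empty when unflagged).
#'
#' @param path TSV file path.
#' @return A validated `data.frame`.
#' @export
read_manifest <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                    colClasses = c(flags = "character"))
  ann$probe_id <- as.character(ann$probe_id)
  ann$flags[is.na(ann$flags)] <- ""
  validate_manifest(ann)
}

#' @rdname read_manifest
#' @param ann Validated manifest.
#' @export
write_manifest <- function(ann, path) {
  keep <- c("probe_id", "chrom", "position", "region_category", "flags")
  write.table(ann[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED4 interval tracks
#'
#' BED files are 0-based half-open on disk; in memory intervals are held as
#' `GRanges` (1-based closed, the Bioconductor convention). The fourth BED
#' column, when present, becomes the `label` metadata column.
#'
#' @param path BED file path.
#' @return A `GRanges` with an optional `label` column.
#' @export
read_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED needs at least chrom, start, end")
  if (any(tab[[2]] >= tab[[3]]))
    stop("BED interval with start >= end")
  if (any(tab[[2]] < 0)) stop("negative BED start")
  gr <- GenomicRanges::GRanges(tab[[1]],
                               IRanges::IRanges(start = tab[[2]] + 1L, end = tab[[3]]))
  if (ncol(tab) >= 4L) S4Vectors::mcols(gr)$label <- as.character(tab[[4]])
  gr
}

#' @rdname read_bed
#' @param gr `GRanges` to write; the `label` column fills BED column 4.
#' @export
write_bed <- function(gr, path) {
  lab <- S4Vectors::mcols(gr)$label
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(lab)) out$label <- lab
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted episignature model
#'
#' Models are stored as single-file JSON carrying the ordered signature probe
#' list, per-probe case/control reference medians, the funnel thresholds, and
#' the linear MVP classifier (weights, offset and Platt calibration
#' coefficients), at full numeric precision. `load_model(save_model(m))`
#' reproduces probe order, medians and classifier scores exactly.
#'
#' @param model An object of class `"episignature"` (see [episignature()]).
#' @param path JSON file path.
#' @return `load_model` returns the restored `"episignature"` object (probe
#'   statistics tables beyond the selected probes are not persisted).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "episignature"))
  payload <- list(
    format = "episignr_model",
    version = MODEL_FORMAT_VERSION,
    probes = model$probes,
    case_median = as.list(model$case_median),
    control_median = as.list(model$control_median),
    funnel = model$funnel,
    config = unclass(model$config),
    classifier = if (is.null(model$classifier)) NULL else unclass(model$classifier)
  )
  # I(17): 17 significant digits, enough for an exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot load model: ", conditionMessage(e)))
  if (!identical(payload$format, "episignr_model"))
    stop("not an episignr model file")
  if (!identical(as.integer(payload$version), MODEL_FORMAT_VERSION))
    stop(sprintf("model format version %s not supported (expected %d)",
                 payload$version, MODEL_FORMAT_VERSION))
  if (is.null(payload$probes) || is.null(payload$case_median))
    stop("truncated model file")
  clf <- payload$classifier
  if (!is.null(clf)) {
    clf$w <- setNames(as.numeric(clf$w), names(clf$w) %||% payload$probes)
    if (is.null(names(clf$w)) || !any(nzchar(names(clf$w))))
      names(clf$w) <- payload$probes
    clf <- structure(clf, class = "mvp_classifier")
  }
  cfg <- payload$config
  structure(list(probes = as.character(payload$probes),
                 case_median = setNames(as.numeric(unlist(payload$case_median)),
                                        names(payload$case_median)),
                 control_median = setNames(as.numeric(unlist(payload$control_median)),
                                           names(payload$control_median)),
                 funnel = payload$funnel,
                 config = structure(cfg, class = "pipeline_config"),
                 classifier = clf,
                 stats = NULL, dmps = NULL,
                 training = NULL),
            class = "episignature")
}
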