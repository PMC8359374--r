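# Synthetic EPIC-like cohorts with known planted truth: manifest with
# CpG-island-like probe clustering, a blood cell mixing model with
# case/control composition confounding, planted hypermethylation signal
# (probe- and region-level), confounder cohorts with disjoint signatures,
# and multi-epigenome chromatin-state segmentations.

#' Simulate an EPIC-like probe manifest
#'
#' Places probes on synthetic chromosomes as a mixture of CpG-island-like
#' clusters (5-15 probes, 50-500 bp gaps) and isolated probes (2-20 kb gaps).
#' Each cluster draws a region-category "theme" from the configured marginal
#' frequencies and its probes keep the theme with probability 0.8 (otherwise
#' an independent draw), so the per-probe category marginals equal the
#' configured frequencies while clusters stay category-coherent. A configured
#' fraction of probes carries a QC flag.
#'
#' @param config A [sim_config()].
#' @return Manifest `data.frame` with attributes `clusters` (cluster extents
#'   and themes) and `chrom_lengths`.
#' @export
simulate_manifest <- function(config = sim_config()) {
  with_seed(config$seed, {
    per_chrom <- diff(round(seq(0, config$n_probes, length.out = config$n_chromosomes + 1)))
    freqs <- config$category_freqs
    rows <- list(); clusters <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- paste0("chr", ci)
      quota <- per_chrom[ci]
      pos <- integer(0); clust <- integer(0)
      cur <- 10000L; cl_id <- 0L
      while (length(pos) < quota) {
        cl_id <- cl_id + 1L
        if (runif(1) < config$cluster_fraction) {
          size <- sample(5:15, 1L)
        } else {
          size <- 1L
        }
        size <- min(size, quota - length(pos))
        gaps <- if (size > 1L) sample(50:500, size - 1L, replace = TRUE) else integer(0)
        p <- cur + c(0L, cumsum(gaps))
        pos <- c(pos, p)
        clust <- c(clust, rep(cl_id, size))
        cur <- p[length(p)] + sample(2000:20000, 1L)
      }
      theme_by_cluster <- sample(names(freqs), max(clust), replace = TRUE, prob = freqs)
      theme <- theme_by_cluster[clust]
      own <- sample(names(freqs), quota, replace = TRUE, prob = freqs)
      use_theme <- runif(quota) < 0.8
      category <- ifelse(use_theme, theme, own)
      rows[[ci]] <- data.frame(chrom = chrom, position = pos,
                               region_category = category,
                               cluster = paste0(chrom, "_c", clust),
                               stringsAsFactors = FALSE)
      cl_sizes <- tabulate(clust)
      clusters[[ci]] <- data.frame(
        chrom = chrom,
        cluster = paste0(chrom, "_c", seq_len(max(clust))),
        start = as.integer(tapply(pos, clust, min)),
        end = as.integer(tapply(pos, clust, max)),
        n = cl_sizes,
        theme = theme_by_cluster,
        stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    n <- nrow(ann)
    ann$probe_id <- sprintf("cg%07d", seq_len(n))
    flagged <- runif(n) < config$flag_fraction
    flags <- character(n)
    flags[flagged] <- sample(PROBE_FLAGS, sum(flagged), replace = TRUE)
    ann$flags <- flags
    ann <- ann[, c("probe_id", "chrom", "position", "region_category",
                   "flags", "cluster")]
    cl <- do.call(rbind, clusters)
    chrom_lengths <- tapply(ann$position, ann$chrom, max) + 10000
    attr(ann, "clusters") <- cl
    attr(ann, "chrom_lengths") <- setNames(as.numeric(chrom_lengths),
                                           names(chrom_lengths))
    validate_manifest(ann)
  })
}

# Unflagged probes eligible for signal planting.
unflagged <- function(ann) ann$probe_id[!nzchar(ann$flags)]

# Pick signal probes: first whole clusters (>= min_run eligible probes,
# promoter-themed clusters upweighted), then isolated probes with
# promoter-category upweighting. Only probes whose baseline leaves headroom
# for the planted shift are eligible, so every planted delta is deliverable
# on the beta scale (hypermethylation needs an unsaturated baseline, the
# situation the promoter-centred biology produces anyway).
plant_signal <- function(ann, config, baseline, exclude = character(0),
                         min_run = 5L) {
  if (config$n_signal_probes == 0L)
    return(list(probes = character(0), region_probes = character(0),
                regions = data.frame()))
  cl <- attr(ann, "clusters")
  dmax <- config$delta_beta_range[2]
  hyper_ok <- baseline <= 0.95 - dmax
  hypo_ok <- baseline >= 0.05 + dmax
  headroom <- if (config$fraction_hyper >= 1) hyper_ok
  else if (config$fraction_hyper <= 0) hypo_ok
  else hyper_ok & hypo_ok
  ok <- !nzchar(ann$flags) & !(ann$probe_id %in% exclude) & headroom
  by_cluster <- split(ann$probe_id[ok], ann$cluster[ok])
  sizes <- lengths(by_cluster)
  # a planted region must be a fully affected cluster: every member probe
  # eligible, so the region-mean effect is not diluted by unplanted members
  total <- table(ann$cluster)
  elig <- names(sizes)[sizes >= min_run &
                         sizes == as.integer(total[names(sizes)])]
  regions <- data.frame()
  region_probes <- character(0)
  if (config$n_signal_regions > 0L && length(elig) > 0L) {
    themes <- cl$theme[match(elig, cl$cluster)]
    wt <- ifelse(themes %in% PROMOTER_CATEGORIES, config$promoter_bias, 1)
    n_reg <- min(config$n_signal_regions, length(elig))
    chosen <- sample(elig, n_reg, prob = wt)
    region_probes <- unlist(by_cluster[chosen], use.names = FALSE)
    i <- match(chosen, cl$cluster)
    regions <- data.frame(chrom = cl$chrom[i],
                          start = cl$start[i] - 1L,  # 0-based half-open
                          end = cl$end[i],
                          cluster = chosen,
                          stringsAsFactors = FALSE)
  }
  n_single <- max(config$n_signal_probes - length(region_probes), 0L)
  singles <- character(0)
  if (n_single > 0L) {
    pool <- ann$probe_id[ok & !(ann$probe_id %in% region_probes)]
    if (length(pool) < n_single) stop("requested signal probes exceed available probes")
    cat_pool <- ann$region_category[match(pool, ann$probe_id)]
    wt <- ifelse(cat_pool %in% PROMOTER_CATEGORIES, config$promoter_bias, 1)
    singles <- sample(pool, n_single, prob = wt)
  }
  list(probes = c(region_probes, singles),
       region_probes = region_probes, regions = regions)
}

#' Simulate a synthetic EPIC-like cohort
#'
#' Generates beta values for cases, a control pool, confounder ("other
#' disorder") cohorts and optional VUS samples. Per-probe baselines are
#' bimodal (low mode near 0.1 at promoter categories, high mode near 0.85 at
#' Body/IGR); each sample mixes six blood cell-type profiles with Dirichlet
#' proportions (cases receive a composition shift, making the covariate
#' adjustment consequential); planted case effects are applied on the logit
#' scale so the beta-scale case-minus-control difference matches the planted
#' delta-beta; Gaussian noise is added on the logit scale, so betas never
#' reach 0 or 1 exactly. Confounder cohorts carry planted signatures disjoint
#' from the case signature and from each other.
#'
#' @param config A [sim_config()].
#' @param manifest Optional manifest from [simulate_manifest()] (generated
#'   from `config` when omitted).
#' @return List with `beta` (probes x samples, detection failures marked when
#'   `det_fail_rate > 0`), `sheet` (sample sheet with true `ct_*`
#'   proportions when configured), `manifest`, and `truth` (a
#'   `SimulationTruth`: signal probes and deltas, planted regions with
#'   direction, confounder signatures, cell reference profiles, true
#'   per-sample proportions).
#' @export
simulate_cohort <- function(config = sim_config(), manifest = NULL) {
  if (is.null(manifest)) manifest <- simulate_manifest(config)
  ann <- manifest
  with_seed(config$seed + 1L, {
    n <- nrow(ann)
    promoter <- ann$region_category %in% PROMOTER_CATEGORIES

    # bimodal baseline: promoter probes mostly unmethylated, gene-body /
    # intergenic probes mostly methylated
    low_mode <- rbeta(n, 4, 36)            # mean 0.1
    high_mode <- rbeta(n, 34, 6)           # mean 0.85
    take_low <- ifelse(promoter, runif(n) < 0.9, runif(n) < 0.2)
    baseline <- ifelse(take_low, low_mode, high_mode)
    baseline <- clip01(baseline, 0.01)

    # cell-type reference profiles on the logit scale
    k <- config$n_cell_types
    mu <- qlogis(baseline)
    informative <- runif(n) < config$celltype_informative_fraction
    ref_logit <- matrix(rep(mu, each = k), nrow = k)
    ref_logit[, informative] <- ref_logit[, informative] +
      matrix(rnorm(k * sum(informative), sd = config$celltype_sd), nrow = k)
    ref_beta <- plogis(ref_logit)
    cell_names <- c("Gran", "CD4T", "CD8T", "Bcell", "NK", "Mono",
                    paste0("ct", seq_len(max(0, k - 6))))[seq_len(k)]
    rownames(ref_beta) <- cell_names
    colnames(ref_beta) <- ann$probe_id

    # cohort layout
    ids <- list(case = sprintf("case_%02d", seq_len(config$n_cases)),
                control = sprintf("ctrl_%03d", seq_len(config$n_controls)))
    other_ids <- lapply(seq_len(config$n_other_disorders), function(d)
      sprintf("dis%d_%02d", d, seq_len(config$n_per_other)))
    vus_ids <- if (config$n_vus > 0L) sprintf("vus_%02d", seq_len(config$n_vus)) else character(0)
    all_ids <- c(ids$case, ids$control, unlist(other_ids), vus_ids)
    n_samp <- length(all_ids)
    group <- c(rep("case", config$n_cases), rep("control", config$n_controls),
               rep("other_disorder", config$n_other_disorders * config$n_per_other),
               rep("vus", length(vus_ids)))
    cohort <- c(rep("", config$n_cases + config$n_controls),
                rep(sprintf("dis%d", seq_len(config$n_other_disorders)),
                    each = config$n_per_other),
                rep("", length(vus_ids)))

    # ages/sexes; controls span the case range so matches always exist
    age <- numeric(n_samp); sex <- character(n_samp)
    is_case_s <- group == "case"
    age[is_case_s] <- round(runif(sum(is_case_s), 5, 25), 1)
    age[!is_case_s] <- round(runif(sum(!is_case_s), 2, 40), 1)
    sex <- sample(c("F", "M"), n_samp, replace = TRUE)
    # control sexes proportional to case sexes so matched controls exist at
    # any ratio up to n_controls / n_cases
    n_case_f <- sum(sex[is_case_s] == "F")
    n_ctrl_f <- ceiling(config$n_controls * n_case_f / config$n_cases)
    is_ctrl <- group == "control"
    sex[is_ctrl] <- sample(c(rep("F", n_ctrl_f),
                             rep("M", config$n_controls - n_ctrl_f)))

    # Dirichlet mixing proportions with a case composition shift
    alpha <- c(11, 3.5, 2.5, 1.5, 1, 1.5, rep(1, max(0, k - 6)))[seq_len(k)]
    alpha_case <- alpha
    alpha_case[1] <- alpha[1] * (1 + config$celltype_case_shift)
    props <- matrix(NA_real_, n_samp, k, dimnames = list(all_ids, cell_names))
    shifted <- group %in% c("case", "vus")   # vus drawn from the case arm
    props[!shifted, ] <- rdirichlet(sum(!shifted), alpha)
    props[shifted, ] <- rdirichlet(sum(shifted), alpha_case)

    # planted case signal (regions first, then promoter-biased singletons)
    names(baseline) <- ann$probe_id
    sig <- plant_signal(ann, config, baseline)
    sign_draw <- function(n) ifelse(runif(n) < config$fraction_hyper, 1, -1)
    region_list <- sig$regions
    delta <- setNames(numeric(0), character(0))
    if (nrow(region_list) > 0L) {
      reg_delta <- runif(nrow(region_list), config$delta_beta_range[1],
                         config$delta_beta_range[2]) * sign_draw(nrow(region_list))
      region_list$direction <- ifelse(reg_delta > 0, "hyper", "hypo")
      region_list$delta_beta <- reg_delta
      for (r in seq_len(nrow(region_list))) {
        pr <- intersect(sig$region_probes,
                        ann$probe_id[ann$cluster == region_list$cluster[r]])
        delta[pr] <- reg_delta[r]
      }
    }
    singles <- setdiff(sig$probes, names(delta))
    if (length(singles))
      delta[singles] <- runif(length(singles), config$delta_beta_range[1],
                              config$delta_beta_range[2]) * sign_draw(length(singles))

    # confounder signatures, disjoint from the case signature and each other
    taken <- sig$probes
    conf_sigs <- list()
    dmax <- config$delta_beta_range[2]
    headroom_ids <- ann$probe_id[if (config$fraction_hyper >= 1)
      baseline <= 0.95 - dmax else if (config$fraction_hyper <= 0)
        baseline >= 0.05 + dmax else
          baseline <= 0.95 - dmax & baseline >= 0.05 + dmax]
    for (d in seq_len(config$n_other_disorders)) {
      pool <- setdiff(intersect(unflagged(ann), headroom_ids), taken)
      n_conf <- min(config$n_signal_probes, length(pool))
      pick <- sample(pool, n_conf)
      dd <- runif(n_conf, config$delta_beta_range[1], config$delta_beta_range[2]) *
        sign_draw(n_conf)
      conf_sigs[[sprintf("dis%d", d)]] <- setNames(dd, pick)
      taken <- c(taken, pick)
    }

    # which vus samples truly carry the case signature
    vus_carrier <- if (length(vus_ids))
      runif(length(vus_ids)) < config$vus_case_fraction else logical(0)

    # assemble betas: logit(cell mixture) + planted offset + noise
    mix_beta <- t(ref_beta) %*% t(props)          # probes x samples
    logit_mix <- qlogis(clip01(mix_beta, 1e-6))
    # Planted offsets are calibrated so the expected beta-scale shift under
    # the noise + composition spread equals the planted delta: per probe the
    # logit values are treated as N(mean, var + noise^2) and the expectation
    # of plogis is taken by Gauss-Hermite quadrature.
    gh <- pracma::gaussHermite(21)
    expected_beta <- function(m, v)
      sum(gh$w * plogis(m + sqrt(2 * v) * gh$x)) / sqrt(pi)
    offset_for <- function(sig_delta) {
      vapply(names(sig_delta), function(j) {
        lj <- logit_mix[j, ]
        m <- mean(lj); v <- var(lj) + config$noise_sd^2
        base <- expected_beta(m, v)
        target <- min(max(base + sig_delta[[j]], 0.001), 0.999)
        uniroot(function(d) expected_beta(m + d, v) - target,
                lower = -25, upper = 25, tol = 1e-10)$root
      }, numeric(1))
    }
    case_off <- offset_for(delta)
    eff <- matrix(0, n, n_samp, dimnames = list(ann$probe_id, all_ids))
    carriers <- c(ids$case, vus_ids[vus_carrier])
    eff[names(case_off), carriers] <- case_off
    if (config$global_shift != 0) {
      bg <- setdiff(ann$probe_id, names(case_off))
      eff[bg, carriers] <- eff[bg, carriers] + config$global_shift
    }
    for (d in seq_along(conf_sigs)) {
      off_d <- offset_for(conf_sigs[[d]])
      eff[names(off_d), other_ids[[d]]] <- off_d
    }
    noise <- matrix(rnorm(n * n_samp, sd = config$noise_sd), n, n_samp)
    beta <- plogis(logit_mix + eff + noise)
    dimnames(beta) <- list(ann$probe_id, all_ids)

    sheet <- data.frame(sample_id = all_ids, group = group, cohort = cohort,
                        sex = sex, age = age, stringsAsFactors = FALSE)
    if (config$include_cell_proportions) {
      pr <- as.data.frame(props)
      names(pr) <- paste0("ct_", cell_names)
      sheet <- cbind(sheet, pr)
    }
    sheet <- validate_sample_sheet(sheet)

    failures <- NULL
    if (config$det_fail_rate > 0) {
      failures <- matrix(runif(n * n_samp) < config$det_fail_rate, n, n_samp,
                         dimnames = dimnames(beta))
      beta[failures] <- NA_real_
    }
    beta <- validate_beta(beta, failures)

    truth <- list(signal_probe_ids = names(delta),
                  signal_delta = delta,
                  signal_regions = region_list,
                  confounder_signature_ids = lapply(conf_sigs, names),
                  confounder_deltas = conf_sigs,
                  cell_reference = ref_beta,
                  per_sample_proportions = props,
                  vus_carriers = vus_ids[vus_carrier])
    list(beta = beta, sheet = sheet, manifest = ann, truth = truth)
  })
}

#' Simulate reference epigenome chromatin-state segmentations
#'
#' Partitions every chromosome of the manifest's genome into labeled segments
#' over the 15-state vocabulary, once per synthetic epigenome. Promoter-themed
#' probe clusters are covered by an "Active TSS" segment (with flanking
#' segments) in most epigenomes, so planted promoter regions are genuinely
#' enriched in that state; the remaining genome is filled with background
#' segments dominated by the quiescent state. Every base of every chromosome
#' is covered by exactly one state.
#'
#' @param config A [sim_config()] (`n_epigenomes` controls the count).
#' @param manifest Manifest from [simulate_manifest()].
#' @return List of `GRanges`, each with a `label` metadata column.
#' @export
simulate_epigenomes <- function(config, manifest) {
  cl <- attr(manifest, "clusters")
  chrom_lengths <- attr(manifest, "chrom_lengths")
  if (is.null(cl) || is.null(chrom_lengths))
    stop("manifest lacks cluster/chromosome annotations (use simulate_manifest)")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  states <- chromatin_states()
  bg_states <- c("Quiescent", "Heterochromatin", "Repressed PolyComb",
                 "Weak Repressed PolyComb", "Weak Transcription",
                 "Strong Transcription", "Enhancers", "Genic Enhancers",
                 "Transcription at 5' and 3'", "ZNF genes & repeats",
                 "Bivalent poised TSS", "Flanking Bivalent TSS/Enhancer",
                 "Bivalent Enhancer", "Flanking Active TSS", "Active TSS")
  bg_prob <- c(0.45, 0.08, 0.05, 0.08, 0.10, 0.06, 0.06, 0.02, 0.02, 0.02,
               0.02, 0.01, 0.02, 0.005, 0.005)
  anchors <- cl[cl$theme %in% PROMOTER_CATEGORIES & cl$n >= 3, ]
  with_seed(config$seed + 2L, {
    lapply(seq_len(config$n_epigenomes), function(e) {
      seg_chrom <- character(0); seg_s <- numeric(0)
      seg_e <- numeric(0); seg_l <- character(0)
      for (chrom in names(chrom_lengths)) {
        L <- chrom_lengths[[chrom]]
        anc <- anchors[anchors$chrom == chrom, ]
        anc <- anc[order(anc$start), ]
        active <- anc[runif(nrow(anc)) < 0.85, , drop = FALSE]
        # active blocks with flanks, clipped to the chromosome
        blocks <- if (nrow(active)) data.frame(
          start = pmax(active$start - 500, 1),
          core_start = pmax(active$start - 200, 1),
          core_end = pmin(active$end + 200, L),
          end = pmin(active$end + 500, L)) else
            data.frame(start = numeric(0), core_start = numeric(0),
                       core_end = numeric(0), end = numeric(0))
        cur <- 1
        out_s <- numeric(0); out_e <- numeric(0); out_l <- character(0)
        fill_bg <- function(from, to) {
          gap <- to - from + 1
          lens <- numeric(0)
          while (sum(lens) < gap)
            lens <- c(lens, pmax(200, round(rexp(max(8, ceiling(gap / 5000)), 1 / 5000))))
          cut <- which(cumsum(lens) >= gap)[1]
          lens <- lens[seq_len(cut)]
          ends <- from - 1 + cumsum(lens)
          ends[cut] <- to
          starts <- c(from, head(ends, -1) + 1)
          out_s <<- c(out_s, starts); out_e <<- c(out_e, ends)
          out_l <<- c(out_l, sample(bg_states, cut, replace = TRUE, prob = bg_prob))
        }
        if (nrow(blocks)) {
          for (b in seq_len(nrow(blocks))) {
            if (blocks$start[b] > cur) fill_bg(cur, blocks$start[b] - 1)
            st <- max(blocks$start[b], cur)
            if (blocks$core_start[b] > st) {
              out_s <- c(out_s, st); out_e <- c(out_e, blocks$core_start[b] - 1)
              out_l <- c(out_l, "Flanking Active TSS")
            }
            out_s <- c(out_s, blocks$core_start[b]); out_e <- c(out_e, blocks$core_end[b])
            out_l <- c(out_l, "Active TSS")
            if (blocks$end[b] > blocks$core_end[b]) {
              out_s <- c(out_s, blocks$core_end[b] + 1); out_e <- c(out_e, blocks$end[b])
              out_l <- c(out_l, "Flanking Active TSS")
            }
            cur <- blocks$end[b] + 1
          }
        }
        if (cur <= L) fill_bg(cur, L)
        seg_chrom <- c(seg_chrom, rep(chrom, length(out_s)))
        seg_s <- c(seg_s, out_s); seg_e <- c(seg_e, out_e)
        seg_l <- c(seg_l, out_l)
      }
      GenomicRanges::GRanges(seg_chrom,
                             IRanges::IRanges(start = seg_s, end = seg_e),
                             label = seg_l,
                             seqlengths = chrom_lengths)
    })
  })
}
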