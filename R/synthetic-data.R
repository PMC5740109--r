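#' Blood leukocyte types modelled by the cell reference
#' @keywords internal
CELL_TYPES <- c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")

#' Generate a synthetic probe-annotation manifest
#'
#' Builds an array-style manifest with autosomal probes laid out in gene runs
#' (3-10 consecutive probes, 20-200 bp apart, so region-level analyses have
#' genuine probe clusters), sex-chromosome probes, SNP-proximal probes, and
#' array control probes. All counts are exact by construction.
#'
#' @param n_autosomal Number of autosomal probes without a SNP flag.
#' @param n_sex Number of probes on chromosomes X/Y (alternating).
#' @param n_snp_flagged Number of additional autosomal probes flagged as lying
#'   within 10 bp of a SNP.
#' @param n_control Number of array control probes (no genomic position).
#' @param n_genes Number of genes available for probe runs; probes beyond the
#'   gene capacity become intergenic singletons.
#' @param seed Integer seed; identical arguments and seed give byte-identical
#'   manifests.
#' @return A tibble with columns `probe_id`, `chromosome`, `position`, `gene`,
#'   `region_class`, `design_type`, `snp_within_10bp`, `is_control`,
#'   `control_class`.
#' @export
generate_manifest <- function(n_autosomal = 5000, n_sex = 130,
                              n_snp_flagged = 400, n_control = 200,
                              n_genes = 600, seed = 1) {
  counts <- c(n_autosomal, n_sex, n_snp_flagged, n_control)
  if (any(counts < 0)) abort("probe counts must be non-negative")
  if (n_genes < 1) abort("n_genes must be >= 1")

  withr::with_seed(seed, {
    cursor <- setNames(rep(1e5, 24), c(as.character(1:22), "X", "Y"))
    n_auto <- n_autosomal + n_snp_flagged
    rows <- list()
    gene_i <- 0L
    remaining <- n_auto
    while (remaining > 0 && gene_i < n_genes) {
      gene_i <- gene_i + 1L
      len <- min(sample(3:10, 1), remaining)
      chrom <- as.character(sample(1:22, 1))
      start <- cursor[[chrom]] + sample(5000:50000, 1)
      pos <- start + c(0, cumsum(sample(20:200, max(len - 1, 1),
                                        replace = TRUE)))[seq_len(len)]
      cursor[[chrom]] <- pos[len]
      region <- c("TSS1500", "TSS200")[seq_len(min(2, len))]
      if (len > 2) {
        region <- c(region, sample(c("Island", "Body"), len - 2,
                                   replace = TRUE, prob = c(0.3, 0.7)))
      }
      rows[[length(rows) + 1L]] <- tibble(
        chromosome = chrom, position = as.integer(round(pos)),
        gene = sprintf("GENE%04d", gene_i), region_class = region)
      remaining <- remaining - len
    }
    if (remaining > 0) {
      chroms <- as.character(sample(1:22, remaining, replace = TRUE))
      pos <- integer(remaining)
      for (i in seq_len(remaining)) {
        cursor[[chroms[i]]] <- cursor[[chroms[i]]] + sample(2000:20000, 1)
        pos[i] <- as.integer(cursor[[chroms[i]]])
      }
      rows[[length(rows) + 1L]] <- tibble(
        chromosome = chroms, position = pos, gene = "",
        region_class = "Intergenic")
    }
    auto <- dplyr::bind_rows(rows)

    sex <- NULL
    if (n_sex > 0) {
      sex_chrom <- rep(c("X", "Y"), length.out = n_sex)
      pos <- integer(n_sex)
      for (i in seq_len(n_sex)) {
        cursor[[sex_chrom[i]]] <- cursor[[sex_chrom[i]]] + sample(2000:20000, 1)
        pos[i] <- as.integer(cursor[[sex_chrom[i]]])
      }
      sex <- tibble(chromosome = sex_chrom, position = pos, gene = "",
                    region_class = "Intergenic")
    }

    noncontrol <- dplyr::bind_rows(auto, sex)
    n_nc <- nrow(noncontrol)
    if (n_nc > 0) {
      noncontrol$probe_id <- sprintf("cg%08d", sample.int(9e7, n_nc))
      noncontrol$design_type <- sample(c("I", "II"), n_nc, replace = TRUE,
                                       prob = c(0.28, 0.72))
      noncontrol$snp_within_10bp <- FALSE
      auto_idx <- which(!noncontrol$chromosome %in% c("X", "Y"))
      if (n_snp_flagged > 0) {
        noncontrol$snp_within_10bp[sample(auto_idx, n_snp_flagged)] <- TRUE
      }
      noncontrol$is_control <- FALSE
      noncontrol$control_class <- ""
    }

    ctrl <- NULL
    if (n_control > 0) {
      classes <- rep_len(c("staining", "extension", "hybridization",
                           "bisulfite_conversion", "specificity", "negative"),
                         n_control)
      ctrl <- tibble(
        probe_id = sprintf("ctrl%05d", seq_len(n_control)),
        chromosome = "", position = NA_integer_, gene = "",
        region_class = "Intergenic", design_type = "II",
        snp_within_10bp = FALSE, is_control = TRUE, control_class = classes)
    }

    out <- dplyr::bind_rows(noncontrol, ctrl)
    dplyr::select(out, "probe_id", "chromosome", "position", "gene",
                  "region_class", "design_type", "snp_within_10bp",
                  "is_control", "control_class")
  })
}

#' Generate a synthetic purified-cell methylation reference
#'
#' For each of the six blood cell types, creates marker probes with expected
#' beta near 0.85 in the owning type and near 0.15 in every other type (small
#' jitter), which guarantees the >= 0.3 cross-type separation that
#' reference-based deconvolution needs.
#'
#' @param n_marker_per_type Marker probes per cell type (>= 1).
#' @param seed Integer seed.
#' @return A `cell_reference` object: list with `profile` (marker x 6 matrix of
#'   expected beta), `cell_types`, and `marker_ids`.
#' @export
generate_cell_reference <- function(n_marker_per_type = 10, seed = 1) {
  if (n_marker_per_type < 1) abort("n_marker_per_type must be >= 1")
  withr::with_seed(seed, {
    n <- 6L * n_marker_per_type
    profile <- matrix(clip01(0.15 + rnorm(n * 6, 0, 0.02), eps = 0.01),
                      nrow = n, ncol = 6)
    ids <- character(n)
    for (k in seq_along(CELL_TYPES)) {
      idx <- (k - 1L) * n_marker_per_type + seq_len(n_marker_per_type)
      profile[idx, k] <- clip01(0.85 + rnorm(n_marker_per_type, 0, 0.02),
                                eps = 0.01)
      ids[idx] <- sprintf("ref_%s_%03d", CELL_TYPES[k],
                          seq_len(n_marker_per_type))
    }
    dimnames(profile) <- list(ids, CELL_TYPES)
    structure(list(profile = profile, cell_types = CELL_TYPES,
                   marker_ids = ids),
              class = "cell_reference")
  })
}

#' @export
print.cell_reference <- function(x, ...) {
  cat("<cell_reference> ", nrow(x$profile), " marker probes x ",
      length(x$cell_types), " cell types\n", sep = "")
  invisible(x)
}

#' Generate a synthetic methylation cohort
#'
#' Simulates a case/control whole-blood methylation study with the structure a
#' control-probe-adjusted EWAS assumes: beta values arise as cell-type mixtures
#' (per-sample Dirichlet proportions against the reference profile), plus small
#' per-probe age and smoking effects, a per-sample batch factor that also
#' drives the control-probe intensities (so control-probe PCA can recover it),
#' spiked case-minus-control effects at chosen probes and gene regions, and
#' logit-scale Gaussian noise. A frailty index in [0, 120] is coupled to the
#' true spiked methylation burden with a chosen correlation. Everything needed
#' to score downstream stages is recorded in the `truth` block.
#'
#' @param manifest Probe manifest from [generate_manifest()]. Reference marker
#'   probes are appended to it in the returned study.
#' @param reference A [generate_cell_reference()] object.
#' @param n_case,n_control Group sizes.
#' @param spike_probes Optional tibble with `probe_id`, `delta_beta`: per-probe
#'   case-minus-control effect on the beta scale.
#' @param spike_regions Optional tibble with `gene`, `delta_beta`: every probe
#'   of the gene receives the effect (a contiguous run, hence a true DMR).
#' @param batch_sd SD of the per-sample batch factor (logit scale). 0 disables
#'   the batch signal entirely.
#' @param batch_group_r Correlation between the batch factor and the case
#'   indicator (0 = technical batch independent of phenotype).
#' @param score_index_r Target correlation between the true methylation burden
#'   and the generated frailty index.
#' @param noise_sd SD of the i.i.d. logit-scale measurement noise.
#' @param age_effect_sd,smoke_effect_sd SDs of the per-probe nuisance effects
#'   (logit units per year / per smoker).
#' @param cell_alpha Dirichlet shape for cell proportions; the default matches
#'   granulocyte-dominated whole blood with printed-SD-scale dispersion.
#' @param seed Integer seed.
#' @param cohort_id Cohort label used in sample ids.
#' @return A `meth_study`: list with `beta` (probe x sample matrix in (0,1)),
#'   `control_intensities`, augmented `manifest`, `samples` tibble, and a
#'   `truth` list (spiked probes/regions, true cell proportions, batch factor,
#'   burden, coupling).
#' @export
generate_cohort <- function(manifest, reference, n_case, n_control,
                            spike_probes = NULL, spike_regions = NULL,
                            batch_sd = 0.3, batch_group_r = 0,
                            score_index_r = 0, noise_sd = 0.2,
                            age_effect_sd = 0.005, smoke_effect_sd = 0.05,
                            cell_alpha = 14 * c(CD4T = 0.05, CD8T = 0.17,
                                                NK = 0.08, Bcell = 0.09,
                                                Mono = 0.11, Gran = 0.50),
                            seed = 1, cohort_id = "cohort1") {
  if (abs(score_index_r) > 1) abort("score_index_r must be in [-1, 1]")
  manifest_nc <- dplyr::filter(manifest, !.data$is_control)

  if (!is.null(spike_probes)) {
    unknown <- setdiff(spike_probes$probe_id, manifest_nc$probe_id)
    if (length(unknown)) {
      abort(paste0("spike_probes refer to unknown probe(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(spike_regions)) {
    unknown <- setdiff(spike_regions$gene, manifest_nc$gene)
    if (length(unknown)) {
      abort(paste0("spike_regions refer to unknown gene(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }

  withr::with_seed(seed, {
    n <- n_case + n_control
    is_case <- rep(c(TRUE, FALSE), c(n_case, n_control))
    samples <- tibble(
      sample_id = sprintf("%s_s%04d", cohort_id, seq_len(n)),
      group = factor(ifelse(is_case, "case", "control"),
                     levels = c("control", "case")),
      idu_recency = ifelse(
        is_case, sample(c("current", "past"), n, replace = TRUE,
                        prob = c(58, 158)), "none"),
      age = round(pmin(75, pmax(25, rnorm(n, ifelse(is_case, 51.4, 47.0),
                                          ifelse(is_case, 4.8, 9.0)))), 1),
      smoker = runif(n) < ifelse(is_case, 0.70, 0.48),
      audit_c = pmax(0, round(rnorm(n, ifelse(is_case, 4.7, 3.0),
                                    ifelse(is_case, 3.7, 3.0)))),
      adherence = round(clip01(rnorm(n, 0.75, 0.15)), 3),
      log10_vl = round(pmax(0, rnorm(n, ifelse(is_case, 2.6, 2.8), 1.2)), 2),
      wbc = round(pmax(2, rnorm(n, 6, 1.8)), 2),
      self_reported_sex = "male",
      cohort_id = cohort_id)

    W <- rdirichlet_mat(n, cell_alpha[CELL_TYPES])

    # marker probes join the manifest as ordinary intergenic probes on chr 22,
    # spaced far beyond any clustering gap
    marker_manifest <- tibble(
      probe_id = reference$marker_ids,
      chromosome = "22",
      position = as.integer(1e8 + seq_along(reference$marker_ids) * 10000),
      gene = "", region_class = "Intergenic", design_type = "II",
      snp_within_10bp = FALSE, is_control = FALSE, control_class = "")
    manifest_aug <- dplyr::bind_rows(manifest, marker_manifest)
    probes_nc <- c(manifest_nc$probe_id, reference$marker_ids)
    p <- length(probes_nc)

    # spike table: explicit probes plus all probes of spiked genes
    spike_tbl <- tibble(probe_id = character(), delta_beta = double(),
                        source = character())
    if (!is.null(spike_probes)) {
      spike_tbl <- dplyr::bind_rows(
        spike_tbl, tibble(probe_id = spike_probes$probe_id,
                          delta_beta = spike_probes$delta_beta,
                          source = "probe"))
    }
    region_tbl <- NULL
    if (!is.null(spike_regions)) {
      region_tbl <- purrr::map_dfr(seq_len(nrow(spike_regions)), function(i) {
        g <- spike_regions$gene[i]
        sub <- dplyr::filter(manifest_nc, .data$gene == g)
        tibble(gene = g, delta_beta = spike_regions$delta_beta[i],
               chromosome = sub$chromosome[1],
               start = min(sub$position), end = max(sub$position),
               n_probes = nrow(sub), probe_ids = list(sub$probe_id))
      })
      spike_tbl <- dplyr::bind_rows(
        spike_tbl,
        purrr::map_dfr(seq_len(nrow(region_tbl)), function(i) {
          tibble(probe_id = region_tbl$probe_ids[[i]],
                 delta_beta = region_tbl$delta_beta[i], source = "region")
        }))
    }
    spike_tbl <- dplyr::distinct(spike_tbl, .data$probe_id, .keep_all = TRUE)

    # per-probe baseline logit: hypo/hemi/hyper mixture (bimodal beta);
    # spiked probes are forced hemi-methylated so the added beta-scale effect
    # stays inside (0, 1)
    comp <- sample(1:3, p, replace = TRUE, prob = c(0.35, 0.15, 0.50))
    base_logit <- rnorm(p, c(-2.2, 0, 2.2)[comp], 0.5)
    names(base_logit) <- probes_nc
    base_logit[spike_tbl$probe_id] <- rnorm(nrow(spike_tbl), 0, 0.3)

    # expected beta as a cell mixture: markers use the reference profile,
    # other probes are cell-type invariant
    R_beta <- matrix(inv_logit(base_logit), nrow = p, ncol = 6,
                     dimnames = list(probes_nc, CELL_TYPES))
    R_beta[reference$marker_ids, ] <- reference$profile
    mu <- R_beta %*% t(W)

    l <- logit(clip01(mu))
    age_coef <- rnorm(p, 0, age_effect_sd)
    smoke_coef <- rnorm(p, 0, smoke_effect_sd)
    l <- l + outer(age_coef, samples$age - 49) +
      outer(smoke_coef, as.numeric(samples$smoker))

    # biological logit: baseline mixture + covariate effects + i.i.d.
    # biological noise; the technical batch factor is added on top and is
    # what the control probes carry
    l_bio <- l + matrix(rnorm(p * n, 0, noise_sd), nrow = p)
    if (batch_sd > 0) {
      gs <- as.numeric(scale(as.numeric(is_case)))
      batch <- batch_sd * (batch_group_r * gs +
                             sqrt(1 - batch_group_r^2) * rnorm(n))
      load_p <- rnorm(p, 0, 1)
      l_obs <- l_bio + outer(load_p, batch)
    } else {
      batch <- rep(0, n)
      l_obs <- l_bio
    }

    beta_bio <- inv_logit(l_bio)
    beta <- inv_logit(l_obs)
    dimnames(beta) <- dimnames(beta_bio) <-
      list(probes_nc, samples$sample_id)

    if (nrow(spike_tbl)) {
      beta[spike_tbl$probe_id, is_case] <-
        beta[spike_tbl$probe_id, is_case] + spike_tbl$delta_beta
      beta <- clip01(beta)
      beta_bio[spike_tbl$probe_id, is_case] <-
        beta_bio[spike_tbl$probe_id, is_case] + spike_tbl$delta_beta
      beta_bio <- clip01(beta_bio)
    }

    # control probes carry the batch factor multiplicatively
    ctrl_ids <- manifest$probe_id[manifest$is_control]
    n_ctrl <- length(ctrl_ids)
    control_intensities <- NULL
    if (n_ctrl > 0) {
      baseline_c <- exp(rnorm(n_ctrl, log(3000), 0.5))
      control_intensities <- outer(baseline_c, exp(batch)) *
        exp(matrix(rnorm(n_ctrl * n, 0, 0.1), nrow = n_ctrl))
      dimnames(control_intensities) <- list(ctrl_ids, samples$sample_id)
    }

    # true burden: spike-weighted *biological* methylation (the frailty
    # index couples to the biology, not to technical batch noise)
    if (nrow(spike_tbl)) {
      burden <- colSums(beta_bio[spike_tbl$probe_id, , drop = FALSE] *
                          spike_tbl$delta_beta)
      z_burden <- as.numeric(scale(burden))
    } else {
      z_burden <- rnorm(n)
    }
    v <- score_index_r * z_burden +
      sqrt(1 - score_index_r^2) * rnorm(n)
    samples$vacs_index <- as.integer(round(pmin(120, pmax(0, 33 + 20 * v))))

    truth <- list(
      spike_probes = spike_tbl,
      spike_regions = region_tbl,
      cell_props = dplyr::bind_cols(tibble(sample_id = samples$sample_id),
                                    as_tibble(W)),
      batch = setNames(batch, samples$sample_id),
      burden = setNames(z_burden, samples$sample_id),
      score_index_r = score_index_r)

    structure(list(beta = beta, control_intensities = control_intensities,
                   manifest = manifest_aug, samples = samples, truth = truth),
              class = "meth_study")
  })
}

#' @export
print.meth_study <- function(x, ...) {
  cat("<meth_study> ", nrow(x$beta), " probes x ", ncol(x$beta),
      " samples (", sum(x$samples$group == "case"), " case / ",
      sum(x$samples$group == "control"), " control)\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  truth block: ", nrow(x$truth$spike_probes), " spiked probes, ",
        if (is.null(x$truth$spike_regions)) 0 else nrow(x$truth$spike_regions),
        " spiked regions\n", sep = "")
  }
  invisible(x)
}

#' Monte-Carlo power for a two-group single-probe comparison
#'
#' Simulates the per-probe linear-model (equal-variance t) test at the given
#' group sizes, beta-scale effect and within-group SD, and reports the
#' rejection fraction at `alpha` with its Monte-Carlo standard error. The
#' within-group SD is a required argument: it is a property of the data, not a
#' default of the method.
#'
#' @param n_case,n_control Group sizes.
#' @param delta_beta True case-minus-control difference on the beta scale.
#' @param sd_beta Within-group SD on the beta scale (> 0).
#' @param alpha Significance level in (0, 1).
#' @param n_reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble: `power`, `mc_se`, `n_reps`, `alpha`.
#' @export
estimate_power <- function(n_case, n_control, delta_beta, sd_beta,
                           alpha = 1e-7, n_reps = 1000, seed = 1) {
  if (sd_beta <= 0) abort("sd_beta must be > 0")
  if (n_reps < 100) abort("n_reps must be >= 100")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n_case * n_reps, delta_beta, sd_beta), nrow = n_case)
    x2 <- matrix(rnorm(n_control * n_reps, 0, sd_beta), nrow = n_control)
    m1 <- colMeans(x1)
    m2 <- colMeans(x2)
    ss <- colSums(sweep(x1, 2, m1)^2) + colSums(sweep(x2, 2, m2)^2)
    df <- n_case + n_control - 2
    tstat <- (m1 - m2) / sqrt((ss / df) * (1 / n_case + 1 / n_control))
    pvals <- 2 * pt(-abs(tstat), df)
    power <- mean(pvals < alpha)
    tibble(power = power,
           mc_se = sqrt(power * (1 - power) / n_reps),
           n_reps = n_reps, alpha = alpha)
  })
}
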