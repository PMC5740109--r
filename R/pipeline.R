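#' Default demonstration configuration
#'
#' A small, fully synthetic three-cohort study (discovery, replication, test)
#' with spiked probes, two spiked gene regions, a batch factor carried by the
#' control probes, and a frailty index coupled to the spiked methylation
#' burden. Every stochastic stage has an explicit seed derived from the
#' top-level seed, so two runs of the same config are identical.
#'
#' @param seed Top-level integer seed.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 42) {
  list(
    seed = seed,
    stages = c("simulate", "qc", "ewas", "dmr", "meta", "panel", "predict"),
    manifest = list(n_autosomal = 7000, n_sex = 150, n_snp_flagged = 400,
                    n_control = 200, n_genes = 800),
    reference = list(n_marker_per_type = 8),
    cohorts = list(
      discovery = list(n_case = 150, n_control = 150),
      replication = list(n_case = 60, n_control = 140),
      test = list(n_case = 80, n_control = 220)),
    spikes = list(
      probe_genes = sprintf("GENE%04d", 101:104),
      probe_delta = c(0.05, -0.05, 0.06, -0.06),
      region_genes = sprintf("GENE%04d", c(5, 10)),
      region_delta = c(0.05, 0.067)),
    batch_sd = 0.3,
    score_index_r = 0.6,
    ewas = list(n_control_pcs = 30, n_residual_pcs = 5,
                covariate_cols = c("age", "smoker", "audit_c", "adherence",
                                   "log10_vl", "wbc"),
                threshold = 5e-7),
    dmr = list(max_gap = 500, window = 3, cutoff_quantile = 0.99,
               min_probes = 3, B = 50),
    panel = list(p_cut = 1e-3, high_cut = 50, low_cut = 16, folds = 5,
                 kernel = "linear"),
    predict = list(null_B = 50, ci_reps = 500))
}

stage_deps <- c(simulate = "", qc = "simulate", ewas = "qc", dmr = "ewas",
                meta = "ewas", panel = "ewas", predict = "panel")

# Per-cohort nuisance design for panel residualization: biological
# covariates, estimated cell proportions, and the cohort's own control-probe
# PCs. Technical axes are cohort-specific, so each cohort is adjusted
# against its own control probes rather than a transferred basis.
pipeline_nuisance <- function(study, cell_props, covariate_cols,
                              n_control_pcs = 0) {
  out <- dplyr::bind_cols(study$samples[, covariate_cols, drop = FALSE],
                          cell_props[, CELL_TYPES])
  if (n_control_pcs > 0 && !is.null(study$control_intensities)) {
    cpcs <- control_probe_pcs(study$control_intensities,
                              k = n_control_pcs)$scores
    out <- dplyr::bind_cols(out, as_tibble(cpcs))
  }
  out
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> qc -> ewas -> dmr -> meta -> panel -> predict in
#' dependency order against a configuration list (see [demo_config()]).
#' Each stage's result is cached under `out_dir/cache` keyed by a hash of its
#' parameters and its upstream hash, so re-running with an identical config
#' skips completed stages. Text outputs (result tables, the summary report)
#' and a run manifest with MD5 hashes are written when `out_dir` is given.
#'
#' @param config Configuration list; `config$stages` toggles stages.
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage messages.
#' @return List with `report` (named summary quantities), `manifest`
#'   (per-stage tibble with hashes and file MD5s), and `results` (in-memory
#'   stage outputs).
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL,
                         quiet = FALSE) {
  stages <- config$stages
  for (s in stages) {
    dep <- stage_deps[[s]]
    if (nzchar(dep) && !dep %in% stages) {
      abort(paste0("stage '", s, "' requires stage '", dep,
                   "' to be enabled"))
    }
  }
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  cache_dir <- if (!is.null(out_dir)) file.path(out_dir, "cache") else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(cache_dir, showWarnings = FALSE)
  }
  hashes <- list()
  status <- list()
  res <- list()

  run_stage <- function(name, params, fun) {
    h <- rlang::hash(list(name = name, params = params,
                          upstream = hashes[stage_deps[[name]]]))
    hashes[[name]] <<- h
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(name, ".rds"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (identical(cached$hash, h)) {
        say("stage '", name, "': cache hit, skipping")
        status[[name]] <<- "skipped (cache)"
        return(cached$value)
      }
    }
    say("stage '", name, "': running")
    value <- fun()
    if (!is.null(cache_file)) saveRDS(list(hash = h, value = value),
                                      cache_file)
    status[[name]] <<- "run"
    value
  }

  report <- list()

  if ("simulate" %in% stages) {
    res$sim <- run_stage("simulate", config[c("seed", "manifest", "reference",
                                              "cohorts", "spikes", "batch_sd",
                                              "score_index_r")], function() {
      manifest <- do.call(generate_manifest,
                          c(config$manifest, list(seed = config$seed)))
      reference <- do.call(generate_cell_reference,
                           c(config$reference, list(seed = config$seed + 1)))
      sp <- config$spikes
      # spiked probes must survive probe filtering to be discoverable
      first_probe_of <- function(g) {
        manifest$probe_id[manifest$gene == g & !manifest$snp_within_10bp][1]
      }
      spike_probes <- tibble(
        probe_id = vapply(sp$probe_genes, first_probe_of, character(1)),
        delta_beta = sp$probe_delta)
      spike_regions <- tibble(gene = sp$region_genes,
                              delta_beta = sp$region_delta)
      cohorts <- purrr::imap(config$cohorts, function(cc, nm) {
        generate_cohort(manifest, reference,
                        n_case = cc$n_case, n_control = cc$n_control,
                        spike_probes = spike_probes,
                        spike_regions = spike_regions,
                        batch_sd = config$batch_sd,
                        score_index_r = config$score_index_r,
                        seed = config$seed + match(nm, names(config$cohorts)),
                        cohort_id = nm)
      })
      list(manifest = manifest, reference = reference, cohorts = cohorts,
           spike_probes = spike_probes, spike_regions = spike_regions)
    })
  }

  if ("qc" %in% stages) {
    res$qc <- run_stage("qc", list(), function() {
      purrr::map(res$sim$cohorts, function(st) {
        filt <- filter_probes(st$manifest)
        sex <- predict_sex(st$beta, st$manifest,
                           self_reported = st$samples$self_reported_sex)
        cells <- estimate_cell_proportions(st$beta, res$sim$reference)
        list(filter = filt, sex = sex, cell_props = cells)
      })
    })
    report$qc_n_retained_probes <-
      res$qc$discovery$filter$report$n_retained
    report$qc_n_sex_mismatches <- sum(res$qc$discovery$sex$mismatch)
  }

  if ("ewas" %in% stages) {
    res$ewas <- run_stage("ewas", config$ewas, function() {
      purrr::imap(res$sim$cohorts[c("discovery", "replication")],
                  function(st, nm) {
        run_ewas(st,
                 covariate_cols = config$ewas$covariate_cols,
                 cell_props = res$qc[[nm]]$cell_props,
                 n_control_pcs = config$ewas$n_control_pcs,
                 n_residual_pcs = config$ewas$n_residual_pcs)
      })
    })
    report$lambda_discovery <- res$ewas$discovery$lambda
    report$lambda_replication <- res$ewas$replication$lambda
    report$n_significant_discovery <-
      sum(res$ewas$discovery$results$p_value < config$ewas$threshold)
  }

  if ("dmr" %in% stages) {
    res$dmr <- run_stage("dmr", config$dmr, function() {
      st <- res$sim$cohorts$discovery
      bump_hunt(res$ewas$discovery, st$beta, st$manifest,
                max_gap = config$dmr$max_gap, window = config$dmr$window,
                cutoff_quantile = config$dmr$cutoff_quantile,
                min_probes = config$dmr$min_probes, B = config$dmr$B,
                seed = config$seed + 11)
    })
    report$n_dmr_q05 <- if (nrow(res$dmr)) sum(res$dmr$q_value < 0.05) else 0L
  }

  if ("meta" %in% stages) {
    res$meta <- run_stage("meta", list(), function() {
      stats <- dplyr::bind_rows(
        dplyr::mutate(res$ewas$discovery$results, study = "discovery",
                      n = res$ewas$discovery$n_samples),
        dplyr::mutate(res$ewas$replication$results, study = "replication",
                      n = res$ewas$replication$n_samples))
      list(inverse_variance = meta_inverse_variance(stats),
           sample_size = meta_sample_size(stats))
    })
    report$n_significant_meta <-
      sum(res$meta$inverse_variance$p_value < config$ewas$threshold &
            res$meta$inverse_variance$pooled)
  }

  if ("panel" %in% stages) {
    res$panel <- run_stage("panel", config$panel, function() {
      st <- res$sim$cohorts$discovery
      panel <- select_panel(res$ewas$discovery, p_cut = config$panel$p_cut,
                            manifest = st$manifest)
      nuis <- pipeline_nuisance(st, res$qc$discovery$cell_props,
                                config$ewas$covariate_cols,
                                config$ewas$n_control_pcs)
      rr <- residualize_panel(st$beta, panel, nuis)
      hc <- hierarchical_cluster(rr$residuals, k = 2)
      assoc <- cluster_phenotype_association(hc$labels, st$samples)
      scores <- cumulative_score(rr$residuals, panel)
      corr <- correlate_score_index(scores, st$samples$vacs_index)
      list(panel = panel, residuals = rr, clusters = hc, assoc = assoc,
           scores = scores, correlation = corr)
    })
    report$panel_size <- nrow(res$panel$panel)
    report$cluster_group_p <-
      res$panel$assoc$p_value[res$panel$assoc$variable == "group"]
    report$score_index_r <- res$panel$correlation$r
    report$score_index_p <- res$panel$correlation$p_value
  }

  if ("predict" %in% stages) {
    res$predict <- run_stage("predict",
                             c(config$predict, config$panel), function() {
      disc <- res$sim$cohorts$discovery
      test <- res$sim$cohorts$test
      panel <- res$panel$panel
      nuis_te <- pipeline_nuisance(test, res$qc$test$cell_props,
                                   config$ewas$covariate_cols,
                                   config$ewas$n_control_pcs)
      rr_te <- residualize_panel(test$beta, panel, nuis_te)
      lab_te <- define_frailty_labels(test$samples$vacs_index,
                                      high_cut = config$panel$high_cut,
                                      low_cut = config$panel$low_cut)
      # one predictive function trained on the index; both binary tasks are
      # scored from its predicted index
      model <- train_frailty_classifier(res$panel$residuals$residuals,
                                        disc$samples$vacs_index,
                                        folds = config$panel$folds,
                                        kernel = config$panel$kernel,
                                        seed = config$seed + 21)
      roc_high <- evaluate_roc(model, rr_te$residuals, lab_te$high_frailty,
                               ci_reps = config$predict$ci_reps,
                               seed = config$seed + 22)
      roc_low <- evaluate_roc(model, rr_te$residuals, lab_te$low_frailty,
                              higher_is_positive = FALSE,
                              ci_reps = config$predict$ci_reps,
                              seed = config$seed + 22)
      nuis_all <- dplyr::bind_rows(
        pipeline_nuisance(disc, res$qc$discovery$cell_props,
                          config$ewas$covariate_cols,
                          config$ewas$n_control_pcs), nuis_te)
      analysed <- intersect(res$ewas$discovery$results$probe_id,
                            rownames(test$beta))
      beta_all <- cbind(disc$beta, test$beta)[analysed, ]
      null <- permutation_panel_null(
        beta_all, nuis_all,
        train_outcome = c(disc$samples$vacs_index,
                          test$samples$vacs_index),
        test_labels = c(rep(FALSE, ncol(disc$beta)), lab_te$high_frailty),
        train_ids = colnames(disc$beta), test_ids = colnames(test$beta),
        panel_size = nrow(panel), observed_auc = roc_high$auc,
        B = config$predict$null_B, seed = config$seed + 23)
      list(model = model, high = list(roc = roc_high),
           low = list(roc = roc_low), null = null)
    })
    report$auc_high_frailty <- res$predict$high$roc$auc
    report$auc_low_frailty <- res$predict$low$roc$auc
    report$null_auc_mean <- mean(res$predict$null$null_auc)
    report$permutation_p_high <- res$predict$null$p
  }

  files <- character()
  if (!is.null(out_dir)) {
    w <- function(nm, writer) {
      path <- file.path(out_dir, nm)
      writer(path)
      files[[nm]] <<- path
    }
    if (!is.null(res$ewas)) {
      w("ewas_discovery.tsv",
        function(p) readr::write_tsv(res$ewas$discovery$results, p))
      w("ewas_replication.tsv",
        function(p) readr::write_tsv(res$ewas$replication$results, p))
    }
    if (!is.null(res$dmr)) {
      w("dmr.tsv", function(p) readr::write_tsv(tidy(res$dmr), p))
      if (nrow(res$dmr)) w("dmr.bed", function(p) write_dmr_bed(res$dmr, p))
    }
    if (!is.null(res$meta)) {
      w("meta_inverse_variance.tsv",
        function(p) readr::write_tsv(res$meta$inverse_variance, p))
    }
    if (!is.null(res$panel)) {
      w("panel.json", function(p) {
        jsonlite::write_json(as_tibble(res$panel$panel), p,
                             auto_unbox = TRUE, digits = NA)
      })
      w("scores.csv", function(p) readr::write_csv(res$panel$scores, p))
    }
    if (!is.null(res$predict)) {
      w("roc_high.tsv",
        function(p) readr::write_tsv(res$predict$high$roc$curve, p))
      w("roc_low.tsv",
        function(p) readr::write_tsv(res$predict$low$roc$curve, p))
      w("null_auc.tsv", function(p) {
        readr::write_tsv(tibble(null_auc = res$predict$null$null_auc), p)
      })
    }
    w("summary.json", function(p) {
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
    })
    w("summary.txt", function(p) {
      writeLines(sprintf("%-28s %s", names(report),
                         vapply(report, function(v) format(v, digits = 6),
                                character(1))), p)
    })
  }

  manifest <- tibble(
    stage = stages,
    status = vapply(stages, function(s) status[[s]] %||% "run", character(1),
                    USE.NAMES = FALSE),
    hash = vapply(stages, function(s) hashes[[s]] %||% "", character(1),
                  USE.NAMES = FALSE))
  file_md5 <- if (length(files)) {
    tibble(file = names(files), md5 = unname(tools::md5sum(unlist(files))))
  } else {
    tibble(file = character(), md5 = character())
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(stages = manifest, files = file_md5),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, manifest = manifest, files = file_md5,
       results = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
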