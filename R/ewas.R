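#' Principal components of control-probe intensities
#'
#' PCA over samples of the log-transformed, per-probe-centred control-probe
#' intensity matrix. These components capture technical structure (batch,
#' plate, staining) because control probes carry no biology; including them as
#' covariates is the first stage of control-probe-adjusted EWAS. Component
#' signs are fixed by making the largest-magnitude probe loading positive, so
#' results are deterministic across platforms.
#'
#' @param control_intensities Control probe x sample matrix (positive).
#' @param k Number of components (default 30; must be < number of samples).
#' @return List with `scores` (sample x k matrix, columns `ctrlPC1..k`),
#'   `var_explained` (all singular-value fractions).
#' @export
control_probe_pcs <- function(control_intensities, k = 30) {
  n <- ncol(control_intensities)
  if (k < 1) abort("k must be >= 1")
  if (k >= n) abort("k must be smaller than the number of samples")
  X <- log(control_intensities + 1)
  Xc <- X - rowMeans(X)
  if (sum(Xc^2) < 1e-20) {
    abort("control intensities have zero variance across samples")
  }
  sv <- svd(t(Xc))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: dominant probe loading positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(control_intensities),
                           paste0("ctrlPC", seq_len(k)))
  list(scores = scores, var_explained = sv$d^2 / sum(sv$d^2))
}

#' Stage-one residuals: methylation adjusted for covariates and control PCs
#'
#' Per-probe OLS residuals of beta on the nuisance design (intercept,
#' covariates, control-probe PCs) with no group term. These residuals feed the
#' second PCA, whose components stand in for global biological confounders not
#' captured by the measured covariates.
#'
#' @param beta Probe x sample beta matrix.
#' @param covariates Tibble of per-sample covariates (rows aligned with
#'   columns of `beta`).
#' @param control_pcs Optional sample x k matrix of control-probe PC scores.
#' @return Residual matrix, same shape as `beta`.
#' @export
stage1_residuals <- function(beta, covariates = NULL, control_pcs = NULL) {
  X <- cbind(`(Intercept)` = rep(1, ncol(beta)),
             design_from_covariates(covariates), control_pcs)
  fit <- ols_fit_matrix(t(beta), X)
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(beta)
  res
}

#' Principal components of stage-one residuals
#'
#' PCA over samples of the probe-centred residual matrix; the top components
#' absorb remaining global covariation. `k = 0` is supported and returns
#' `NULL` (skip the stage).
#'
#' @param residuals Probe x sample residual matrix.
#' @param k Number of components (default 5).
#' @return Sample x k score matrix (columns `resPC1..k`), or `NULL`.
#' @export
residual_pcs <- function(residuals, k = 5) {
  if (k == 0) return(NULL)
  if (k >= ncol(residuals)) abort("k must be smaller than the number of samples")
  Xc <- residuals - rowMeans(residuals)
  if (sum(Xc^2) < 1e-20) abort("residuals have zero variance across samples")
  sv <- svd(t(Xc), nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(residuals), paste0("resPC", seq_len(k)))
  scores
}

#' Final per-probe association model
#'
#' Mass-univariate OLS of beta on the case indicator plus all nuisance terms
#' (covariates, control-probe PCs, residual PCs). Reports the group
#' coefficient (delta-beta units), its SE, t, two-sided p from the t
#' distribution with residual df, BH q-values, and the genomic inflation
#' factor lambda computed on the group-term p-values. Samples with any missing
#' model term are dropped listwise with a message.
#'
#' @param beta Probe x sample beta matrix.
#' @param group Two-level group (logical, 0/1, or factor; the level "case", or
#'   the second level, is the case).
#' @param covariates Optional tibble of per-sample covariates.
#' @param control_pcs,residual_pcs Optional score matrices.
#' @return An `ewas_fit` object; use [tidy()] for the per-probe table and
#'   [glance()] for the model summary.
#' @export
fit_final_glm <- function(beta, group, covariates = NULL,
                          control_pcs = NULL, residual_pcs = NULL) {
  g <- group_indicator(group)
  cov_mm <- design_from_covariates(covariates)
  parts <- cbind(group = g, cov_mm, control_pcs, residual_pcs)
  ok <- complete.cases(parts)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " sample(s) with missing model terms")
  }
  X <- cbind(`(Intercept)` = 1, parts[ok, , drop = FALSE])
  fit <- ols_fit_matrix(t(beta[, ok, drop = FALSE]), X)
  gi <- match("group", colnames(fit$X))
  est <- fit$coef[gi, ]
  se <- ols_se(fit, gi)
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), fit$df)
  results <- tibble(
    probe_id = rownames(beta),
    estimate = unname(est), std_error = unname(se),
    statistic = unname(tstat), p_value = unname(p),
    q_value = p.adjust(p, method = "BH"))
  lambda <- tryCatch(genomic_inflation(results$p_value),
                     error = function(e) NA_real_)
  structure(list(results = results, lambda = lambda,
                 n_samples = sum(ok), df = fit$df,
                 design = X, group_col = match("group", colnames(X)),
                 sample_ids = colnames(beta)[ok],
                 terms = colnames(X)),
            class = "ewas_fit")
}

#' @export
print.ewas_fit <- function(x, ...) {
  cat("<ewas_fit> ", nrow(x$results), " probes, ", x$n_samples,
      " samples, lambda = ", format(x$lambda, digits = 4), "\n", sep = "")
  cat("  ", sum(x$results$q_value < 0.05), " probes at q < 0.05\n", sep = "")
  invisible(x)
}

#' Run the full two-stage PCA-adjusted EWAS on a study
#'
#' Convenience wrapper: filters probes (control/sex/SNP), computes
#' control-probe PCs, estimates cell proportions when a reference is supplied,
#' takes stage-one residuals, extracts residual PCs, and fits the final model
#' with the group term.
#'
#' @param study A `meth_study`.
#' @param covariate_cols Sample-table columns used as nuisance covariates.
#' @param reference Optional `cell_reference`; when given, estimated cell
#'   proportions join the nuisance design.
#' @param cell_props Optional precomputed cell-proportion tibble (overrides
#'   `reference`).
#' @param n_control_pcs,n_residual_pcs PC counts for the two stages
#'   (defaults 30 and 5; either may be 0 to skip).
#' @param probes Optional probe ids to analyse (defaults to the filtered set).
#' @return An `ewas_fit`.
#' @export
run_ewas <- function(study,
                     covariate_cols = c("age", "smoker", "audit_c",
                                        "adherence", "log10_vl", "wbc"),
                     reference = NULL, cell_props = NULL,
                     n_control_pcs = 30, n_residual_pcs = 5, probes = NULL) {
  if (is.null(probes)) {
    probes <- intersect(filter_probes(study$manifest)$probes,
                        rownames(study$beta))
  }
  beta <- study$beta[probes, , drop = FALSE]
  covs <- study$samples[, covariate_cols, drop = FALSE]
  if (is.null(cell_props) && !is.null(reference)) {
    cell_props <- estimate_cell_proportions(study$beta, reference)
  }
  if (!is.null(cell_props)) {
    covs <- dplyr::bind_cols(covs, cell_props[, CELL_TYPES])
  }
  cpcs <- NULL
  if (n_control_pcs > 0 && !is.null(study$control_intensities)) {
    cpcs <- control_probe_pcs(study$control_intensities, k = n_control_pcs)$scores
  }
  resid1 <- stage1_residuals(beta, covs, cpcs)
  rpcs <- residual_pcs(resid1, k = n_residual_pcs)
  fit <- fit_final_glm(beta, study$samples$group, covs, cpcs, rpcs)
  fit$covariates <- covs
  fit$control_pcs <- cpcs
  fit$residual_pcs <- rpcs
  fit
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, 1, lower = FALSE)) / qchisq(0.5, 1)`: the median
#' association chi-square divided by its null median (0.4549364). Values near
#' 1 indicate calibrated tests; inflation above ~1.1 suggests residual
#' confounding.
#'
#' @param p_values At least 100 p-values in (0, 1].
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) < 100) abort("need at least 100 p-values")
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values))) {
    abort("p-values must lie in (0, 1]")
  }
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; monotone in the ranked p-values
#' and invariant to input order.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values, same length and order as the input.
#' @export
adjust_fdr <- function(p_values) {
  if (!length(p_values)) abort("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values))) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Label-permutation robustness check for selected probes
#'
#' Permutes the case/control labels B times, refits the final model, and
#' reports the empirical p-value `(1 + #{|t_perm| >= |t_obs|}) / (B + 1)` per
#' probe. A probe whose observed statistic exceeds every permuted one sits at
#' the floor `1/(B+1)`. The nuisance design is held fixed: only the group
#' column is shuffled.
#'
#' @param fit An `ewas_fit`.
#' @param beta The probe x sample beta matrix the fit was run on.
#' @param probe_ids Probes to check (default: all probes in the fit).
#' @param B Number of permutations (default 100; fewer than 20 warns).
#' @param seed Integer seed; fixes the permutation stream.
#' @return Tibble: `probe_id`, `statistic` (observed t), `p_empirical`.
#' @export
permutation_check <- function(fit, beta, probe_ids = NULL, B = 100, seed = 1) {
  if (B < 20) warn("fewer than 20 permutations gives very coarse p-values")
  if (is.null(probe_ids)) probe_ids <- fit$results$probe_id
  bad <- setdiff(probe_ids, fit$results$probe_id)
  if (length(bad)) {
    abort(paste0("probe(s) not in the fitted set: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  Y <- t(beta[probe_ids, fit$sample_ids, drop = FALSE])
  t_obs <- fit$results$statistic[match(probe_ids, fit$results$probe_id)]
  gi <- fit$group_col
  X <- fit$design
  count <- rep(0L, length(probe_ids))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      Xp <- X
      Xp[, gi] <- sample(X[, gi])
      pf <- ols_fit_matrix(Y, Xp)
      tp <- pf$coef[gi, ] / ols_se(pf, gi)
      count <- count + (abs(tp) >= abs(t_obs))
    }
  })
  tibble(probe_id = probe_ids, statistic = t_obs,
         p_empirical = unname((1 + count) / (B + 1)))
}

#' One-way ANOVA across exposure-recency groups
#'
#' Per-probe one-way ANOVA of beta across three groups (e.g. current / past /
#' never exposed), with the pairwise current-vs-past contrast from the pooled
#' residual variance. With two groups the identity `F = t^2` holds.
#'
#' @param beta Probe x sample beta matrix.
#' @param probe_ids Probes to test.
#' @param groups Factor-like vector aligned with the columns of `beta`; every
#'   level needs at least 2 samples.
#' @param contrast Character pair naming the two levels to contrast (default
#'   `c("current", "past")` when present).
#' @return Tibble: `probe_id`, `f_statistic`, `p_value`, and when the contrast
#'   levels exist, `contrast_estimate`, `contrast_t`, `contrast_p`.
#' @export
three_group_anova <- function(beta, probe_ids, groups,
                              contrast = c("current", "past")) {
  g <- as.factor(groups)
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    abort(paste0("group(s) with fewer than 2 samples: ",
                 paste(small, collapse = ", ")))
  }
  do_contrast <- all(contrast %in% levels(g))
  purrr::map_dfr(probe_ids, function(pid) {
    y <- beta[pid, ]
    a <- stats::anova(stats::lm(y ~ g))
    row <- tibble(probe_id = pid, f_statistic = a$`F value`[1],
                  p_value = a$`Pr(>F)`[1])
    if (do_contrast) {
      mse <- a$`Mean Sq`[2]
      df_res <- a$Df[2]
      n1 <- sum(g == contrast[1])
      n2 <- sum(g == contrast[2])
      est <- mean(y[g == contrast[1]]) - mean(y[g == contrast[2]])
      tval <- est / sqrt(mse * (1 / n1 + 1 / n2))
      row$contrast_estimate <- est
      row$contrast_t <- tval
      row$contrast_p <- 2 * pt(-abs(tval), df_res)
    }
    row
  })
}
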