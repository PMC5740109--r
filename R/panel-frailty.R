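#' Select a probe panel from EWAS results
#'
#' Probes with association p below `p_cut` (default 1e-3) form the panel;
#' their weights are the group coefficients. Within each annotated gene the
#' probe with the smallest p-value is marked as the gene's representative.
#'
#' @param fit An `ewas_fit` (or its tidied results tibble).
#' @param p_cut Inclusion threshold on the association p-value.
#' @param manifest Optional manifest supplying gene annotation.
#' @return A `meth_panel`: tibble with `probe_id`, `weight`, `p_value`,
#'   `gene`, `representative`; attribute `p_cut`.
#' @export
select_panel <- function(fit, p_cut = 1e-3, manifest = NULL) {
  results <- if (inherits(fit, "ewas_fit")) fit$results else fit
  sel <- dplyr::filter(results, .data$p_value < p_cut)
  if (!nrow(sel)) {
    abort(paste0("no probes pass p < ", format(p_cut),
                 "; consider a looser cut"))
  }
  out <- tibble(probe_id = sel$probe_id, weight = sel$estimate,
                p_value = sel$p_value)
  if (!is.null(manifest)) {
    out <- dplyr::left_join(
      out, dplyr::select(manifest, "probe_id", "gene"), by = "probe_id")
    out$gene[is.na(out$gene)] <- ""
  } else {
    out$gene <- ""
  }
  out <- out |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(representative = .data$gene != "" &
                    .data$p_value == min(.data$p_value)) |>
    dplyr::ungroup()
  structure(out, class = c("meth_panel", class(out)), p_cut = p_cut)
}

#' Residualize panel methylation against nuisance covariates
#'
#' Per-probe OLS residuals of panel beta values on the nuisance design. When
#' fitted on a training set, the returned recipe stores the fitted
#' coefficients so held-out samples are residualized with training-fitted
#' coefficients only - no information leaks from test to training.
#'
#' @param beta Probe x sample beta matrix covering the panel probes.
#' @param panel A `meth_panel` (or anything with a `probe_id` column).
#' @param covariates Tibble of nuisance covariates aligned with the columns
#'   of `beta`. An empty/`NULL` design centres each probe on the (training)
#'   mean.
#' @param recipe Optional recipe from a previous (training) call; when given,
#'   its coefficients are applied instead of refitting.
#' @return List with `residuals` (panel probe x sample matrix) and `recipe`
#'   (list of `terms` and the fitted coefficient matrix).
#' @export
residualize_panel <- function(beta, panel, covariates = NULL, recipe = NULL) {
  ids <- panel$probe_id
  missing <- setdiff(ids, rownames(beta))
  if (length(missing)) {
    abort(paste0("beta is missing panel probe(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  Y <- t(beta[ids, , drop = FALSE])
  if (is.null(recipe)) {
    X <- cbind(`(Intercept)` = rep(1, nrow(Y)),
               design_from_covariates(covariates))
    fit <- ols_fit_matrix(Y, X)
    recipe <- list(terms = colnames(fit$X), coef = fit$coef)
    res <- t(fit$residuals)
  } else {
    X <- cbind(`(Intercept)` = rep(1, nrow(Y)),
               design_from_covariates(covariates))
    missing_terms <- setdiff(recipe$terms, colnames(X))
    if (length(missing_terms)) {
      abort(paste0("covariates lack recipe term(s): ",
                   paste(missing_terms, collapse = ", ")))
    }
    res <- t(Y - X[, recipe$terms, drop = FALSE] %*% recipe$coef)
  }
  dimnames(res) <- list(ids, rownames(Y))
  colnames(res) <- colnames(beta)
  list(residuals = res, recipe = recipe)
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distances over the
#' supplied (residual) methylation matrix, with the tree cut into `k` groups.
#'
#' @param residuals Probe x sample matrix.
#' @param k Number of clusters (default 2).
#' @return List with `labels` (tibble `sample_id`, `cluster`), `heights`
#'   (merge heights) and the `hclust` object.
#' @export
hierarchical_cluster <- function(residuals, k = 2) {
  if (ncol(residuals) < k) abort("need at least k samples")
  hc <- hclust(dist(t(residuals)), method = "complete")
  cl <- cutree(hc, k = k)
  list(labels = tibble(sample_id = colnames(residuals),
                       cluster = unname(cl)),
       heights = hc$height, hclust = hc)
}

#' Associate cluster membership with phenotypes
#'
#' Chi-square tests for categorical variables and one-way ANOVA for
#' continuous ones, per variable, across the cluster labels. A chi-square
#' with any expected cell below 5 gets a note rather than an error.
#'
#' @param labels Tibble with `sample_id` and `cluster`.
#' @param samples Sample covariate tibble (must contain `sample_id`).
#' @param categorical,continuous Variable names to test.
#' @return Tibble: `variable`, `type`, `statistic`, `p_value`, `note`.
#' @export
cluster_phenotype_association <- function(labels, samples,
                                          categorical = c("group", "smoker"),
                                          continuous = c("age", "wbc",
                                                         "log10_vl",
                                                         "adherence",
                                                         "audit_c")) {
  d <- dplyr::inner_join(labels, samples, by = "sample_id")
  if (length(unique(d$cluster)) < 2) abort("need at least 2 clusters")
  cat_rows <- purrr::map_dfr(intersect(categorical, names(d)), function(v) {
    tab <- table(d$cluster, d[[v]])
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    note <- if (any(ct$expected < 5)) "expected cell count < 5" else ""
    tibble(variable = v, type = "categorical",
           statistic = unname(ct$statistic), p_value = ct$p.value,
           note = note)
  })
  cont_rows <- purrr::map_dfr(intersect(continuous, names(d)), function(v) {
    a <- stats::anova(stats::lm(d[[v]] ~ factor(d$cluster)))
    tibble(variable = v, type = "continuous",
           statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1], note = "")
  })
  dplyr::bind_rows(cat_rows, cont_rows)
}

#' Cumulative methylation score
#'
#' Weighted sum of methylation values over the panel, divided by the panel
#' size: `score(sample) = sum_i w_i v_i(sample) / |panel|`. The value matrix
#' may hold raw beta values or residualized methylation, per the caller's
#' choice.
#'
#' @param values Probe x sample matrix covering every panel probe.
#' @param panel A `meth_panel` (columns `probe_id`, `weight`).
#' @return Tibble: `sample_id`, `score`.
#' @export
cumulative_score <- function(values, panel) {
  missing <- setdiff(panel$probe_id, rownames(values))
  if (length(missing)) {
    abort(paste0("values are missing panel probe(s): ",
                 paste(missing, collapse = ", ")))
  }
  v <- values[panel$probe_id, , drop = FALSE]
  tibble(sample_id = colnames(values),
         score = unname(colSums(v * panel$weight) / nrow(panel)))
}

#' Pearson correlation of score with a frailty index
#'
#' @param scores Numeric vector (or tibble from [cumulative_score()]).
#' @param vacs_index Numeric frailty index, same length/order.
#' @return One-row tibble: `r`, `p_value`, `n`, `conf_low`, `conf_high`.
#' @export
correlate_score_index <- function(scores, vacs_index) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (length(s) != length(vacs_index)) abort("length mismatch")
  if (length(s) < 3) abort("need at least 3 samples")
  if (sd(s) == 0 || sd(vacs_index) == 0) {
    abort("zero variance in scores or index")
  }
  ct <- cor.test(s, vacs_index, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n = length(s), conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
}

#' Frailty labels from the index
#'
#' Assigns the five-band partition (`<16`, `17-24`, `25-34`, `35-50`, `>50`)
#' and the two binary tasks: high frailty (`index > high_cut`) and low
#' frailty (`index < low_cut`). The printed band labels leave edge values
#' ambiguous; the documented convention here is right-open bands
#' `[16, 25)`, `[25, 35)` and right-closed `[35, 50]`, so an index of 16
#' falls in "17-24" while the binary low task, whose cut is unambiguous,
#' treats 16 as not-low. Cuts can be re-derived as the 20%/80% quantiles of a
#' training index.
#'
#' @param vacs_index Integer index values in [0, 120].
#' @param high_cut,low_cut Binary task cuts (defaults 50 and 16).
#' @param train_index Optional training index vector; when given, the cuts
#'   are its 80% and 20% quantiles.
#' @return Tibble: `vacs_index`, `band`, `high_frailty`, `low_frailty`;
#'   attributes `high_cut`, `low_cut`.
#' @export
define_frailty_labels <- function(vacs_index, high_cut = 50, low_cut = 16,
                                  train_index = NULL) {
  if (any(vacs_index < 0 | vacs_index > 120)) {
    abort("index values must lie in [0, 120]")
  }
  if (!is.null(train_index)) {
    high_cut <- unname(quantile(train_index, 0.8))
    low_cut <- unname(quantile(train_index, 0.2))
  }
  rng <- range(vacs_index)
  if (high_cut >= rng[2] || low_cut <= rng[1]) {
    warn("a binary cut falls outside the observed index range; task degenerate")
  }
  band <- cut(vacs_index, breaks = c(-Inf, 15.5, 24.5, 34.5, 50.5, Inf),
              labels = c("<16", "17-24", "25-34", "35-50", ">50"))
  structure(
    tibble(vacs_index = vacs_index, band = as.character(band),
           high_frailty = vacs_index > high_cut,
           low_frailty = vacs_index < low_cut),
    high_cut = high_cut, low_cut = low_cut)
}

# stratified fold assignment; every fold gets both classes when feasible
stratified_folds <- function(labels, k) {
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# SVM with standardised features; classification gets inverse-frequency
# class weights, numeric responses get epsilon-regression
svm_balanced <- function(x, y, kernel, cost) {
  if (is.logical(y)) {
    cw <- length(y) / (2 * c("FALSE" = sum(!y), "TRUE" = sum(y)))
    suppressWarnings(e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                                kernel = kernel, cost = cost, scale = TRUE,
                                class.weights = cw))
  } else {
    suppressWarnings(e1071::svm(x, y, type = "eps-regression",
                                kernel = kernel, cost = cost, scale = TRUE))
  }
}

svm_decision_scores <- function(model, x) {
  pr <- predict(model, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

#' Train a maximum-margin frailty model
#'
#' Fits a support vector machine on panel residuals, choosing the cost
#' parameter by stratified k-fold cross-validation. With a numeric response
#' (the frailty index itself) the model is epsilon-regression and CV ranks
#' costs by held-out Pearson correlation; the single predictive function then
#' serves both binary tasks through its predicted index. With a logical
#' response the model is class-weighted C-classification, CV ranks costs by
#' held-out AUC, and the decision-score orientation is fixed so larger scores
#' mean the positive class.
#'
#' @param train_residuals Panel probe x sample matrix (training samples).
#' @param train_labels Numeric frailty index, or logical labels (TRUE =
#'   positive class).
#' @param folds Cross-validation folds (default 10; reduced with a warning if
#'   the minority class is smaller).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param costs Cost grid for CV. Features are standardised inside the SVM and
#'   classes are inversely weighted, so minority-class signal is not drowned
#'   by the margin penalty.
#' @param seed Integer seed fixing fold assignment.
#' @return A `frailty_classifier`: list with the fitted `model`, chosen
#'   `cost`, `cv` tibble (cost, cv_auc), `flip`, `kernel`.
#' @export
train_frailty_classifier <- function(train_residuals, train_labels,
                                     folds = 10, kernel = "linear",
                                     costs = 10^(-2:1), seed = 1) {
  regression <- !is.logical(train_labels)
  y <- train_labels
  if (regression) {
    if (length(y) < 2 * folds) abort("too few samples for the fold count")
    # stratify folds over the index quantiles so every fold spans the range
    strat <- dplyr::ntile(y, 5) >= 4
  } else {
    n_min <- min(sum(y), sum(!y))
    if (n_min < 2) abort("both classes need at least 2 training samples")
    if (n_min < folds) {
      warn(paste0("minority class smaller than fold count; using ", n_min,
                  " folds"))
      folds <- n_min
    }
    strat <- y
  }
  x <- t(train_residuals)
  withr::with_seed(seed, {
    fold <- stratified_folds(strat, folds)
    cv <- purrr::map_dfr(costs, function(cost) {
      perf <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        m <- svm_balanced(x[tr, , drop = FALSE], y[tr], kernel, cost)
        if (regression) {
          cor(predict(m, x[!tr, , drop = FALSE]), y[!tr])
        } else {
          sc <- svm_decision_scores(m, x[!tr, , drop = FALSE])
          # orient on the training fold, score the held-out fold
          if (auc_from_scores(svm_decision_scores(m, x[tr, , drop = FALSE]),
                              y[tr]) < 0.5) sc <- -sc
          auc_from_scores(sc, y[!tr])
        }
      }, numeric(1))
      tibble(cost = cost, cv_metric = mean(perf))
    })
    best <- cv$cost[which.max(cv$cv_metric)]
    model <- svm_balanced(x, y, kernel, best)
    flip <- if (!regression &&
                auc_from_scores(svm_decision_scores(model, x), y) < 0.5) {
      -1
    } else 1
    structure(list(model = model, cost = best, cv = cv, flip = flip,
                   kernel = kernel, folds = fold, n_train = length(y),
                   type = if (regression) "regression" else "classification"),
              class = "frailty_classifier")
  })
}

#' @export
print.frailty_classifier <- function(x, ...) {
  cat("<frailty_classifier> ", x$kernel, " SVM ", x$type, ", cost = ",
      x$cost, ", trained on ", x$n_train, " samples\n", sep = "")
  invisible(x)
}

#' Classifier decision scores for new samples
#'
#' @param object A `frailty_classifier`.
#' @param residuals Panel probe x sample matrix.
#' @param ... Unused.
#' @return Numeric scores: the predicted index (regression) or oriented
#'   decision values (classification); larger = more frail.
#' @export
predict.frailty_classifier <- function(object, residuals, ...) {
  if (object$type == "regression") {
    unname(predict(object$model, t(residuals)))
  } else {
    object$flip * svm_decision_scores(object$model, t(residuals))
  }
}

#' ROC evaluation on a held-out test set
#'
#' AUC of the classifier's decision scores on test samples, with a stratified
#' bootstrap 95% confidence interval and the full ROC curve.
#'
#' @param model A `frailty_classifier`.
#' @param test_residuals Panel probe x sample matrix (test samples, disjoint
#'   from training).
#' @param test_labels Logical test labels; both classes must be present.
#' @param higher_is_positive Whether larger model scores indicate the
#'   positive class (set `FALSE` for a low-frailty task scored by a
#'   predicted frailty index; this is an a-priori orientation, not fitted to
#'   the test data).
#' @param ci_reps Bootstrap replicates for the CI (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return A `roc_summary`: list with `auc`, `ci_lower`, `ci_upper`, `curve`
#'   (tibble of `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
evaluate_roc <- function(model, test_residuals, test_labels,
                         higher_is_positive = TRUE, ci_reps = 2000,
                         seed = 1) {
  y <- as.logical(test_labels)
  if (length(unique(y)) < 2) abort("test set must contain both classes")
  scores <- predict(model, test_residuals)
  if (!higher_is_positive) scores <- -scores
  r <- pROC::roc(response = y, predictor = scores, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  ci <- withr::with_seed(seed, {
    suppressWarnings(pROC::ci.auc(r, method = "bootstrap", boot.n = ci_reps,
                                  boot.stratified = TRUE, progress = "none"))
  })
  curve <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_lower = as.numeric(ci[1]), ci_upper = as.numeric(ci[3]),
                 curve = curve, n_pos = sum(y), n_neg = sum(!y),
                 ci_reps = ci_reps),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC = %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_lower, x$ci_upper, x$n_pos, x$n_neg))
  invisible(x)
}

#' Random-panel permutation null for classifier performance
#'
#' Draws B random probe panels of the observed panel's size (without
#' replacement within a panel), reruns the full residualize -> train -> test
#' pipeline for each, and collects the null AUC distribution. The permutation
#' p-value is `(1 + #{null AUC >= observed}) / (B + 1)`. Cost tuning is
#' skipped inside the null (fixed cost) to keep the null pipeline identical
#' across draws.
#'
#' @param beta Probe x sample beta matrix for all candidate probes (training
#'   and test samples as columns).
#' @param covariates Nuisance covariate tibble aligned with `beta` columns;
#'   each cohort is residualized against its own rows.
#' @param train_outcome Training response aligned with `beta` columns:
#'   numeric frailty index (regression) or logical labels (classification).
#' @param test_labels Logical task labels aligned with `beta` columns, used
#'   for the test AUC.
#' @param train_ids,test_ids Disjoint sample-id sets (column names of `beta`).
#' @param panel_size Probes per random panel.
#' @param observed_auc Optional observed AUC to score against the null.
#' @param B Number of random panels (default 1000).
#' @param cost,kernel SVM settings used for every draw.
#' @param seed Integer seed.
#' @return List with `null_auc` (length B), `p` (or `NA` when no observed
#'   AUC was supplied), `observed_auc`, `B`.
#' @export
permutation_panel_null <- function(beta, covariates, train_outcome,
                                   test_labels, train_ids, test_ids,
                                   panel_size, observed_auc = NULL,
                                   B = 1000, cost = 1, kernel = "linear",
                                   seed = 1) {
  if (panel_size > nrow(beta)) abort("panel_size exceeds available probes")
  if (length(intersect(train_ids, test_ids))) {
    abort("train and test samples must be disjoint")
  }
  tr_idx <- match(train_ids, colnames(beta))
  te_idx <- match(test_ids, colnames(beta))
  tr_cov <- covariates[tr_idx, , drop = FALSE]
  te_cov <- covariates[te_idx, , drop = FALSE]
  y_tr <- train_outcome[tr_idx]
  y_te <- as.logical(test_labels[te_idx])
  regression <- !is.logical(y_tr)
  null_auc <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ids <- sample(rownames(beta), panel_size)
      fake_panel <- tibble(probe_id = ids, weight = 1)
      tr <- residualize_panel(beta[, train_ids, drop = FALSE], fake_panel,
                              tr_cov)
      te <- residualize_panel(beta[, test_ids, drop = FALSE], fake_panel,
                              te_cov)
      m <- svm_balanced(t(tr$residuals), y_tr, kernel, cost)
      if (regression) {
        sc <- predict(m, t(te$residuals))
      } else {
        sc <- svm_decision_scores(m, t(te$residuals))
        if (auc_from_scores(svm_decision_scores(m, t(tr$residuals)),
                            y_tr) < 0.5) sc <- -sc
      }
      auc_from_scores(sc, y_te)
    }, numeric(1))
  })
  p <- if (is.null(observed_auc)) {
    NA_real_
  } else {
    (1 + sum(null_auc >= observed_auc)) / (B + 1)
  }
  list(null_auc = null_auc, p = p, observed_auc = observed_auc, B = B)
}
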