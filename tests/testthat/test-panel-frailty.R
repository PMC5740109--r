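fake_ewas_results <- function(p, est = NULL, ids = sprintf("cg%03d", seq_along(p))) {
  tibble::tibble(probe_id = ids,
                 estimate = if (is.null(est)) rnorm(length(p), 0, 0.02) else est,
                 std_error = 0.01, statistic = 1, p_value = p,
                 q_value = p.adjust(p, "BH"))
}

test_that("panel selection applies the p cut and smallest-p gene representative", {
  res <- fake_ewas_results(c(1e-5, 1e-4, 0.5, 0.9))
  man <- tibble::tibble(probe_id = sprintf("cg%03d", 1:4),
                        gene = c("G1", "G1", "G2", ""))
  panel <- select_panel(res, p_cut = 1e-3, manifest = man)
  expect_equal(panel$probe_id, c("cg001", "cg002"))
  expect_equal(panel$representative, c(TRUE, FALSE))
  expect_equal(panel$weight, res$estimate[1:2])

  all_in <- select_panel(res, p_cut = 1.0000001)
  expect_equal(nrow(all_in), 4)
  expect_error(select_panel(res, p_cut = 1e-9), "looser")
})

test_that("panel captures spiked probes with few extras", {
  man <- tiny_manifest()
  ref <- tiny_reference()
  ids <- man$probe_id[!man$is_control][seq(1, 120, 4)]
  st <- generate_cohort(man, ref, 150, 150,
                        spike_probes = tibble::tibble(probe_id = ids,
                                                      delta_beta = 0.08),
                        seed = 151)
  cells <- estimate_cell_proportions(st$beta, ref)
  fit <- run_ewas(st, cell_props = cells, n_control_pcs = 5,
                  n_residual_pcs = 0)
  panel <- select_panel(fit, 1e-3, st$manifest)
  expect_gte(sum(ids %in% panel$probe_id), 0.8 * length(ids))
  n_null <- nrow(tidy(fit)) - length(ids)
  extras <- sum(!panel$probe_id %in% ids)
  expect_lt(extras, 1e-3 * n_null + 3 * sqrt(1e-3 * n_null) + 3)
})

test_that("residualization is orthogonal, reusable without leakage", {
  st <- small_cohort(seed = 161)
  cells <- estimate_cell_proportions(st$beta, tiny_reference())
  covs <- nuisance_tbl(st, cells)
  panel <- tibble::tibble(probe_id = rownames(st$beta)[1:30], weight = 1)
  rr <- residualize_panel(st$beta, panel, covs)
  for (v in c("age", "wbc")) {
    expect_lt(max(abs(cor(t(rr$residuals), covs[[v]]))), 0.05)
  }
  # recipe reuse: identical samples get identical residuals
  rr2 <- residualize_panel(st$beta, panel, covs, recipe = rr$recipe)
  expect_equal(rr2$residuals, rr$residuals, tolerance = 1e-12)
  # zero-covariate recipe = centring
  rc <- residualize_panel(st$beta, panel, covariates = NULL)
  expect_equal(rc$residuals, st$beta[panel$probe_id, ] -
                 rowMeans(st$beta[panel$probe_id, ]), tolerance = 1e-12)
  expect_error(residualize_panel(st$beta[1:3, ], panel, covs), "missing")
})

test_that("complete-linkage clustering matches hand and brute-force oracles", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  res <- t(x)
  colnames(res) <- c("a", "b", "c")
  out <- hierarchical_cluster(res, k = 2)
  expect_equal(out$labels$cluster[1], out$labels$cluster[2])
  expect_false(out$labels$cluster[3] == out$labels$cluster[1])

  set.seed(16)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(n * 3), nrow = n)
    res <- t(pts)
    colnames(res) <- sprintf("s%d", 1:n)
    k <- sample(2:3, 1)
    got <- hierarchical_cluster(res, k = k)$labels$cluster
    want <- complete_linkage_oracle(pts, k)
    expect_equal(length(unique(got)), k)
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("well-separated blobs are recovered exactly and phenotypes associate", {
  set.seed(17)
  blob <- cbind(matrix(rnorm(20 * 25, 0, 0.3), 20),
                matrix(rnorm(20 * 25, 8, 0.3), 20))
  colnames(blob) <- sprintf("s%02d", 1:50)
  out <- hierarchical_cluster(blob, k = 2)
  membership <- rep(1:2, each = 25)
  expect_true(all(tapply(out$labels$cluster, membership,
                         function(v) length(unique(v))) == 1))

  samples <- tibble::tibble(
    sample_id = colnames(blob),
    group = factor(rep(c("control", "case"), each = 25)),
    smoker = rep(c(FALSE, TRUE), 25),
    age = rnorm(50, 50, 5), wbc = rnorm(50, 6, 1),
    log10_vl = rnorm(50, 2.5, 1), adherence = runif(50),
    audit_c = rpois(50, 3))
  assoc <- cluster_phenotype_association(out$labels, samples)
  expect_lt(assoc$p_value[assoc$variable == "group"], 1e-10)
  expect_gt(min(assoc$p_value[assoc$type == "continuous"]), 1e-4)
})

test_that("chi-square on a perfectly split contingency equals n", {
  labels <- tibble::tibble(sample_id = sprintf("s%03d", 1:100),
                           cluster = rep(1:2, each = 50))
  samples <- tibble::tibble(sample_id = labels$sample_id,
                            group = factor(rep(c("case", "control"),
                                               each = 50)))
  assoc <- cluster_phenotype_association(labels, samples,
                                         categorical = "group",
                                         continuous = character())
  expect_equal(assoc$statistic, 100)
})

test_that("cumulative score arithmetic, linearity, and missing-probe errors", {
  v <- matrix(0.5, nrow = 3, ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  panel <- tibble::tibble(probe_id = c("a", "b", "c"), weight = c(1, -1, 2))
  sc <- cumulative_score(v, panel)
  expect_equal(sc$score, c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(cumulative_score(v * 0, panel)$score, c(0, 0))
  expect_equal(cumulative_score(3 * v, panel)$score, 3 * sc$score)
  expect_error(cumulative_score(v[1:2, ], panel), "c")
})

test_that("score-index correlation recovers the generator coupling", {
  man <- tiny_manifest()
  ref <- tiny_reference()
  ids <- man$probe_id[!man$is_control][1:10]
  st <- generate_cohort(man, ref, 200, 200,
                        spike_probes = tibble::tibble(probe_id = ids,
                                                      delta_beta = 0.05),
                        score_index_r = 0.6, seed = 171)
  out <- correlate_score_index(st$truth$burden, st$samples$vacs_index)
  fisher_band <- tanh(atanh(0.6) + c(-1, 1) * 1.96 / sqrt(out$n - 3))
  expect_gt(out$r, fisher_band[1] - 0.02)
  expect_lt(out$r, fisher_band[2] + 0.02)
  expect_lt(out$p_value, 1e-10)

  perfect <- correlate_score_index(1:50, 2 * (1:50) + 3)
  expect_equal(perfect$r, 1)
  expect_error(correlate_score_index(rep(1, 10), 1:10), "variance")
  expect_error(correlate_score_index(1:2, 1:2), "3")
})

test_that("frailty bands and binary cuts follow the documented edge rules", {
  lab <- define_frailty_labels(c(0, 15, 16, 24, 25, 34, 35, 50, 51, 120))
  expect_equal(lab$band,
               c("<16", "<16", "17-24", "17-24", "25-34", "25-34", "35-50",
                 "35-50", ">50", ">50"))
  expect_equal(lab$high_frailty, c(rep(FALSE, 8), TRUE, TRUE))
  expect_equal(lab$low_frailty, c(TRUE, TRUE, rep(FALSE, 8)))

  set.seed(18)
  idx <- sample(0:120, 500, replace = TRUE)
  q <- define_frailty_labels(idx, train_index = idx)
  expect_equal(mean(q$high_frailty), 0.2, tolerance = 0.06)
  expect_equal(mean(q$low_frailty), 0.2, tolerance = 0.06)
  expect_warning(define_frailty_labels(c(10, 20, 30), high_cut = 50), "cut")
})

test_that("classifier separates separable classes and is seed-stable", {
  set.seed(19)
  n <- 60
  x <- rbind(f1 = c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3)),
             f2 = rnorm(n))
  colnames(x) <- sprintf("s%02d", 1:n)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  m <- train_frailty_classifier(x, y, folds = 5, seed = 20)
  expect_equal(auc_train <- methfrail:::auc_from_scores(predict(m, x), y), 1)

  m2 <- train_frailty_classifier(x, y, folds = 5, seed = 20)
  expect_identical(m$folds, m2$folds)
  expect_equal(predict(m, x), predict(m2, x))

  # shuffled labels carry no signal
  set.seed(21)
  cvs <- vapply(1:3, function(s) {
    ys <- sample(y)
    ms <- train_frailty_classifier(x, ys, folds = 5, seed = s)
    ms$cv$cv_metric[ms$cv$cost == ms$cost][1]
  }, numeric(1))
  expect_lt(mean(cvs), 0.65)
})

test_that("regression-trained model predicts the index and serves both tasks", {
  set.seed(22)
  n <- 120
  latent <- rnorm(n)
  x <- rbind(a = latent + rnorm(n, 0, 0.4), b = -latent + rnorm(n, 0, 0.4),
             c = rnorm(n))
  colnames(x) <- sprintf("s%03d", 1:n)
  index <- round(pmin(120, pmax(0, 35 + 18 * latent)))
  m <- train_frailty_classifier(x, index, folds = 5, seed = 23)
  expect_equal(m$type, "regression")
  sc <- predict(m, x)
  expect_gt(cor(sc, index), 0.8)
  roc_high <- evaluate_roc(m, x, index > 50, ci_reps = 100, seed = 1)
  roc_low <- evaluate_roc(m, x, index < 16, higher_is_positive = FALSE,
                          ci_reps = 100, seed = 1)
  expect_gt(roc_high$auc, 0.8)
  expect_gt(roc_low$auc, 0.8)
})

test_that("ROC evaluation matches the rank-statistic identity and degenerate CI", {
  set.seed(24)
  n <- 80
  x <- rbind(f = rnorm(n))
  colnames(x) <- sprintf("s%02d", 1:n)
  y <- x["f", ] + rnorm(n) > 0
  m <- train_frailty_classifier(x, y, folds = 5, seed = 25)
  roc <- evaluate_roc(m, x, y, ci_reps = 200, seed = 26)
  sc <- predict(m, x)
  expect_equal(roc$auc, methfrail:::auc_from_scores(sc, y), tolerance = 1e-12)
  expect_true(roc$ci_lower <= roc$auc && roc$auc <= roc$ci_upper)
  expect_true(all(diff(roc$curve$tpr) >= 0))
  # monotone transform invariance
  m_id <- m
  roc2 <- evaluate_roc(m_id, x * 1, y, ci_reps = 100, seed = 26)
  expect_equal(roc2$auc, roc$auc)

  # scores identical to labels: AUC 1 with CI [1, 1]
  xs <- rbind(f1 = c(rep(-3, 10), rep(3, 10)), f2 = rep(0.001, 20))
  colnames(xs) <- sprintf("t%02d", 1:20)
  ys <- rep(c(FALSE, TRUE), each = 10)
  ms <- train_frailty_classifier(xs, ys, folds = 5, seed = 27)
  rs <- evaluate_roc(ms, xs, ys, ci_reps = 200, seed = 28)
  expect_equal(rs$auc, 1)
  expect_equal(c(rs$ci_lower, rs$ci_upper), c(1, 1))
  expect_error(evaluate_roc(ms, xs, rep(TRUE, 20)), "both classes")
})

test_that("random-panel permutation null is reproducible and respects its floor", {
  man <- tiny_manifest()
  ref <- tiny_reference()
  ids <- man$probe_id[!man$is_control][1:6]
  st <- generate_cohort(man, ref, 100, 100,
                        spike_probes = tibble::tibble(
                          probe_id = ids,
                          delta_beta = rep(c(0.08, -0.08), 3)),
                        score_index_r = 0.9, seed = 181, cohort_id = "tr")
  te <- generate_cohort(man, ref, 60, 140,
                        spike_probes = tibble::tibble(
                          probe_id = ids,
                          delta_beta = rep(c(0.08, -0.08), 3)),
                        score_index_r = 0.9, seed = 182, cohort_id = "te")
  cells <- estimate_cell_proportions(st$beta, ref)
  cells_te <- estimate_cell_proportions(te$beta, ref)
  beta_all <- cbind(st$beta, te$beta)
  covs <- dplyr::bind_rows(nuisance_tbl(st, cells), nuisance_tbl(te, cells_te))
  outcome <- c(st$samples$vacs_index, te$samples$vacs_index)
  lab <- c(rep(FALSE, ncol(st$beta)), te$samples$vacs_index > 50)
  panel <- tibble::tibble(probe_id = ids, weight = 1)
  rr <- residualize_panel(st$beta, panel, nuisance_tbl(st, cells))
  rr_te <- residualize_panel(te$beta, panel, nuisance_tbl(te, cells_te))
  m <- train_frailty_classifier(rr$residuals, st$samples$vacs_index,
                                folds = 5, seed = 31)
  obs <- methfrail:::auc_from_scores(predict(m, rr_te$residuals),
                                     te$samples$vacs_index > 50)
  null <- permutation_panel_null(beta_all, covs, outcome, lab,
                                 train_ids = colnames(st$beta),
                                 test_ids = colnames(te$beta),
                                 panel_size = 6, observed_auc = obs, B = 40,
                                 seed = 32)
  expect_equal(length(null$null_auc), 40)
  expect_equal(null$p, (1 + sum(null$null_auc >= obs)) / 41)
  null2 <- permutation_panel_null(beta_all, covs, outcome, lab,
                                  train_ids = colnames(st$beta),
                                  test_ids = colnames(te$beta),
                                  panel_size = 6, observed_auc = obs, B = 40,
                                  seed = 32)
  expect_identical(null$null_auc, null2$null_auc)
  expect_error(
    permutation_panel_null(beta_all, covs, outcome, lab,
                           train_ids = colnames(st$beta),
                           test_ids = c(colnames(st$beta)[1],
                                        colnames(te$beta)),
                           panel_size = 6, B = 5, seed = 1),
    "disjoint")
})
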