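test_that("detection p follows the background normal tail", {
  set.seed(1)
  bg <- matrix(rnorm(200, 1000, 50), nrow = 20,
               dimnames = list(sprintf("bg%02d", 1:20), sprintf("s%d", 1:10)))
  probes <- rbind(bg, at_mean = colMeans(bg),
                  bright = colMeans(bg) + 10 * apply(bg, 2, sd))
  p <- compute_detection_p(probes, rownames(bg))
  expect_equal(unname(p["at_mean", ]), rep(0.5, 10), tolerance = 1e-12)
  expect_true(all(p["bright", ] < 1e-12))
  expect_error(compute_detection_p(probes, "bg01"), ">= 2")
  expect_warning(compute_detection_p(probes, rownames(bg)[1:5]), "fewer than 10")
})

test_that("detection p is uniform under the all-background null", {
  set.seed(2)
  x <- matrix(rnorm(5000 * 4, 500, 30), nrow = 5000,
              dimnames = list(sprintf("p%04d", 1:5000), sprintf("s%d", 1:4)))
  p <- compute_detection_p(x, rownames(x))
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("probe filtering removes by precedence and the report reconciles", {
  man <- generate_manifest(1000, 50, 30, 20, 100, seed = 1)
  out <- filter_probes(man)
  expect_equal(out$report$n_removed_control, 20)
  expect_equal(out$report$n_removed_sex, 50)
  expect_equal(out$report$n_removed_snp, 30)
  expect_equal(out$report$n_retained, 1000)
  with(out$report, expect_equal(
    n_input, n_retained + n_removed_control + n_removed_sex + n_removed_snp +
      n_removed_detection))
})

test_that("detection-based probe removal and the identity filter behave", {
  man <- tibble::tibble(
    probe_id = c("a", "b", "c"), chromosome = "1", position = 1:3 * 1000L,
    gene = "", region_class = "Intergenic", design_type = "II",
    snp_within_10bp = FALSE, is_control = FALSE, control_class = "")
  det <- matrix(c(0, 0, 0, 0, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  out <- filter_probes(man, det, threshold = 1e-12, max_fail_fraction = 0.5)
  expect_equal(out$probes, c("a", "b"))
  expect_equal(out$report$n_removed_detection, 1)

  all_pass <- filter_probes(man, det, threshold = 1.000001,
                            max_fail_fraction = 0.5)
  expect_equal(all_pass$probes, man$probe_id)
})

test_that("sample call-rate filter is strict at the boundary", {
  det <- matrix(1, nrow = 100, ncol = 3,
                dimnames = list(sprintf("p%d", 1:100), c("good", "edge", "bad")))
  det[, "good"] <- 0
  det[1:98, "edge"] <- 0    # exactly 98%
  det[1:97, "bad"] <- 0     # 97% -> removed
  out <- filter_samples(det, threshold = 1e-12, call_rate_threshold = 0.98)
  expect_setequal(out$samples, c("good", "edge"))
  expect_equal(out$removed$sample_id, "bad")
  det[] <- 1
  expect_error(filter_samples(det), "all samples")
})

test_that("sex prediction calls an all-male synthetic cohort male", {
  st <- small_cohort(seed = 61)
  calls <- predict_sex(st$beta, st$manifest,
                       self_reported = st$samples$self_reported_sex)
  expect_true(all(calls$predicted_sex == "male"))
  expect_equal(sum(calls$mismatch), 0)
  expect_warning(
    one <- predict_sex(st$beta[, 1, drop = FALSE], st$manifest),
    "indeterminate")
  expect_equal(one$predicted_sex, "indeterminate")
  expect_error(predict_sex(st$beta[1:5, ], st$manifest), "X and .* Y")
})

test_that("sex prediction separates two clusters of Y signal", {
  man <- tiny_manifest()
  y_ids <- man$probe_id[man$chromosome == "Y"]
  x_ids <- man$probe_id[man$chromosome == "X"]
  set.seed(3)
  beta <- matrix(runif(length(c(y_ids, x_ids)) * 10, 0.4, 0.6),
                 nrow = length(c(y_ids, x_ids)),
                 dimnames = list(c(y_ids, x_ids), sprintf("s%02d", 1:10)))
  beta[y_ids, 6:10] <- matrix(runif(length(y_ids) * 5, 0, 0.1),
                              nrow = length(y_ids))
  calls <- predict_sex(beta, man)
  expect_equal(calls$predicted_sex, rep(c("male", "female"), each = 5))
})

test_that("quantile normalization matches the rank-mean oracle and is idempotent", {
  x <- cbind(s1 = c(1, 2, 3), s2 = c(10, 20, 30))
  rownames(x) <- c("a", "b", "c")
  norm <- quantile_normalize(x)
  expect_equal(unname(norm[, 1]), c(5.5, 11, 16.5))
  expect_equal(unname(norm[, 2]), c(5.5, 11, 16.5))

  set.seed(4)
  y <- matrix(rexp(600), nrow = 100)
  once <- quantile_normalize(y)
  twice <- quantile_normalize(once)
  expect_equal(once, twice, tolerance = 1e-12)

  same <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)

  strata <- rep(c("I", "II"), c(40, 60))
  strat_norm <- quantile_normalize(y, strata)
  expect_equal(strat_norm[1:40, ], quantile_normalize(y[1:40, ]))
})

test_that("beta transform arithmetic holds", {
  expect_equal(beta_from_intensity(matrix(0), matrix(0))[1, 1], 0)
  expect_equal(beta_from_intensity(matrix(900), matrix(0))[1, 1], 0.9)
  expect_equal(beta_from_intensity(matrix(1e6), matrix(1e6))[1, 1], 0.5,
               tolerance = 1e-4)
  expect_error(beta_from_intensity(matrix(-1), matrix(0)), "non-negative")
})

test_that("deconvolution recovers pure and mixed samples", {
  ref <- tiny_reference()
  pure_cd8 <- ref$profile[, "CD8T", drop = FALSE]
  colnames(pure_cd8) <- "s1"
  w <- estimate_cell_proportions(pure_cd8, ref)
  expect_equal(as.numeric(w[1, ref$cell_types]), c(0, 1, 0, 0, 0, 0),
               tolerance = 0.02)

  mix <- 0.5 * ref$profile[, "Gran"] + 0.5 * ref$profile[, "CD4T"]
  m <- estimate_cell_proportions(matrix(mix, ncol = 1,
                                        dimnames = list(rownames(ref$profile),
                                                        "s1")), ref)
  expect_equal(as.numeric(m[1, c("Gran", "CD4T")]), c(0.5, 0.5),
               tolerance = 0.05)
  expect_lt(sum(as.numeric(m[1, ref$cell_types])), 1 + 1e-6)
})

test_that("deconvolution RMSE on a Dirichlet cohort is small and invariant", {
  ref <- tiny_reference()
  st <- small_cohort(reference = ref, n_case = 50, n_control = 50, seed = 71)
  est <- estimate_cell_proportions(st$beta, ref)
  truth <- st$truth$cell_props
  rmse <- sqrt(mean((as.matrix(est[, ref$cell_types]) -
                       as.matrix(truth[, ref$cell_types]))^2))
  expect_lt(rmse, 0.05)

  # invariant to sample order and to adding non-marker probes
  perm <- sample(ncol(st$beta))
  est_perm <- estimate_cell_proportions(st$beta[, perm], ref)
  expect_equal(as.matrix(est_perm[, ref$cell_types]),
               as.matrix(est[perm, ref$cell_types]), tolerance = 1e-10)
  only_markers <- st$beta[ref$marker_ids, ]
  est_markers <- estimate_cell_proportions(only_markers, ref)
  expect_equal(est_markers, est, tolerance = 1e-10)

  # missing >20% of markers errors
  expect_error(
    estimate_cell_proportions(st$beta[ref$marker_ids[1:20], ], ref),
    "20%")
})

test_that("sum-to-one deconvolution constraint holds when requested", {
  ref <- tiny_reference()
  st <- small_cohort(reference = ref, n_case = 10, n_control = 10, seed = 81)
  est <- estimate_cell_proportions(st$beta, ref, sum_to_one = TRUE)
  sums <- rowSums(as.matrix(est[, ref$cell_types]))
  # the equality constraint is enforced through a penalty row, so it holds
  # to the penalty precision rather than machine precision
  expect_lt(max(abs(sums - 1)), 1e-3)
})
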