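#' Detection p-values against an empirical background
#'
#' For each sample, estimates a normal background (mean, SD) from a designated
#' background probe set and scores every probe's intensity by its upper-tail
#' probability under that background. Small p means the probe signal clearly
#' exceeds background. Arrays of all-male cohorts conventionally reuse
#' Y-chromosome probes as the background set.
#'
#' @param intensities Non-negative probe x sample intensity matrix.
#' @param background_probe_ids Probe ids (rows of `intensities`) forming the
#'   background set; fewer than 10 warns, fewer than 2 errors.
#' @return Matrix of detection p-values, same shape and dimnames as the input.
#' @export
compute_detection_p <- function(intensities, background_probe_ids) {
  if (any(intensities < 0)) abort("intensities must be non-negative")
  bg_ids <- intersect(background_probe_ids, rownames(intensities))
  if (length(bg_ids) < 2) abort("background set must contain >= 2 probes")
  if (length(bg_ids) < 10) warn("background set has fewer than 10 probes")
  bg <- intensities[bg_ids, , drop = FALSE]
  mu <- colMeans(bg)
  sdev <- apply(bg, 2, sd)
  if (any(sdev == 0)) abort("background SD is zero in at least one sample")
  p <- pnorm(sweep(sweep(intensities, 2, mu), 2, sdev, "/"),
             lower.tail = FALSE)
  dimnames(p) <- dimnames(intensities)
  p
}

#' Filter probes by control status, chromosome, SNP proximity and detection
#'
#' Removal precedence is fixed and documented so that every probe has exactly
#' one removal reason and the report reconciles: control probes first, then
#' sex-chromosome (X/Y) probes, then SNP-proximal probes, then probes failing
#' detection (p >= `threshold`) in more than `max_fail_fraction` of samples.
#'
#' @param manifest Probe manifest covering every probe in `detection`.
#' @param detection Optional detection p-value matrix; `NULL` skips the
#'   detection rule.
#' @param threshold Detection p-value threshold (default 1e-12).
#' @param max_fail_fraction Maximum tolerated fraction of samples in which a
#'   probe may fail detection.
#' @return List with `probes` (retained ids, manifest order) and `report`
#'   (one-row tibble of counts; `n_input = n_retained + sum(removals)`).
#' @export
filter_probes <- function(manifest, detection = NULL, threshold = 1e-12,
                          max_fail_fraction = 0.05) {
  reason <- rep(NA_character_, nrow(manifest))
  reason[manifest$is_control] <- "control"
  sex <- is.na(reason) & manifest$chromosome %in% c("X", "Y")
  reason[sex] <- "sex"
  snp <- is.na(reason) & manifest$snp_within_10bp
  reason[snp] <- "snp"
  if (!is.null(detection)) {
    missing <- setdiff(rownames(detection), manifest$probe_id)
    if (length(missing)) {
      abort(paste0("manifest does not cover detection probe(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    fail_frac <- rowMeans(detection >= threshold)
    failing <- rownames(detection)[fail_frac > max_fail_fraction]
    det <- is.na(reason) & manifest$probe_id %in% failing
    reason[det] <- "detection"
  }
  retained <- manifest$probe_id[is.na(reason)]
  if (!length(retained)) abort("all probes removed by filtering")
  report <- tibble(
    n_input = nrow(manifest),
    n_removed_control = sum(reason == "control", na.rm = TRUE),
    n_removed_sex = sum(reason == "sex", na.rm = TRUE),
    n_removed_snp = sum(reason == "snp", na.rm = TRUE),
    n_removed_detection = sum(reason == "detection", na.rm = TRUE),
    n_retained = length(retained))
  list(probes = retained, report = report)
}

#' Filter samples by detection call rate
#'
#' A sample's call rate is the fraction of probes detected (p < `threshold`);
#' samples strictly below `call_rate_threshold` are removed.
#'
#' @param detection Detection p-value matrix (computed on the post-probe-filter
#'   set).
#' @param threshold Detection p-value threshold defining "detected".
#' @param call_rate_threshold Minimum acceptable call rate (default 0.98; a
#'   sample at exactly the threshold is retained).
#' @return List with `samples` (retained ids), `removed` (tibble of sample id,
#'   call rate, reason) and `call_rates`.
#' @export
filter_samples <- function(detection, threshold = 1e-12,
                           call_rate_threshold = 0.98) {
  call_rate <- colMeans(detection < threshold)
  drop <- call_rate < call_rate_threshold
  if (all(drop)) abort("all samples fall below the call-rate threshold")
  list(samples = colnames(detection)[!drop],
       removed = tibble(sample_id = colnames(detection)[drop],
                        call_rate = unname(call_rate[drop]),
                        reason = "low_call_rate"),
       call_rates = tibble(sample_id = colnames(detection),
                           call_rate = unname(call_rate)))
}

#' Predict sample sex from Y-chromosome methylation
#'
#' Computes each sample's mean beta over Y-chromosome probes. With a mixed
#' cohort the samples split into two clusters (largest 1-D gap); when the two
#' cluster means differ by more than 0.15 the high cluster is called male and
#' the low cluster female. Otherwise the cohort is treated as single-sex and an
#' absolute threshold (mean Y beta >= 0.2 = male) is applied. A cohort of one
#' sample is indeterminate. Mismatches against self-report are flagged, not
#' dropped - the caller decides.
#'
#' @param beta Probe x sample beta matrix.
#' @param manifest Manifest with at least one X and one Y probe.
#' @param self_reported Optional vector of self-reported sex, aligned with the
#'   columns of `beta`.
#' @return Tibble with `sample_id`, `mean_y_beta`, `predicted_sex`, and (when
#'   self-report is given) `self_reported` and `mismatch`.
#' @export
predict_sex <- function(beta, manifest, self_reported = NULL) {
  y_ids <- intersect(rownames(beta),
                     manifest$probe_id[manifest$chromosome == "Y" &
                                         !manifest$is_control])
  x_ids <- intersect(rownames(beta),
                     manifest$probe_id[manifest$chromosome == "X" &
                                         !manifest$is_control])
  if (!length(y_ids) || !length(x_ids)) {
    abort("manifest must provide at least one X and one Y probe present in beta")
  }
  my <- colMeans(beta[y_ids, , drop = FALSE])
  n <- length(my)
  if (n == 1) {
    warn("single-sample cohort: sex call is indeterminate")
    call <- "indeterminate"
  } else {
    ord <- order(my)
    gaps <- diff(my[ord])
    split_at <- which.max(gaps)
    lo <- my[ord][seq_len(split_at)]
    hi <- my[ord][-seq_len(split_at)]
    if (mean(hi) - mean(lo) > 0.15) {
      call <- unname(ifelse(my > (max(lo) + min(hi)) / 2, "male", "female"))
    } else {
      call <- rep(if (mean(my) >= 0.2) "male" else "female", n)
    }
  }
  out <- tibble(sample_id = colnames(beta), mean_y_beta = unname(my),
                predicted_sex = call)
  if (!is.null(self_reported)) {
    out$self_reported <- as.character(self_reported)
    out$mismatch <- out$predicted_sex != out$self_reported &
      out$predicted_sex != "indeterminate"
  }
  out
}

#' Quantile normalization within probe strata
#'
#' Within each stratum of probes (by default a single stratum; array practice
#' stratifies by probe design type), every sample's sorted values are mapped to
#' the across-sample mean of sorted values, making the per-sample distributions
#' identical within the stratum. The transform is idempotent.
#'
#' @param x Probe x sample numeric matrix.
#' @param strata Optional vector (length `nrow(x)`) partitioning the probes.
#' @return Normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(x, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, nrow(x))
  if (length(strata) != nrow(x)) abort("strata must have one entry per probe")
  out <- x
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) == 1) {
      warn(paste0("stratum '", s, "' has a single probe; passing through"))
      next
    }
    out[idx, ] <- limma::normalizeQuantiles(x[idx, , drop = FALSE])
  }
  out
}

#' Beta values from methylated/unmethylated intensities
#'
#' `beta = meth / (meth + unmeth + offset)`; the offset stabilises low-intensity
#' probes and keeps values in `[0, 1)`.
#'
#' @param meth,unmeth Non-negative intensity matrices of identical shape.
#' @param offset Stabilising constant (default 100).
#' @return Beta matrix.
#' @export
beta_from_intensity <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0) || any(unmeth < 0)) abort("intensities must be non-negative")
  if (!all(dim(meth) == dim(unmeth))) abort("meth and unmeth shapes differ")
  meth / (meth + unmeth + offset)
}

#' Reference-based cell-type deconvolution
#'
#' Estimates the six leukocyte proportions per sample by constrained least
#' squares against the reference profile at its marker probes: weights are
#' non-negative and, by default, sum to at most 1 (whole-blood fractions need
#' not be exhaustive); `sum_to_one = TRUE` enforces the equality constraint.
#' The constraint is imposed through a slack variable and a heavy penalty row
#' on top of non-negative least squares.
#'
#' @param beta Probe x sample beta matrix containing the reference markers
#'   (up to 20% may be missing).
#' @param reference A `cell_reference`.
#' @param sum_to_one Force proportions to sum to exactly 1.
#' @return Tibble: `sample_id`, one column per cell type, `residual_norm`.
#' @export
estimate_cell_proportions <- function(beta, reference, sum_to_one = FALSE) {
  pres <- intersect(reference$marker_ids, rownames(beta))
  if (length(pres) < 0.8 * length(reference$marker_ids)) {
    abort("more than 20% of reference marker probes are missing from beta")
  }
  R <- reference$profile[pres, , drop = FALSE]
  lam <- 50
  if (sum_to_one) {
    A <- rbind(R, lam * rep(1, ncol(R)))
  } else {
    A <- rbind(cbind(R, 0), lam * rep(1, ncol(R) + 1))
  }
  W <- vapply(seq_len(ncol(beta)), function(j) {
    b <- beta[pres, j]
    sol <- pracma::lsqnonneg(A, c(b, lam))$x
    w <- sol[seq_len(ncol(R))]
    c(w, sqrt(sum((b - R %*% w)^2)))
  }, numeric(ncol(R) + 1))
  out <- as_tibble(t(W), .name_repair = "minimal")
  names(out) <- c(colnames(R), "residual_norm")
  dplyr::bind_cols(tibble(sample_id = colnames(beta)), out)
}
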