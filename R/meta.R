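check_meta_stats <- function(stats) {
  need <- c("study", "probe_id", "estimate", "std_error")
  missing <- setdiff(need, names(stats))
  if (length(missing)) {
    abort(paste0("meta input is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(stats$std_error <= 0)) abort("standard errors must be > 0")
  invisible(stats)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-probe study estimates with weights `1/SE^2`: pooled coefficient
#' `sum(w b)/sum(w)`, pooled SE `1/sqrt(sum(w))`, `z = coef/SE`, two-sided
#' normal p, plus Cochran's Q and the I-squared heterogeneity percentage
#' `max(0, 100 (Q - (k-1)) / Q)`. Probes present in a single study are passed
#' through unpooled (`pooled = FALSE`) so the cross-platform probe overlap is
#' always explicit. Pooled p-values get their own BH pass; unpooled probes
#' carry `NA` q-values.
#'
#' @param stats Long tibble with one row per study x probe and columns
#'   `study`, `probe_id`, `estimate`, `std_error`.
#' @return Tibble per probe: `probe_id`, `k`, `estimate`, `std_error`,
#'   `statistic` (z), `p_value`, `q_value`, `Q`, `i_squared`, `direction`
#'   (one sign character per study), `pooled`.
#' @export
meta_inverse_variance <- function(stats) {
  check_meta_stats(stats)
  out <- stats |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      k = dplyr::n(),
      direction = paste(ifelse(.data$estimate < 0, "-", "+"), collapse = ""),
      est = sum(.data$estimate / .data$std_error^2) /
        sum(1 / .data$std_error^2),
      se = 1 / sqrt(sum(1 / .data$std_error^2)),
      Q = sum((.data$estimate - est)^2 / .data$std_error^2),
      .groups = "drop") |>
    dplyr::mutate(
      estimate = .data$est, std_error = .data$se,
      statistic = .data$estimate / .data$std_error,
      # extreme z underflows to 0; clip to the smallest positive double
      p_value = pmax(2 * pnorm(-abs(.data$statistic)),
                     .Machine$double.xmin),
      i_squared = ifelse(.data$Q > 0,
                         pmax(0, 100 * (.data$Q - (.data$k - 1)) / .data$Q),
                         0),
      pooled = .data$k >= 2,
      q_value = NA_real_) |>
    dplyr::select("probe_id", "k", "estimate", "std_error", "statistic",
                  "p_value", "q_value", "Q", "i_squared", "direction",
                  "pooled")
  out$q_value[out$pooled] <- adjust_fdr(out$p_value[out$pooled])
  out
}

#' Sample-size-weighted meta-analysis
#'
#' METAL-style scheme: each study contributes a signed z-score
#' `z_i = sign(estimate_i) * qnorm(p_i / 2, lower = FALSE)`, combined as
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))` with a two-sided normal p.
#' Zero p-values are clipped to the smallest representable positive double
#' with a warning.
#'
#' @param stats Long tibble with columns `study`, `probe_id`, `estimate`
#'   (its sign is the study direction), `p_value`, `n`.
#' @return Tibble per probe: `probe_id`, `k`, `statistic` (Z), `p_value`,
#'   `direction`, `pooled`.
#' @export
meta_sample_size <- function(stats) {
  need <- c("study", "probe_id", "estimate", "p_value", "n")
  missing <- setdiff(need, names(stats))
  if (length(missing)) {
    abort(paste0("meta input is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(stats$p_value == 0)) {
    warn("p-values of 0 clipped to the smallest representable double")
    stats$p_value <- pmax(stats$p_value, .Machine$double.xmin)
  }
  stats |>
    dplyr::mutate(z_i = sign(.data$estimate) *
                    qnorm(.data$p_value / 2, lower.tail = FALSE)) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      k = dplyr::n(),
      direction = paste(ifelse(.data$estimate < 0, "-", "+"), collapse = ""),
      statistic = sum(sqrt(.data$n) * .data$z_i) / sqrt(sum(.data$n)),
      .groups = "drop") |>
    dplyr::mutate(p_value = 2 * pnorm(-abs(.data$statistic)),
                  pooled = .data$k >= 2) |>
    dplyr::select("probe_id", "k", "statistic", "p_value", "direction",
                  "pooled")
}

#' Between-study heterogeneity (Cochran's Q and I-squared)
#'
#' `Q = sum(w_i (b_i - b_pooled)^2)` with inverse-variance weights and
#' `I^2 = max(0, 100 (Q - (k-1)) / Q)` percent.
#'
#' @inheritParams meta_inverse_variance
#' @return Tibble per probe: `probe_id`, `k`, `Q`, `i_squared`.
#' @export
meta_heterogeneity <- function(stats) {
  check_meta_stats(stats)
  meta_inverse_variance(stats) |>
    dplyr::select("probe_id", "k", "Q", "i_squared")
}
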