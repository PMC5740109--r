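#' Tidy an EWAS fit
#'
#' @param x An `ewas_fit`.
#' @param ... Unused.
#' @return The per-probe result tibble (`probe_id`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `q_value`).
#' @export
tidy.ewas_fit <- function(x, ...) x$results

#' One-row summary of an EWAS fit
#'
#' @param x An `ewas_fit`.
#' @param ... Unused.
#' @return Tibble: `lambda`, `n_probes`, `n_samples`, `df`,
#'   `n_significant_q05`.
#' @export
glance.ewas_fit <- function(x, ...) {
  tibble(lambda = x$lambda, n_probes = nrow(x$results),
         n_samples = x$n_samples, df = x$df,
         n_significant_q05 = sum(x$results$q_value < 0.05))
}

#' Tidy a DMR result
#'
#' @param x A `dmr_result`.
#' @param ... Unused.
#' @return The region tibble without the list column.
#' @export
tidy.dmr_result <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of("probe_ids"))
}

#' One-row summary of a DMR result
#'
#' @param x A `dmr_result`.
#' @param ... Unused.
#' @return Tibble: `n_candidates`, `n_significant_q05`, `B`, `n_null`.
#' @export
glance.dmr_result <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_significant_q05 = if (nrow(x)) sum(x$q_value < 0.05) else 0L,
         B = attr(x, "B"), n_null = attr(x, "n_null"))
}

#' Tidy a ROC summary (the curve points)
#'
#' @param x A `roc_summary`.
#' @param ... Unused.
#' @return Tibble of `fpr`, `tpr`.
#' @export
tidy.roc_summary <- function(x, ...) x$curve

#' One-row summary of a ROC evaluation
#'
#' @param x A `roc_summary`.
#' @param ... Unused.
#' @return Tibble: `auc`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`.
#' @export
glance.roc_summary <- function(x, ...) {
  tibble(auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' One-row summary of a frailty classifier
#'
#' @param x A `frailty_classifier`.
#' @param ... Unused.
#' @return Tibble: `type`, `kernel`, `cost`, `cv_metric`, `n_train`.
#' @export
glance.frailty_classifier <- function(x, ...) {
  tibble(type = x$type, kernel = x$kernel, cost = x$cost,
         cv_metric = x$cv$cv_metric[x$cv$cost == x$cost][1],
         n_train = x$n_train)
}
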