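#' Plot an EWAS fit: QQ, volcano or Manhattan
#'
#' The QQ plot compares observed -log10 p against the uniform expectation and
#' annotates the genomic inflation factor; the volcano shows effect size
#' against -log10 p; the Manhattan view needs a manifest for positions.
#'
#' @param object An `ewas_fit`.
#' @param type One of "qq", "volcano", "manhattan".
#' @param manifest Manifest with positions (Manhattan only).
#' @param threshold Significance line (default 5e-7).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ewas_fit <- function(object, type = c("qq", "volcano", "manhattan"),
                              manifest = NULL, threshold = 5e-7, ...) {
  type <- match.arg(type)
  res <- object$results
  if (type == "qq") {
    d <- tibble(
      expected = -log10(stats::ppoints(nrow(res))),
      observed = -log10(sort(res$p_value)))
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$expected,
                                      y = .data$observed)) +
        ggplot2::geom_point(size = 0.6, alpha = 0.6) +
        ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
        ggplot2::labs(
          x = expression(Expected ~ -log[10](p)),
          y = expression(Observed ~ -log[10](p)),
          title = sprintf("QQ plot (lambda = %.3f)", object$lambda)) +
        ggplot2::theme_minimal())
  }
  if (type == "volcano") {
    return(
      ggplot2::ggplot(res, ggplot2::aes(x = .data$estimate,
                                        y = -log10(.data$p_value))) +
        ggplot2::geom_point(size = 0.6, alpha = 0.6) +
        ggplot2::geom_hline(yintercept = -log10(threshold),
                            colour = "red", linetype = 2) +
        ggplot2::labs(x = "Group coefficient (delta beta)",
                      y = expression(-log[10](p))) +
        ggplot2::theme_minimal())
  }
  if (is.null(manifest)) abort("manhattan plot needs a manifest")
  d <- dplyr::inner_join(res, manifest, by = "probe_id") |>
    dplyr::filter(!is.na(.data$position)) |>
    dplyr::mutate(chromosome = factor(
      .data$chromosome, levels = c(as.character(1:22), "X", "Y")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = -log10(.data$p_value),
                                  colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), colour = "red",
                        linetype = 2) +
    ggplot2::facet_grid(~chromosome, scales = "free_x", space = "free_x",
                        switch = "x") +
    ggplot2::labs(x = "Chromosome", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0, "pt"))
}

#' Plot a ROC curve with its AUC
#'
#' @param object A `roc_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_summary <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.1f%% (95%% CI %.1f-%.1f%%)",
                      100 * object$auc, 100 * object$ci_lower,
                      100 * object$ci_upper)) +
    ggplot2::theme_minimal()
}

#' Plot DMR areas against their FDR
#'
#' @param object A `dmr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area,
                                  y = -log10(.data$q_value),
                                  size = .data$n_probes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(0.05), colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "Region area statistic", y = expression(-log[10](q)),
                  size = "Probes") +
    ggplot2::theme_minimal()
}

#' Scatter of cumulative methylation score against the frailty index
#'
#' @param scores Tibble from [cumulative_score()].
#' @param vacs_index Index values aligned with `scores`.
#' @return A ggplot object with a least-squares line.
#' @export
plot_score_index <- function(scores, vacs_index) {
  d <- tibble(score = scores$score, vacs_index = vacs_index)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$vacs_index)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "red") +
    ggplot2::labs(x = "Cumulative methylation score", y = "Frailty index") +
    ggplot2::theme_minimal()
}
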