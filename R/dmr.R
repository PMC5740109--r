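#' Cluster probes into genomic neighbourhoods
#'
#' Maximal runs of probes on the same chromosome whose consecutive gaps are at
#' most `max_gap` bp. Singleton clusters are allowed. Duplicate
#' (chromosome, position) pairs are tolerated with a warning and a stable
#' tie-break by probe id.
#'
#' @param manifest Probe manifest; control probes and probes without a
#'   position are ignored.
#' @param max_gap Maximum within-cluster gap in bp (default 500).
#' @return Tibble sorted by chromosome and position: `probe_id`, `chromosome`,
#'   `position`, `cluster_id`.
#' @export
cluster_probes <- function(manifest, max_gap = 500) {
  m <- manifest |>
    dplyr::filter(!.data$is_control, !is.na(.data$position)) |>
    dplyr::arrange(.data$chromosome, .data$position, .data$probe_id)
  if (anyDuplicated(m[, c("chromosome", "position")])) {
    warn("duplicate (chromosome, position) entries; ties broken by probe id")
  }
  m |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(cid = cumsum(c(1L, as.integer(diff(.data$position) >
                                                  max_gap)))) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster_id = paste0(.data$chromosome, "_", .data$cid)) |>
    dplyr::select("probe_id", "chromosome", "position", "cluster_id")
}

#' Running-mean smoothing of per-probe coefficients
#'
#' Centred running mean with the window shrinking at the edges (the mean is
#' taken over whatever part of the window falls inside the vector). Constant
#' input is a fixed point; a singleton passes through unchanged.
#'
#' @param coefficients Numeric vector, ordered by genomic position within one
#'   cluster.
#' @param window Odd window width (default 3).
#' @return Smoothed vector of the same length.
#' @export
smooth_coefficients <- function(coefficients, window = 3) {
  if (window < 1 || window %% 2 == 0) abort("window must be odd and >= 1")
  n <- length(coefficients)
  if (n == 0) return(coefficients)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, coefficients))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# run detection shared by the observed pass and the permutation passes:
# maximal same-sign runs of |smoothed| >= cutoff within a cluster
find_runs <- function(cluster_int, smoothed, cutoff, min_probes) {
  sgn <- integer(length(smoothed))
  sgn[smoothed >= cutoff] <- 1L
  sgn[smoothed <= -cutoff] <- -1L
  code <- cluster_int * 4L + (sgn + 2L)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_sgn <- sgn[starts]
  keep <- which(seg_sgn != 0L & r$lengths >= min_probes)
  data.frame(
    start_idx = starts[keep], end_idx = ends[keep],
    direction = seg_sgn[keep],
    area = vapply(keep, function(i) sum(abs(smoothed[starts[i]:ends[i]])),
                  numeric(1)))
}

smooth_within_clusters <- function(values, cluster_int, window) {
  out <- numeric(length(values))
  for (idx in split(seq_along(values), cluster_int)) {
    out[idx] <- smooth_coefficients(values[idx], window)
  }
  out
}

#' Candidate differentially methylated regions
#'
#' Thresholds the smoothed coefficients at the `cutoff_quantile` of their
#' absolute values and reports maximal same-sign runs of at least `min_probes`
#' probes within a cluster. The area statistic is the sum of |smoothed| over
#' the run. Regions never span cluster (hence chromosome) boundaries, and
#' their [start, end] equals the min/max position of member probes. No
#' candidates is an empty result, not an error.
#'
#' @param probe_tbl Tibble from [cluster_probes()] with an added `smoothed`
#'   column (and optionally `mean_delta` = raw case-minus-control mean
#'   difference), in cluster order.
#' @param cutoff_quantile Quantile of |smoothed| defining the threshold,
#'   strictly in (0, 1).
#' @param min_probes Minimum probes per region (default 3).
#' @return Tibble of candidate regions: `region_id`, `chromosome`, `start`,
#'   `end`, `n_probes`, `area`, `direction`, `mean_delta_beta` (if available),
#'   `probe_ids` (list column).
#' @export
find_candidate_regions <- function(probe_tbl, cutoff_quantile = 0.99,
                                   min_probes = 3) {
  if (cutoff_quantile <= 0 || cutoff_quantile >= 1) {
    abort("cutoff_quantile must be in (0, 1)")
  }
  cl <- as.integer(factor(probe_tbl$cluster_id,
                          levels = unique(probe_tbl$cluster_id)))
  cutoff <- unname(quantile(abs(probe_tbl$smoothed), cutoff_quantile))
  runs <- find_runs(cl, probe_tbl$smoothed, cutoff, min_probes)
  if (!nrow(runs)) {
    return(tibble(region_id = character(), chromosome = character(),
                  start = integer(), end = integer(), n_probes = integer(),
                  area = double(), direction = integer(),
                  mean_delta_beta = double(), probe_ids = list()))
  }
  purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    idx <- runs$start_idx[i]:runs$end_idx[i]
    tibble(
      region_id = sprintf("dmr_%03d", i),
      chromosome = probe_tbl$chromosome[idx[1]],
      start = min(probe_tbl$position[idx]),
      end = max(probe_tbl$position[idx]),
      n_probes = length(idx),
      area = runs$area[i],
      direction = runs$direction[i],
      mean_delta_beta = if ("mean_delta" %in% names(probe_tbl)) {
        mean(probe_tbl$mean_delta[idx])
      } else NA_real_,
      probe_ids = list(probe_tbl$probe_id[idx]))
  })
}

#' Permutation null and FDR for candidate regions
#'
#' Permutes the case/control labels B times; each permutation reruns the full
#' coefficient -> smoothing -> candidate pass (the cutoff is re-derived from
#' the permuted statistics) and contributes its region areas to a pooled null
#' (per-region nulls at B = 100 are too coarse). Region p-values are
#' `min(1, (1 + #{pooled null area >= observed area}) / (1 + B))`: the
#' denominator is the number of permutation passes, so a region larger than
#' every null area sits at the floor `1/(B+1)` even when permutations produce
#' no null areas at all. BH adjustment follows across candidates.
#'
#' @param fit The `ewas_fit` whose adjusted group coefficients seeded the
#'   candidates.
#' @param beta Probe x sample beta matrix the fit was run on.
#' @param probe_tbl Clustered probe table used for the observed pass.
#' @param candidates Candidate regions from [find_candidate_regions()].
#' @param window,cutoff_quantile,min_probes Parameters of the observed pass.
#' @param B Number of permutations (>= 20).
#' @param seed Integer seed.
#' @return `dmr_result`: the candidate tibble with `p_value` and `q_value`,
#'   and attributes `B`, `n_null`.
#' @export
dmr_permutation_fdr <- function(fit, beta, probe_tbl, candidates,
                                window = 3, cutoff_quantile = 0.99,
                                min_probes = 3, B = 100, seed = 1) {
  if (B < 20) abort("B must be >= 20")
  if (!nrow(candidates)) {
    return(structure(candidates, class = c("dmr_result", class(candidates)),
                     B = B, n_null = 0L))
  }
  Y <- t(beta[probe_tbl$probe_id, fit$sample_ids, drop = FALSE])
  X <- fit$design
  gi <- fit$group_col
  cl <- as.integer(factor(probe_tbl$cluster_id,
                          levels = unique(probe_tbl$cluster_id)))
  null_areas <- withr::with_seed(seed, {
    unlist(lapply(seq_len(B), function(b) {
      Xp <- X
      Xp[, gi] <- sample(X[, gi])
      coef_p <- qr.coef(qr(Xp), Y)[gi, ]
      sm <- smooth_within_clusters(coef_p, cl, window)
      cutoff_b <- unname(quantile(abs(sm), cutoff_quantile))
      find_runs(cl, sm, cutoff_b, min_probes)$area
    }))
  })
  n_null <- length(null_areas)
  if (n_null == 0) {
    warn("no null areas in any permutation; p-values sit at the 1/(B+1) floor")
  }
  p <- vapply(candidates$area,
              function(a) min(1, (1 + sum(null_areas >= a)) / (1 + B)),
              numeric(1))
  out <- candidates
  out$p_value <- p
  out$q_value <- adjust_fdr(p)
  structure(out, class = c("dmr_result", class(candidates)),
            B = B, n_null = n_null)
}

#' Bump-hunting DMR detection, end to end
#'
#' Clusters the analysed probes, smooths the covariate-adjusted per-probe
#' group coefficients from the EWAS fit (so regions inherit the adjustment),
#' extracts candidate regions above the `cutoff_quantile`, and assigns
#' permutation p-values and FDR q-values against the pooled permutation null.
#'
#' @inheritParams dmr_permutation_fdr
#' @param manifest Probe manifest (positions for the analysed probes).
#' @param max_gap Maximum within-cluster gap in bp.
#' @return A `dmr_result` tibble (possibly empty).
#' @export
bump_hunt <- function(fit, beta, manifest, max_gap = 500, window = 3,
                      cutoff_quantile = 0.99, min_probes = 3, B = 100,
                      seed = 1) {
  ids <- intersect(fit$results$probe_id, rownames(beta))
  probe_tbl <- cluster_probes(
    manifest[manifest$probe_id %in% ids, , drop = FALSE], max_gap = max_gap)
  est <- fit$results$estimate[match(probe_tbl$probe_id, fit$results$probe_id)]
  case <- fit$design[, fit$group_col] == 1
  bsub <- beta[probe_tbl$probe_id, fit$sample_ids, drop = FALSE]
  probe_tbl$mean_delta <- rowMeans(bsub[, case, drop = FALSE]) -
    rowMeans(bsub[, !case, drop = FALSE])
  cl <- as.integer(factor(probe_tbl$cluster_id,
                          levels = unique(probe_tbl$cluster_id)))
  probe_tbl$smoothed <- smooth_within_clusters(est, cl, window)
  candidates <- find_candidate_regions(probe_tbl, cutoff_quantile, min_probes)
  dmr_permutation_fdr(fit, beta, probe_tbl, candidates, window,
                      cutoff_quantile, min_probes, B, seed)
}
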