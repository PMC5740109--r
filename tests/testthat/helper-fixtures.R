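# Shared small fixtures and independent oracles used across test files.

tiny_manifest <- function(seed = 11) {
  generate_manifest(n_autosomal = 400, n_sex = 30, n_snp_flagged = 40,
                    n_control = 60, n_genes = 60, seed = seed)
}

tiny_reference <- function(seed = 12) generate_cell_reference(6, seed = seed)

small_cohort <- function(manifest = tiny_manifest(), reference = tiny_reference(),
                         n_case = 40, n_control = 40, seed = 13, ...) {
  generate_cohort(manifest, reference, n_case = n_case, n_control = n_control,
                  seed = seed, ...)
}

nuisance_tbl <- function(study, cells) {
  dplyr::bind_cols(
    study$samples[, c("age", "smoker", "audit_c", "adherence",
                      "log10_vl", "wbc")],
    cells[, c("CD4T", "CD8T", "NK", "Bcell", "Mono", "Gran")])
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force fixed-effect inverse-variance pooling for one probe
iv_oracle <- function(b, se) {
  w <- 1 / se^2
  est <- sum(w * b) / sum(w)
  pse <- sqrt(1 / sum(w))
  Q <- sum(w * (b - est)^2)
  k <- length(b)
  i2 <- if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0
  list(estimate = est, se = pse, z = est / pse,
       p = 2 * pnorm(-abs(est / pse)), Q = Q, i2 = i2)
}

# O(n^2) pairwise-gap clustering oracle: two probes share a cluster iff a
# chain of same-chromosome gaps <= max_gap connects them
cluster_oracle <- function(chrom, pos, max_gap) {
  n <- length(pos)
  o <- order(chrom, pos)
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    idx <- o[i]
    if (i == 1 || chrom[o[i - 1]] != chrom[idx] ||
        pos[idx] - pos[o[i - 1]] > max_gap) {
      lab <- lab + 1L
    }
    labels[idx] <- lab
  }
  labels
}

# exhaustive candidate-region oracle for one cluster: all maximal contiguous
# same-sign runs of length >= min_probes with |smoothed| >= cutoff
candidate_oracle_1cluster <- function(smoothed, cutoff, min_probes) {
  n <- length(smoothed)
  ok <- abs(smoothed) >= cutoff
  sgn <- sign(smoothed)
  runs <- list()
  for (start in seq_len(n)) {
    for (end in start:n) {
      idx <- start:end
      if (end - start + 1 < min_probes) next
      if (!all(ok[idx])) next
      if (length(unique(sgn[idx])) != 1) next
      maximal <- (start == 1 || !ok[start - 1] ||
                    sgn[start - 1] != sgn[start]) &&
        (end == n || !ok[end + 1] || sgn[end + 1] != sgn[end])
      if (maximal) {
        runs[[length(runs) + 1]] <- list(start = start, end = end,
                                         area = sum(abs(smoothed[idx])))
      }
    }
  }
  runs
}

# brute-force complete-linkage agglomeration for <= 8 points
complete_linkage_oracle <- function(x, k) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- as.matrix(dist(x))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(nrow(x))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# closed-form two-sample normal power at two-sided level alpha
power_oracle <- function(n1, n2, delta, sd, alpha) {
  se <- sd * sqrt(1 / n1 + 1 / n2)
  z <- qnorm(1 - alpha / 2)
  pnorm(abs(delta) / se - z) + pnorm(-abs(delta) / se - z)
}
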