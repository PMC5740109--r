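logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# n draws from a Dirichlet with shape `alpha`; rows sum to 1
rdirichlet_mat <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  colnames(g) <- names(alpha)
  g / rowSums(g)
}

# Mass-univariate OLS: one design, many response columns.
# Y is samples x responses, X is samples x p (intercept included by caller).
# Aliased columns are dropped with a warning naming them.
ols_fit_matrix <- function(Y, X) {
  stopifnot(nrow(Y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warn(paste0("dropping aliased design column(s): ",
                paste(dropped, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  if (nrow(X) < ncol(X) + 2) {
    abort("not enough samples for the requested design (need n >= p + 2)")
  }
  xtx_inv <- solve(crossprod(X))
  coef <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  list(coef = coef, residuals = res, df = df,
       sigma2 = colSums(res^2) / df, xtx_inv = xtx_inv, X = X)
}

# standard errors for one design column across all responses
ols_se <- function(fit, term_idx) {
  sqrt(fit$sigma2 * fit$xtx_inv[term_idx, term_idx])
}

# Build a numeric design matrix (no intercept column) from a covariate tibble.
design_from_covariates <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(NULL)
  }
  mm <- model.matrix(~., data = as.data.frame(covariates))
  mm[, -1, drop = FALSE]
}

# Normalise a two-level group vector to a 0/1 case indicator.
# logical: TRUE = case; factor/character: the level "case" if present,
# otherwise the second level.
group_indicator <- function(group) {
  if (is.logical(group)) return(as.numeric(group))
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1))) abort("numeric `group` must be 0/1")
    return(as.numeric(group))
  }
  f <- as.factor(group)
  if (nlevels(f) != 2) abort("`group` must have exactly two levels")
  case_level <- if ("case" %in% levels(f)) "case" else levels(f)[2]
  as.numeric(f == case_level)
}

# Mann-Whitney identity AUC for a score vector against logical labels.
auc_from_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
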