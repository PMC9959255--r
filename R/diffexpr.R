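# Covariate-adjusted differential expression and design-stage power
# calculation.
#
# "ANCOVA" here is gene-wise ordinary least squares on a design of
# intercept + group indicator + covariates; with no covariates this is
# algebraically the pooled-variance two-sample t-test.  All genes share one
# design matrix, so coefficients, residual variances and t-statistics are
# obtained for the whole matrix with a single QR decomposition.

#' Gene-wise covariate-adjusted differential expression
#'
#' Fits, per gene, an ordinary least-squares model of log2 expression on a
#' group indicator (EA = 1, the second condition level = 0) plus the named
#' covariates, and tests the group coefficient with a two-sided t-test on
#' the residual degrees of freedom.
#'
#' @param dataset A log2-scale [expression_dataset()] whose `samples` table
#'   contains the covariate columns.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return Data frame with one row per gene: `gene`, `log2fc` (group
#'   coefficient), `p_raw`, `p_adj` (Benjamini-Hochberg), `df_resid`,
#'   `flag` (`"zero-variance"` for degenerate genes, else `""`).
#' @export
fit_gene_ancova <- function(dataset, covariates = character()) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  samples <- dataset$samples
  cond <- samples$condition
  if (nlevels(cond) != 2L) stopf("`condition` must have exactly 2 levels")
  group <- as.numeric(cond == levels(cond)[1L])
  X <- cbind(intercept = 1, group = group)
  for (nm in covariates) {
    if (is.null(samples[[nm]])) stopf("covariate '%s' not found in sample table", nm)
    v <- samples[[nm]]
    if (is.factor(v) || is.character(v) || is.logical(v)) {
      v <- as.numeric(as.factor(v)) - 1
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nm
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stopf("need more samples (%d) than model parameters (%d)", n, p)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stopf("rank-deficient design: column(s) %s confounded with the rest",
          paste(bad, collapse = ", "))
  }

  Y <- t(dataset$exprs)                       # samples x genes
  B <- qr.coef(qx, Y)                         # p x genes
  fitted <- X %*% B
  rss <- colSums((Y - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  XtXinv_gg <- solve(crossprod(X))["group", "group"]
  beta <- B["group", ]
  # zero residual variance (up to numerical noise relative to signal size)
  zv <- sqrt(sigma2) <= 1e-10 * (1 + sqrt(colMeans(Y^2)))
  se <- sqrt(sigma2 * XtXinv_gg)
  tstat <- ifelse(zv, 0, beta / se)
  p_raw <- ifelse(zv, 1, 2 * stats::pt(-abs(tstat), df))
  flag <- ifelse(zv, "zero-variance", "")
  beta[zv & abs(beta) < 1e-10] <- 0
  data.frame(gene = rownames(dataset$exprs), log2fc = unname(beta),
             p_raw = unname(p_raw), p_adj = bh_adjust(unname(p_raw)),
             df_resid = df, flag = flag, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, in input order: `min over j >= i of
#'   m * p_(j) / j`, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Sample size under expected-false-positive control
#'
#' Design-stage calculator for a many-gene two-group comparison: the
#' per-gene two-sided level is set to `expected_fp / m` so that the expected
#' number of false positives among `m` null genes equals `expected_fp`, and
#' the per-group sample size follows the normal-quantile formula
#' `n = ceil(2 * (z_{1-alpha/2} + z_power)^2 * sigma^2 / delta^2)` with
#' `delta = log2(fold)`.
#'
#' @param m Number of genes tested.
#' @param fold Desired detectable fold change (> 1).
#' @param sigma Per-gene standard deviation on the log2 scale.
#' @param power Desired power (0 < power < 1).
#' @param expected_fp Acceptable expected number of false positives
#'   (0 < expected_fp < m).
#' @return List with `n_per_group`, `alpha` (the implied per-gene level) and
#'   `delta`.
#' @export
sample_size_efp <- function(m, fold, sigma, power, expected_fp) {
  if (!is_count(m)) stopf("`m` must be a positive integer")
  if (!is_number(fold) || fold <= 1) stopf("`fold` must be > 1")
  if (!is_number(sigma) || sigma <= 0) stopf("`sigma` must be > 0")
  if (!is_number(power) || power <= 0 || power >= 1) stopf("`power` must be in (0, 1)")
  if (!is_number(expected_fp) || expected_fp <= 0 || expected_fp >= m) {
    stopf("`expected_fp` must be in (0, m)")
  }
  alpha <- expected_fp / m
  delta <- log2(fold)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(2 * z^2 * sigma^2 / delta^2)
  list(n_per_group = as.integer(n), alpha = alpha, delta = delta)
}
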