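# Clinical statistics layer: normality-gated two-group comparisons,
# correlations, the logistic-regression optimal cut-off, and harmonic-mean
# summarization of reticular-basement-membrane measurements.

#' Compare a variable between two groups
#'
#' Continuous variables: Shapiro-Wilk normality is checked in each group;
#' if either p-value falls below `normality_alpha` a Mann-Whitney U-test
#' (normal approximation with tie correction, no continuity correction) is
#' used and groups are summarized as median (IQR), otherwise a
#' pooled-variance unpaired t-test with mean +/- SD summaries.  Categorical
#' variables: Pearson chi-squared on the contingency table, without
#' continuity correction by default.
#'
#' @param values_a,values_b Observations per group (continuous), or
#'   category labels (categorical).
#' @param variable_type `"continuous"` or `"categorical"`.
#' @param normality_alpha Shapiro-Wilk gate level (default 0.05).
#' @param variable Optional variable name carried into the result.
#' @param correct Continuity correction for the chi-squared test
#'   (default `FALSE`).
#' @return A `GroupTestResult` list: `variable`, `test`, `statistic`, `p`,
#'   `summary_a`, `summary_b`, `flag`.
#' @export
compare_groups <- function(values_a, values_b,
                           variable_type = c("continuous", "categorical"),
                           normality_alpha = 0.05, variable = "",
                           correct = FALSE) {
  variable_type <- match.arg(variable_type)
  if (variable_type == "categorical") {
    lev <- sort(unique(c(as.character(values_a), as.character(values_b))))
    tab <- rbind(A = table(factor(values_a, levels = lev)),
                 B = table(factor(values_b, levels = lev)))
    if (all(tab[1, ] == tab[2, ])) {
      # identical distributions: chi-squared is exactly 0
      res <- list(statistic = 0, p.value = 1)
    } else {
      res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    }
    fmt <- function(cnt) paste(sprintf("%s:%d", lev, cnt), collapse = " ")
    return(structure(list(variable = variable, test = "chi2",
                          statistic = unname(res$statistic), p = res$p.value,
                          summary_a = fmt(tab[1, ]), summary_b = fmt(tab[2, ]),
                          flag = ""),
                     class = "GroupTestResult"))
  }

  if (length(values_a) < 3L || length(values_b) < 3L) {
    stopf("need >= 3 observations per group")
  }
  sw_p <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_) # Shapiro-Wilk undefined
    stats::shapiro.test(v)$p.value
  }
  pa <- sw_p(values_a); pb <- sw_p(values_b)
  flag <- ""
  if (is.na(pa) || is.na(pb)) {
    normal <- FALSE
    flag <- "constant-input"
  } else {
    normal <- pa >= normality_alpha && pb >= normality_alpha
  }
  if (normal) {
    res <- stats::t.test(values_a, values_b, var.equal = TRUE)
    summ <- function(v) sprintf("%.3g +/- %.3g", mean(v), stats::sd(v))
    test <- "t"
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = FALSE))
    summ <- function(v) sprintf("%.3g (%.3g-%.3g)", stats::median(v),
                                stats::quantile(v, 0.25), stats::quantile(v, 0.75))
    test <- "mann-whitney"
  }
  structure(list(variable = variable, test = test,
                 statistic = unname(res$statistic), p = res$p.value,
                 summary_a = summ(values_a), summary_b = summ(values_b),
                 flag = flag),
            class = "GroupTestResult")
}

#' @export
print.GroupTestResult <- function(x, ...) {
  cat(sprintf("%s [%s] statistic = %.4g, p = %.4g\n  A: %s\n  B: %s\n",
              if (nzchar(x$variable)) x$variable else "(variable)",
              x$test, x$statistic, x$p, x$summary_a, x$summary_b))
  invisible(x)
}

#' Correlation with a t-approximation p-value
#'
#' Pearson's r, or Spearman's rho as Pearson on average ranks; two-sided p
#' from the t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return List `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) stopf("need equal lengths >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance input")
  r <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n, method = method)
}

#' Optimal biomarker cut-off from univariate logistic regression
#'
#' Fits `P(label = 1) = logit^{-1}(b0 + b1 * marker)` by iteratively
#' reweighted least squares and returns the probability-0.5 point
#' `-b0 / b1`.  Under complete separation (non-convergent likelihood) the
#' midpoint between the closest opposing-class values is returned with a
#' `separation` flag.  A Youden-index alternative on the empirical ROC is
#' available via `method = "youden"`.
#'
#' @param marker Numeric biomarker values.
#' @param labels Binary labels (two distinct values; the larger/second
#'   level is the positive class).
#' @param method `"logistic"` (default) or `"youden"`.
#' @return List `cutoff`, `beta0`, `beta1`, `converged`, `flag`.
#' @export
optimal_cutoff <- function(marker, labels, method = c("logistic", "youden")) {
  method <- match.arg(method)
  if (!all(is.finite(marker))) stopf("`marker` must be finite")
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stopf("both classes must be present")

  if (method == "youden") {
    cuts <- sort(unique(marker))
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
    j <- vapply(cuts, function(ct) {
      sens <- mean(marker[y == 1] > ct)
      spec <- mean(marker[y == 0] <= ct)
      sens + spec - 1
    }, numeric(1))
    return(list(cutoff = cuts[which.max(j)], beta0 = NA_real_, beta1 = NA_real_,
                converged = NA, flag = "youden"))
  }

  separable <- max(marker[y == 0]) < min(marker[y == 1]) ||
    max(marker[y == 1]) < min(marker[y == 0])
  fit <- suppressWarnings(
    stats::glm(y ~ marker, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  beta <- unname(stats::coef(fit))
  if (separable || !fit$converged || abs(beta[2]) < 1e-12) {
    # midpoint between the closest opposing-class values
    hi_class <- if (stats::median(marker[y == 1]) >= stats::median(marker[y == 0])) 1L else 0L
    cutoff <- (max(marker[y != hi_class]) + min(marker[y == hi_class])) / 2
    return(list(cutoff = cutoff, beta0 = beta[1], beta1 = beta[2],
                converged = FALSE, flag = "separation"))
  }
  list(cutoff = -beta[1] / beta[2], beta0 = beta[1], beta1 = beta[2],
       converged = TRUE, flag = "")
}

#' Harmonic-mean summary of membrane thickness measurements
#'
#' @param measurements Positive lengths in micrometres; a warning is issued
#'   below the conventional minimum of 30 measurements.
#' @return An `RbmMeasurementSet` list: `measurements`, `n`,
#'   `harmonic_mean`, `arithmetic_mean`.
#' @export
rbm_harmonic_mean <- function(measurements) {
  if (length(measurements) == 0 || any(!is.finite(measurements)) ||
      any(measurements <= 0)) {
    stopf("all measurements must be positive and finite")
  }
  if (length(measurements) < 30L) {
    warnf("only %d measurements; at least 30 are recommended", length(measurements))
  }
  structure(list(measurements = measurements, n = length(measurements),
                 harmonic_mean = length(measurements) / sum(1 / measurements),
                 arithmetic_mean = mean(measurements)),
            class = "RbmMeasurementSet")
}

#' Group-comparison table for a clinical data frame
#'
#' Applies [compare_groups()] to every requested column of a clinical
#' table, mirroring the usual cohort-characteristics layout.
#'
#' @param clinical Data frame with a `condition` column (two levels).
#' @param continuous,categorical Column names to test.
#' @return Data frame: `variable`, `test`, `statistic`, `p`, `summary_a`,
#'   `summary_b`.
#' @export
clinical_comparison_table <- function(clinical,
                                      continuous = character(),
                                      categorical = character()) {
  cond <- as.factor(clinical$condition)
  if (nlevels(cond) != 2L) stopf("`condition` must have exactly 2 levels")
  a <- cond == levels(cond)[1]
  one <- function(nm, type) {
    r <- compare_groups(clinical[[nm]][a], clinical[[nm]][!a],
                        variable_type = type, variable = nm)
    data.frame(variable = nm, test = r$test, statistic = r$statistic,
               p = r$p, summary_a = r$summary_a, summary_b = r$summary_b,
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(continuous, one, type = "continuous"),
            lapply(categorical, one, type = "categorical"))
  do.call(rbind, rows)
}
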