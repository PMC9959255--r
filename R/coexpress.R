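# Differential co-expression by gene-group resampling.
#
# Groups of genes are found by hierarchical clustering on 1 - r distance in
# one condition; each group's coherence in each condition is scored by a
# one-sample t-statistic over its within-group pairwise correlations, and
# the statistic is referred to a null distribution of equally sized gene
# groups resampled from the filtered pool of the same condition.  A group
# that is non-random in the clustering condition (p < alpha) and random in
# the other (p >= alpha) is a differential co-expression group (DCG);
# groups are ranked by the mean pairwise correlation difference.

#' Differential co-expression parameters
#'
#' @param cluster_condition Condition in which genes are clustered
#'   (default `"EA"`).
#' @param linkage `"average"` or `"complete"` agglomeration.
#' @param cut_height Tree cut height on the `1 - r` distance scale, in
#'   (0, 2); default 0.6 (mean within-cluster correlation of roughly 0.4 or
#'   more).
#' @param min_group Minimum group size (>= 3, so that a group has at least
#'   three pairwise correlations).
#' @param n_resamples Number of resampled null groups per test (>= 100).
#' @param alpha Significance level of the decision rule (default 0.05).
#' @param fisher_z If `TRUE`, correlations are Fisher z-transformed before
#'   the t-statistic; the default keeps the plain r scale.
#' @param seed Integer seed for the resampling stream.
#' @return A `CoexParams` list.
#' @export
coex_params <- function(cluster_condition = "EA",
                        linkage = c("average", "complete"),
                        cut_height = 0.6, min_group = 3L,
                        n_resamples = 1000L, alpha = 0.05,
                        fisher_z = FALSE, seed = 1L) {
  linkage <- match.arg(linkage)
  if (!is_number(cut_height) || cut_height <= 0 || cut_height >= 2) {
    stopf("`cut_height` must lie in (0, 2)")
  }
  if (!is_count(min_group, 3L)) stopf("`min_group` must be >= 3")
  if (!is_count(n_resamples, 100L)) stopf("`n_resamples` must be >= 100")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  structure(list(cluster_condition = cluster_condition, linkage = linkage,
                 cut_height = cut_height, min_group = as.integer(min_group),
                 n_resamples = as.integer(n_resamples), alpha = alpha,
                 fisher_z = isTRUE(fisher_z), seed = as.integer(seed)),
            class = "CoexParams")
}

# rows centered and scaled to unit norm, so tcrossprod gives Pearson r
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  d <- x - mu
  nrm <- sqrt(rowSums(d^2))
  zero <- nrm == 0
  if (any(zero)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(which(zero))
    stopf("zero-variance gene(s): %s",
          paste(utils::head(ids[zero], 5L), collapse = ", "))
  }
  d / nrm
}

#' Pairwise Pearson correlations of a gene block
#'
#' @param sub_matrix Numeric matrix, genes in rows (>= 2), samples in
#'   columns (>= 3).
#' @return Correlations of all unordered gene pairs in row-major order:
#'   (1,2), (1,3), ..., (2,3), ...
#' @export
pairwise_correlations <- function(sub_matrix) {
  if (nrow(sub_matrix) < 2L || ncol(sub_matrix) < 3L) {
    stopf("need >= 2 genes and >= 3 samples")
  }
  z <- standardize_rows(sub_matrix)
  r <- tcrossprod(z)
  r[lower.tri(r)]
}

#' One-sample t-statistic of a correlation set
#'
#' `t = mean(r) / (sd(r) / sqrt(n))`.  When the correlations have zero
#' spread the statistic is `+Inf`, `-Inf` or `0` according to the sign of
#' the mean.
#'
#' @param correlations Numeric vector of >= 3 pairwise correlations.
#' @return The t-statistic.
#' @export
group_statistic <- function(correlations) {
  n <- length(correlations)
  if (n < 3L) stopf("need >= 3 correlations, got %d", n)
  m <- mean(correlations)
  s <- stats::sd(correlations)
  if (s == 0) return(if (m > 0) Inf else if (m < 0) -Inf else 0)
  m / (s / sqrt(n))
}

#' Cluster genes by correlation in one condition
#'
#' Agglomerative clustering on `1 - r` distance, tree cut at
#' `params$cut_height`; groups smaller than `params$min_group` are
#' discarded.  Output is deterministic given the input row order: groups
#' are ordered by their smallest gene index.
#'
#' @param x Numeric matrix of the clustering condition (genes x samples).
#' @param params A [coex_params()].
#' @return List of character vectors of gene ids.
#' @export
cluster_genes <- function(x, params = coex_params()) {
  if (nrow(x) < params$min_group) stopf("fewer than min_group genes")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  z <- standardize_rows(x)
  d <- stats::as.dist(1 - tcrossprod(z))
  hc <- stats::hclust(d, method = params$linkage)
  cl <- stats::cutree(hc, h = params$cut_height)
  groups <- split(seq_along(cl), cl)
  groups <- groups[vapply(groups, length, integer(1)) >= params$min_group]
  groups <- groups[order(vapply(groups, min, integer(1)))]
  unname(lapply(groups, function(i) ids[i]))
}

#' Resampling p-value for a group coherence statistic
#'
#' Draws `B` uniform random gene sets of the same size from the filtered
#' pool of one condition, recomputes the coherence t-statistic for each,
#' and returns the one-sided exceedance probability with the add-one
#' estimator `p = (1 + #\{t_null >= t_obs\}) / (B + 1)`.
#'
#' @param x Condition matrix (genes x samples), the resampling pool.
#' @param group_size Size of the tested group.
#' @param observed_t Observed t-statistic.
#' @param B Number of resamples.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [differential_coexpression()]).
#' @param fisher_z Apply Fisher's z to correlations before the statistic.
#' @return The resampling p-value, in `(0, 1]`.
#' @export
resample_null_p <- function(x, group_size, observed_t, B = 1000L, seed = NULL,
                            fisher_z = FALSE) {
  n_genes <- nrow(x)
  if (n_genes < 2L * group_size) {
    stopf("resampling pool too small: %d genes for group size %d", n_genes, group_size)
  }
  z <- standardize_rows(x)
  draw <- function() {
    idx <- sample.int(n_genes, group_size)
    r <- tcrossprod(z[idx, , drop = FALSE])
    r <- r[lower.tri(r)]
    if (fisher_z) r <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    group_statistic(r)
  }
  run <- function() {
    t_null <- vapply(seq_len(B), function(i) draw(), numeric(1))
    (1 + sum(t_null >= observed_t)) / (B + 1)
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

# score one gene group in both conditions; draws from the current RNG stream
score_group <- function(genes, z_by_cond, params) {
  k <- length(genes)
  rs <- lapply(z_by_cond, function(z) {
    r <- tcrossprod(z[genes, , drop = FALSE])
    r[lower.tri(r)]
  })
  tr <- function(r) if (params$fisher_z)
    atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) else r
  tt <- vapply(rs, function(r) group_statistic(tr(r)), numeric(1))
  pp <- vapply(names(z_by_cond), function(cond) {
    z <- z_by_cond[[cond]]
    n_genes <- nrow(z)
    t_null <- vapply(seq_len(params$n_resamples), function(i) {
      idx <- sample.int(n_genes, k)
      r <- tcrossprod(z[idx, , drop = FALSE])
      group_statistic(tr(r[lower.tri(r)]))
    }, numeric(1))
    (1 + sum(t_null >= tt[[cond]])) / (params$n_resamples + 1)
  }, numeric(1))
  conds <- names(z_by_cond)
  other <- setdiff(conds, params$cluster_condition)
  mean_dr <- mean(rs[[params$cluster_condition]] - rs[[other]])
  list(genes = genes, t = tt, p = pp, mean_dr = mean_dr,
       is_dcg = unname(pp[params$cluster_condition] < params$alpha &
                         pp[other] >= params$alpha))
}

#' Evaluate given gene groups for differential co-expression
#'
#' Scores each supplied group in both conditions (t-statistic and
#' resampling p-value, nulls drawn from the same condition's matrix),
#' applies the DCG decision rule and computes the mean pairwise correlation
#' difference.  Used by [differential_coexpression()] after clustering, and
#' directly for calibration studies on externally defined groups.
#'
#' @param dataset A two-condition [expression_dataset()] (log2 scale).
#' @param groups List of character vectors of gene ids.
#' @param params A [coex_params()].
#' @return A `CoexResult`: list with `table` (one row per group) and
#'   `groups` (gene-id lists), ranked by `mean_dr` descending, ties broken
#'   by larger size then lexicographic gene ids.
#' @export
evaluate_groups <- function(dataset, groups, params = coex_params()) {
  stopifnot(inherits(dataset, "ExpressionDataset"), inherits(params, "CoexParams"))
  conds <- levels(dataset$samples$condition)
  if (length(conds) != 2L) stopf("dataset must have exactly 2 conditions")
  if (!params$cluster_condition %in% conds) {
    stopf("cluster_condition '%s' not among conditions %s",
          params$cluster_condition, paste(conds, collapse = ", "))
  }
  z_by_cond <- lapply(stats::setNames(conds, conds), function(cond) {
    standardize_rows(dataset$exprs[, dataset$samples$condition == cond, drop = FALSE])
  })
  local_seed(params$seed, {
    scored <- lapply(groups, score_group, z_by_cond = z_by_cond, params = params)
    finalize_coex(scored, conds, params)
  })
}

finalize_coex <- function(scored, conds, params) {
  if (length(scored) == 0L) {
    tab <- data.frame(group_id = integer(0), size = integer(0),
                      t_A = numeric(0), t_B = numeric(0),
                      p_A = numeric(0), p_B = numeric(0),
                      mean_dr = numeric(0), is_dcg = logical(0),
                      genes = character(0))
    names(tab)[3:6] <- c(paste0("t_", conds), paste0("p_", conds))
    return(structure(list(table = tab, groups = list(), params = params),
                     class = "CoexResult"))
  }
  key <- vapply(scored, function(s)
    paste(sort(s$genes), collapse = ";"), character(1))
  ord <- order(-vapply(scored, `[[`, numeric(1), "mean_dr"),
               -vapply(scored, function(s) length(s$genes), integer(1)),
               key)
  scored <- scored[ord]
  tab <- data.frame(
    group_id = seq_along(scored),
    size = vapply(scored, function(s) length(s$genes), integer(1)),
    t_A = vapply(scored, function(s) unname(s$t[conds[1]]), numeric(1)),
    t_B = vapply(scored, function(s) unname(s$t[conds[2]]), numeric(1)),
    p_A = vapply(scored, function(s) unname(s$p[conds[1]]), numeric(1)),
    p_B = vapply(scored, function(s) unname(s$p[conds[2]]), numeric(1)),
    mean_dr = vapply(scored, `[[`, numeric(1), "mean_dr"),
    is_dcg = vapply(scored, `[[`, logical(1), "is_dcg"),
    genes = key[ord],
    stringsAsFactors = FALSE)
  names(tab)[3:6] <- c(paste0("t_", conds), paste0("p_", conds))
  structure(list(table = tab, groups = lapply(scored, `[[`, "genes"),
                 params = params),
            class = "CoexResult")
}

#' @export
print.CoexResult <- function(x, ...) {
  cat(sprintf("CoexResult: %d group(s), %d flagged DCG\n",
              nrow(x$table), sum(x$table$is_dcg)))
  print(utils::head(x$table[, setdiff(names(x$table), "genes")], 10))
  invisible(x)
}

#' Differential co-expression analysis of a two-condition dataset
#'
#' Clusters genes in the configured condition, scores every retained group
#' in both conditions and returns the ranked group table (see
#' [evaluate_groups()] for the scoring and ranking rules).
#'
#' @param dataset A two-condition [expression_dataset()] (log2 scale,
#'   already preprocessed).
#' @param params A [coex_params()].
#' @return A `CoexResult`.
#' @export
differential_coexpression <- function(dataset, params = coex_params()) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  x_cluster <- dataset$exprs[, dataset$samples$condition == params$cluster_condition,
                             drop = FALSE]
  if (ncol(x_cluster) == 0) {
    stopf("no samples in cluster condition '%s'", params$cluster_condition)
  }
  groups <- cluster_genes(x_cluster, params)
  evaluate_groups(dataset, groups, params)
}
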