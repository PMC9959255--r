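two_cond_dataset <- function(x_ea, x_nea) {
  x <- cbind(x_ea, x_nea)
  colnames(x) <- c(paste0("EA", seq_len(ncol(x_ea))),
                   paste0("NEA", seq_len(ncol(x_nea))))
  expression_dataset(x, data.frame(
    condition = factor(rep(c("EA", "NEA"), c(ncol(x_ea), ncol(x_nea))),
                       levels = c("EA", "NEA")),
    row.names = colnames(x)))
}

test_that("pairwise correlations: sign cases and direct-formula oracle", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(pairwise_correlations(x), 1.0)
  x2 <- rbind(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4))
  expect_equal(pairwise_correlations(x2), -1.0)
  set.seed(1)
  x3 <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  r <- pairwise_correlations(x3)
  direct <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(r, c(direct(x3[1, ], x3[2, ]), direct(x3[1, ], x3[3, ]),
                    direct(x3[2, ], x3[3, ])), tolerance = 1e-12)
  expect_error(pairwise_correlations(rbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("group statistic: arithmetic and degenerate sentinels", {
  expect_equal(group_statistic(c(0.8, 0.6, 0.7)), 0.7 / (0.1 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(group_statistic(c(0, 0, 0)), 0)
  expect_equal(group_statistic(c(0.5, 0.5, 0.5)), Inf)
  expect_equal(group_statistic(c(-0.5, -0.5, -0.5)), -Inf)
  expect_error(group_statistic(c(0.5, 0.6)), ">= 3")
})

test_that("clustering recovers perfect blocks and discards singletons", {
  set.seed(2)
  base1 <- rnorm(10); base2 <- rnorm(10)
  x <- rbind(a1 = base1, a2 = base1 * 2 + 3, a3 = base1 - 1,
             b1 = base2, b2 = base2 * 0.5, b3 = base2 + 2)
  g <- cluster_genes(x, coex_params(cut_height = 0.6))
  expect_equal(g, list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  # mutually uncorrelated genes: no group survives
  set.seed(3)
  y <- matrix(rnorm(20 * 100), 20, 100)
  rownames(y) <- paste0("g", 1:20)
  expect_length(cluster_genes(y, coex_params(cut_height = 0.1)), 0)
})

test_that("clustering finds a planted module among null genes", {
  sim <- simulate_expression(
    sim_config(530, modules = list(module_spec(30, 0.7, 0)), seed = 7))
  x_ea <- sim$dataset$exprs[, sim$dataset$samples$condition == "EA"]
  groups <- cluster_genes(x_ea, coex_params())
  truth <- names(sim$truth$module_membership)
  jac <- vapply(groups, function(g)
    length(intersect(g, truth)) / length(union(g, truth)), numeric(1))
  expect_gte(max(jac), 0.8)
})

test_that("resampling p-value: sentinels and null uniformity", {
  set.seed(4)
  x <- matrix(rnorm(60 * 12), 60, 12)
  rownames(x) <- paste0("g", 1:60)
  expect_equal(resample_null_p(x, 5, Inf, B = 199, seed = 1), 1 / 200)
  expect_equal(resample_null_p(x, 5, -Inf, B = 199, seed = 1), 1)
  expect_error(resample_null_p(x, 40, 1, B = 100, seed = 1), "pool too small")
  # on independent data, p for random groups is approximately uniform
  set.seed(5)
  pool <- matrix(rnorm(200 * 20), 200, 20)
  rownames(pool) <- paste0("g", 1:200)
  ps <- vapply(1:200, function(i) {
    idx <- sample(200, 5)
    t_obs <- group_statistic(pairwise_correlations(pool[idx, ]))
    resample_null_p(pool, 5, t_obs, B = 500)
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.02)
  expect_lte(mean(ps < 0.05), 0.09)
})

test_that("DCG decision rule and ranking behave per contract", {
  sim <- simulate_expression(
    sim_config(200, modules = list(module_spec(10, 0.7, 0),
                                   module_spec(10, 0.7, 0.7)), seed = 9))
  res <- differential_coexpression(sim$dataset,
                                   coex_params(n_resamples = 200, seed = 9))
  tab <- res$table
  # flag always equals the rule recomputed from stored p-values
  expect_equal(tab$is_dcg, tab$p_EA < 0.05 & tab$p_NEA >= 0.05)
  # the rho_EA = rho_NEA module must not be a DCG (coherent in both)
  both <- names(sim$truth$module_membership)[sim$truth$module_membership == 2]
  hit2 <- which(vapply(res$groups, function(g)
    length(intersect(g, both)) / length(union(g, both)) >= 0.8, logical(1)))
  expect_true(length(hit2) >= 1 && !any(tab$is_dcg[hit2]))
  # the differential module is a DCG
  diffm <- names(sim$truth$module_membership)[sim$truth$module_membership == 1]
  hit1 <- which(vapply(res$groups, function(g)
    length(intersect(g, diffm)) / length(union(g, diffm)) >= 0.8, logical(1)))
  expect_true(length(hit1) >= 1 && any(tab$is_dcg[hit1]))
  # ranking is by mean_dr descending
  expect_true(all(diff(tab$mean_dr) <= 1e-12))
  # determinism
  res2 <- differential_coexpression(sim$dataset,
                                    coex_params(n_resamples = 200, seed = 9))
  expect_identical(res$table, res2$table)
})

test_that("swapping condition labels swaps statistics and verdict", {
  sim <- simulate_expression(
    sim_config(200, modules = list(module_spec(10, 0.7, 0)), seed = 10))
  ds <- sim$dataset
  swapped <- ds
  swapped$samples$condition <- factor(
    ifelse(ds$samples$condition == "EA", "NEA", "EA"), levels = c("EA", "NEA"))
  p <- coex_params(n_resamples = 200, seed = 10)
  module <- list(names(sim$truth$module_membership))
  res <- evaluate_groups(ds, module, p)
  res_sw <- evaluate_groups(swapped, module, p)
  # deterministic quantities swap exactly
  expect_equal(res$table$t_EA, res_sw$table$t_NEA, tolerance = 1e-12)
  expect_equal(res$table$t_NEA, res_sw$table$t_EA, tolerance = 1e-12)
  expect_equal(res$table$mean_dr, -res_sw$table$mean_dr, tolerance = 1e-12)
  # the module is coherent in the original EA labels only
  expect_true(res$table$is_dcg)
  expect_false(res_sw$table$is_dcg)
})

test_that("mean_dr is zero when both condition matrices are identical", {
  set.seed(11)
  x <- matrix(rnorm(40 * 8), 40, 8)
  rownames(x) <- paste0("g", 1:40)
  ds <- two_cond_dataset(x, x)
  res <- evaluate_groups(ds, list(paste0("g", 1:5), paste0("g", 10:15)),
                         coex_params(n_resamples = 100, seed = 2))
  expect_equal(res$table$mean_dr, c(0, 0), tolerance = 1e-12)
  expect_false(any(res$table$is_dcg))
})
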