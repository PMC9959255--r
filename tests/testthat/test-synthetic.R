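test_that("simulator is deterministic and respects its invariants", {
  cfg <- sim_config(200, n_per_group = 10, de_fraction = 0.1,
                    modules = list(module_spec(10, 0.5, 0.1)), seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$dataset$exprs, b$dataset$exprs)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  # DE genes and module genes are disjoint
  expect_length(intersect(names(a$truth$de_genes),
                          names(a$truth$module_membership)), 0)
  expect_equal(dim(a$dataset$exprs), c(200, 20))
})

test_that("planted module correlation matches the factor-model closed form", {
  cfg <- sim_config(1000, modules = list(module_spec(30, 0.7, 0)), seed = 7)
  sim <- simulate_expression(cfg)
  ids <- names(sim$truth$module_membership)
  ea <- sim$dataset$exprs[ids, sim$dataset$samples$condition == "EA"]
  nea <- sim$dataset$exprs[ids, sim$dataset$samples$condition == "NEA"]
  r_ea <- mean(pairwise_correlations(ea))
  r_nea <- mean(pairwise_correlations(nea))
  expect_lt(abs(r_ea - 0.7), 0.1)   # n = 20 sampling error band
  expect_lt(abs(r_nea), 0.1)
})

test_that("null configuration has no planted structure", {
  cfg <- sim_config(300, n_per_group = 10, seed = 5)
  sim <- simulate_expression(cfg)
  expect_length(sim$truth$de_genes, 0)
  grp <- sim$dataset$samples$condition
  diffs <- rowMeans(sim$dataset$exprs[, grp == "EA"]) -
    rowMeans(sim$dataset$exprs[, grp == "NEA"])
  expect_lt(abs(mean(diffs)), 3 * 0.7 * sqrt(2 / 10) / sqrt(300))
})

test_that("DE genes carry the planted effect at the expected z-scale", {
  # E[z] = delta / (sigma * sqrt(2/n)) = 1 / (0.7 * sqrt(0.1)) = 4.52
  cfg <- sim_config(2000, de_fraction = 0.1, seed = 11)
  sim <- simulate_expression(cfg)
  grp <- sim$dataset$samples$condition
  d <- rowMeans(sim$dataset$exprs[, grp == "EA"]) -
    rowMeans(sim$dataset$exprs[, grp == "NEA"])
  z <- d[names(sim$truth$de_genes)] / (0.7 * sqrt(2 / 20))
  expect_lt(abs(mean(z) - 1 / (0.7 * sqrt(2 / 20))), 3 / sqrt(length(z)))
})

test_that("covariate effects shift expression linearly", {
  cfg0 <- sim_config(50, n_per_group = 5, seed = 9)
  cfg1 <- sim_config(50, n_per_group = 5, seed = 9,
                     covariate_effects = c(age = 0.02))
  x0 <- simulate_expression(cfg0)
  x1 <- simulate_expression(cfg1)
  shift <- x1$dataset$exprs - x0$dataset$exprs
  expect_equal(unname(shift[1, ]), 0.02 * x0$dataset$samples$age,
               tolerance = 1e-12)
})

test_that("sim_config rejects invalid inputs", {
  expect_error(sim_config(10, n_per_group = 1), "n_per_group")
  expect_error(sim_config(10, de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(10, gene_sd = 0), "gene_sd")
  expect_error(module_spec(2, 0.5, 0.1), ">= 3")
  expect_error(module_spec(5, 1.0, 0.1), "rho")
  expect_error(simulate_expression(
    sim_config(5, modules = list(module_spec(10, 0.5, 0)))), "exceed")
})

test_that("clinical table obeys the phenotype constraints", {
  tab <- simulate_clinical_table(20, seed = 1)
  expect_identical(tab, simulate_clinical_table(20, seed = 1))
  expect_true(all(tab$bal_eos_pct[tab$condition == "EA"] >= 1))
  expect_true(all(tab$bal_eos_pct[tab$condition == "NEA"] < 1))
  big <- simulate_clinical_table(1000, seed = 3)
  expect_gt(median(big$blood_eos[big$condition == "EA"]),
            median(big$blood_eos[big$condition == "NEA"]))
})

test_that("scan truth is consistent and rendering is exact where stated", {
  d <- demo_scan()
  tr <- d$scan$truth
  expect_equal(nrow(tr$spots), d$layout$rows * d$layout$cols)
  expect_true(all(tr$spots$x >= 1 & tr$spots$x <= ncol(d$scan$image)))
  expect_true(all(tr$spots$y >= 1 & tr$spots$y <= nrow(d$scan$image)))
  # identity displacement, no noise: per-spot argmax within 1 px of center
  img <- d$scan$image
  for (i in seq_len(nrow(tr$spots))) {
    x0 <- tr$spots$x[i]; y0 <- tr$spots$y[i]
    win <- img[(round(y0) - 3):(round(y0) + 3), (round(x0) - 3):(round(x0) + 3)]
    am <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(am - 4)), 1.5)
  }
  # pure translation moves all true centers by exactly (dx, dy)
  d2 <- demo_scan(displacement = affine_params(dx = 3.2, dy = -2.7))
  expect_equal(d2$scan$truth$spots$x, tr$spots$x + 3.2, tolerance = 1e-9)
  expect_equal(d2$scan$truth$spots$y, tr$spots$y - 2.7, tolerance = 1e-9)
})

test_that("scan background level matches the configured baseline under noise", {
  lay <- grid_layout(3, 3)
  I <- matrix(20000, 3, 3)
  sc <- simulate_array_scan(lay, I, noise_sd = 0.05 * 65535, seed = 11,
                            baseline = 1000)
  img <- sc$image
  # canvas corners are far from any spot or marker; at this noise level the
  # zero clip shifts the background mean, so the Monte-Carlo reference is
  # the clipped-noise expectation, not the raw baseline
  h <- nrow(img); w <- ncol(img)
  bgpx <- c(img[1:8, 1:8], img[1:8, (w - 7):w],
            img[(h - 7):h, 1:8], img[(h - 7):h, (w - 7):w])
  set.seed(99)
  expected <- mean(pmin(pmax(stats::rnorm(2e5, 1000, 0.05 * 65535), 0), 65535))
  expect_lt(abs(mean(bgpx) - expected) / 65535, 0.02)
})

test_that("off-canvas spots are an error", {
  lay <- grid_layout(3, 3)
  I <- matrix(1000, 3, 3)
  expect_error(simulate_array_scan(lay, I, affine_params(dx = 1000)),
               "outside the canvas")
})

test_that("PGM round trip is exact", {
  d <- demo_scan(rows = 2, cols = 2)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(d$scan$image, path)
  back <- read_pgm(path)
  expect_equal(back, round(d$scan$image))
})
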