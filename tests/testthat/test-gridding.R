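test_that("noise-free markers are detected exactly (count and position)", {
  # markers-only scan (zero spot amplitudes): exactly the four markers
  lay <- grid_layout(4, 4)
  sc <- simulate_array_scan(lay, matrix(0, 4, 4))
  mk <- detect_markers(sc$image, marker_mser_params(lay))
  expect_equal(nrow(mk), 4)
  tr <- sc$truth$markers
  for (i in seq_len(4)) {
    err <- min(sqrt((mk$x - tr$x[i])^2 + (mk$y - tr$y[i])^2))
    expect_lt(err, 0.5)
  }
})

test_that("uniform image yields no regions; empty image errors", {
  expect_equal(nrow(detect_markers(matrix(500, 40, 40),
                                   mser_params(10, 200))), 0)
  expect_error(detect_markers(matrix(numeric(0), 0, 0), mser_params(10, 200)),
               "non-empty")
})

test_that("noisy markers: the four most stable regions match truth anchors", {
  d <- demo_scan(noise_sd = 0.05 * 65535, seed = 11)
  mk <- detect_markers(d$scan$image, marker_mser_params(d$layout))
  expect_gte(nrow(mk), 4)
  top4 <- mk[1:4, ]
  tr <- d$scan$truth$markers
  for (i in seq_len(4)) {
    err <- min(sqrt((top4$x - tr$x[i])^2 + (top4$y - tr$y[i])^2))
    expect_lt(err, 2)
  }
})

test_that("MSER agrees with the brute-force component-tree oracle", {
  # several small images: a rendered mini-scan and random blob fields
  lay <- grid_layout(2, 2, pitch = 12, spot_radius = 2, marker_radius = 4,
                     margin = 10)
  sc <- simulate_array_scan(lay, matrix(20000, 2, 2), noise_sd = 2000, seed = 3)
  imgs <- list(sc$image)  # 56 x 56
  set.seed(21)
  for (k in 1:3) {
    img <- matrix(500, 48, 48)
    for (b in 1:3) {
      cx <- runif(1, 10, 38); cy <- runif(1, 10, 38)
      d2 <- outer((1:48 - cy)^2, (1:48 - cx)^2, `+`)
      img <- img + 40000 * (d2 <= runif(1, 9, 25))
    }
    img <- pmin(img + matrix(rnorm(48 * 48, 0, 1500), 48, 48), 65535)
    imgs[[k + 1]] <- pmax(img, 0)
  }
  for (img in imgs) {
    p <- mser_params(min_area = 20, max_area = 150, delta = 2,
                     max_stability = 0.5)
    got <- detect_markers(img, p)
    want <- oracle_mser(img, 2, 20, 150, 0.5)
    want <- want[order(want$stability, -want$area), , drop = FALSE]
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      o1 <- order(got$x, got$y); o2 <- order(want$x, want$y)
      expect_equal(got$stability[o1], want$stability[o2], tolerance = 1e-12)
      expect_equal(got$area[o1], want$area[o2])
      expect_equal(got$x[o1], want$x[o2], tolerance = 1e-9)
      expect_equal(got$y[o1], want$y[o2], tolerance = 1e-9)
    }
  }
})

test_that("detection is equivariant under integer translation", {
  d <- demo_scan(rows = 2, cols = 2)
  img <- d$scan$image
  dx <- 7L; dy <- 4L
  big <- matrix(img[1, 1], nrow(img) + dy, ncol(img) + dx)
  big[(dy + 1):(dy + nrow(img)), (dx + 1):(dx + ncol(img))] <- img
  p <- marker_mser_params(d$layout)
  a <- detect_markers(img, p)
  b <- detect_markers(big, p)
  expect_equal(nrow(a), nrow(b))
  oa <- order(a$x, a$y); ob <- order(b$x, b$y)
  expect_equal(b$x[ob], a$x[oa] + dx, tolerance = 1e-9)
  expect_equal(b$y[ob], a$y[oa] + dy, tolerance = 1e-9)
})

test_that("exact affine recovery from exact marker positions", {
  lay <- grid_layout(5, 5)
  anchors <- dcx:::lattice_to_px(lay, lay$marker_anchors[, "row"],
                                 lay$marker_anchors[, "col"])
  aff_true <- affine_params(dx = 3.2, dy = -2.7)
  mk <- as.data.frame(dcx:::apply_affine(aff_true, anchors))
  g <- fit_grid(mk, lay)
  expect_lt(g$residual_rms, 1e-6)
  expect_equal(unname(g$affine), unname(aff_true), tolerance = 1e-9)
  # identity
  g0 <- fit_grid(as.data.frame(anchors), lay)
  expect_equal(unname(g0$affine), unname(affine_params()), tolerance = 1e-9)
  expect_lt(g0$residual_rms, 1e-9)
})

test_that("fit_grid handles noise, rejects degenerate inputs", {
  lay <- grid_layout(5, 5)
  anchors <- dcx:::lattice_to_px(lay, lay$marker_anchors[, "row"],
                                 lay$marker_anchors[, "col"])
  set.seed(5)
  mk <- as.data.frame(anchors + matrix(rnorm(8, 0, 0.5), ncol = 2))
  names(mk) <- c("x", "y")
  g <- fit_grid(mk, lay)
  expect_lt(g$residual_rms, 1)
  # each affine parameter within 3 standard errors of the identity truth
  # (least-squares sampling distribution with sigma = 0.5 per coordinate)
  X <- cbind(anchors[, 1], anchors[, 2], 1)
  se <- 0.5 * sqrt(diag(solve(crossprod(X))))
  truth <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_true(all(abs(g$affine - truth) <= 3 * rbind(se, se)))
  expect_error(fit_grid(mk[1:2, ], lay), "at least 3")
})

test_that("quantified signal tracks planted intensities", {
  d <- demo_scan(rows = 6, cols = 6,
                 displacement = affine_params(dx = 2, dy = -1, rotate_deg = 0.5))
  res <- grid_scan(d$scan$image, d$layout)
  expect_gte(cor(res$quant$signal, d$scan$truth$spots$intensity), 0.99)
  expect_true(all(res$quant$flag == "ok"))
  # blank image: all signals 0
  lay <- d$layout
  blank <- matrix(100, nrow(d$scan$image), ncol(d$scan$image))
  g <- res$grid
  q <- quantify_spots(blank, g, lay)
  expect_true(all(q$signal == 0))
})

test_that("spots at the canvas edge are flagged clipped", {
  d <- demo_scan(rows = 3, cols = 3)
  g <- grid_scan(d$scan$image, d$layout)$grid
  g$spot_centers$x[1] <- 1.5  # push one fitted center to the border
  q <- quantify_spots(d$scan$image, g, d$layout)
  expect_equal(q$flag[1], "clipped")
})

test_that("marker localization error grows with noise", {
  err_at <- function(noise) {
    errs <- vapply(1:3, function(s) {
      d <- demo_scan(noise_sd = noise, seed = s, rows = 3, cols = 3)
      mk <- detect_markers(d$scan$image, marker_mser_params(d$layout))[1:4, ]
      tr <- d$scan$truth$markers
      mean(vapply(seq_len(4), function(i)
        min(sqrt((mk$x - tr$x[i])^2 + (mk$y - tr$y[i])^2)), numeric(1)))
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(0), err_at(2000), err_at(6000))
  expect_true(all(diff(e) >= -1e-9))
})
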