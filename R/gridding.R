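# Array gridding: MSER marker detection, affine grid fitting, spot
# quantification.

#' MSER detector parameters
#'
#' @param min_area,max_area Admissible region area in pixels squared.
#' @param delta Threshold step (on the 0..255 quantized scale; images are
#'   quantized from the 16-bit range by a fixed factor of 257).
#' @param max_stability Maximum admissible relative area change per
#'   `2*delta` levels.
#' @param polarity `"bright"` (bright regions on dark background, the
#'   fluorescence-scan default) or `"dark"`.
#' @return An `MserParams` list.
#' @export
mser_params <- function(min_area, max_area, delta = 2L, max_stability = 0.5,
                        polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is_count(delta)) stopf("`delta` must be a positive integer")
  if (!is_number(min_area) || !is_number(max_area) || min_area <= 0 ||
      max_area <= min_area) {
    stopf("need 0 < min_area < max_area")
  }
  structure(list(delta = as.integer(delta), min_area = min_area,
                 max_area = max_area, max_stability = max_stability,
                 polarity = polarity),
            class = "MserParams")
}

#' Default MSER parameters for a layout's positioning markers
#'
#' Area band centred on the marker disc area: `0.5 * pi * r^2` to
#' `2 * pi * r^2`.
#'
#' @param layout A [grid_layout()].
#' @inheritParams mser_params
#' @return An `MserParams` list.
#' @export
marker_mser_params <- function(layout, delta = 2L, max_stability = 0.5) {
  r <- layout$marker_radius
  mser_params(min_area = 0.5 * pi * r^2, max_area = 2 * pi * r^2,
              delta = delta, max_stability = max_stability)
}

#' Detect positioning markers by maximally stable extremal regions
#'
#' Connected extremal regions are tracked across an intensity-threshold
#' sweep; a region is reported at its branch's most stable level when the
#' relative area change over `2*delta` levels is below `max_stability` and
#' its area lies within the configured band.  Nested duplicates collapse to
#' the most stable region.  Centroids are intensity-weighted and sub-pixel.
#'
#' @param image Numeric matrix (grayscale, 16-bit scale).
#' @param params An [mser_params()].
#' @return Data frame with columns `x`, `y` (sub-pixel centroid), `area`,
#'   `stability`, `level`, sorted by increasing stability (most stable
#'   first).  Empty (zero rows) when no region qualifies.
#' @export
detect_markers <- function(image, params) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0) {
    stopf("`image` must be a non-empty numeric matrix")
  }
  stopifnot(inherits(params, "MserParams"))
  out <- .mser_detect_cpp(image, params$delta, params$min_area,
                          params$max_area, params$max_stability,
                          params$polarity == "bright")
  out[order(out$stability, -out$area), , drop = FALSE]
}

# least-squares affine mapping nominal (x, y) -> observed (x, y);
# returns list(affine 2x3, residual_rms) or NULL on singular fit
fit_affine_ls <- function(nominal, observed) {
  X <- cbind(nominal[, 1], nominal[, 2], 1)
  qx <- qr(X)
  if (qx$rank < 3L) return(NULL)
  bx <- qr.coef(qx, observed[, 1])
  by <- qr.coef(qx, observed[, 2])
  aff <- rbind(x = bx, y = by)
  colnames(aff) <- c("a", "b", "t")
  pred <- apply_affine(aff, nominal)
  res <- observed - pred
  list(affine = aff, residual_rms = sqrt(mean(rowSums(res^2))))
}

#' Fit the spot grid from detected markers
#'
#' Estimates the affine map from the nominal marker anchor positions to the
#' detected marker centroids by least squares.  With at most eight detected
#' markers the marker-to-anchor correspondence is found by exhaustive
#' assignment minimizing the residual; with more, markers are pre-aligned to
#' the anchors by a centroid-and-scale similarity and matched to their
#' nearest anchor.
#'
#' @param markers Data frame with columns `x`, `y` (from
#'   [detect_markers()] or a manual override table).
#' @param layout A [grid_layout()].
#' @return A `SpotGrid`: list with `affine` (2x3), `spot_centers` (data
#'   frame `row`, `col`, `x`, `y`), `residual_rms`, `markers_used`.
#' @export
fit_grid <- function(markers, layout) {
  stopifnot(inherits(layout, "GridLayout"))
  markers <- as.data.frame(markers)
  n_m <- nrow(markers)
  if (n_m < 3L) stopf("need at least 3 markers, got %d", n_m)
  anchors_px <- lattice_to_px(layout, layout$marker_anchors[, "row"],
                              layout$marker_anchors[, "col"])
  n_a <- nrow(anchors_px)
  obs <- cbind(markers$x, markers$y)

  best <- NULL
  if (n_m <= 8L) {
    k <- min(n_a, n_m)
    anchor_sets <- utils::combn(n_a, k, simplify = FALSE)
    marker_sets <- utils::combn(n_m, k, simplify = FALSE)
    perms <- permutations_of(k)
    # a symmetric anchor layout (four corners of a square) admits rotated
    # correspondences with identical residual; ties are broken towards the
    # affine closest to the identity, i.e. a roughly upright scan
    deviation <- function(aff) sqrt(sum((aff[, 1:2] - diag(2))^2))
    for (aset in anchor_sets) {
      for (mset in marker_sets) {
        for (p in seq_len(nrow(perms))) {
          midx <- mset[perms[p, ]]
          fit <- fit_affine_ls(anchors_px[aset, , drop = FALSE],
                               obs[midx, , drop = FALSE])
          if (is.null(fit)) next
          fit$dev <- deviation(fit$affine)
          if (is.null(best) ||
              fit$residual_rms < best$residual_rms - 1e-6 ||
              (abs(fit$residual_rms - best$residual_rms) <= 1e-6 &&
                 fit$dev < best$dev)) {
            best <- c(fit, list(anchor_idx = aset, marker_idx = midx))
          }
        }
      }
    }
    if (is.null(best)) stopf("collinear marker anchors: affine fit is singular")
  } else {
    # similarity pre-alignment, then nearest-neighbour assignment
    ca <- colMeans(anchors_px)
    cm <- colMeans(obs)
    sa <- sqrt(mean(rowSums(sweep(anchors_px, 2, ca)^2)))
    sm <- sqrt(mean(rowSums(sweep(obs, 2, cm)^2)))
    pred <- sweep(sweep(anchors_px, 2, ca) * (sm / sa), 2, cm, `+`)
    midx <- integer(n_a)
    taken <- rep(FALSE, n_m)
    for (i in seq_len(n_a)) {
      d <- rowSums(sweep(obs, 2, pred[i, ])^2)
      d[taken] <- Inf
      midx[i] <- which.min(d)
      taken[midx[i]] <- TRUE
    }
    best <- fit_affine_ls(anchors_px, obs[midx, , drop = FALSE])
    if (is.null(best)) stopf("collinear marker anchors: affine fit is singular")
    best$anchor_idx <- seq_len(n_a)
    best$marker_idx <- midx
  }

  grid_rc <- expand.grid(row = seq_len(layout$rows), col = seq_len(layout$cols))
  grid_rc <- grid_rc[order(grid_rc$row, grid_rc$col), ]
  nominal <- lattice_to_px(layout, grid_rc$row, grid_rc$col)
  centers <- apply_affine(best$affine, nominal)
  structure(list(affine = best$affine,
                 spot_centers = data.frame(row = grid_rc$row, col = grid_rc$col,
                                           x = centers[, "x"], y = centers[, "y"]),
                 residual_rms = best$residual_rms,
                 markers_used = data.frame(anchor = best$anchor_idx,
                                           marker = best$marker_idx)),
            class = "SpotGrid")
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

#' @export
print.SpotGrid <- function(x, ...) {
  cat(sprintf("SpotGrid: %d spots, residual RMS %.4f px\naffine:\n",
              nrow(x$spot_centers), x$residual_rms))
  print(round(x$affine, 6))
  invisible(x)
}

#' Quantify spot intensities on a fitted grid
#'
#' Foreground is the mean intensity over a disc of `spot_radius` around each
#' fitted center; background the median over an annulus `[1.5r, 2.5r]`;
#' signal their difference.  Spots whose disc exits the canvas are flagged
#' `clipped`; non-positive signals are flagged `low`.
#'
#' @param image Numeric matrix.
#' @param grid A `SpotGrid` from [fit_grid()].
#' @param layout A [grid_layout()].
#' @return Data frame: `row`, `col`, `x`, `y`, `foreground`, `background`,
#'   `signal`, `flag`.
#' @export
quantify_spots <- function(image, grid, layout) {
  stopifnot(inherits(grid, "SpotGrid"), inherits(layout, "GridLayout"))
  h <- nrow(image); w <- ncol(image)
  r <- layout$spot_radius
  sc <- grid$spot_centers
  n <- nrow(sc)
  fg <- bg <- numeric(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    x0 <- sc$x[i]; y0 <- sc$y[i]
    ext <- ceiling(2.5 * r) + 1L
    xs <- floor(x0 - ext):ceiling(x0 + ext)
    ys <- floor(y0 - ext):ceiling(y0 + ext)
    clipped <- (x0 - r < 1) || (x0 + r > w) || (y0 - r < 1) || (y0 + r > h)
    xs_in <- xs[xs >= 1 & xs <= w]
    ys_in <- ys[ys >= 1 & ys <= h]
    if (length(xs_in) == 0 || length(ys_in) == 0) {
      fg[i] <- NA_real_; bg[i] <- NA_real_; flag[i] <- "clipped"
      next
    }
    d <- sqrt(outer((ys_in - y0)^2, (xs_in - x0)^2, `+`))
    patch <- image[ys_in, xs_in, drop = FALSE]
    disc <- d <= r
    annulus <- d >= 1.5 * r & d <= 2.5 * r
    fg[i] <- if (any(disc)) mean(patch[disc]) else NA_real_
    bg[i] <- if (any(annulus)) stats::median(patch[annulus]) else NA_real_
    flag[i] <- if (clipped) "clipped" else if (!is.na(fg[i]) && !is.na(bg[i]) &&
                                               fg[i] - bg[i] <= 0) "low" else "ok"
  }
  data.frame(row = sc$row, col = sc$col, x = sc$x, y = sc$y,
             foreground = fg, background = bg, signal = fg - bg, flag = flag,
             stringsAsFactors = FALSE)
}

#' End-to-end gridding of one scan
#'
#' Convenience wrapper: detect markers, fit the grid, quantify spots, and
#' return a QC summary (residual RMS and flag counts) in lieu of the manual
#' verification step of interactive gridding software.  A marker override
#' data frame (columns `x`, `y`) replaces detection when supplied.
#'
#' @param image Numeric matrix.
#' @param layout A [grid_layout()].
#' @param params MSER parameters; defaults to [marker_mser_params()].
#' @param marker_override Optional data frame of manual marker positions.
#' @return List with `grid`, `quant`, `markers`, `qc`.
#' @export
grid_scan <- function(image, layout, params = marker_mser_params(layout),
                      marker_override = NULL) {
  markers <- if (is.null(marker_override)) detect_markers(image, params)
             else as.data.frame(marker_override)
  # keep the most stable regions so the exhaustive correspondence search in
  # fit_grid can discard any remaining spurious detections by residual
  fit_set <- if (!is.null(markers$stability) && nrow(markers) > 8L) {
    markers[seq_len(8L), , drop = FALSE]
  } else markers
  grid <- fit_grid(fit_set, layout)
  quant <- quantify_spots(image, grid, layout)
  list(grid = grid, quant = quant, markers = markers,
       qc = list(residual_rms = grid$residual_rms,
                 n_markers = nrow(markers),
                 flags = table(quant$flag)))
}
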