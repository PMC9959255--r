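# Synthetic microarray scans.
#
# Coordinate convention used throughout the imaging code: x = column,
# y = row, origin at the top-left, pixel centers at integer coordinates
# (1-based, matching R matrix indexing).  Images are numeric matrices on a
# 16-bit scale (0..65535).

#' Describe an array grid layout
#'
#' Spots sit on a `rows` x `cols` lattice with spacing `pitch`; four larger
#' positioning markers sit one pitch outside the spot lattice at the corners
#' (lattice coordinates (0,0), (0,cols+1), (rows+1,0), (rows+1,cols+1)),
#' the simplest identifiable marker geometry.
#'
#' @param rows,cols Spot lattice dimensions.
#' @param pitch Lattice spacing in pixels; must exceed `2 * spot_radius`.
#' @param spot_radius Spot radius in pixels.
#' @param marker_radius Positioning-marker radius (default twice the spot
#'   radius).
#' @param margin Blank border in pixels around the marker lattice.
#' @return A `GridLayout` list with the canvas size and nominal marker
#'   anchor positions.
#' @export
grid_layout <- function(rows, cols, pitch = 18, spot_radius = 3,
                        marker_radius = 2 * spot_radius,
                        margin = 2 * marker_radius + 2) {
  if (!is_count(rows) || !is_count(cols)) stopf("`rows` and `cols` must be positive integers")
  if (pitch <= 2 * spot_radius) stopf("`pitch` must exceed 2 * spot_radius")
  anchors <- rbind(c(0L, 0L), c(0L, cols + 1L), c(rows + 1L, 0L), c(rows + 1L, cols + 1L))
  colnames(anchors) <- c("row", "col")
  structure(list(rows = as.integer(rows), cols = as.integer(cols), pitch = pitch,
                 spot_radius = spot_radius, marker_radius = marker_radius,
                 margin = margin, marker_anchors = anchors,
                 width = ceiling(2 * margin + (cols + 1L) * pitch),
                 height = ceiling(2 * margin + (rows + 1L) * pitch)),
            class = "GridLayout")
}

# Nominal pixel position of lattice coordinates (r, c): spots occupy
# r = 1..rows, c = 1..cols; markers use r/c 0 and rows+1/cols+1.
lattice_to_px <- function(layout, r, c) {
  cbind(x = layout$margin + c * layout$pitch,
        y = layout$margin + r * layout$pitch)
}

#' Build a 2x3 affine displacement
#'
#' Rotation and scaling act about `center` (defaults to the grid centroid
#' when applied by [simulate_array_scan()]), then the translation is added,
#' so small rotations do not push the grid off the canvas.
#'
#' @param dx,dy Translation in pixels.
#' @param rotate_deg Rotation in degrees, counter-clockwise.
#' @param scale Isotropic scale factor.
#' @param center Optional length-2 rotation center `(x, y)`.
#' @return A 2x3 affine matrix `[a b tx; c d ty]` mapping `(x, y, 1)`.
#' @export
affine_params <- function(dx = 0, dy = 0, rotate_deg = 0, scale = 1, center = NULL) {
  th <- rotate_deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  t <- c(dx, dy)
  if (!is.null(center)) t <- t + center - R %*% center
  m <- cbind(R, t)
  dimnames(m) <- list(c("x", "y"), c("a", "b", "t"))
  m
}

apply_affine <- function(affine, xy) {
  out <- t(affine[, 1:2] %*% t(xy[, 1:2, drop = FALSE])) +
    matrix(affine[, 3], nrow(xy), 2L, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

identity_affine <- function() affine_params()

#' Render a synthetic array scan
#'
#' Draws Gaussian-profile spots at the affine-transformed nominal lattice
#' positions (plus optional per-spot jitter) and flat positioning markers
#' with a one-pixel linear edge ramp at the transformed anchor positions,
#' over a constant baseline with optional Gaussian pixel noise, clipped to
#' the 16-bit range.
#'
#' @param layout A [grid_layout()].
#' @param intensities `rows x cols` matrix of spot amplitudes (16-bit scale).
#' @param displacement 2x3 affine from [affine_params()]; rotation/scale act
#'   about the grid centroid unless the affine already encodes a center.
#' @param noise_sd Gaussian pixel-noise standard deviation (16-bit units).
#' @param jitter_max Maximum absolute per-spot positional jitter in pixels
#'   (uniform per axis).
#' @param baseline Background level (default 1000).
#' @param marker_amplitude Marker brightness above background.
#' @param seed Integer seed.
#' @return List with `image` (height x width numeric matrix) and `truth`
#'   (spot centers with planted intensities, marker centers, parameters).
#' @export
simulate_array_scan <- function(layout, intensities,
                                displacement = affine_params(),
                                noise_sd = 0, jitter_max = 0,
                                baseline = 1000, marker_amplitude = 50000,
                                seed = 1L) {
  stopifnot(inherits(layout, "GridLayout"))
  if (!is.matrix(intensities) || nrow(intensities) != layout$rows ||
      ncol(intensities) != layout$cols) {
    stopf("`intensities` must be a %d x %d matrix", layout$rows, layout$cols)
  }
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")

  grid_rc <- expand.grid(row = seq_len(layout$rows), col = seq_len(layout$cols))
  grid_rc <- grid_rc[order(grid_rc$row, grid_rc$col), ]
  nominal_spots <- lattice_to_px(layout, grid_rc$row, grid_rc$col)
  nominal_markers <- lattice_to_px(layout, layout$marker_anchors[, "row"],
                                   layout$marker_anchors[, "col"])

  center <- colMeans(rbind(nominal_spots, nominal_markers))
  aff <- displacement
  # re-anchor rotation/scale about the grid centroid
  R <- aff[, 1:2]
  t0 <- aff[, 3]
  aff <- cbind(R, t0 + center - R %*% center)

  local_seed(seed, {
    spot_centers <- apply_affine(aff, nominal_spots)
    if (jitter_max > 0) {
      spot_centers <- spot_centers +
        matrix(stats::runif(2L * nrow(spot_centers), -jitter_max, jitter_max),
               ncol = 2L)
    }
    marker_centers <- apply_affine(aff, nominal_markers)

    w <- layout$width; h <- layout$height
    pad <- layout$marker_radius + 2
    all_xy <- rbind(spot_centers, marker_centers)
    if (any(all_xy[, "x"] < 1 + 0 | all_xy[, "x"] > w | all_xy[, "y"] < 1 | all_xy[, "y"] > h)) {
      stopf("displacement pushes spots or markers outside the canvas")
    }

    img <- matrix(baseline, nrow = h, ncol = w)

    add_gaussian <- function(img, x0, y0, amp, sigma, extent) {
      xs <- max(1L, floor(x0 - extent)):min(w, ceiling(x0 + extent))
      ys <- max(1L, floor(y0 - extent)):min(h, ceiling(y0 + extent))
      dx2 <- (xs - x0)^2
      dy2 <- (ys - y0)^2
      img[ys, xs] <- img[ys, xs] + amp * exp(-(outer(dy2, dx2, `+`)) / (2 * sigma^2))
      img
    }
    add_disc <- function(img, x0, y0, amp, radius) {
      ext <- radius + 2
      xs <- max(1L, floor(x0 - ext)):min(w, ceiling(x0 + ext))
      ys <- max(1L, floor(y0 - ext)):min(h, ceiling(y0 + ext))
      d <- sqrt(outer((ys - y0)^2, (xs - x0)^2, `+`))
      ramp <- pmin(1, pmax(0, radius + 0.5 - d))
      img[ys, xs] <- img[ys, xs] + amp * ramp
      img
    }

    sigma <- layout$spot_radius / 2
    amps <- intensities[cbind(grid_rc$row, grid_rc$col)]
    for (i in seq_len(nrow(spot_centers))) {
      img <- add_gaussian(img, spot_centers[i, "x"], spot_centers[i, "y"],
                          amps[i], sigma, 3 * sigma)
    }
    for (i in seq_len(nrow(marker_centers))) {
      img <- add_disc(img, marker_centers[i, "x"], marker_centers[i, "y"],
                      marker_amplitude, layout$marker_radius)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 65535)

    truth <- list(
      spots = data.frame(row = grid_rc$row, col = grid_rc$col,
                         x = spot_centers[, "x"], y = spot_centers[, "y"],
                         intensity = amps),
      markers = data.frame(anchor_row = layout$marker_anchors[, "row"],
                           anchor_col = layout$marker_anchors[, "col"],
                           x = marker_centers[, "x"], y = marker_centers[, "y"]),
      affine = aff, baseline = baseline, noise_sd = noise_sd,
      marker_amplitude = marker_amplitude
    )
    list(image = img, truth = truth)
  })
}

#' Write / read a grayscale image as plain-text PGM (P2)
#'
#' Plain PGM is the only image format the package reads and writes: it is
#' plain text, self-describing, and round-trips 16-bit grayscale exactly.
#'
#' @param img Numeric matrix (values 0..65535; rounded on write).
#' @param path File path.
#' @return `read_pgm` returns a numeric matrix; `write_pgm` its path,
#'   invisibly.
#' @export
write_pgm <- function(img, path) {
  img <- round(pmin(pmax(img, 0), 65535))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "65535"), con)
  write(t(img), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stopf("only plain (P2) PGM files are supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stopf("corrupt PGM: expected %d values, found %d", w * h, length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
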