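# Images are numeric matrices in EBImage convention: first index x (column
# in the rendered image), second index y; pixel centres at integer
# coordinates starting at 1.

bilinear_interp <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1L), nx - 1L)
  y0 <- pmin(pmax(floor(y), 1L), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(x0, y0)]
  i10 <- img[cbind(x0 + 1L, y0)]
  i01 <- img[cbind(x0, y0 + 1L)]
  i11 <- img[cbind(x0 + 1L, y0 + 1L)]
  (1 - fx) * (1 - fy) * i00 + fx * (1 - fy) * i10 +
    (1 - fx) * fy * i01 + fx * fy * i11
}

#' Detect the cell boundary in an equatorial confocal image
#'
#' Segmentation of a single dominant bright cell on a darker background:
#' Gaussian smoothing, Otsu threshold, hole filling, largest connected
#' component, and extraction of the component's closed outer contour. A
#' user-supplied binary mask bypasses detection and its contour is returned
#' instead.
#'
#' @param image Numeric matrix (x, y indexing; any intensity scale).
#' @param px_size_um Pixel size (µm/px).
#' @param sigma_px Gaussian smoothing SD in pixels (default 2).
#' @param mask Optional binary/logical matrix of the same size; when given,
#'   detection is skipped.
#' @param min_fraction Components smaller than this fraction of the largest
#'   are ignored; a second component above it makes the image ambiguous and
#'   raises an error.
#'
#' @return A tibble of class `cell_contour` with columns `x_px`, `y_px`
#'   (pixel coordinates, 1-based), `x_um`, `y_um`; vertices ordered
#'   counter-clockwise around the cell. Pixel size kept in attribute
#'   `px_size_um`.
#' @export
detect_boundary <- function(image, px_size_um, sigma_px = 2, mask = NULL,
                            min_fraction = 0.25) {
  if (is.null(mask)) {
    rng <- range(image)
    if (diff(rng) <= 0) {
      stop("segmentation error: image has no contrast (0 candidate components)",
           call. = FALSE)
    }
    norm <- (image - rng[1]) / diff(rng)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(norm), sigma = sigma_px))
    thr <- EBImage::otsu(EBImage::Image(sm))
    mask <- sm > thr
  } else {
    mask <- mask > 0
  }
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1)))
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  areas <- tabulate(as.integer(as.matrix(lab)))
  if (length(areas) == 0 || max(areas) == 0) {
    stop("segmentation error: 0 candidate components above threshold",
         call. = FALSE)
  }
  big <- which(areas >= min_fraction * max(areas))
  if (length(big) > 1) {
    stop(sprintf("segmentation error: %d candidate components above threshold",
                 length(big)), call. = FALSE)
  }
  keep <- which.max(areas)
  comp <- (as.matrix(lab) == keep) * 1
  oc <- EBImage::ocontour(EBImage::Image(comp))[[1]]
  xy <- oc + 1  # ocontour is 0-based
  # enforce counter-clockwise orientation (positive signed area)
  x <- xy[, 1]; y <- xy[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  out <- tibble::tibble(x_px = xy[, 1], y_px = xy[, 2],
                        x_um = xy[, 1] * px_size_um,
                        y_um = xy[, 2] * px_size_um)
  attr(out, "px_size_um") <- px_size_um
  class(out) <- c("cell_contour", class(out))
  out
}

# equidistant arc-length anchors with outward unit normals
contour_anchors <- function(contour, n_lines) {
  x <- contour$x_px; y <- contour$y_px
  xc <- c(x, x[1]); yc <- c(y, y[1])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  s_target <- seq(0, L, length.out = n_lines + 1)[-(n_lines + 1)]
  ax <- stats::approx(s, xc, xout = s_target)$y
  ay <- stats::approx(s, yc, xout = s_target)$y
  # tangent by central differences along arc length (periodic)
  ds <- L / n_lines
  tx <- (c(ax[-1], ax[1]) - c(ax[n_lines], ax[-n_lines])) / (2 * ds)
  ty <- (c(ay[-1], ay[1]) - c(ay[n_lines], ay[-n_lines])) / (2 * ds)
  nrm <- sqrt(tx^2 + ty^2)
  # rotate tangent -90 deg; flip to point away from the centroid
  nx <- ty / nrm; ny <- -tx / nrm
  cx <- mean(x); cy <- mean(y)
  flip <- (ax - cx) * nx + (ay - cy) * ny < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  list(x = ax, y = ay, nx = nx, ny = ny)
}

#' Circumference-averaged radial intensity profile
#'
#' Samples the image along lines normal to the cell boundary at `n_lines`
#' equidistant arc-length positions, each extending `reach_um` into the cell
#' interior and `reach_um` into the exterior, with bilinear interpolation at
#' steps of at most half a pixel, and averages the per-line profiles.
#'
#' @param image Numeric matrix.
#' @param contour A [detect_boundary()] contour (or any tibble with `x_px`,
#'   `y_px` and a `px_size_um` attribute).
#' @param px_size_um Pixel size (µm/px); defaults to the contour attribute.
#' @param n_lines Number of radial lines (default 200).
#' @param reach_um Half-extent of each line (µm, default 2).
#'
#' @return A `radial_profile` tibble (`r_um`, `intensity`), `r_um` negative
#'   inside the cell, with attributes `n_lines` and `px_size_um`.
#' @export
radial_profile <- function(image, contour, px_size_um = NULL, n_lines = 200,
                           reach_um = 2) {
  if (is.null(px_size_um)) px_size_um <- attr(contour, "px_size_um")
  stopifnot(is.numeric(px_size_um), px_size_um > 0)
  reach_px <- reach_um / px_size_um
  step_px <- 0.5
  r_px <- seq(-reach_px, reach_px, by = step_px)
  an <- contour_anchors(contour, n_lines)
  X <- outer(an$nx, r_px) + an$x   # n_lines x n_r
  Y <- outer(an$ny, r_px) + an$y
  if (any(X < 1 | X > nrow(image) | Y < 1 | Y > ncol(image))) {
    stop("contour too close to the image edge for the requested reach",
         call. = FALSE)
  }
  vals <- matrix(bilinear_interp(image, as.vector(X), as.vector(Y)),
                 nrow = n_lines)
  new_radial_profile(r_um = r_px * px_size_um, intensity = colMeans(vals),
                     n_lines = n_lines, px_size_um = px_size_um)
}

#' Lateral registration of two imaging channels
#'
#' Estimates the lateral shift between two channels as the difference of
#' their intensity centres of gravity (computed over pixels above an Otsu
#' foreground threshold) and returns it; [apply_shift()] resamples a channel
#' to remove it before profile extraction.
#'
#' @param imageA,imageB Numeric matrices of equal size (reference and moving
#'   channel).
#' @param px_size_um Pixel size (µm/px).
#' @return A one-row tibble: `dx_px`, `dy_px`, `dx_um`, `dy_um`
#'   (centroid(B) - centroid(A)).
#' @export
register_channels <- function(imageA, imageB, px_size_um = 1) {
  cog <- function(img) {
    rng <- range(img)
    if (diff(rng) <= 0) {
      stop("registration error: channel has empty foreground", call. = FALSE)
    }
    norm <- (img - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm))
    fg <- norm > thr
    if (!any(fg)) {
      stop("registration error: channel has empty foreground", call. = FALSE)
    }
    w <- img * fg
    idx <- which(fg, arr.ind = TRUE)
    ww <- w[fg]
    c(sum(idx[, 1] * ww), sum(idx[, 2] * ww)) / sum(ww)
  }
  a <- cog(imageA); b <- cog(imageB)
  tibble::tibble(dx_px = b[1] - a[1], dy_px = b[2] - a[2],
                 dx_um = (b[1] - a[1]) * px_size_um,
                 dy_um = (b[2] - a[2]) * px_size_um)
}

#' Shift an image by a subpixel translation
#'
#' Bilinear resampling of `image` by `(-dx, -dy)` pixels, i.e. it removes the
#' shift reported by [register_channels()] when applied to the moving
#' channel.
#'
#' @param image Numeric matrix.
#' @param dx_px,dy_px Shift to remove (px).
#' @return Shifted matrix of the same size (edges padded by clamping).
#' @export
apply_shift <- function(image, dx_px, dy_px) {
  nx <- nrow(image); ny <- ncol(image)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  xs <- pmin(pmax(g$x + dx_px, 1), nx)
  ys <- pmin(pmax(g$y + dy_px, 1), ny)
  matrix(bilinear_interp(image, xs, ys), nrow = nx)
}

#' Cortex quantification of one equatorial image
#'
#' Convenience wrapper chaining [detect_boundary()], [radial_profile()] and
#' [fit_profile()], returning the fit together with the cortex-to-cytoplasm
#' ratio.
#'
#' @inheritParams detect_boundary
#' @inheritParams radial_profile
#' @param skewed Passed to [fit_profile()].
#' @return A `profile_fit` object (see [fit_profile()]).
#' @export
quantify_cortex <- function(image, px_size_um, mask = NULL, n_lines = 200,
                            reach_um = 2, skewed = TRUE) {
  contour <- detect_boundary(image, px_size_um, mask = mask)
  prof <- radial_profile(image, contour, n_lines = n_lines,
                         reach_um = reach_um)
  fit_profile(prof, skewed = skewed)
}

#' Cortical thickness from a two-channel equatorial image
#'
#' Registers the membrane channel onto the actin channel (centres of
#' gravity), extracts both circumference-averaged radial profiles along the
#' actin-channel boundary, fits the symmetric profile model to each and
#' reports twice the peak offset as the thickness estimate.
#'
#' @param image_actin,image_membrane Numeric matrices of equal size.
#' @param px_size_um Pixel size (µm/px).
#' @inheritParams radial_profile
#' @return A one-row tibble as [estimate_thickness()], plus the registration
#'   shift columns.
#' @export
thickness_from_images <- function(image_actin, image_membrane, px_size_um,
                                  n_lines = 200, reach_um = 2) {
  sh <- register_channels(image_actin, image_membrane, px_size_um)
  mem_reg <- apply_shift(image_membrane, sh$dx_px, sh$dy_px)
  contour <- detect_boundary(image_actin, px_size_um)
  prof_a <- radial_profile(image_actin, contour, n_lines = n_lines,
                           reach_um = reach_um)
  prof_m <- radial_profile(mem_reg, contour, n_lines = n_lines,
                           reach_um = reach_um)
  fit_a <- fit_profile(prof_a, skewed = FALSE)
  fit_m <- fit_profile(prof_m, skewed = FALSE)
  dplyr::bind_cols(estimate_thickness(fit_a, fit_m), sh)
}
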