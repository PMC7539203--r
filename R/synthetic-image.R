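#' Simulate an equatorial confocal image of a round cell
#'
#' Renders a disk-shaped cell whose boundary-centred radial intensity
#' cross-section follows [cortex_profile_model()] with the given parameters:
#' a cytoplasmic plateau inside, a (skewed-)Gaussian cortical rim at the
#' boundary and a constant background outside. Optional angular modulation
#' of the cortical amplitude tests the circumferential averaging; optional
#' Poisson or Gaussian noise tests robustness.
#'
#' @param radius_um Cell radius (µm); the cortical rim sits at this radius
#'   (plus `mu`).
#' @param px_size_um Pixel size (µm/px).
#' @param mu,sigma1,sigma2,I_cyt,I_cort,I_BG,alpha Profile parameters, as in
#'   [cortex_profile_model()]; `mu` is relative to `radius_um`.
#' @param margin_um Background margin beyond the profile reach (µm).
#' @param angular_mod Relative amplitude of a `cos(3*theta)` modulation of
#'   `I_cort` (default 0: radially symmetric).
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param peak_snr Peak signal-to-noise ratio for Poisson noise: intensities
#'   are scaled so the profile peak corresponds to `peak_snr^2` expected
#'   photons.
#' @param sigma_noise SD for Gaussian noise (a.u.).
#' @param seed Integer seed (used only when noise is added).
#'
#' @return A list of class `synthetic_image`: `image` (numeric matrix),
#'   `truth` (one-row tibble of all parameters plus the image centre and
#'   `ratio_true`), and `px_size_um`.
#' @export
gen_equatorial_image <- function(radius_um = 8, px_size_um = 0.1,
                                 mu = 0, sigma1 = 0.3, sigma2 = 0.25,
                                 I_cyt = 50, I_cort = 100, I_BG = 5,
                                 alpha = 0, margin_um = 3, angular_mod = 0,
                                 noise = c("none", "poisson", "gaussian"),
                                 peak_snr = 10, sigma_noise = 1, seed = NULL) {
  noise <- match.arg(noise)
  if (sigma1 <= 0 || sigma2 <= 0 || I_cyt < 0 || I_cort < 0 || radius_um <= 0) {
    stop("parameter out of admissible range", call. = FALSE)
  }
  local_seed(seed)
  half_px <- ceiling((radius_um + margin_um) / px_size_um)
  n <- 2 * half_px + 1
  cx <- half_px + 1
  xs <- (seq_len(n) - cx) * px_size_um
  RHO <- sqrt(outer(xs^2, xs^2, `+`))
  r <- RHO - radius_um
  img <- cortex_profile_model(r, mu, sigma1, sigma2, I_cyt, I_cort, I_BG, alpha)
  if (angular_mod != 0) {
    TH <- atan2(rep(xs, each = n), rep(xs, times = n))
    dim(TH) <- c(n, n)
    peak <- I_cort * exp(-(r - mu)^2 / (2 * sigma2^2)) *
      (1 + erf(alpha * (r - mu) / (sigma2 * sqrt(2))))
    img <- img + angular_mod * cos(3 * TH) * peak
  }
  if (noise == "poisson") {
    peak_I <- max(img)
    scale <- peak_snr^2 / peak_I
    img <- stats::rpois(length(img), as.vector(img * scale)) / scale
    dim(img) <- c(n, n)
  } else if (noise == "gaussian") {
    img <- img + stats::rnorm(length(img), 0, sigma_noise)
    dim(img) <- c(n, n)
  }
  truth <- tibble::tibble(
    radius_um = radius_um, px_size_um = px_size_um, mu = mu, sigma1 = sigma1,
    sigma2 = sigma2, I_cyt = I_cyt, I_cort = I_cort, I_BG = I_BG,
    alpha = alpha, angular_mod = angular_mod, noise = noise,
    peak_snr = peak_snr, sigma_noise = sigma_noise,
    center_px = cx, ratio_true = I_cort * sigma2 * sqrt(2 * pi) / I_cyt,
    seed = if (is.null(seed)) NA_integer_ else seed
  )
  structure(list(image = img, truth = truth, px_size_um = px_size_um),
            class = "synthetic_image")
}

#' Simulate a two-channel cell with known cortical thickness
#'
#' Renders an actin channel whose cortical peak sits half the true thickness
#' inside the membrane-dye peak, so that [thickness_from_images()] (or
#' [estimate_thickness()] on the two profile fits) should recover
#' `thickness_um`. The membrane channel has no cytoplasmic step. An optional
#' lateral offset of the membrane channel exercises channel registration.
#'
#' @param thickness_um True cortical thickness (µm); the actin peak is
#'   rendered at `radius_um - thickness_um/2`, the membrane peak at
#'   `radius_um`.
#' @inheritParams gen_equatorial_image
#' @param shift_px Length-2 lateral offset applied to the membrane channel
#'   (px, may be fractional).
#' @param sigma2_mem Membrane peak width (µm).
#' @param I_mem Membrane peak amplitude (a.u.).
#' @return A list of class `synthetic_two_channel`: `actin`, `membrane`
#'   (matrices), `truth`, `px_size_um`.
#' @export
gen_two_channel_cell <- function(thickness_um = 0.3, radius_um = 8,
                                 px_size_um = 0.05, sigma1 = 0.3,
                                 sigma2 = 0.2, I_cyt = 40, I_cort = 100,
                                 I_BG = 5, sigma2_mem = 0.2, I_mem = 120,
                                 shift_px = c(0, 0),
                                 noise = c("none", "poisson", "gaussian"),
                                 peak_snr = 10, sigma_noise = 1,
                                 seed = NULL) {
  noise <- match.arg(noise)
  local_seed(seed)
  seeds <- if (is.null(seed)) c(NA, NA) else seed + c(101L, 202L)
  act <- gen_equatorial_image(radius_um = radius_um - thickness_um / 2,
                              px_size_um = px_size_um, sigma1 = sigma1,
                              sigma2 = sigma2, I_cyt = I_cyt, I_cort = I_cort,
                              I_BG = I_BG,
                              margin_um = 3 + thickness_um / 2, noise = noise,
                              peak_snr = peak_snr, sigma_noise = sigma_noise,
                              seed = if (is.na(seeds[1])) NULL else seeds[1])
  mem <- gen_equatorial_image(radius_um = radius_um, px_size_um = px_size_um,
                              sigma1 = sigma1, sigma2 = sigma2_mem,
                              I_cyt = 0, I_cort = I_mem, I_BG = I_BG,
                              margin_um = 3, noise = noise,
                              peak_snr = peak_snr, sigma_noise = sigma_noise,
                              seed = if (is.na(seeds[2])) NULL else seeds[2])
  A <- act$image
  M <- mem$image
  # pad/crop membrane render to the actin frame size (centres aligned)
  if (!all(dim(M) == dim(A))) {
    out <- matrix(I_BG, nrow(A), ncol(A))
    off <- (dim(A) - dim(M)) %/% 2
    sx <- seq_len(min(nrow(M), nrow(A))); sy <- seq_len(min(ncol(M), ncol(A)))
    out[off[1] + sx, off[2] + sy] <- M[sx, sy]
    M <- out
  }
  if (any(shift_px != 0)) M <- apply_shift(M, -shift_px[1], -shift_px[2])
  truth <- tibble::tibble(thickness_um = thickness_um, radius_um = radius_um,
                          px_size_um = px_size_um, shift_x_px = shift_px[1],
                          shift_y_px = shift_px[2], noise = noise,
                          seed = if (is.null(seed)) NA_integer_ else seed)
  structure(list(actin = A, membrane = M, truth = truth,
                 px_size_um = px_size_um),
            class = "synthetic_two_channel")
}

#' Simulate a z-stack of ellipsoid cross-section masks
#'
#' Voxelises an axis-aligned ellipsoid with semi-axes `(a, b, c)` (x, y, z;
#' µm) into binary equatorial-plane masks, one per z-slice, together with the
#' analytic per-slice cross-sectional areas. Used to validate
#' [largest_cross_section()] and [roundness()].
#'
#' @param semi_axes_um Length-3 numeric: semi-axes `(a, b, c)` in µm.
#' @param px_size_um Pixel size (µm/px).
#' @param z_step_um z spacing of the stack (µm).
#' @param seed Integer seed (kept for interface symmetry; the voxelisation
#'   is deterministic).
#' @return A list of class `synthetic_spheroid`: `masks` (list of binary
#'   matrices, ordered by z), `truth` (tibble `z_index`, `z_um`,
#'   `area_analytic_um2`, semi-axes) and `px_size_um`.
#' @export
gen_spheroid_masks <- function(semi_axes_um = c(20, 20, 20), px_size_um = 0.5,
                               z_step_um = 1, seed = NULL) {
  stopifnot(length(semi_axes_um) == 3)
  if (any(semi_axes_um <= 0)) stop("semi-axes must be positive", call. = FALSE)
  a <- semi_axes_um[1]; b <- semi_axes_um[2]; cc <- semi_axes_um[3]
  z <- seq(-cc + z_step_um / 2, cc - z_step_um / 2, by = z_step_um)
  half_px <- ceiling((max(a, b) + 2) / px_size_um)
  n <- 2 * half_px + 1
  xs <- (seq_len(n) - (half_px + 1)) * px_size_um
  masks <- lapply(z, function(zj) {
    s <- sqrt(max(1 - (zj / cc)^2, 0))
    az <- a * s; bz <- b * s
    if (az < px_size_um / 2) return(matrix(0L, n, n))
    E <- outer(xs^2 / az^2, xs^2 / bz^2, `+`)
    (E <= 1) * 1L
  })
  truth <- tibble::tibble(
    z_index = seq_along(z), z_um = z,
    area_analytic_um2 = pi * a * b * pmax(1 - (z / cc)^2, 0),
    a_um = a, b_um = b, c_um = cc
  )
  structure(list(masks = masks, truth = truth, px_size_um = px_size_um),
            class = "synthetic_spheroid")
}

#' Simulate a circumference-averaged radial profile directly
#'
#' Evaluates [cortex_profile_model()] on a uniform boundary-centred grid and
#' optionally adds Poisson noise at a prescribed peak signal-to-noise ratio
#' (intensities are scaled so the profile peak corresponds to `peak_snr^2`
#' expected photons, sampled, and scaled back). This is the direct fixture
#' for [fit_profile()] round-trip tests, bypassing image rendering.
#'
#' @inheritParams gen_equatorial_image
#' @param reach_um Half-extent of the radial grid (µm).
#' @param dr_um Grid step (µm).
#' @param n_avg Number of noisy radial lines averaged into the profile
#'   (default 200, matching the circumferential averaging of the
#'   measurement); `peak_snr` always refers to a single pixel before
#'   averaging.
#' @return A `radial_profile` tibble with the ground-truth parameters in
#'   attribute `truth`.
#' @export
gen_radial_profile <- function(mu = 0, sigma1 = 0.3, sigma2 = 0.25,
                               I_cyt = 50, I_cort = 100, I_BG = 5, alpha = 0,
                               reach_um = 2, dr_um = 0.02,
                               noise = c("none", "poisson"), peak_snr = 10,
                               n_avg = 200, seed = NULL) {
  noise <- match.arg(noise)
  local_seed(seed)
  r <- seq(-reach_um, reach_um, by = dr_um)
  I <- cortex_profile_model(r, mu, sigma1, sigma2, I_cyt, I_cort, I_BG, alpha)
  if (noise == "poisson") {
    # mean of n_avg iid Poisson draws == one draw at n_avg-fold rate
    scale <- peak_snr^2 / max(I)
    I <- stats::rpois(length(I), I * scale * n_avg) / (scale * n_avg)
  }
  out <- new_radial_profile(r, I, n_lines = NA_integer_, px_size_um = dr_um)
  attr(out, "truth") <- tibble::tibble(mu = mu, sigma1 = sigma1,
                                       sigma2 = sigma2, I_cyt = I_cyt,
                                       I_cort = I_cort, I_BG = I_BG,
                                       alpha = alpha, noise = noise,
                                       peak_snr = peak_snr, n_avg = n_avg)
  out
}
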