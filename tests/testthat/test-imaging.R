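test_that("cortex integral closed form matches adaptive quadrature", {
  for (alpha in c(-5, -2, 0, 1, 3, 5)) {
    for (sigma2 in c(0.1, 0.25, 0.6)) {
      closed <- 100 * sigma2 * sqrt(2 * pi)
      expect_equal(closed, quad_cortex_integral(100, 0.2, sigma2, alpha),
                   tolerance = 1e-8)
    }
  }
})

test_that("cortex ratio follows from the fitted parameters", {
  prof <- gen_radial_profile(sigma2 = 0.5, I_cyt = 50, I_cort = 100)
  fit <- fit_profile(prof, skewed = FALSE)
  expect_equal(cortex_ratio(fit), 100 * 0.5 * sqrt(2 * pi) / 50,
               tolerance = 1e-3)
  # no cortical peak: ratio collapses to zero
  prof0 <- gen_radial_profile(I_cort = 0)
  fit0 <- fit_profile(prof0, skewed = FALSE)
  expect_lt(fit0$par$I_cort, 0.01 * fit0$par$I_cyt)
  expect_lt(cortex_ratio(fit0), 1e-2)
})

test_that("noise-free profile fits recover all seven parameters within 1%", {
  cases <- list(
    c(mu = 0, sigma1 = 0.3, sigma2 = 0.25, I_cyt = 50, I_cort = 100,
      I_BG = 5, alpha = 1),
    c(mu = -0.15, sigma1 = 0.2, sigma2 = 0.35, I_cyt = 80, I_cort = 60,
      I_BG = 10, alpha = -2),
    c(mu = 0.1, sigma1 = 0.4, sigma2 = 0.15, I_cyt = 30, I_cort = 150,
      I_BG = 2, alpha = 0)
  )
  for (p in cases) {
    prof <- gen_radial_profile(mu = p["mu"], sigma1 = p["sigma1"],
                               sigma2 = p["sigma2"], I_cyt = p["I_cyt"],
                               I_cort = p["I_cort"], I_BG = p["I_BG"],
                               alpha = p["alpha"])
    fit <- fit_profile(prof, skewed = TRUE)
    est <- unlist(fit$par[c("mu", "sigma1", "sigma2", "I_cyt", "I_cort",
                            "I_BG", "alpha")])
    scale <- pmax(abs(p), 0.1)  # relative where possible, absolute near zero
    expect_true(all(abs(est - p) / scale < 0.01),
                info = paste("case alpha =", p["alpha"]))
  }
})

test_that("a symmetric profile fitted with free skewness stays symmetric", {
  prof <- gen_radial_profile(alpha = 0)
  fit <- fit_profile(prof, skewed = TRUE)
  expect_lt(abs(fit$par$alpha), 0.1)
})

test_that("boundary detection finds a synthetic disk to pixel accuracy", {
  n <- 121
  xs <- seq_len(n) - 61
  img <- 5 + 95 * (sqrt(outer(xs^2, xs^2, `+`)) <= 50)
  ct <- detect_boundary(img, px_size_um = 0.2)
  rad <- sqrt((ct$x_px - 61)^2 + (ct$y_px - 61)^2)
  expect_true(all(abs(rad - 50) <= 1.5))
  expect_error(detect_boundary(matrix(3, 50, 50), 0.2), "segmentation")
  # two comparable blobs are ambiguous
  img2 <- matrix(0, 101, 101)
  img2[11:30, 11:30] <- 1
  img2[70:95, 70:95] <- 1
  expect_error(detect_boundary(img2, 0.2), "2 candidate")
})

test_that("a user-supplied mask bypasses detection", {
  img <- matrix(runif(101 * 101), 101, 101)  # pure noise image
  mask <- ellipse_mask(30, 30, n = 101)
  ct <- detect_boundary(img, px_size_um = 0.1, mask = mask)
  rad <- sqrt((ct$x_px - 51)^2 + (ct$y_px - 51)^2)
  expect_true(all(abs(rad - 30) <= 1.5))
})

test_that("radial profiles reproduce the generating cross-section", {
  si <- gen_equatorial_image(radius_um = 8, px_size_um = 0.1)
  ct <- detect_boundary(si$image, si$px_size_um)
  prof <- radial_profile(si$image, ct)
  # compare against the generating model on the same grid, allowing for the
  # subpixel offset between the detected contour and the true radius
  fit <- fit_profile(prof, skewed = FALSE)
  model <- cortex_profile_model(prof$r_um, fit$par$mu, si$truth$sigma1,
                                si$truth$sigma2, si$truth$I_cyt,
                                si$truth$I_cort, si$truth$I_BG)
  expect_lt(sqrt(mean((prof$intensity - model)^2)), 0.02 * si$truth$I_cort)
})

test_that("line anchors are equidistant in arc length", {
  ct <- detect_boundary(5 + 95 * ellipse_mask(40, 40, n = 121), 0.1,
                        mask = ellipse_mask(40, 40, n = 121))
  an <- cortexmech:::contour_anchors(ct, 4)
  expect_length(an$x, 4)
  d <- sqrt(diff(c(an$x, an$x[1]))^2 + diff(c(an$y, an$y[1]))^2)
  expect_lt(diff(range(d)) / mean(d), 0.1)
})

test_that("profiles near the frame edge raise a margin error", {
  si <- gen_equatorial_image(radius_um = 8, px_size_um = 0.1, margin_um = 3)
  ct <- detect_boundary(si$image, si$px_size_um)
  expect_error(radial_profile(si$image, ct, reach_um = 4), "edge")
})

test_that("quantified ratio is rotation-invariant", {
  si <- gen_equatorial_image(radius_um = 8, px_size_um = 0.1, alpha = 1)
  r0 <- cortex_ratio(quantify_cortex(si$image, si$px_size_um))
  rot <- as.matrix(EBImage::rotate(EBImage::Image(si$image), 37,
                                   bg.col = si$truth$I_BG))
  r37 <- cortex_ratio(quantify_cortex(rot, si$px_size_um))
  expect_lt(abs(r37 / r0 - 1), 0.01)
  expect_lt(abs(r0 / si$truth$ratio_true - 1), 0.01)
})

test_that("angular modulation averages out over the circumference", {
  plain <- gen_equatorial_image(radius_um = 8, px_size_um = 0.1)
  modded <- gen_equatorial_image(radius_um = 8, px_size_um = 0.1,
                                 angular_mod = 0.3)
  r_plain <- cortex_ratio(quantify_cortex(plain$image, 0.1))
  r_mod <- cortex_ratio(quantify_cortex(modded$image, 0.1))
  expect_lt(abs(r_mod / r_plain - 1), 0.02)
})

test_that("channel registration recovers translations to subpixel accuracy", {
  si <- gen_equatorial_image(radius_um = 6, px_size_um = 0.1)
  A <- si$image
  expect_equal(unlist(register_channels(A, A, 0.1)[c("dx_px", "dy_px")]),
               c(dx_px = 0, dy_px = 0), tolerance = 1e-9)
  B <- apply_shift(A, -3, 2)  # content moved by (+3, -2)
  sh <- register_channels(A, B, 0.1)
  expect_equal(sh$dx_px, 3, tolerance = 0.1)
  expect_equal(sh$dy_px, -2, tolerance = 0.1)
  # centroid shift is invariant to intensity scaling
  sh2 <- register_channels(A, B * 2.7, 0.1)
  expect_equal(sh2$dx_px, sh$dx_px, tolerance = 1e-6)
})

test_that("thickness estimate is the doubled peak offset", {
  mk <- function(mu) {
    fit_profile(gen_radial_profile(mu = mu, alpha = 0), skewed = FALSE)
  }
  fa <- mk(-0.2); fm <- mk(0)
  th <- estimate_thickness(fa, fm)
  expect_equal(th$thickness_um, 0.4, tolerance = 1e-3)
  expect_false(th$unphysical)
  same <- estimate_thickness(fa, fa)
  expect_equal(same$thickness_um, 0, tolerance = 1e-9)
  flipped <- estimate_thickness(fm, fa)
  expect_true(flipped$unphysical)
})

test_that("two-channel synthetic cells recover the true thickness within 10%", {
  tc <- gen_two_channel_cell(thickness_um = 0.3, seed = 13,
                             shift_px = c(2.5, -1.5))
  th <- thickness_from_images(tc$actin, tc$membrane, tc$px_size_um)
  expect_lt(abs(th$thickness_um / 0.3 - 1), 0.1)
  expect_equal(th$dx_px, 2.5, tolerance = 0.15)
  expect_equal(th$dy_px, -1.5, tolerance = 0.15)
})

test_that("profile-fit tidiers and plots expose the model parameters", {
  prof <- gen_radial_profile(seed = 2)
  fit <- fit_profile(prof, skewed = TRUE)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("mu", "sigma1", "sigma2", "I_cyt", "I_cort",
                             "I_BG", "alpha"))
  expect_s3_class(generics::glance(fit), "tbl_df")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
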