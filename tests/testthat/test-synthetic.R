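test_that("generators are bit-identical under a fixed seed", {
  a <- gen_afm_trace(seed = 123, sigma_F = 0.1)
  b <- gen_afm_trace(seed = 123, sigma_F = 0.1)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth, b$truth)
  i1 <- gen_equatorial_image(seed = 5, noise = "poisson")
  i2 <- gen_equatorial_image(seed = 5, noise = "poisson")
  expect_identical(i1$image, i2$image)
  c1 <- gen_cohort(seed = 9, n_per_group = 5)
  c2 <- gen_cohort(seed = 9, n_per_group = 5)
  expect_identical(c1$truth, c2$truth)
  s1 <- gen_spheroid_masks(c(10, 8, 9), seed = 1)
  s2 <- gen_spheroid_masks(c(10, 8, 9), seed = 1)
  expect_identical(s1$masks, s2$masks)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(42)
  x1 <- runif(1)
  set.seed(42)
  invisible(gen_afm_trace(seed = 7, sigma_F = 0.1))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("zero drive amplitude gives a constant baseline force", {
  fx <- gen_afm_trace(dh_um = 0, sigma_F = 0, seed = 1)
  expect_lt(diff(range(fx$trace$force_nN)), 1e-9)
  sh <- solve_shape(fx$truth$V, fx$truth$h0)
  expect_equal(fx$trace$force_nN[1],
               fx$truth$gamma0 * sh$A_con * (1 / sh$R1 + 1 / sh$R2),
               tolerance = 1e-9)
})

test_that("infeasible confinement is rejected", {
  expect_error(gen_afm_trace(confinement = 1.2), "infeasible")
  expect_error(gen_cohort(n_per_group = 2), "design error")
  expect_error(gen_spheroid_masks(c(-1, 2, 3)), "positive")
})

test_that("piecewise-linear drive still recovers the cortex parameters", {
  fx <- gen_afm_trace(pwl_drive = TRUE, K_true = 25, phi_true_deg = 20,
                      seed = 17)
  s <- rheology_summary(fx$trace, fx$truth$V, fx$calibration)$summary
  expect_lt(abs(s$K / 25 - 1), 0.02)
  expect_lt(abs(s$phi_deg - 20), 1)
})

test_that("cohort design shifts medians in the configured directions", {
  co <- gen_cohort(n_per_group = 200, effect = 0.5, cv = 0.2, seed = 31)
  med <- co$truth |>
    dplyr::group_by(condition, phase) |>
    dplyr::summarise(gamma = median(gamma), K = median(K),
                     phi = median(phi_deg), .groups = "drop")
  pre_i <- med[med$condition == "pre" & med$phase == "interphase", ]
  post_i <- med[med$condition == "post" & med$phase == "interphase", ]
  pre_m <- med[med$condition == "pre" & med$phase == "mitosis", ]
  post_m <- med[med$condition == "post" & med$phase == "mitosis", ]
  expect_lt(post_i$gamma, pre_i$gamma)
  expect_lt(post_i$K, pre_i$K)
  expect_gt(post_m$gamma, pre_m$gamma)
  expect_gt(post_m$K, pre_m$K)
  expect_lt(post_m$phi, pre_m$phi)
})

test_that("null cohorts give uniform-ish Mann-Whitney p-values", {
  # quick type-I smoke check at the parameter level (the full calibration
  # run lives in the acceptance suite)
  rej <- sapply(1:50, function(s) {
    co <- gen_cohort(n_per_group = 10, effect = 0, seed = 5000 + s)
    sub <- co$truth[co$truth$phase == "interphase", ]
    p <- tidy(mann_whitney(sub$gamma[sub$condition == "pre"],
                           sub$gamma[sub$condition == "post"]))$p_value
    p < 0.05
  })
  expect_lt(mean(rej), 0.2)
})

test_that("power: strong effects are detected with the designed direction", {
  hits <- sapply(1:20, function(s) {
    co <- gen_cohort(n_per_group = 25, effect = 0.5, cv = 0.2, seed = 600 + s)
    sub <- co$truth[co$truth$phase == "mitosis", ]
    cmp <- mann_whitney(sub$K[sub$condition == "pre"],
                        sub$K[sub$condition == "post"],
                        labels = c("pre", "post"))$comparison
    cmp$p_value < 0.05 && cmp$median_diff > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("two-channel generator nests the actin peak inside the membrane", {
  tc <- gen_two_channel_cell(thickness_um = 0.4, seed = 3)
  ctA <- detect_boundary(tc$actin, tc$px_size_um)
  profA <- radial_profile(tc$actin, ctA)
  profM <- radial_profile(tc$membrane, ctA)
  peakA <- profA$r_um[which.max(profA$intensity)]
  peakM <- profM$r_um[which.max(profM$intensity)]
  expect_gt(peakM, peakA)
  expect_equal(2 * (peakM - peakA), 0.4, tolerance = 0.1)
})
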