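make_cal <- function(k = 0.5, elevation = 15, spike = 0.5, f = 1) {
  afm_calibration(k = k, elevation_um = elevation, spike_um = spike,
                  piezo_ref_um = 0, f = f)
}

test_that("cell-height reconstruction inverts the generator exactly", {
  fx <- gen_afm_trace(seed = 11, sigma_F = 0.1)
  tr <- compute_cell_height(fx$trace, fx$calibration)
  h_true <- fx$truth$h0 + fx$truth$dh_um * sin(2 * pi * fx$truth$f * tr$time_s)
  expect_equal(tr$h_um, h_true, tolerance = 1e-12)
})

test_that("cell height terms behave as expected in limits", {
  cal <- make_cal()
  tr <- tibble::tibble(time_s = seq(0, 1, by = 0.002),
                       force_nN = 0, piezo_um = 5)
  h <- compute_cell_height(tr, cal)$h_um
  expect_equal(h, rep(15 - 5 + 0.5, length(h)))
  # stiff cantilever: deflection term vanishes
  tr$force_nN <- 10
  h_stiff <- compute_cell_height(tr, make_cal(k = 1e9))$h_um
  expect_equal(h_stiff, rep(10.5, length(h_stiff)), tolerance = 1e-9)
  # deflection term is F/k in um
  h_soft <- compute_cell_height(tr, make_cal(k = 0.5))$h_um
  expect_equal(h_soft - h_stiff, rep(1e-3 * 10 / 0.5, length(h_soft)),
               tolerance = 1e-9)
  # corrupt calibration
  tr$piezo_um <- 30
  expect_error(compute_cell_height(tr, cal), "non-positive")
})

test_that("tension/strain series: constants, linearity and zero-mean strain", {
  tr <- tibble::tibble(time_s = seq(0, 2, by = 0.002),
                       force_nN = 5, h_um = 9)
  ss <- tension_strain_series(tr, V = 3000)
  expect_true(all(abs(ss$eps_A) < 1e-14))
  expect_equal(ss$gamma_eff, rep(ss$gamma_eff[1], nrow(ss)))
  ss2 <- tension_strain_series(dplyr::mutate(tr, force_nN = 10), V = 3000)
  expect_equal(ss2$gamma_eff, 2 * ss$gamma_eff)
  # zero mean over the analysis window by construction
  fx <- gen_afm_trace(seed = 3)
  trc <- compute_cell_height(fx$trace, fx$calibration)
  ss3 <- tension_strain_series(trc, fx$truth$V, window = c(1001L, 5000L))
  expect_lt(abs(mean(ss3$eps_A)), 1e-12)
  # generated gamma_eff is recovered from force and geometry
  ss4 <- tension_strain_series(trc, fx$truth$V)
  eps_fit <- fit_oscillation(ss4$time_s, ss4$eps_A, 1)
  gam_true <- fx$truth$gamma0 + fx$truth$K_true * fx$truth$eps_amp_true *
    sin(2 * pi * ss4$time_s + fx$truth$eps_phase_true_deg * pi / 180 +
          fx$truth$phi_true_deg * pi / 180)
  expect_equal(ss4$gamma_eff, gam_true, tolerance = 1e-9)
})

test_that("unconfined samples are reported with the offending time", {
  tr <- tibble::tibble(time_s = c(0, 0.1, 0.2), force_nN = 1,
                       h_um = c(9, 9, 25))
  expect_error(tension_strain_series(tr, V = 3000), "0.2")
})

test_that("harmonic fit recovers amplitude, phase and mean exactly", {
  t <- seq(0, 8, by = 0.002)
  f <- 1
  fit <- fit_oscillation(t, 2 * sin(2 * pi * f * t), f)
  expect_equal(fit$amplitude, 2, tolerance = 1e-12)
  expect_equal(fit$phase_deg, 0, tolerance = 1e-9)
  expect_equal(fit$mean, 0, tolerance = 1e-12)
  fit2 <- fit_oscillation(t, 1 + 0.5 * cos(2 * pi * f * t), f)
  expect_equal(fit2$mean, 1, tolerance = 1e-12)
  expect_equal(fit2$amplitude, 0.5, tolerance = 1e-12)
  expect_equal(fit2$phase_deg, 90, tolerance = 1e-9)
})

test_that("harmonic fit is robust to additive noise", {
  t <- seq(0, 8, length.out = 4000)
  amp <- 2
  withr::with_seed(42, {
    errs <- replicate(100, {
      y <- amp * sin(2 * pi * t + 0.7) + rnorm(4000, 0, 0.1 * amp)
      abs(fit_oscillation(t, y, 1)$amplitude / amp - 1)
    })
  })
  expect_gte(mean(errs < 0.02), 0.95)
})

test_that("low-amplitude fits are flagged as low SNR", {
  t <- seq(0, 8, by = 0.002)
  withr::with_seed(7, y <- 1e-4 * sin(2 * pi * t) + rnorm(length(t)))
  expect_true(fit_oscillation(t, y, 1)$low_snr)
})

test_that("steady-window selection returns the latest steady periods", {
  fx <- gen_afm_trace(seed = 5, n_periods = 12)
  win <- select_steady_window(fx$trace, fx$calibration)
  expect_equal(win$periods, 5:12)
  expect_equal(win$W, 8L)
})

test_that("steady-window selection skips a transient relaxation phase", {
  fx <- gen_afm_trace(seed = 6, n_periods = 15, transient_tau_s = 1,
                      K_true = 40)
  win <- select_steady_window(fx$trace, fx$calibration)
  expect_gte(min(win$periods), 4)
  # the per-period force amplitudes in the window really are steady
  amps <- win$per_period$amp_force[win$periods]
  expect_lt(max(abs(amps - median(amps)) / median(amps)), 0.05)
})

test_that("short recordings clamp to the 5-period minimum window", {
  fx <- gen_afm_trace(seed = 7, n_periods = 6)
  win <- select_steady_window(fx$trace, fx$calibration, window_periods = 8)
  expect_equal(win$W, 5L)
  fx4 <- gen_afm_trace(seed = 8, n_periods = 4)
  expect_error(select_steady_window(fx4$trace, fx4$calibration), "fewer than 5")
})

test_that("an unsteady recording raises a no-steady-state error", {
  fx <- gen_afm_trace(seed = 9, n_periods = 12)
  tr <- fx$trace
  # force amplitude keeps growing throughout: no window can qualify
  tr$force_nN <- tr$force_nN * (1 + 0.6 * tr$time_s)
  expect_error(select_steady_window(tr, fx$calibration), "no steady-state")
})

test_that("noise-free parameter recovery across the study parameter grid", {
  grid <- expand.grid(gamma0 = c(0.5, 5), K = c(5, 100), phi = c(0, 45, 90),
                      conf = c(0.6, 0.7))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fx <- gen_afm_trace(gamma0 = g$gamma0, K_true = g$K, phi_true_deg = g$phi,
                        confinement = g$conf, sigma_F = 0, seed = 100 + i)
    s <- rheology_summary(fx$trace, fx$truth$V, fx$calibration)$summary
    expect_lt(abs(s$K / g$K - 1), 0.02)
    expect_lt(abs(s$phi_deg - g$phi), 1)
    expect_lt(abs(s$gamma / g$gamma0 - 1), 0.01)
  }
})

test_that("phase from harmonic fits matches cross-correlation lag", {
  fx <- gen_afm_trace(phi_true_deg = 35, seed = 21)
  res <- rheology_summary(fx$trace, fx$truth$V, fx$calibration)
  ser <- res$series
  cc <- stats::ccf(ser$gamma_eff, ser$eps_A, lag.max = 300, plot = FALSE)
  lag_samples <- cc$lag[which.max(cc$acf)]
  dt <- median(diff(ser$time_s))
  phi_cc <- -lag_samples * dt * res$f * 360
  expect_lt(abs(cortexmech:::wrap_deg(phi_cc - res$summary$phi_deg)), 1)
  # lag time and phase are consistent
  expect_equal(res$summary$lag_s * res$f * 360, res$summary$phi_deg,
               tolerance = 1e-6)
})

test_that("longer analysis windows reduce the median noisy recovery error", {
  errs <- sapply(c(5, 10), function(W) {
    median(sapply(1:12, function(s) {
      fx <- gen_afm_trace(K_true = 20, sigma_F = 0.5, n_periods = 12,
                          seed = 900 + s)
      r <- rheology_summary(fx$trace, fx$truth$V, fx$calibration,
                            window_periods = W)$summary
      abs(r$K / 20 - 1)
    }))
  })
  expect_lte(errs[2], errs[1])
})

test_that("height-error sensitivity report brackets the point estimate", {
  fx <- gen_afm_trace(seed = 31)
  sens <- rheology_sensitivity(fx$trace, fx$truth$V, fx$calibration,
                               delta_um = 0.5)
  expect_equal(nrow(sens), 3)
  expect_equal(sens$delta_um, c(-0.5, 0, 0.5))
  # stiffness readout responds smoothly to the height calibration offset
  expect_true(all(is.finite(sens$K)))
  expect_gt(diff(range(sens$K)), 0)
})

test_that("tidy and glance expose the rheology readouts", {
  fx <- gen_afm_trace(seed = 41)
  res <- rheology_summary(fx$trace, fx$truth$V, fx$calibration)
  td <- generics::tidy(res)
  expect_equal(td$term, c("gamma", "K", "phi"))
  gl <- generics::glance(res)
  expect_equal(gl$window_periods, 8L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
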