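#' AFM calibration record
#'
#' Bundles the per-recording calibration constants needed to reconstruct the
#' confined cell height from an AFM force/piezo trace.
#'
#' @param k Cantilever spring constant (N/m), from thermal-noise calibration.
#' @param elevation_um Height the cantilever was elevated above the dish
#'   surface before being placed on the cell (µm).
#' @param spike_um Spike-height correction at the wedge boundary (µm).
#' @param piezo_ref_um Piezo reading at the surface-touch reference, so that
#'   `piezo_um - piezo_ref_um` is the lowering onto the cell (µm).
#' @param f Drive frequency of the height oscillation (Hz).
#' @param drive_amplitude_um Piezo oscillation amplitude (µm).
#'
#' @return A list of class `afm_calibration`.
#' @export
afm_calibration <- function(k, elevation_um, spike_um = 0, piezo_ref_um = 0,
                            f = 1, drive_amplitude_um = 0.25) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k <= 0) stop("spring constant k must be positive", call. = FALSE)
  if (f <= 0) stop("drive frequency f must be positive", call. = FALSE)
  structure(list(k = k, elevation_um = elevation_um, spike_um = spike_um,
                 piezo_ref_um = piezo_ref_um, f = f,
                 drive_amplitude_um = drive_amplitude_um),
            class = "afm_calibration")
}

#' Reconstruct the confined cell height from an AFM trace
#'
#' The cell height is the cantilever elevation above the dish minus the
#' lowering onto the cell (piezo travel past the surface-touch reference),
#' plus the wedge spike-height correction and the force-induced cantilever
#' deflection `F/k`.
#'
#' @param trace A data frame with columns `time_s`, `force_nN`, `piezo_um`
#'   (uniform sampling, strictly increasing time).
#' @param calibration An [afm_calibration()] object.
#'
#' @return The input tibble with an added `h_um` column.
#' @export
compute_cell_height <- function(trace, calibration) {
  trace <- validate_afm_trace(trace, calibration)
  cal <- calibration
  lowering <- trace$piezo_um - cal$piezo_ref_um
  deflection_um <- 1e-3 * trace$force_nN / cal$k  # nN / (N/m) = 1e-3 um
  h <- cal$elevation_um - lowering + cal$spike_um + deflection_um
  if (any(h <= 0)) {
    stop("corrupt calibration: reconstructed cell height is non-positive",
         call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(trace), h_um = h)
}

validate_afm_trace <- function(trace, calibration = NULL) {
  need <- c("time_s", "force_nN", "piezo_um")
  miss <- setdiff(need, names(trace))
  if (length(miss) > 0) {
    stop("AFM trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(trace$time_s) <= 0)) {
    stop("AFM trace time must be strictly increasing", call. = FALSE)
  }
  if (!is.null(calibration)) {
    fs <- 1 / stats::median(diff(trace$time_s))
    if (fs < 20 * calibration$f) {
      stop(sprintf("sampling rate %.1f Hz is below 20x the drive frequency", fs),
           call. = FALSE)
    }
  }
  trace
}

#' Per-sample tension and area strain of a confined cell
#'
#' Converts heights and forces into the stress and strain readouts of
#' confinement rheology: for every sample the constant-volume shape is solved
#' at the current plate gap, the effective tension follows from the
#' Laplace-pressure balance, and the area strain is the relative deviation of
#' total surface area from its window average.
#'
#' @param trace A tibble with columns `time_s`, `force_nN` and `h_um`
#'   (see [compute_cell_height()]).
#' @param V Cell volume (µm³), held constant over the recording.
#' @param window Optional integer vector `c(first, last)` of sample indices;
#'   the area average (and hence the strain) is taken over this window only.
#'   Default: the whole trace.
#'
#' @return A tibble of class `strain_series` with columns `time_s`, `h_um`,
#'   `force_nN`, `gamma_eff` (mN/m), `A_um2` and `eps_A`; the window average
#'   area is stored in attribute `A_mean`.
#' @export
tension_strain_series <- function(trace, V, window = NULL) {
  stopifnot(all(c("time_s", "force_nN", "h_um") %in% names(trace)))
  if (is.null(window)) window <- c(1L, nrow(trace))
  idx <- seq.int(window[1], window[2])
  sub <- trace[idx, ]
  V_min <- (4 / 3) * pi * (sub$h_um / 2)^3
  bad <- which(V < V_min)
  if (length(bad) > 0) {
    stop(sprintf("unconfined geometry at t = %.4f s: cell volume too small for gap %.3f um",
                 sub$time_s[bad[1]], sub$h_um[bad[1]]), call. = FALSE)
  }
  shp <- solve_shape(V, sub$h_um)
  gamma_eff <- effective_tension(sub$force_nN, shp)
  A_mean <- mean(shp$A)
  out <- tibble::tibble(time_s = sub$time_s, h_um = sub$h_um,
                        force_nN = sub$force_nN, gamma_eff = gamma_eff,
                        A_um2 = shp$A, eps_A = (shp$A - A_mean) / A_mean)
  attr(out, "A_mean") <- A_mean
  class(out) <- c("strain_series", class(out))
  out
}

#' Harmonic least-squares fit at a known drive frequency
#'
#' Fits `a + b*sin(2*pi*f*t) + c*cos(2*pi*f*t)` by ordinary least squares and
#' reports mean `a`, amplitude `sqrt(b^2 + c^2)` and phase `atan2(c, b)`, so
#' the fitted oscillation is `amplitude * sin(2*pi*f*t + phase)`. This is
#' exact for non-integer period counts and uses only the fundamental
#' component, which is how the rheological readouts are defined.
#'
#' @param time_s Time stamps (s).
#' @param values Signal samples.
#' @param f Drive frequency (Hz).
#' @param min_snr Amplitudes below `min_snr * residual RMS / sqrt(n)` are
#'   flagged as low SNR (the fit is still returned).
#'
#' @return A one-row tibble: `mean`, `amplitude`, `phase_rad`, `phase_deg`,
#'   `resid_rms`, `low_snr`.
#' @export
fit_oscillation <- function(time_s, values, f, min_snr = 3) {
  stopifnot(length(time_s) == length(values), length(time_s) > 3)
  s <- sin(2 * pi * f * time_s)
  c_ <- cos(2 * pi * f * time_s)
  fit <- stats::lm.fit(cbind(1, s, c_), values)
  cf <- fit$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  resid_rms <- sqrt(mean(fit$residuals^2))
  tibble::tibble(
    mean = unname(cf[1]),
    amplitude = unname(amp),
    phase_rad = unname(atan2(cf[3], cf[2])),
    phase_deg = unname(atan2(cf[3], cf[2])) * 180 / pi,
    resid_rms = resid_rms,
    low_snr = amp < min_snr * resid_rms / sqrt(length(values))
  )
}

#' Select the steady-state analysis window of an oscillatory recording
#'
#' Splits the recording into whole drive periods, measures the per-period
#' force and height oscillation amplitudes by harmonic fits, and returns the
#' latest contiguous window of `window_periods` periods in which both
#' amplitudes stay within `tol` (relative) of their window medians — i.e. an
#' interval of steady-state oscillation after the transient relaxation phase.
#'
#' @inheritParams compute_cell_height
#' @param window_periods Target window length in periods; clamped to 5–10.
#' @param tol Maximum relative deviation of any per-period amplitude from the
#'   window median (default 0.05).
#'
#' @return A list of class `steady_window`: `first`/`last` sample indices,
#'   `periods` (indices of the selected periods), `W`, and `per_period`
#'   (tibble of per-period amplitudes).
#' @export
select_steady_window <- function(trace, calibration, window_periods = 8,
                                 tol = 0.05) {
  trace <- compute_cell_height(trace, calibration)
  f <- calibration$f
  t0 <- trace$time_s[1]
  period_id <- floor((trace$time_s - t0) * f) + 1
  n_per <- max(period_id)
  # drop a trailing partial period
  cnt <- tabulate(period_id)
  if (cnt[n_per] < 0.99 * stats::median(cnt[-n_per])) n_per <- n_per - 1
  if (n_per < 5) {
    stop("recording too short: fewer than 5 whole drive periods", call. = FALSE)
  }
  W <- max(5L, min(10L, as.integer(window_periods)))
  # recordings shorter than the requested window fall back to the 5-period
  # minimum rather than silently using everything
  if (n_per < W) W <- 5L
  per_period <- purrr::map_dfr(seq_len(n_per), function(p) {
    i <- which(period_id == p)
    tibble::tibble(
      period = p,
      amp_force = fit_oscillation(trace$time_s[i], trace$force_nN[i], f)$amplitude,
      amp_height = fit_oscillation(trace$time_s[i], trace$h_um[i], f)$amplitude
    )
  })
  ok_window <- function(last) {
    ps <- (last - W + 1):last
    for (col in c("amp_force", "amp_height")) {
      a <- per_period[[col]][ps]
      m <- stats::median(a)
      if (m <= 0 || any(abs(a - m) / m > tol)) return(FALSE)
    }
    TRUE
  }
  last <- NA_integer_
  for (cand in rev(seq.int(W, n_per))) {
    if (ok_window(cand)) { last <- cand; break }
  }
  if (is.na(last)) {
    msg <- paste0(
      "no steady-state window of ", W, " periods found (tolerance ", tol, ")\n",
      paste(utils::capture.output(print(as.data.frame(per_period))), collapse = "\n")
    )
    stop(msg, call. = FALSE)
  }
  periods <- (last - W + 1):last
  idx <- which(period_id %in% periods)
  structure(list(first = min(idx), last = max(idx), periods = periods, W = W,
                 per_period = per_period),
            class = "steady_window")
}

wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Cortex rheology summary of one AFM confinement recording
#'
#' Full per-cell analysis: reconstructs the cell height, selects a
#' steady-state window, converts force and height into effective tension
#' (stress) and area strain (strain), extracts amplitude and phase of each at
#' the drive frequency by harmonic least squares, and reports
#'
#' * cortical tension `gamma` — window average of the effective tension (mN/m),
#' * cortical stiffness `K = gamma_hat / eps_hat` — ratio of the tension and
#'   strain oscillation amplitudes (mN/m),
#' * phase shift `phi = phi_gamma - phi_eps` (degrees, wrapped to
#'   (-180, 180]); 0° is an elastic solid, 90° a viscous liquid,
#' * the complex modulus `K* = K exp(i phi)`.
#'
#' @inheritParams compute_cell_height
#' @param V Cell volume (µm³), e.g. from [volume_from_equatorial_area()].
#' @inheritParams select_steady_window
#' @param min_snr Low-SNR flag threshold passed to [fit_oscillation()].
#'
#' @return An object of class `rheology_result`: a list with `summary`
#'   (one-row tibble: `gamma`, `K`, `phi_deg`, `K_star`, `gamma_amp`,
#'   `eps_amp`, `phase_gamma_deg`, `phase_eps_deg`, `lag_s`, `unphysical`,
#'   `low_snr`, residual RMS per channel), `series` (the windowed
#'   [tension_strain_series()]), `window` and the two harmonic fits.
#'   Use [generics::tidy()] / [generics::glance()] or `autoplot()`.
#' @export
rheology_summary <- function(trace, V, calibration, window_periods = 8,
                             tol = 0.05, min_snr = 3) {
  f <- calibration$f
  tr <- compute_cell_height(trace, calibration)
  win <- select_steady_window(trace, calibration, window_periods, tol)
  series <- tension_strain_series(tr, V, window = c(win$first, win$last))
  fit_g <- fit_oscillation(series$time_s, series$gamma_eff, f, min_snr)
  fit_e <- fit_oscillation(series$time_s, series$eps_A, f, min_snr)
  K <- fit_g$amplitude / fit_e$amplitude
  phi <- wrap_deg(fit_g$phase_deg - fit_e$phase_deg)
  summary <- tibble::tibble(
    gamma = mean(series$gamma_eff),
    K = K,
    phi_deg = phi,
    K_star = complex(modulus = K, argument = phi * pi / 180),
    gamma_amp = fit_g$amplitude,
    eps_amp = fit_e$amplitude,
    phase_gamma_deg = fit_g$phase_deg,
    phase_eps_deg = fit_e$phase_deg,
    lag_s = phi / 360 / f,
    resid_rms_gamma = fit_g$resid_rms,
    resid_rms_eps = fit_e$resid_rms,
    low_snr = fit_g$low_snr || fit_e$low_snr,
    unphysical = phi < -5 || phi > 95
  )
  structure(list(summary = summary, series = series, window = win,
                 fit_gamma = fit_g, fit_eps = fit_e, V = V, f = f,
                 calibration = calibration),
            class = "rheology_result")
}

#' @export
print.rheology_result <- function(x, ...) {
  s <- x$summary
  cat("Cortex rheology result (f =", x$f, "Hz, V =", round(x$V, 1), "um^3)\n")
  cat(sprintf("  cortical tension gamma = %.4g mN/m\n", s$gamma))
  cat(sprintf("  cortical stiffness K   = %.4g mN/m\n", s$K))
  cat(sprintf("  phase shift phi        = %.3g deg\n", s$phi_deg))
  cat(sprintf("  window: periods %d-%d (%d samples)\n",
              min(x$window$periods), max(x$window$periods),
              nrow(x$series)))
  if (s$low_snr) cat("  WARNING: low signal-to-noise amplitude fit\n")
  if (s$unphysical) cat("  WARNING: phase shift outside [-5, 95] deg\n")
  invisible(x)
}

#' Sensitivity of the rheology readouts to the cell-height error
#'
#' The absolute cell height carries a systematic uncertainty (wedge
#' irregularities, cantilever positioning) of about 0.5 µm. This helper
#' re-runs the analysis with the elevation calibration shifted by
#' `+/- delta_um` and reports the spread of tension, stiffness and phase.
#'
#' @inheritParams rheology_summary
#' @param delta_um Height offset applied symmetrically (µm), default 0.5.
#' @return A tibble with rows `low`, `center`, `high` and the three readouts.
#' @export
rheology_sensitivity <- function(trace, V, calibration, delta_um = 0.5, ...) {
  run <- function(dz, label) {
    cal <- calibration
    cal$elevation_um <- cal$elevation_um + dz
    s <- rheology_summary(trace, V, cal, ...)$summary
    tibble::tibble(offset = label, delta_um = dz, gamma = s$gamma, K = s$K,
                   phi_deg = s$phi_deg)
  }
  dplyr::bind_rows(run(-delta_um, "low"), run(0, "center"),
                   run(delta_um, "high"))
}
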