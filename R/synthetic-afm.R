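# All generators route randomness through local_seed() so that a given seed
# yields a bit-identical fixture without disturbing the caller's RNG state.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  restore <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

# piecewise-linear rendering of sin(2*pi*f*t): linear interpolation between
# nodes spaced 1/(f*n_seg) apart, mimicking how the piezo approximates a sine
pwl_sine <- function(t, f, n_seg = 12) {
  nodes <- seq(0, max(t) + 1 / (f * n_seg), by = 1 / (f * n_seg))
  stats::approx(nodes, sin(2 * pi * f * nodes), xout = t)$y
}

#' Simulate an AFM confinement recording with known cortex mechanics
#'
#' Forward model of oscillatory parallel-plate cell confinement. The plate
#' gap oscillates as `h(t) = h0 + dh*sin(2*pi*f*t)` (optionally rendered as a
#' piecewise-linear sine, as a piezo drive would produce). The constant-volume
#' shape model gives per-sample geometry and the area strain; the cortex
#' responds linearly on the strain's fundamental Fourier component with
#' stiffness `K_true` and phase lag `phi_true_deg` around a baseline tension
#' `gamma0`, so
#' `gamma_eff(t) = gamma0 + env(t) * K_true * eps_amp * sin(2*pi*f*t + phase_eps + phi_true)`.
#' The recorded force is `gamma_eff * A_con * (1/R1 + 1/R2)` plus Gaussian
#' sensor noise, and the piezo channel is built so that height reconstruction
#' inverts exactly.
#'
#' @param gamma0 Baseline cortical tension (mN/m).
#' @param K_true Cortical stiffness (mN/m).
#' @param phi_true_deg Phase shift of the cortex response (degrees; 0 elastic,
#'   90 viscous).
#' @param free_diameter_um Diameter of the unconfined (spherical) cell (µm);
#'   sets the volume.
#' @param confinement Confined height as a fraction of the free height
#'   (default 0.65, i.e. 60–70% regime).
#' @param dh_um Height oscillation amplitude (µm).
#' @param f Drive frequency (Hz).
#' @param fs Sampling rate (Hz).
#' @param n_periods Number of drive periods recorded.
#' @param sigma_F Gaussian force-noise SD (nN); 0 for a noise-free trace.
#' @param transient_tau_s If positive, the oscillatory force component is
#'   multiplied by `1 - exp(-t/tau)` to mimic the transient relaxation phase.
#' @param pwl_drive Render the drive as a piecewise-linear sine (default
#'   FALSE: exact sine).
#' @param k Cantilever spring constant (N/m).
#' @param seed Integer seed; the same seed gives a bit-identical fixture.
#'
#' @return A list of class `synthetic_afm`: `trace` (tibble `time_s`,
#'   `force_nN`, `piezo_um`), `calibration` ([afm_calibration()]) and `truth`
#'   (one-row tibble of all ground-truth parameters, including the realised
#'   fundamental strain amplitude/phase).
#' @export
gen_afm_trace <- function(gamma0 = 1.5, K_true = 20, phi_true_deg = 30,
                          free_diameter_um = 20, confinement = 0.65,
                          dh_um = 0.25, f = 1, fs = 500, n_periods = 12,
                          sigma_F = 0, transient_tau_s = 0, pwl_drive = FALSE,
                          k = 0.5, seed = NULL) {
  local_seed(seed)
  R_free <- free_diameter_um / 2
  V <- (4 / 3) * pi * R_free^3
  h0 <- confinement * free_diameter_um
  if ((4 / 3) * pi * ((h0 + dh_um) / 2)^3 > V) {
    stop("infeasible geometry: confinement height exceeds free cell height",
         call. = FALSE)
  }
  t <- seq(0, n_periods / f - 1 / fs, by = 1 / fs)
  drive <- if (pwl_drive) pwl_sine(t, f) else sin(2 * pi * f * t)
  h <- h0 + dh_um * drive
  shp <- solve_shape(V, h)
  A_mean <- mean(shp$A)
  eps_A <- (shp$A - A_mean) / A_mean
  fe <- fit_oscillation(t, eps_A, f)
  env <- if (transient_tau_s > 0) 1 - exp(-t / transient_tau_s) else rep(1, length(t))
  osc <- K_true * fe$amplitude * sin(2 * pi * f * t + fe$phase_rad +
                                       phi_true_deg * pi / 180)
  gamma_eff <- gamma0 + env * osc
  F_clean <- gamma_eff * shp$A_con * (1 / shp$R1 + 1 / shp$R2)
  F_nN <- F_clean + if (sigma_F > 0) stats::rnorm(length(t), 0, sigma_F) else 0
  cal <- afm_calibration(k = k, elevation_um = h0 + 5, spike_um = 0.5,
                         piezo_ref_um = 0, f = f, drive_amplitude_um = dh_um)
  # invert the height reconstruction so compute_cell_height() returns h exactly
  piezo <- cal$elevation_um + cal$spike_um + 1e-3 * F_nN / cal$k - h
  trace <- tibble::tibble(time_s = t, force_nN = F_nN, piezo_um = piezo)
  truth <- tibble::tibble(
    gamma0 = gamma0, K_true = K_true, phi_true_deg = phi_true_deg,
    V = V, h0 = h0, dh_um = dh_um, f = f, fs = fs, n_periods = n_periods,
    sigma_F = sigma_F, transient_tau_s = transient_tau_s,
    eps_amp_true = fe$amplitude, eps_phase_true_deg = fe$phase_deg,
    seed = if (is.null(seed)) NA_integer_ else seed
  )
  structure(list(trace = trace, calibration = cal, truth = truth),
            class = "synthetic_afm")
}

#' Simulate a cohort of cells with group-structured cortex mechanics
#'
#' Draws per-cell rheological parameters from lognormal distributions whose
#' medians differ between experimental groups, mimicking a two-condition
#' (e.g. pre/post EMT) by two-cell-state (interphase/mitosis) comparison.
#' The default design encodes the qualitative directions seen after EMT
#' induction: interphase tension and stiffness drop, mitotic tension and
#' stiffness rise, and the mitotic phase shift drops. Effect sizes are user
#' parameters, not literature values.
#'
#' @param n_per_group Cells per (condition, phase) group.
#' @param effect Relative shift of post-condition medians for tension and
#'   stiffness (e.g. 0.5 = 50%); the phase-shift effect is `-effect/2 * phi`
#'   applied in mitosis only.
#' @param cv Lognormal coefficient of variation of every parameter.
#' @param base Named list of pre-condition medians per phase:
#'   `interphase = c(gamma, K, phi_deg)`, `mitosis = c(gamma, K, phi_deg)`.
#' @param generate_traces If `TRUE`, also synthesise one noise-free-geometry
#'   AFM trace per cell (with force noise `sigma_F`) so the full pipeline can
#'   be run on the cohort.
#' @param sigma_F Force-noise SD for generated traces (nN).
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_cohort`: `truth` (tibble with one row
#'   per cell: `cell_id`, `condition` pre/post, `phase`
#'   interphase/mitosis, true `gamma`, `K`, `phi_deg`, per-cell seed) and
#'   `traces` (list of [gen_afm_trace()] fixtures, or `NULL`).
#' @export
gen_cohort <- function(n_per_group = 25, effect = 0.5, cv = 0.2,
                       base = list(interphase = c(gamma = 1.5, K = 20, phi_deg = 25),
                                   mitosis = c(gamma = 2.5, K = 40, phi_deg = 25)),
                       generate_traces = FALSE, sigma_F = 0.1, seed = NULL) {
  if (n_per_group < 3) stop("design error: need at least 3 cells per group",
                            call. = FALSE)
  local_seed(seed)
  design <- tidyr::expand_grid(condition = c("pre", "post"),
                               phase = c("interphase", "mitosis"))
  draw <- function(median, cv, n) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
  }
  truth <- purrr::pmap_dfr(design, function(condition, phase) {
    b <- base[[phase]]
    mult <- if (condition == "pre") c(1, 1, 1) else {
      if (phase == "interphase") c(1 - effect / 2, 1 - effect / 2, 1)
      else c(1 + effect, 1 + effect, 1 - effect / 2)
    }
    med <- b * mult
    tibble::tibble(
      condition = condition, phase = phase,
      gamma = draw(med[["gamma"]], cv, n_per_group),
      K = draw(med[["K"]], cv, n_per_group),
      phi_deg = pmin(draw(med[["phi_deg"]], cv, n_per_group), 89)
    )
  })
  truth <- dplyr::mutate(truth,
                         cell_id = sprintf("cell%03d", dplyr::row_number()),
                         cell_seed = sample.int(.Machine$integer.max %/% 2,
                                                dplyr::n()),
                         .before = 1)
  traces <- NULL
  if (generate_traces) {
    traces <- purrr::pmap(
      list(truth$gamma, truth$K, truth$phi_deg, truth$cell_seed),
      function(g, K, phi, s) {
        gen_afm_trace(gamma0 = g, K_true = K, phi_true_deg = phi,
                      sigma_F = sigma_F, seed = s)
      })
    names(traces) <- truth$cell_id
  }
  structure(list(truth = truth, traces = traces), class = "synthetic_cohort")
}

#' Analyse a simulated cohort with the full rheology pipeline
#'
#' Runs [rheology_summary()] on every generated trace of a
#' [gen_cohort()] fixture and returns a tidy per-cell table of recovered
#' tension, stiffness and phase shift alongside the group labels.
#'
#' @param cohort A `synthetic_cohort` with `generate_traces = TRUE`.
#' @param ... Passed to [rheology_summary()].
#' @return A tibble: `cell_id`, `condition`, `phase`, `gamma`, `K`, `phi_deg`.
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$traces)) {
    stop("cohort was generated without traces; rerun gen_cohort(generate_traces = TRUE)",
         call. = FALSE)
  }
  res <- purrr::map_dfr(cohort$traces, function(fx) {
    s <- rheology_summary(fx$trace, fx$truth$V, fx$calibration, ...)$summary
    tibble::tibble(gamma = s$gamma, K = s$K, phi_deg = s$phi_deg)
  }, .id = "cell_id")
  dplyr::left_join(dplyr::select(cohort$truth, "cell_id", "condition", "phase"),
                   res, by = "cell_id")
}
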