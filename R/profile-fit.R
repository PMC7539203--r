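#' Error function
#'
#' `erf(x) = 2*pnorm(x*sqrt(2)) - 1`, used throughout the radial profile
#' model.
#' @param x Numeric.
#' @return Numeric.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Radial intensity model of an equatorial cortex profile
#'
#' The circumference-averaged radial fluorescence profile of a round cell is
#' modelled as a smoothed cytoplasmic step, a skewed-Gaussian cortical peak
#' and a constant background:
#'
#' \deqn{I(r) = I_{cyt}\,\tfrac12\left[1 - \mathrm{erf}\!\left(\frac{r-\mu}{\sigma_1\sqrt2}\right)\right]
#'   + I_{cort}\, e^{-\frac{(r-\mu)^2}{2\sigma_2^2}}
#'     \left[1 + \mathrm{erf}\!\left(\frac{\alpha (r-\mu)}{\sigma_2\sqrt2}\right)\right] + I_{BG}}
#'
#' The Gaussian is unit-peak so `I_cort` is an intensity amplitude. `r` is
#' boundary-centred: negative values lie inside the cell, positive outside,
#' and `mu` locates the cell boundary. The erf arguments use the
#' standardised residual `(r - mu)/(sigma*sqrt(2))` (standard skew-normal
#' convention).
#'
#' @param r Radial coordinate (µm, boundary-centred).
#' @param mu Boundary location (µm).
#' @param sigma1 Cytoplasm edge smearing (µm).
#' @param sigma2 Cortex peak width (µm).
#' @param I_cyt Cytoplasmic amplitude (a.u.).
#' @param I_cort Cortical peak amplitude (a.u.).
#' @param I_BG Background (a.u.).
#' @param alpha Skewness (dimensionless; 0 = symmetric peak).
#' @return Model intensity at `r`.
#' @export
cortex_profile_model <- function(r, mu, sigma1, sigma2, I_cyt, I_cort, I_BG,
                                 alpha = 0) {
  step <- I_cyt * 0.5 * (1 - erf((r - mu) / (sigma1 * sqrt(2))))
  peak <- I_cort * exp(-(r - mu)^2 / (2 * sigma2^2)) *
    (1 + erf(alpha * (r - mu) / (sigma2 * sqrt(2))))
  step + peak + I_BG
}

new_radial_profile <- function(r_um, intensity, n_lines = NA_integer_,
                               px_size_um = NA_real_) {
  stopifnot(length(r_um) == length(intensity))
  if (any(diff(r_um) <= 0)) stop("r must be strictly increasing", call. = FALSE)
  if (length(r_um) < 20) stop("profile too short (< 20 samples)", call. = FALSE)
  out <- tibble::tibble(r_um = r_um, intensity = intensity)
  attr(out, "n_lines") <- n_lines
  attr(out, "px_size_um") <- px_size_um
  class(out) <- c("radial_profile", class(out))
  out
}

#' Fit the cortex profile model to a radial intensity profile
#'
#' Nonlinear least squares (Levenberg–Marquardt) over the parameters
#' `{mu, sigma1, sigma2, I_cyt, I_cort, I_BG, alpha}` of
#' [cortex_profile_model()]. Initialisation is deterministic: `mu` at the
#' profile maximum, `I_BG` as the median of the outer 10% tail, `I_cyt` as
#' the inner 10% median minus `I_BG`, `I_cort` from the peak height above the
#' cytoplasmic plateau, `sigma1 = sigma2 =` three sample steps, `alpha = 0`.
#' On non-convergence up to `restarts` retries are made with deterministic
#' jitter of the width initialisations.
#'
#' @param profile A data frame with columns `r_um` (strictly increasing,
#'   spanning the boundary) and `intensity`, e.g. from [radial_profile()] or
#'   [read_radial_profile()].
#' @param skewed Fit the skewness `alpha` (`TRUE`) or fix it to zero
#'   (`FALSE`, as used for thickness estimation).
#' @param restarts Maximum number of jittered re-initialisations.
#'
#' @return An object of class `profile_fit`: a list with `par` (one-row
#'   tibble of the seven parameters plus `I2D_cortex`, `ratio_um`,
#'   `resid_rms`), `data`, `fitted` and `skewed`. See [cortex_ratio()],
#'   [estimate_thickness()], `tidy()`, `autoplot()`.
#' @export
fit_profile <- function(profile, skewed = TRUE, restarts = 5) {
  r <- profile$r_um
  I <- profile$intensity
  stopifnot(length(r) >= 20)
  dr <- stats::median(diff(r))
  n_tail <- max(3L, round(0.1 * length(r)))
  I_BG0 <- stats::median(utils::tail(I, n_tail))
  I_cyt0 <- max(stats::median(utils::head(I, n_tail)) - I_BG0, 1e-6)
  mu0 <- r[which.max(I)]
  # fallback boundary guess for peak-free profiles: steepest descent of the
  # lightly smoothed profile
  I_sm <- stats::filter(I, rep(1 / 5, 5), sides = 2)
  mu_step <- r[which.min(diff(I_sm[!is.na(I_sm)])) + 2]
  I_cort0 <- max(max(I) - I_BG0 - I_cyt0 / 2, 1e-3 * I_cyt0)
  s0 <- 3 * dr
  lower <- c(mu = min(r), sigma1 = dr / 4, sigma2 = dr / 4, I_cyt = 0,
             I_cort = 0, I_BG = -Inf)
  upper <- c(mu = max(r), sigma1 = diff(range(r)), sigma2 = diff(range(r)),
             I_cyt = Inf, I_cort = Inf, I_BG = Inf)
  if (skewed) {
    lower <- c(lower, alpha = -20)
    upper <- c(upper, alpha = 20)
  }
  dat <- data.frame(r = r, I = I)
  form <- if (skewed) {
    I ~ cortex_profile_model(r, mu, sigma1, sigma2, I_cyt, I_cort, I_BG, alpha)
  } else {
    I ~ cortex_profile_model(r, mu, sigma1, sigma2, I_cyt, I_cort, I_BG, 0)
  }
  # deterministic multi-start: width jitter ladder x skewness grid; the fit
  # with the smallest residual RMS wins (skewed profiles have local optima)
  jit <- c(1, 0.5, 2, 0.25, 4, 8)[seq_len(min(restarts + 1, 6))]
  alpha0 <- if (skewed) c(0, 1, -1, 3, -3) else 0
  # the near-zero cortex start goes first so peak-free profiles settle at
  # I_cort = 0 instead of a degenerate shifted-step + tiny-peak solution
  starts <- rbind(expand.grid(jit = 1, alpha = 0, cort_fac = 1e-3,
                              mu = unique(c(mu_step, mu0))),
                  expand.grid(jit = jit, alpha = alpha0, cort_fac = 1,
                              mu = mu0))
  fit <- NULL
  best_rms <- Inf
  tried <- character(0)
  for (j in seq_len(nrow(starts))) {
    start <- list(mu = starts$mu[j], sigma1 = s0 * starts$jit[j],
                  sigma2 = s0 * starts$jit[j],
                  I_cyt = I_cyt0, I_cort = I_cort0 * starts$cort_fac[j],
                  I_BG = I_BG0)
    if (skewed) start$alpha <- starts$alpha[j]
    tried <- c(tried, sprintf("sigma init %.3g, alpha init %g",
                              s0 * starts$jit[j], starts$alpha[j]))
    cand <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rms <- sqrt(mean(stats::resid(cand)^2))
    if (rms < best_rms) {
      best_rms <- rms
      fit <- cand
    }
    if (best_rms < 1e-6 * max(abs(I))) break
  }
  if (is.null(fit)) {
    stop("profile fit failed to converge; initialisations tried: ",
         paste(tried, collapse = "; "), call. = FALSE)
  }
  cf <- as.list(stats::coef(fit))
  if (!skewed) cf$alpha <- 0
  # parsimony guard: a peak-free profile is fit equally well (the peak term
  # is then non-identifiable); prefer the reduced step-only model when it
  # loses essentially nothing
  red <- tryCatch(
    minpack.lm::nlsLM(I ~ cortex_profile_model(r, mu, sigma1, 1, I_cyt, 0,
                                               I_BG, 0),
                      data = dat,
                      start = list(mu = mu_step, sigma1 = s0 * 3,
                                   I_cyt = I_cyt0, I_BG = I_BG0),
                      lower = lower[c("mu", "sigma1", "I_cyt", "I_BG")],
                      upper = upper[c("mu", "sigma1", "I_cyt", "I_BG")],
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(red)) {
    rms_red <- sqrt(mean(stats::resid(red)^2))
    if (rms_red <= 1.02 * sqrt(mean(stats::resid(fit)^2))) {
      cr <- as.list(stats::coef(red))
      cf <- list(mu = cr$mu, sigma1 = cr$sigma1, sigma2 = s0,
                 I_cyt = cr$I_cyt, I_cort = 0, I_BG = cr$I_BG, alpha = 0)
    }
  }
  fitted_I <- cortex_profile_model(r, cf$mu, cf$sigma1, cf$sigma2, cf$I_cyt,
                                   cf$I_cort, cf$I_BG, cf$alpha)
  par <- tibble::tibble(
    mu = cf$mu, sigma1 = cf$sigma1, sigma2 = cf$sigma2, I_cyt = cf$I_cyt,
    I_cort = cf$I_cort, I_BG = cf$I_BG, alpha = cf$alpha,
    I2D_cortex = cf$I_cort * cf$sigma2 * sqrt(2 * pi),
    ratio_um = cf$I_cort * cf$sigma2 * sqrt(2 * pi) / cf$I_cyt,
    resid_rms = sqrt(mean((I - fitted_I)^2))
  )
  structure(list(par = par, data = tibble::as_tibble(dat),
                 fitted = fitted_I, skewed = skewed),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat("Cortex radial-profile fit (skewness ",
      if (x$skewed) "free" else "fixed to 0", ")\n", sep = "")
  print(as.data.frame(round(x$par, 4)), row.names = FALSE)
  invisible(x)
}

#' Cortex-to-cytoplasm ratio from a profile fit
#'
#' Integrates the skewed-Gaussian cortical component of the fitted profile
#' along the radial direction and normalises by the cytoplasmic amplitude.
#' The integral has the closed form `I_cort * sigma2 * sqrt(2*pi)` — the odd
#' erf term integrates to zero for every skewness — so the ratio is
#' `I_cort * sigma2 * sqrt(2*pi) / I_cyt`, with units of µm.
#'
#' @param fit A [fit_profile()] result.
#' @return The cortex-to-cytoplasm ratio (µm), numeric.
#' @export
cortex_ratio <- function(fit) {
  stopifnot(inherits(fit, "profile_fit"))
  p <- fit$par
  if (p$I_cyt <= 0) {
    stop("undefined ratio: fitted cytoplasmic amplitude I_cyt <= 0",
         call. = FALSE)
  }
  p$I_cort * p$sigma2 * sqrt(2 * pi) / p$I_cyt
}

#' Cortical thickness from paired actin and membrane profile fits
#'
#' With a membrane dye marking the outer surface and an F-actin label marking
#' the cortex, the fitted peak positions of the two circumference-averaged
#' profiles differ by about half the cortical thickness; twice the offset is
#' reported as the thickness estimate. Both fits should use a symmetric peak
#' (`skewed = FALSE`).
#'
#' @param fit_actin [fit_profile()] result of the F-actin channel.
#' @param fit_membrane [fit_profile()] result of the membrane-dye channel.
#' @return A one-row tibble: `thickness_um = 2*(mu_membrane - mu_actin)`,
#'   the two peak positions, and `unphysical` (`TRUE` when the estimate is
#'   negative, i.e. the actin peak lies outside the membrane peak).
#' @export
estimate_thickness <- function(fit_actin, fit_membrane) {
  stopifnot(inherits(fit_actin, "profile_fit"),
            inherits(fit_membrane, "profile_fit"))
  if (fit_actin$skewed || fit_membrane$skewed) {
    warning("thickness estimation expects symmetric fits (skewed = FALSE)")
  }
  th <- 2 * (fit_membrane$par$mu - fit_actin$par$mu)
  tibble::tibble(thickness_um = th, mu_actin = fit_actin$par$mu,
                 mu_membrane = fit_membrane$par$mu, unphysical = th < 0)
}
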