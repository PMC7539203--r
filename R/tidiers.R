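#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the readouts of a rheology result
#'
#' @param x A [rheology_summary()] result.
#' @param ... Unused.
#' @return A tibble with one row per readout: `term`, `estimate`, `unit`.
#' @export
tidy.rheology_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    term = c("gamma", "K", "phi"),
    estimate = c(s$gamma, s$K, s$phi_deg),
    unit = c("mN/m", "mN/m", "deg")
  )
}

#' @rdname tidy.rheology_result
#' @return `glance()`: the one-row summary tibble with fit diagnostics.
#' @export
glance.rheology_result <- function(x, ...) {
  dplyr::mutate(x$summary, n_samples = nrow(x$series),
                window_periods = x$window$W, f_Hz = x$f, V_um3 = x$V)
}

#' Tidy a radial-profile fit
#'
#' @param x A [fit_profile()] result.
#' @param ... Unused.
#' @return One row per fitted parameter: `term`, `estimate`.
#' @export
tidy.profile_fit <- function(x, ...) {
  p <- x$par[c("mu", "sigma1", "sigma2", "I_cyt", "I_cort", "I_BG", "alpha")]
  tidyr::pivot_longer(p, dplyr::everything(), names_to = "term",
                      values_to = "estimate")
}

#' @rdname tidy.profile_fit
#' @return `glance()`: one row with derived quantities and fit diagnostics.
#' @export
glance.profile_fit <- function(x, ...) {
  dplyr::mutate(x$par, skewed = x$skewed, n = nrow(x$data))
}

#' Tidy a Mann-Whitney group comparison
#'
#' @param x A [mann_whitney()] result.
#' @param ... Unused.
#' @return The one-row comparison tibble.
#' @export
tidy.group_comparison <- function(x, ...) x$comparison

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::bind_cols(x$comparison["p_value"],
                   tidyr::pivot_wider(x$groups[c("group", "n", "median")],
                                      names_from = "group",
                                      values_from = c("n", "median")))
}
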