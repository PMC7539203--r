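#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot stress and strain oscillations of a rheology result
#'
#' Overlays the windowed effective-tension and area-strain series with their
#' fitted fundamental sinusoids, on separate facets.
#'
#' @param object A [rheology_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rheology_result <- function(object, ...) {
  s <- object$series
  f <- object$f
  model <- function(fit) fit$mean + fit$amplitude *
    sin(2 * pi * f * s$time_s + fit$phase_rad)
  df <- dplyr::bind_rows(
    tibble::tibble(time_s = s$time_s, value = s$gamma_eff,
                   fitted = model(object$fit_gamma),
                   channel = "effective tension (mN/m)"),
    tibble::tibble(time_s = s$time_s, value = s$eps_A,
                   fitted = model(object$fit_eps),
                   channel = "area strain")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("gamma = %.2f mN/m, K = %.1f mN/m, phi = %.1f deg",
                      object$summary$gamma, object$summary$K,
                      object$summary$phi_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a radial profile and its fitted model
#'
#' @param object A [fit_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$I), size = 0.8,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$par$mu, linetype = 2) +
    ggplot2::labs(x = "radial coordinate r (um, exterior positive)",
                  y = "intensity (a.u.)",
                  title = sprintf("cortex/cytoplasm ratio = %.3f um",
                                  object$par$ratio_um)) +
    ggplot2::theme_minimal()
}

#' Annotated boxplot of a two-group comparison
#'
#' @param object A [mann_whitney()] result.
#' @param ... Unused.
#' @return A ggplot object with the significance tier annotated.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(group = object$labels[1], value = object$values$a),
    tibble::tibble(group = object$labels[2], value = object$values$b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = 1) +
    ggplot2::annotate("text", x = 1.5, y = max(df$value),
                      label = object$comparison$tier, vjust = -0.3) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = sprintf("Mann-Whitney two-tailed p = %.3g",
                                     object$comparison$p_value)) +
    ggplot2::theme_minimal()
}

#' Boxplots of cohort readouts by condition and phase
#'
#' @param data A tidy per-cell tibble (see [cohort_stats()]).
#' @param metric Column to plot (default `"gamma"`).
#' @return A ggplot object faceted by phase.
#' @export
plot_cohort <- function(data, metric = "gamma") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$condition,
                                     y = .data[[metric]])) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = 1) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
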