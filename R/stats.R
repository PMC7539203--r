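mw_u_statistic <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  rk <- rank(c(a, b))
  sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
}

# exact permutation null of U by full enumeration of group assignments
mw_exact_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  rk <- rank(c(a, b))
  mu <- n_a * n_b / 2
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  dev_obs <- abs(u_obs - mu)
  sums <- utils::combn(n_a + n_b, n_a, FUN = function(i) sum(rk[i]))
  u_all <- sums - n_a * (n_a + 1) / 2
  mean(abs(u_all - mu) >= dev_obs - 1e-9)
}

mw_asymptotic_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  n <- n_a + n_b
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- table(rk)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

significance_tier <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

boxplot_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  tibble::tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
                 whisker_hi = max(x[x <= q[3] + 1.5 * iqr]))
}

#' Two-tailed Mann–Whitney U test with boxplot summaries
#'
#' Rank-sum U statistic with midrank tie handling. For combined sample sizes
#' up to `exact_max` the two-tailed p-value is exact, from full enumeration
#' of all group assignments of the (mid)ranks — valid with ties; above that
#' a normal approximation with tie-corrected variance and continuity
#' correction is used. Per-group five-number boxplot summaries (median,
#' quartiles, whiskers at 1.5 IQR) and the significance tier
#' (ns / * / ** / *** at 0.05 / 0.01 / 0.001) are attached.
#'
#' @param a,b Numeric vectors (each of length at least 3).
#' @param labels Length-2 character group labels.
#' @param exact_max Combined-n threshold for the exact enumeration
#'   (default 20).
#'
#' @return An object of class `group_comparison`: list with `comparison`
#'   (one-row tibble: `U`, `p_value`, `method`, `tier`,
#'   `median_diff` = median(b) - median(a)) and `groups` (per-group summary
#'   tibble). `tidy()` returns the comparison row; `autoplot()` draws the
#'   annotated boxplot.
#' @export
mann_whitney <- function(a, b, labels = c("a", "b"), exact_max = 20) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    warning("degenerate test: all values identical across both groups; p = 1")
    p <- 1
    method <- "degenerate"
  } else if (length(a) + length(b) <= exact_max) {
    p <- mw_exact_p(a, b)
    method <- "exact enumeration"
  } else {
    p <- mw_asymptotic_p(a, b)
    method <- "normal approximation, tie-corrected"
  }
  comparison <- tibble::tibble(
    group_a = labels[1], group_b = labels[2],
    U = mw_u_statistic(a, b), p_value = p, method = method,
    tier = significance_tier(p),
    median_diff = stats::median(b) - stats::median(a)
  )
  groups <- dplyr::bind_rows(
    dplyr::mutate(boxplot_summary(a), group = labels[1], .before = 1),
    dplyr::mutate(boxplot_summary(b), group = labels[2], .before = 1)
  )
  structure(list(comparison = comparison, groups = groups,
                 values = list(a = a, b = b), labels = labels),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  c_ <- x$comparison
  cat(sprintf("Mann-Whitney U test (%s): %s vs %s\n", c_$method,
              c_$group_a, c_$group_b))
  cat(sprintf("  U = %g, two-tailed p = %.4g  [%s]\n", c_$U, c_$p_value,
              c_$tier))
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' One-sample test of relative changes against unity
#'
#' One-sided univariate t-test of the hypothesis that the mean of a set of
#' relative changes (e.g. band-intensity ratios against control) is larger
#' or smaller than one.
#'
#' @param ratios Numeric vector of relative changes (n >= 3).
#' @param direction `"greater"` or `"less"`: the alternative hypothesis for
#'   the mean relative to 1.
#' @return A one-row tibble: `estimate` (mean ratio), `statistic`, `df`,
#'   `p_value`, `direction`.
#' @export
relative_change_test <- function(ratios, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(ratios) < 3) stop("need at least 3 ratios", call. = FALSE)
  if (stats::sd(ratios) == 0) {
    warning("degenerate test: zero variance in ratios")
    m <- mean(ratios)
    p <- if (m == 1) 0.5 else if ((m > 1) == (direction == "greater")) 0 else 1
    return(tibble::tibble(estimate = m, statistic = NA_real_,
                          df = length(ratios) - 1, p_value = p,
                          direction = direction))
  }
  tt <- stats::t.test(ratios, mu = 1, alternative = direction)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 direction = direction)
}

#' Group comparisons of cohort rheology readouts
#'
#' For each cell state (e.g. interphase/mitosis) and each mechanical readout
#' (`gamma`, `K`, `phi_deg`), compares the two conditions with a two-tailed
#' Mann–Whitney U test and reports the direction of the median change.
#'
#' @param data A tidy per-cell tibble with columns `condition` (two levels),
#'   `phase`, and the metric columns.
#' @param metrics Character vector of metric column names.
#' @param ref Reference (baseline) level of `condition`; the reported
#'   `median_diff` is other minus `ref`.
#' @return A tibble: `phase`, `metric`, `U`, `p_value`, `tier`,
#'   `median_diff`, `direction` (sign of `median_diff`).
#' @export
cohort_stats <- function(data, metrics = c("gamma", "K", "phi_deg"),
                         ref = "pre") {
  stopifnot(all(c("condition", "phase", metrics) %in% names(data)))
  lv <- unique(data$condition)
  if (length(lv) != 2 || !(ref %in% lv)) {
    stop("condition must have exactly two levels including the reference",
         call. = FALSE)
  }
  other <- setdiff(lv, ref)
  tidyr::expand_grid(phase = unique(data$phase), metric = metrics) |>
    purrr::pmap_dfr(function(phase, metric) {
      sub <- data[data$phase == phase, ]
      a <- sub[[metric]][sub$condition == ref]
      b <- sub[[metric]][sub$condition == other]
      cmp <- mann_whitney(a, b, labels = c(ref, other))$comparison
      tibble::tibble(phase = phase, metric = metric, U = cmp$U,
                     p_value = cmp$p_value, tier = cmp$tier,
                     median_diff = cmp$median_diff,
                     direction = sign(cmp$median_diff))
    })
}
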