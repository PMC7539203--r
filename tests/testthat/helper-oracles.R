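# Independent numerical oracles used across the suite.

# Volume of the circular-arc confined shape by solid-of-revolution quadrature:
# profile x(z) = r_con + sqrt(R2^2 - z^2), z in [-h/2, h/2], V = pi * int x^2 dz
quad_volume <- function(R1, h) {
  R2 <- h / 2
  r_con <- R1 - R2
  f <- function(z) (r_con + sqrt(pmax(R2^2 - z^2, 0)))^2
  pi * stats::integrate(f, -R2, R2, rel.tol = 1e-10)$value
}

# Lateral surface area by 2*pi*int x ds over the arc, parameterised by the
# polar angle of the meridional circle; caps added analytically.
quad_area <- function(R1, h, include_caps = TRUE) {
  R2 <- h / 2
  r_con <- R1 - R2
  f <- function(theta) (r_con + R2 * cos(theta)) * R2
  a_lat <- 2 * pi * stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-10)$value
  a_lat + if (include_caps) 2 * pi * r_con^2 else 0
}

# Brute-force two-tailed Mann-Whitney p: U from pairwise comparisons (not
# rank sums) and full enumeration of index assignments.
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  u_of <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  mu <- n_a * (n - n_a) / 2
  u_obs <- u_of(seq_len(n_a))
  u_all <- utils::combn(n, n_a, FUN = u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Numerical integral of the skewed-Gaussian cortical component
quad_cortex_integral <- function(I_cort, mu, sigma2, alpha) {
  f <- function(r) {
    I_cort * exp(-(r - mu)^2 / (2 * sigma2^2)) *
      (1 + cortexmech::erf(alpha * (r - mu) / (sigma2 * sqrt(2))))
  }
  stats::integrate(f, mu - 40 * sigma2, mu + 40 * sigma2,
                   rel.tol = 1e-12, subdivisions = 1000)$value
}

# Binary mask of a filled ellipse, optionally rotated, on an n x n grid
ellipse_mask <- function(a_px, b_px, n = 2 * ceiling(max(a_px, b_px)) + 21,
                         angle_deg = 0, center = c((n + 1) / 2, (n + 1) / 2)) {
  th <- angle_deg * pi / 180
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  dx <- g$x - center[1]; dy <- g$y - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  matrix((u^2 / a_px^2 + v^2 / b_px^2 <= 1) * 1L, nrow = n)
}
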