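#' Confined-cell geometry from the equatorial radius
#'
#' Models a non-adherent cell squeezed between two parallel plates as a
#' surface of minimal area at constant volume, realised as the standard
#' circular-arc (constant-mean-curvature) profile with a 90-degree contact
#' angle at each plate. Under that closed form the meridional profile radius
#' is `R2 = h/2` and the contact radius is `r_con = R1 - h/2`.
#'
#' All lengths are in micrometres, areas in µm² and volumes in µm³.
#'
#' @param R1 Equatorial radius of the confined cell (µm).
#' @param h Plate gap, i.e. confined cell height (µm). Must satisfy
#'   `R1 >= h/2`; equality is the free-sphere limit with zero plate contact.
#' @param include_caps Should the total surface area `A` include the two
#'   plate-contact disks? The cortex covers the whole cell surface, so the
#'   default is `TRUE`; set `FALSE` to restrict `A` to the free (lateral)
#'   surface.
#'
#' @return A one-row tibble of class `cell_shape` with columns `h`, `V`,
#'   `R1`, `R2`, `r_con`, `A_con` (contact area per plate), `A_lat`
#'   (lateral surface area) and `A` (total surface area).
#'
#' @examples
#' cell_shape(R1 = 10, h = 10)
#' # free sphere of radius 5: no plate contact
#' cell_shape(R1 = 5, h = 10)
#' @export
cell_shape <- function(R1, h, include_caps = TRUE) {
  stopifnot(is.numeric(R1), is.numeric(h), length(R1) == length(h) || length(h) == 1L)
  if (any(h <= 0)) stop("plate gap h must be positive", call. = FALSE)
  if (any(R1 < h / 2 - 1e-12 * h)) {
    stop("unconfined geometry: R1 < h/2, the cell does not span the plate gap",
         call. = FALSE)
  }
  R2 <- h / 2
  r_con <- pmax(R1 - R2, 0)
  A_con <- pi * r_con^2
  V <- pi * (2 * R2 * r_con^2 + pi * r_con * R2^2 + (4 / 3) * R2^3)
  A_lat <- 2 * pi * R2 * (pi * r_con + 2 * R2)
  A <- A_lat + if (include_caps) 2 * A_con else 0
  out <- tibble::tibble(h = h + 0 * R1, V = V, R1 = R1, R2 = R2 + 0 * R1,
                        r_con = r_con, A_con = A_con, A_lat = A_lat, A = A)
  class(out) <- c("cell_shape", class(out))
  out
}

#' Confined-cell geometry from volume and plate gap
#'
#' Inverts the closed-form volume of the circular-arc profile for the contact
#' radius at fixed volume `V` and plate gap `h`. The volume is quadratic in
#' `r_con`; the unique non-negative root is taken, so
#' `solve_shape(cell_shape(R1, h)$V, h)` returns `R1` exactly (to round-off).
#'
#' @param V Cell volume (µm³). Vectorised over `V` and/or `h`.
#' @param h Plate gap (µm).
#' @inheritParams cell_shape
#'
#' @return A `cell_shape` tibble, one row per input.
#' @seealso [cell_shape()], [volume_from_equatorial_area()]
#' @examples
#' solve_shape(V = 2542.6, h = 10)
#' @export
solve_shape <- function(V, h, include_caps = TRUE) {
  stopifnot(is.numeric(V), is.numeric(h))
  if (any(h <= 0)) stop("plate gap h must be positive", call. = FALSE)
  R2 <- h / 2
  V_min <- (4 / 3) * pi * R2^3
  if (any(V < V_min * (1 - 1e-12))) {
    stop("cell too small to touch both plates: V < (4/3)*pi*(h/2)^3",
         call. = FALSE)
  }
  # pi*(2*R2*r^2 + pi*R2^2*r + (4/3)*R2^3) = V  =>  a r^2 + b r + c = 0
  a <- 2 * R2
  b <- pi * R2^2
  cc <- (4 / 3) * R2^3 - V / pi
  disc <- pmax(b^2 - 4 * a * cc, 0)
  r_con <- (-b + sqrt(disc)) / (2 * a)
  cell_shape(R1 = R2 + pmax(r_con, 0), h = h + 0 * V, include_caps = include_caps)
}

#' Cell volume from the equatorial cross-sectional area
#'
#' A bright-field image of the equatorial plane at a known plate gap gives the
#' equatorial cross-sectional area; the closed-form shape model converts it to
#' a volume estimate used for the whole recording.
#'
#' @param A_eq Equatorial cross-sectional area (µm²); must be at least
#'   `pi*(h/2)^2`.
#' @param h Plate gap at which the image was taken (µm).
#' @return Cell volume (µm³), numeric.
#' @examples
#' volume_from_equatorial_area(100 * pi, h = 10)
#' @export
volume_from_equatorial_area <- function(A_eq, h) {
  stopifnot(is.numeric(A_eq), is.numeric(h))
  if (any(A_eq < pi * (h / 2)^2 * (1 - 1e-12))) {
    stop("unconfined geometry: A_eq < pi*(h/2)^2", call. = FALSE)
  }
  cell_shape(R1 = sqrt(A_eq / pi), h = h)$V
}

#' Effective cortical tension from AFM force and cell geometry
#'
#' Laplace-pressure force balance for a cell confined between parallel
#' plates: `gamma_eff = F / (A_con * (1/R1 + 1/R2))`. With force in nN and
#' lengths in µm the result is in mN/m.
#'
#' @param F AFM force (nN); vectorised.
#' @param shape A `cell_shape` tibble ([cell_shape()] or [solve_shape()])
#'   with either one row (recycled) or one row per force sample.
#' @return Effective tension (mN/m), numeric.
#' @examples
#' sh <- cell_shape(R1 = 10, h = 10)
#' effective_tension(23.56, sh)
#' @export
effective_tension <- function(F, shape) {
  stopifnot(inherits(shape, "cell_shape"))
  if (any(shape$A_con <= 0)) {
    stop("undefined tension: A_con = 0 (no plate confinement)", call. = FALSE)
  }
  F / (shape$A_con * (1 / shape$R1 + 1 / shape$R2))
}
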