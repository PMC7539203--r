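check_single_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image((mask > 0) * 1))
  n <- max(as.matrix(lab))
  if (n == 0) stop("morphometry error: empty mask", call. = FALSE)
  if (n > 1) {
    stop(sprintf("morphometry error: mask has %d foreground components", n),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Roundness of a binary cross-section
#'
#' Fits an ellipse to the foreground by second central moments (the standard
#' "fit ellipse" definition of image-analysis software) and returns the
#' shape factor `4*Area / (pi * major_axis^2)`, where the major axis is the
#' full axis length `4*sqrt(lambda_max)` of the moment ellipse. A circle
#' gives 1; an ellipse with semi-axes `a >= b` gives `b/a`.
#'
#' @param mask Binary/logical matrix with exactly one foreground component.
#' @param px_size_um Pixel size (µm/px); only affects the reported area.
#' @return A one-row tibble: `roundness` (dimensionless, in (0, 1] up to
#'   discretisation), `area_um2`, `major_um`, `minor_um`.
#' @export
roundness <- function(mask, px_size_um = 1) {
  check_single_component(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(idx)
  mx <- mean(idx[, 1]); my <- mean(idx[, 2])
  cxx <- mean((idx[, 1] - mx)^2)
  cyy <- mean((idx[, 2] - my)^2)
  cxy <- mean((idx[, 1] - mx) * (idx[, 2] - my))
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  lam1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det_, 0))
  lam2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det_, 0))
  major <- 4 * sqrt(lam1)
  minor <- 4 * sqrt(lam2)
  area_px <- n
  r <- 4 * area_px / (pi * major^2)
  tibble::tibble(roundness = min(r, 1 + 1e-6), area_um2 = area_px * px_size_um^2,
                 major_um = major * px_size_um, minor_um = minor * px_size_um)
}

#' Largest cross-section of a z-stack of masks
#'
#' Scans a stack of binary cross-section masks and returns the slice with
#' the largest foreground area (object size readout for spheroids and
#' mitotic cells). Ties are broken toward the lowest z-index.
#'
#' @param stack A list of binary matrices, ordered by z.
#' @param px_size_um Pixel size (µm/px).
#' @return A one-row tibble: `z_index`, `area_um2`.
#' @export
largest_cross_section <- function(stack, px_size_um = 1) {
  if (length(stack) == 0) stop("empty z-stack", call. = FALSE)
  areas <- vapply(stack, function(m) sum(m > 0), numeric(1))
  z <- which.max(areas)  # which.max takes the first (lowest z) on ties
  tibble::tibble(z_index = z, area_um2 = areas[z] * px_size_um^2)
}

#' Morphometry table for a set of labelled masks
#'
#' Applies [roundness()] to each mask and returns a tidy per-object table.
#'
#' @param masks Named list of binary matrices.
#' @param px_size_um Pixel size (µm/px).
#' @return A tibble: `id`, `roundness`, `area_um2`, `major_um`, `minor_um`.
#' @export
morphometry_table <- function(masks, px_size_um = 1) {
  purrr::map_dfr(masks, roundness, px_size_um = px_size_um, .id = "id")
}
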