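#' Shape features of an ROI mask
#'
#' Five size/geometry features of a single-slice ROI treated as a slab of the
#' given thickness: pixel count, physical volume, lateral surface (boundary
#' edge count times spacing times thickness) and two surface-to-volume
#' ratios. Sphericity is `pi^(1/3) * (6 V)^(2/3) / A` and compacity
#' `V / (sqrt(pi) * A^(3/2))` with `V` the slab volume in mm3 and `A` the
#' lateral surface in mm2.
#'
#' @param mask logical or integer matrix, non-zero = in ROI.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slab thickness, mm.
#' @return Named numeric vector of length 5 (`SHAPE_*`).
#' @export
#' @examples
#' shape_features(matrix(1, 10, 10), 1, 5)[["SHAPE_Volume_mL"]]
shape_features <- function(mask, pixel_spacing, slice_thickness) {
  inroi <- mask != 0
  n <- sum(inroi)
  if (n == 0) abort("empty mask", class = "stirq_radiomics_error")
  # boundary edges: pixel sides adjacent to background or the image border
  padded <- matrix(FALSE, nrow(inroi) + 2, ncol(inroi) + 2)
  padded[2:(nrow(inroi) + 1), 2:(ncol(inroi) + 1)] <- inroi
  core <- padded[2:(nrow(padded) - 1), 2:(ncol(padded) - 1), drop = FALSE]
  up    <- padded[1:(nrow(padded) - 2), 2:(ncol(padded) - 1), drop = FALSE]
  down  <- padded[3:nrow(padded),       2:(ncol(padded) - 1), drop = FALSE]
  left  <- padded[2:(nrow(padded) - 1), 1:(ncol(padded) - 2), drop = FALSE]
  right <- padded[2:(nrow(padded) - 1), 3:ncol(padded),       drop = FALSE]
  n_edges <- sum(core & !up) + sum(core & !down) +
    sum(core & !left) + sum(core & !right)
  perim_mm <- n_edges * pixel_spacing
  vol_mm3 <- n * pixel_spacing^2 * slice_thickness
  surf_mm2 <- perim_mm * slice_thickness
  c(
    SHAPE_Volume_vx = n,
    SHAPE_Volume_mL = vol_mm3 / 1000,
    SHAPE_Surface_mm2 = surf_mm2,
    SHAPE_Sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / surf_mm2,
    SHAPE_Compacity = vol_mm3 / (sqrt(pi) * surf_mm2^1.5)
  )
}
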