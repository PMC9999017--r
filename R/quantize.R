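#' Gray-level quantization of a region of interest
#'
#' Discretizes ROI intensities into `G` equal-width bins spanning the ROI's
#' own min--max range (relative bounds, as used by common texture software).
#' Level assignment is `ceiling((x - min) * G / (max - min))` with the
#' minimum forced to level 1, i.e. first bin closed on both sides, later bins
#' left-open, so the maximum lands exactly on level `G`. A constant ROI maps
#' entirely to level 1.
#'
#' @param pixels numeric matrix (a full slice or an ROI crop).
#' @param mask logical or integer matrix of the same shape selecting ROI
#'   pixels (non-zero = in ROI); `NULL` means every pixel.
#' @param G number of gray levels (>= 2, default 64).
#' @return A `quantized_roi`: list with `grid` (bounding-box matrix of levels
#'   in 1..G, `NA` outside the ROI), `G`, `bin_edges` (length G+1, original
#'   intensity units), `values` (raw in-ROI intensities) and `levels`
#'   (their quantized levels, same order).
#' @export
#' @examples
#' q <- quantize_roi(matrix(0:63, 8, 8), G = 64)
#' range(q$levels)
quantize_roi <- function(pixels, mask = NULL, G = 64L) {
  stopifnot(is.matrix(pixels))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  inroi <- mask != 0
  if (!any(inroi)) {
    abort("empty ROI: no pixels selected", class = "stirq_radiomics_error")
  }
  if (G < 2) abort("G must be >= 2", class = "stirq_radiomics_error")
  vals <- pixels[inroi]
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) {
    lev_fun <- function(x) rep(1L, length(x))
    edges <- rep(lo, G + 1)
  } else {
    width <- (hi - lo) / G
    lev_fun <- function(x) {
      pmin(pmax(ceiling((x - lo) * G / (hi - lo)), 1L), G)
    }
    edges <- lo + (0:G) * width
  }
  rows <- range(which(rowSums(inroi) > 0))
  cols <- range(which(colSums(inroi) > 0))
  grid <- matrix(NA_integer_, rows[2] - rows[1] + 1, cols[2] - cols[1] + 1)
  sub_mask <- inroi[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub_px <- pixels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  grid[sub_mask] <- lev_fun(sub_px[sub_mask])
  structure(list(grid = grid, G = as.integer(G), bin_edges = edges,
                 values = vals, levels = lev_fun(vals)),
            class = "quantized_roi")
}
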