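#' Phantom generator parameters
#'
#' Bundles and validates every knob of the synthetic calf-slice generator.
#' Intensities are on an abstract 0--255-like scale (no MR physics is
#' simulated): suppressed fat sits low (mode 30), normal muscle mid
#' (mean 100), edema high (mean 180), echoing the STIR contrast where
#' fat is dark and edema bright. The ground-truth link is linear with
#' Gaussian noise: `FF = ff_slope * f + noise` (f = fat-pixel fraction,
#' left/right mean) and `wT2 = wt2_baseline + wt2_slope * e + noise`
#' (e = edema-pixel fraction).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the parameter set including this seed.
#' @param image_size integer c(height, width) in pixels, each >= 64.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param muscle_intensity_mean,muscle_intensity_sd normal-muscle intensity
#'   law (normal, truncated at 0).
#' @param fat_intensity_mode,fat_intensity_sd suppressed-fat intensity law;
#'   the mode of the generated subcutaneous-fat histogram equals
#'   `fat_intensity_mode`.
#' @param edema_intensity_mean,edema_intensity_sd edema intensity law.
#' @param ff_noise_sd ground-truth fat-fraction noise, percentage points.
#' @param wt2_noise_sd ground-truth water-T2 noise, ms.
#' @param ff_slope percentage points of FF per unit fat-pixel fraction.
#' @param wt2_baseline healthy water T2, ms.
#' @param wt2_slope ms of wT2 per unit edema-pixel fraction.
#' @param roi_size nominal side length of each square muscle ROI in pixels;
#'   each subject-muscle gets an integer size jitter in \[-2, 2\] (equal on
#'   both sides) so muscle volumes vary across subjects. The jittered region
#'   must keep >= 64 pixels.
#' @param subcut_thickness thickness in pixels of the subcutaneous-fat band
#'   drawn on healthy-control slices (about 10 px, ~10.5 mm at 1 mm spacing).
#' @param n_slices_fshd slices per FSHD subject (mid slice used downstream).
#' @param background_mean,background_sd air-background intensity law.
#' @param vessel_fraction fraction of subcutaneous-fat pixels replaced by
#'   bright vessel-like pixels (<= 0.05); these shift the band's mean but
#'   not its mode.
#' @param mean_patch_size mean size (pixels) of the connected fat/edema
#'   patches grown inside each ROI; patches are 8-connected so size-zone
#'   statistics are non-degenerate.
#' @param lr_correlation correlation of the latent fat (and edema) fractions
#'   across the left and right side of the same muscle.
#'
#' @return A `phantom_params` list.
#' @export
#' @examples
#' p <- phantom_params(n_subjects = 4, seed = 1)
#' p$image_size
phantom_params <- function(n_subjects = 25,
                           seed = 1234,
                           image_size = c(128L, 128L),
                           pixel_spacing = 1,
                           slice_thickness = 5,
                           muscle_intensity_mean = 100,
                           muscle_intensity_sd = 10,
                           fat_intensity_mode = 30,
                           fat_intensity_sd = 8,
                           edema_intensity_mean = 180,
                           edema_intensity_sd = 15,
                           ff_noise_sd = 3,
                           wt2_noise_sd = 1,
                           ff_slope = 100,
                           wt2_baseline = 30,
                           wt2_slope = 25,
                           roi_size = 22L,
                           subcut_thickness = 10L,
                           n_slices_fshd = 3L,
                           background_mean = 5,
                           background_sd = 2,
                           vessel_fraction = 0.04,
                           mean_patch_size = 30,
                           lr_correlation = 0.8) {
  p <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    muscle_intensity_mean = muscle_intensity_mean,
    muscle_intensity_sd = muscle_intensity_sd,
    fat_intensity_mode = fat_intensity_mode,
    fat_intensity_sd = fat_intensity_sd,
    edema_intensity_mean = edema_intensity_mean,
    edema_intensity_sd = edema_intensity_sd,
    ff_noise_sd = ff_noise_sd, wt2_noise_sd = wt2_noise_sd,
    ff_slope = ff_slope, wt2_baseline = wt2_baseline, wt2_slope = wt2_slope,
    roi_size = as.integer(roi_size),
    subcut_thickness = as.integer(subcut_thickness),
    n_slices_fshd = as.integer(n_slices_fshd),
    background_mean = background_mean, background_sd = background_sd,
    vessel_fraction = vessel_fraction,
    mean_patch_size = mean_patch_size,
    lr_correlation = lr_correlation
  )
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  bad <- function(field, why) {
    abort(sprintf("invalid phantom parameter `%s`: %s", field, why),
          class = "stirq_config_error")
  }
  if (is.na(p$n_subjects) || p$n_subjects < 2) bad("n_subjects", "must be >= 2")
  if (length(p$seed) != 1 || is.na(p$seed)) bad("seed", "must be a single integer")
  if (length(p$image_size) != 2 || any(p$image_size < 64)) {
    bad("image_size", "must be two dimensions each >= 64")
  }
  for (f in c("muscle_intensity_sd", "fat_intensity_sd", "edema_intensity_sd",
              "ff_noise_sd", "wt2_noise_sd", "background_sd")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      bad(f, "must be a single value > 0")
    }
  }
  if (!(p$fat_intensity_mode < p$muscle_intensity_mean &&
        p$muscle_intensity_mean < p$edema_intensity_mean)) {
    bad("fat_intensity_mode",
        "intensity ordering fat mode < muscle mean < edema mean is required")
  }
  if (p$pixel_spacing <= 0) bad("pixel_spacing", "must be > 0")
  if (p$slice_thickness <= 0) bad("slice_thickness", "must be > 0")
  if ((p$roi_size - 2)^2 < 64) {
    bad("roi_size", "each muscle region needs >= 64 pixels after size jitter")
  }
  if (p$subcut_thickness < 1) bad("subcut_thickness", "must be >= 1")
  if (p$n_slices_fshd < 1) bad("n_slices_fshd", "must be >= 1")
  if (p$vessel_fraction < 0 || p$vessel_fraction > 0.05) {
    bad("vessel_fraction", "must be in [0, 0.05]")
  }
  if (p$lr_correlation < 0 || p$lr_correlation >= 1) {
    bad("lr_correlation", "must be in [0, 1)")
  }
  if (p$mean_patch_size < 1) bad("mean_patch_size", "must be >= 1")
  layout <- try(phantom_layout(p), silent = TRUE)
  if (inherits(layout, "try-error")) {
    bad("image_size", "too small for the ROI layout; increase image_size or shrink roi_size")
  }
  invisible(p)
}

# Deterministic ROI layout: a 3 x 4 grid of square muscle ROIs (columns 1-2 =
# left calf, 3-4 = right calf) below a full-width subcutaneous band (used on
# healthy-control slices only).
phantom_layout <- function(p) {
  h <- p$image_size[1]; w <- p$image_size[2]
  band_rows <- seq.int(3L, 3L + p$subcut_thickness - 1L)
  y0 <- max(band_rows) + 6L
  pitch_y <- (h - y0 - 2L) %/% 3L
  pitch_x <- (w - 8L) %/% 4L
  if (pitch_y < p$roi_size + 2L || pitch_x < p$roi_size + 2L) {
    stop("layout does not fit")
  }
  lab <- roi_label_table(include_subcut = FALSE)
  pos <- purrr::pmap_dfr(lab, function(label, muscle, side) {
    m <- match(muscle, calf_muscles())
    r <- (m - 1L) %/% 2L          # grid row 0..2
    cw <- (m - 1L) %% 2L          # column within side 0..1
    cc <- if (side == "left") cw else 2L + cw
    tibble::tibble(
      label = label, muscle = muscle, side = side,
      row0 = y0 + r * pitch_y, col0 = 5L + cc * pitch_x,
      size = p$roi_size
    )
  })
  list(rois = pos, band_rows = band_rows, band_label = 13L)
}

#' @method print phantom_params
#' @export
print.phantom_params <- function(x, ...) {
  cat("<phantom_params>\n")
  cat(sprintf("  %d subjects, seed %d, image %dx%d px (%.1f mm, thickness %.1f mm)\n",
              x$n_subjects, x$seed, x$image_size[1], x$image_size[2],
              x$pixel_spacing, x$slice_thickness))
  cat(sprintf("  intensities: fat mode %g, muscle %g (sd %g), edema %g (sd %g)\n",
              x$fat_intensity_mode, x$muscle_intensity_mean,
              x$muscle_intensity_sd, x$edema_intensity_mean,
              x$edema_intensity_sd))
  cat(sprintf("  ground truth: FF = %g * f + N(0, %g); wT2 = %g + %g * e + N(0, %g)\n",
              x$ff_slope, x$ff_noise_sd, x$wt2_baseline, x$wt2_slope,
              x$wt2_noise_sd))
  invisible(x)
}
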