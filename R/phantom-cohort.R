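#' Synthetic cohorts of calf STIR-like slices
#'
#' `generate_hc_cohort()` builds a healthy-control cohort: each subject has
#' exactly six contiguous mid-calf slices with the twelve muscle regions drawn
#' from the normal-muscle intensity law and a subcutaneous-fat band whose
#' intensity mode equals `fat_intensity_mode` (plus a small bright vessel
#' admixture, which shifts the band's mean but not its mode).
#'
#' `generate_fshd_cohort()` builds a diseased cohort: per muscle and side a
#' latent fat-pixel fraction `f ~ U(0, 0.6)` and edema-pixel fraction
#' `e ~ U(0, 0.3)` are drawn (correlated across sides of the same muscle via a
#' Gaussian copula), pixels inside each ROI are a spatial mixture of
#' contiguous fat, edema and muscle patches in those proportions, and the
#' per-muscle ground truth is `FF = ff_slope * mean(f_L, f_R) + noise`
#' (clipped to [0, 100]) and `wT2 = wt2_baseline + wt2_slope * mean(e) +
#' noise`.
#'
#' Both generators are fully deterministic given the parameter set (seed
#' included).
#'
#' @param params a [phantom_params()] object. `generate_hc_cohort()` defaults
#'   to 6 subjects (seed 7), `generate_fshd_cohort()` to 25 (seed 1234).
#' @param latent_override optional tibble with columns `muscle`, `side`, `f`,
#'   `e` applied to every subject in place of random latent draws (used to
#'   probe degenerate settings such as `f = e = 0`).
#' @return A `stirq_cohort`: a list of subjects, each a list with
#'   `subject_id`, `cohort`, `slices` (list of [slice_image()]), `masks`
#'   (integer label matrices), `label_table`, and for FSHD subjects
#'   `ground_truth` (tibble: muscle, FF_pp, wT2_ms) and `latent`
#'   (tibble: muscle, side, f, e).
#' @export
#' @examples
#' hc <- generate_hc_cohort(phantom_params(n_subjects = 2, seed = 7))
#' length(hc[[1]]$slices)
generate_hc_cohort <- function(params = phantom_params(n_subjects = 6, seed = 7)) {
  validate_phantom_params(params)
  layout <- phantom_layout(params)
  set.seed(params$seed)
  subjects <- lapply(seq_len(params$n_subjects), function(i) {
    sub_layout <- jitter_layout(layout, params)
    slices <- vector("list", 6L)
    masks <- vector("list", 6L)
    for (s in 1:6) {
      im <- render_slice(params, sub_layout, latent = NULL, with_band = TRUE)
      slices[[s]] <- im$slice
      masks[[s]] <- im$mask
    }
    list(
      subject_id = sprintf("HC%02d", i), cohort = "HC",
      slices = slices, masks = masks,
      label_table = roi_label_table(include_subcut = TRUE),
      ground_truth = NULL, latent = NULL
    )
  })
  new_cohort(subjects, params)
}

#' @rdname generate_hc_cohort
#' @export
generate_fshd_cohort <- function(params = phantom_params(n_subjects = 25, seed = 1234),
                                 latent_override = NULL) {
  validate_phantom_params(params)
  layout <- phantom_layout(params)
  set.seed(params$seed)
  subjects <- lapply(seq_len(params$n_subjects), function(i) {
    sub_layout <- jitter_layout(layout, params)
    latent <- if (is.null(latent_override)) {
      draw_latent(params)
    } else {
      latent_override[c("muscle", "side", "f", "e")]
    }
    n_sl <- params$n_slices_fshd
    slices <- vector("list", n_sl)
    masks <- vector("list", n_sl)
    for (s in seq_len(n_sl)) {
      im <- render_slice(params, sub_layout, latent = latent, with_band = FALSE)
      slices[[s]] <- im$slice
      masks[[s]] <- im$mask
    }
    gt <- latent |>
      dplyr::group_by(.data$muscle) |>
      dplyr::summarise(f_bar = mean(.data$f), e_bar = mean(.data$e),
                       .groups = "drop") |>
      dplyr::mutate(
        FF_pp = pmin(pmax(params$ff_slope * .data$f_bar +
                            rnorm(dplyr::n(), 0, params$ff_noise_sd), 0), 100),
        wT2_ms = pmax(params$wt2_baseline + params$wt2_slope * .data$e_bar +
                        rnorm(dplyr::n(), 0, params$wt2_noise_sd), 0.1)
      ) |>
      dplyr::select("muscle", "FF_pp", "wT2_ms") |>
      dplyr::arrange(match(.data$muscle, calf_muscles()))
    list(
      subject_id = sprintf("FSHD%02d", i), cohort = "FSHD",
      slices = slices, masks = masks,
      label_table = roi_label_table(include_subcut = FALSE),
      ground_truth = gt, latent = latent
    )
  })
  new_cohort(subjects, params)
}

new_cohort <- function(subjects, params) {
  structure(subjects, class = "stirq_cohort", params = params)
}

#' @method print stirq_cohort
#' @export
print.stirq_cohort <- function(x, ...) {
  kinds <- table(vapply(x, function(s) s$cohort, character(1)))
  cat(sprintf("<stirq_cohort> %d subjects (%s), %d slice(s) each\n",
              length(x), paste(names(kinds), kinds, sep = "=", collapse = ", "),
              length(x[[1]]$slices)))
  invisible(x)
}

#' A single 2D slice
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @return A `slice_image` list.
#' @export
slice_image <- function(pixels, pixel_spacing = 1, slice_thickness = 5) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            pixel_spacing > 0, slice_thickness > 0)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "slice_image")
}

# Per-subject anatomical size variability: each muscle's square ROI side
# length gets an integer jitter in [-2, 2] (both sides of a muscle equal, as
# anatomy is roughly symmetric), so muscle volumes vary across subjects the
# way real cross-sectional areas do. The jitter never exceeds the layout
# pitch slack checked at validation time.
jitter_layout <- function(layout, p) {
  jit <- sample(-2:2, 6, replace = TRUE)
  rois <- layout$rois
  rois$size <- p$roi_size + jit[match(rois$muscle, calf_muscles())]
  layout$rois <- rois
  layout
}

# latent fat/edema fractions per muscle and side, Gaussian copula across sides
draw_latent <- function(p) {
  rho <- p$lr_correlation
  one_pair <- function(scale) {
    z1 <- rnorm(1); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
    scale * stats::pnorm(c(z1, z2))
  }
  purrr::map_dfr(calf_muscles(), function(m) {
    f <- one_pair(0.6)
    e <- one_pair(0.3)
    tibble::tibble(muscle = m, side = roi_sides(), f = f, e = e)
  })
}

# Render one slice: background everywhere, then each ROI filled with a
# contiguous-patch mixture; returns the slice_image and the label mask.
render_slice <- function(p, layout, latent, with_band) {
  h <- p$image_size[1]; w <- p$image_size[2]
  px <- matrix(pmax(rnorm(h * w, p$background_mean, p$background_sd), 0), h, w)
  mask <- matrix(0L, h, w)

  for (k in seq_len(nrow(layout$rois))) {
    roi <- layout$rois[k, ]
    rows <- roi$row0 + seq_len(roi$size) - 1L
    cols <- roi$col0 + seq_len(roi$size) - 1L
    n <- roi$size^2
    if (is.null(latent)) {
      f <- 0; e <- 0
    } else {
      lt <- latent[latent$muscle == roi$muscle & latent$side == roi$side, ]
      f <- lt$f[1]; e <- lt$e[1]
    }
    assign <- mix_roi_pixels(roi$size, round(f * n), round(e * n), p$mean_patch_size)
    vals <- numeric(n)
    vals[assign == 0L] <- rnorm(sum(assign == 0L), p$muscle_intensity_mean,
                                p$muscle_intensity_sd)
    vals[assign == 1L] <- rnorm(sum(assign == 1L), p$fat_intensity_mode,
                                p$fat_intensity_sd)
    vals[assign == 2L] <- rnorm(sum(assign == 2L), p$edema_intensity_mean,
                                p$edema_intensity_sd)
    px[rows, cols] <- matrix(pmax(vals, 0), roi$size, roi$size)
    mask[rows, cols] <- roi$label
  }

  if (with_band) {
    rows <- layout$band_rows
    n <- length(rows) * w
    vals <- rnorm(n, p$fat_intensity_mode, p$fat_intensity_sd)
    n_vessel <- round(p$vessel_fraction * n)
    if (n_vessel > 0) {
      idx <- sample.int(n, n_vessel)
      vals[idx] <- rnorm(n_vessel, p$edema_intensity_mean, p$edema_intensity_sd)
    }
    px[rows, ] <- matrix(pmax(vals, 0), length(rows), w)
    mask[rows, ] <- layout$band_label
  }

  list(slice = slice_image(px, p$pixel_spacing, p$slice_thickness),
       mask = mask)
}

# Assign each cell of an s x s ROI to 0 = muscle, 1 = fat, 2 = edema with the
# requested pixel counts; fat and edema are grown as 8-connected random-walk
# patches so flat zones have non-trivial sizes.
mix_roi_pixels <- function(s, n_fat, n_edema, mean_patch) {
  assign <- matrix(0L, s, s)
  if (n_fat > 0)  assign <- grow_patches(assign, 1L, n_fat, mean_patch)
  if (n_edema > 0) assign <- grow_patches(assign, 2L, n_edema, mean_patch)
  assign
}

grow_patches <- function(assign, code, n_target, mean_patch) {
  s <- nrow(assign)
  free <- which(assign == 0L)
  placed <- 0L
  while (placed < n_target && length(free) > 0) {
    want <- min(1L + stats::rgeom(1, 1 / mean_patch), n_target - placed)
    seed_cell <- free[sample.int(length(free), 1L)]
    blob <- integer(0)
    frontier <- seed_cell
    while (length(blob) < want && length(frontier) > 0) {
      pick <- frontier[sample.int(length(frontier), 1L)]
      frontier <- frontier[frontier != pick]
      if (assign[pick] != 0L) next
      assign[pick] <- code
      blob <- c(blob, pick)
      frontier <- unique(c(frontier, free_neighbors(pick, assign, s)))
    }
    placed <- placed + length(blob)
    free <- which(assign == 0L)
  }
  assign
}

free_neighbors <- function(cell, assign, s) {
  r <- (cell - 1L) %% s + 1L
  c <- (cell - 1L) %/% s + 1L
  rr <- pmax(r - 1L, 1L):pmin(r + 1L, s)
  cc <- pmax(c - 1L, 1L):pmin(c + 1L, s)
  nb <- as.vector(outer(rr, (cc - 1L) * s, "+"))
  nb <- nb[nb != cell]
  nb[assign[nb] == 0L]
}

#' Extract the pixel values of one region of interest
#'
#' @param subject a cohort subject.
#' @param slice_index which slice.
#' @param muscle muscle name (or `"SUBCUT_FAT"`).
#' @param side `"left"`, `"right"`, or `NULL` for both/any.
#' @return Numeric vector of intensities.
#' @export
roi_pixels <- function(subject, slice_index, muscle, side = NULL) {
  lt <- subject$label_table
  sel <- lt$muscle == muscle
  if (!is.null(side)) sel <- sel & !is.na(lt$side) & lt$side == side
  labels <- lt$label[sel]
  if (length(labels) == 0) {
    abort(sprintf("no ROI label for muscle '%s'%s", muscle,
                  if (is.null(side)) "" else paste0(" side '", side, "'")))
  }
  mask <- subject$masks[[slice_index]]
  subject$slices[[slice_index]]$pixels[mask %in% labels]
}

#' Mid-slice index of a subject
#' @param subject a cohort subject.
#' @return Integer index of the middle slice (stack midpoint).
#' @export
mid_slice <- function(subject) (length(subject$slices) + 1L) %/% 2L

#' Ground-truth table of a cohort
#'
#' @param cohort a `stirq_cohort` with ground truth attached (FSHD phantom).
#' @return Tibble with columns subject_id, muscle, FF_pp, wT2_ms.
#' @export
ground_truth_table <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    if (is.null(s$ground_truth)) return(NULL)
    dplyr::mutate(s$ground_truth, subject_id = s$subject_id, .before = 1)
  })
}
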