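#' Histogram matching of a slice onto a reference
#'
#' Inter-subject intensity harmonization: the image's empirical quantiles at
#' `n_quantiles` equally spaced probability landmarks (type-7 quantiles) are
#' mapped onto the reference's by a monotone piecewise-linear map, and every
#' pixel is sent through that map (clamped to the reference's range).
#'
#' The map is monotone non-decreasing, so within-image intensity ranks are
#' preserved; matching an image to itself is the identity.
#'
#' @param image,reference [slice_image()] objects (both non-constant).
#' @param config a [histogram_match_config()].
#' @return A [slice_image()] with mapped intensities.
#' @export
histogram_match <- function(image, reference, config = histogram_match_config()) {
  px <- image$pixels
  ref <- reference$pixels
  if (diff(range(px)) == 0) {
    abort("cannot histogram-match a constant image (quantile map undefined)",
          class = "stirq_preprocess_error")
  }
  if (diff(range(ref)) == 0) {
    abort("constant reference image (quantile map undefined)",
          class = "stirq_preprocess_error")
  }
  probs <- seq(0, 1, length.out = config$n_quantiles)
  xs <- quantile(as.vector(px), probs, type = 7, names = FALSE)
  ys <- quantile(as.vector(ref), probs, type = 7, names = FALSE)
  mapped <- approx(xs, ys, xout = as.vector(px), rule = 2, ties = mean)$y
  slice_image(matrix(mapped, nrow(px), ncol(px)),
              pixel_spacing = image$pixel_spacing,
              slice_thickness = image$slice_thickness)
}

#' Histogram-matching configuration
#'
#' @param n_quantiles number of quantile landmarks (>= 2; default 256).
#' @param reference_id subject id to use as reference, or `"first_hc"` for
#'   the mid-calf slice of the first healthy control in sorted-id order.
#' @return A `histogram_match_config` list.
#' @export
histogram_match_config <- function(n_quantiles = 256L, reference_id = "first_hc") {
  if (!is.numeric(n_quantiles) || n_quantiles < 2) {
    abort("invalid preprocess parameter `n_quantiles`: must be >= 2",
          class = "stirq_config_error")
  }
  structure(list(n_quantiles = as.integer(n_quantiles),
                 reference_id = reference_id),
            class = "histogram_match_config")
}

# locate the reference slice in a cohort (or pair of cohorts)
find_reference_slice <- function(cohorts, config) {
  subjects <- do.call(c, lapply(cohorts, unclass))
  if (identical(config$reference_id, "first_hc")) {
    hc <- subjects[vapply(subjects, function(s) s$cohort == "HC", logical(1))]
    if (length(hc) == 0) {
      abort("no healthy-control subject available as histogram-matching reference",
            class = "stirq_preprocess_error")
    }
    ids <- vapply(hc, function(s) s$subject_id, character(1))
    ref_sub <- hc[[order(ids)[1]]]
  } else {
    ids <- vapply(subjects, function(s) s$subject_id, character(1))
    hit <- which(ids == config$reference_id)
    if (length(hit) == 0) {
      abort(sprintf("reference subject '%s' not found", config$reference_id),
            class = "stirq_preprocess_error")
    }
    ref_sub <- subjects[[hit[1]]]
  }
  list(subject_id = ref_sub$subject_id,
       slice = ref_sub$slices[[mid_slice(ref_sub)]])
}

#' Harmonize every slice of a cohort onto a reference slice
#'
#' Each slice of each subject is histogram-matched onto the designated
#' reference slice (the reference slice itself is left untouched). Subjects
#' are processed independently, so cohort order does not affect the result.
#'
#' An optional `pre_hook` runs on each slice before matching; it is the
#' attachment point for externally bias-field-corrected images (the phantoms
#' are generated bias-free, so the default is the identity).
#'
#' @param cohort a `stirq_cohort`.
#' @param config a [histogram_match_config()].
#' @param reference optional [slice_image()] to use as the reference (e.g.
#'   from another cohort); overrides `config$reference_id`.
#' @param pre_hook optional `function(slice_image) -> slice_image`.
#' @return The cohort with mapped intensities.
#' @export
normalize_cohort <- function(cohort, config = histogram_match_config(),
                             reference = NULL, pre_hook = NULL) {
  if (is.null(reference)) {
    ref <- find_reference_slice(list(cohort), config)
    reference <- ref$slice
    ref_id <- ref$subject_id
  } else {
    ref_id <- NULL
  }
  out <- purrr::map(cohort, function(s) {
    mid <- mid_slice(s)
    s$slices <- purrr::imap(s$slices, function(sl, k) {
      if (!is.null(pre_hook)) sl <- pre_hook(sl)
      if (!is.null(ref_id) && s$subject_id == ref_id && k == mid) return(sl)
      histogram_match(sl, reference, config)
    })
    s
  })
  new_cohort(out, attr(cohort, "params"))
}
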