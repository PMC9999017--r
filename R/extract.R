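#' The 56-feature radiomic catalog
#'
#' The catalog is stored as a versioned JSON file under `extdata` so its
#' membership can be revised without code changes: 25 first-order + 26
#' second-order (7 GLCM + 11 GLZLM + 8 GLRLM) + 5 shape features.
#'
#' @param grouped return a list split by feature family instead of a single
#'   character vector.
#' @return Character vector of the 56 feature names (catalog order), or a
#'   named list of families when `grouped = TRUE`.
#' @export
#' @examples
#' length(feature_catalog())
feature_catalog <- function(grouped = FALSE) {
  path <- system.file("extdata", "feature_catalog.json", package = "stirq")
  cat <- jsonlite::read_json(path, simplifyVector = TRUE)
  fams <- cat[c("first_order", "glcm", "glzlm", "glrlm", "shape")]
  if (grouped) fams else unlist(fams, use.names = FALSE)
}

# all 56 features for one ROI side
roi_feature_vector <- function(pixels, mask, pixel_spacing, slice_thickness,
                               G = 64L) {
  q <- quantize_roi(pixels, mask, G = G)
  c(first_order_features(q),
    glcm_features(q),
    glzlm_features(q),
    glrlm_features(q),
    shape_features(mask, pixel_spacing, slice_thickness))
}

#' Extract the radiomic feature vector for every muscle of a subject
#'
#' Computes the full 56-feature catalog independently on the left and right
#' ROI of each muscle on one slice and returns the arithmetic mean per
#' feature. If one side is missing from the mask the available side is used
#' alone (with a message).
#'
#' @param subject a cohort subject.
#' @param slice_index slice to use (default: mid slice).
#' @param G gray levels for quantization (default 64).
#' @return A tibble with one row per muscle: `muscle` plus the 56 features.
#' @export
extract_features <- function(subject, slice_index = mid_slice(subject), G = 64L) {
  if (slice_index < 1 || slice_index > length(subject$slices)) {
    abort(sprintf("subject %s has no slice %d", subject$subject_id, slice_index),
          class = "stirq_radiomics_error")
  }
  sl <- subject$slices[[slice_index]]
  mask <- subject$masks[[slice_index]]
  lt <- subject$label_table
  purrr::map_dfr(calf_muscles(), function(m) {
    sides <- purrr::compact(purrr::map(roi_sides(), function(sd) {
      lab <- lt$label[lt$muscle == m & !is.na(lt$side) & lt$side == sd]
      if (length(lab) == 0 || !any(mask == lab)) return(NULL)
      roi_feature_vector(sl$pixels, mask == lab, sl$pixel_spacing,
                         sl$slice_thickness, G = G)
    }))
    if (length(sides) == 0) {
      abort(sprintf("no ROI found for muscle %s on subject %s", m,
                    subject$subject_id),
            class = "stirq_radiomics_error")
    }
    if (length(sides) == 1) {
      inform(sprintf("subject %s muscle %s: single side available, no averaging",
                     subject$subject_id, m))
    }
    fv <- Reduce(`+`, sides) / length(sides)
    fv <- fv[feature_catalog()]
    dplyr::bind_cols(tibble::tibble(muscle = m), tibble::as_tibble_row(fv))
  })
}

#' Per-muscle feature tables for a whole cohort
#'
#' One table per muscle, one row per subject: 56 feature columns plus the
#' ground-truth targets `FF_pp` and `wT2_ms`. Subjects without ground truth
#' are excluded with a warning.
#'
#' @param cohort a `stirq_cohort` with ground truth (FSHD phantom or
#'   equivalent).
#' @param slice_selector function(subject) -> slice index; default the mid
#'   slice of each subject's stack.
#' @param G gray levels for quantization.
#' @return Named list of six tibbles (one per muscle).
#' @export
build_feature_tables <- function(cohort, slice_selector = mid_slice, G = 64L) {
  if (length(cohort) == 0) {
    abort("empty cohort", class = "stirq_radiomics_error")
  }
  rows <- purrr::map_dfr(cohort, function(s) {
    if (is.null(s$ground_truth)) {
      warn(sprintf("subject %s has no ground truth; excluded", s$subject_id))
      return(NULL)
    }
    feats <- extract_features(s, slice_selector(s), G = G)
    feats |>
      dplyr::left_join(s$ground_truth, by = "muscle") |>
      dplyr::mutate(subject_id = s$subject_id, .before = 1)
  })
  if (nrow(rows) == 0) {
    abort("no subject with ground truth in cohort",
          class = "stirq_radiomics_error")
  }
  split(rows, rows$muscle)[calf_muscles()] |>
    purrr::map(~ dplyr::select(.x, -"muscle"))
}
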