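#' Write and read cohorts on disk
#'
#' Slices and label masks are serialized as NIfTI (`.nii.gz`, one file per
#' subject-slice; masks as unsigned integers with the label map in a JSON
#' sidecar), ground truth and latent fractions as CSV, and a manifest JSON
#' listing one row per subject-slice. `read_cohort()` inverts
#' `write_cohort()` field by field.
#'
#' @param cohort a `stirq_cohort`.
#' @param dir directory to write into (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a `stirq_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- purrr::map(cohort, function(s) {
    slice_files <- character(length(s$slices))
    mask_files <- character(length(s$slices))
    for (k in seq_along(s$slices)) {
      slice_files[k] <- sprintf("%s_slice%02d.nii.gz", s$subject_id, k)
      mask_files[k] <- sprintf("%s_slice%02d_mask.nii.gz", s$subject_id, k)
      sl <- s$slices[[k]]
      hdr <- RNifti::niftiHeader(list(
        pixdim = c(-1, sl$pixel_spacing, sl$pixel_spacing, 1, 1, 1, 1, 1)))
      img <- RNifti::asNifti(sl$pixels, reference = hdr, datatype = "double")
      RNifti::writeNifti(img, file.path(dir, slice_files[k]))
      msk <- RNifti::asNifti(s$masks[[k]], reference = hdr, datatype = "uint8")
      RNifti::writeNifti(msk, file.path(dir, mask_files[k]))
    }
    list(subject_id = s$subject_id, cohort = s$cohort,
         pixel_spacing = s$slices[[1]]$pixel_spacing,
         slice_thickness = s$slices[[1]]$slice_thickness,
         slices = slice_files, masks = mask_files,
         has_subcut = subcut_label() %in% s$label_table$muscle)
  })
  gt <- purrr::map_dfr(cohort, function(s) {
    if (is.null(s$ground_truth)) return(NULL)
    dplyr::mutate(s$ground_truth, subject_id = s$subject_id, .before = 1)
  })
  if (nrow(gt) > 0) {
    write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  lat <- purrr::map_dfr(cohort, function(s) {
    if (is.null(s$latent)) return(NULL)
    dplyr::mutate(s$latent, subject_id = s$subject_id, .before = 1)
  })
  if (nrow(lat) > 0) {
    write.csv(lat, file.path(dir, "latent.csv"), row.names = FALSE)
  }
  jsonlite::write_json(roi_label_table(TRUE), file.path(dir, "labels.json"))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("not a cohort directory: missing %s", manifest_path),
          class = "stirq_io_error")
  }
  manifest <- jsonlite::read_json(manifest_path)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) tibble::as_tibble(read.csv(gt_path)) else NULL
  lat_path <- file.path(dir, "latent.csv")
  lat <- if (file.exists(lat_path)) tibble::as_tibble(read.csv(lat_path)) else NULL

  subjects <- purrr::map(manifest, function(m) {
    slices <- purrr::map(m$slices, function(f) {
      path <- file.path(dir, f)
      if (!file.exists(path)) {
        abort(sprintf("missing slice file %s", path), class = "stirq_io_error")
      }
      arr <- RNifti::readNifti(path)
      slice_image(matrix(as.numeric(arr), nrow(arr), ncol(arr)),
                  pixel_spacing = m$pixel_spacing,
                  slice_thickness = m$slice_thickness)
    })
    masks <- purrr::map(m$masks, function(f) {
      path <- file.path(dir, f)
      if (!file.exists(path)) {
        abort(sprintf("missing mask file %s", path), class = "stirq_io_error")
      }
      arr <- RNifti::readNifti(path)
      matrix(as.integer(arr), nrow(arr), ncol(arr))
    })
    sub_gt <- if (!is.null(gt) && m$subject_id %in% gt$subject_id) {
      dplyr::select(gt[gt$subject_id == m$subject_id, ], -"subject_id")
    } else NULL
    sub_lat <- if (!is.null(lat) && m$subject_id %in% lat$subject_id) {
      dplyr::select(lat[lat$subject_id == m$subject_id, ], -"subject_id")
    } else NULL
    list(subject_id = m$subject_id, cohort = m$cohort,
         slices = slices, masks = masks,
         label_table = roi_label_table(include_subcut = isTRUE(m$has_subcut)),
         ground_truth = sub_gt, latent = sub_lat)
  })
  new_cohort(subjects, params = NULL)
}
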