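#' Healthy-control reference limits
#'
#' Per muscle, pixels are pooled across every healthy-control subject, both
#' sides and all six slices, and the upper limit is `UL_i = mu_i + 2 sigma_i`
#' (population SD of the pooled pixels). The lower limit LL is the mode of
#' the pooled subcutaneous-fat intensity histogram (fixed-width bins,
#' default 1 intensity unit; ties go to the lowest bin) -- the mode rather
#' than the mean so that bright blood-vessel pixels inside the fat band do
#' not drag the limit upward.
#'
#' @param hc_cohort a healthy-control `stirq_cohort` (each subject carries a
#'   `SUBCUT_FAT` region).
#' @param bin_width histogram bin width for the LL mode, intensity units.
#' @param pool `"pixels"` pools pixels across subjects (default);
#'   `"subjects"` computes per-subject statistics first and averages them.
#' @return A `stirq_limits` list: `UL` (named per muscle), `LL`, `bin_width`,
#'   and provenance fields.
#' @export
compute_reference_limits <- function(hc_cohort, bin_width = 1,
                                     pool = c("pixels", "subjects")) {
  pool <- match.arg(pool)
  subjects <- hc_cohort[vapply(hc_cohort, function(s)
    subcut_label() %in% s$label_table$muscle, logical(1))]
  if (length(subjects) == 0) {
    abort("no subject with a SUBCUT_FAT region: cannot compute LL",
          class = "stirq_wf3_error")
  }
  pooled <- function(muscle) {
    purrr::map(subjects, function(s) {
      unlist(lapply(seq_along(s$slices), function(k)
        roi_pixels(s, k, muscle)))
    })
  }
  UL <- vapply(calf_muscles(), function(m) {
    per_sub <- pooled(m)
    if (all(lengths(per_sub) == 0)) {
      abort(sprintf("empty pixel pool for muscle %s", m),
            class = "stirq_wf3_error")
    }
    if (pool == "pixels") {
      px <- unlist(per_sub)
      mean(px) + 2 * sqrt(mean((px - mean(px))^2))
    } else {
      mean(vapply(per_sub, function(px)
        mean(px) + 2 * sqrt(mean((px - mean(px))^2)), numeric(1)))
    }
  }, numeric(1))

  fat <- unlist(pooled(subcut_label()))
  LL <- histogram_mode(fat, bin_width)
  if (LL >= min(UL)) {
    warn(sprintf("LL (%.2f) is not below every UL (min %.2f); check cohort scale",
                 LL, min(UL)))
  }
  structure(list(
    UL = UL, LL = LL, bin_width = bin_width, pool = pool,
    hc_subjects = vapply(subjects, function(s) s$subject_id, character(1)),
    n_fat_pixels = length(fat)
  ), class = "stirq_limits")
}

# mode of a fixed-bin-width histogram; bins are centered on multiples of the
# width ([k*w - w/2, k*w + w/2)), the mode is the fullest bin's center,
# ties to the lowest bin
histogram_mode <- function(x, bin_width = 1) {
  bins <- round(x / bin_width)
  tab <- table(bins)
  k <- as.numeric(names(tab)[which.max(tab)])
  k * bin_width
}

#' @method print stirq_limits
#' @export
print.stirq_limits <- function(x, ...) {
  cat(sprintf("<stirq_limits> LL = %.2f (mode of %d fat pixels, bin %.1f)\n",
              x$LL, x$n_fat_pixels, x$bin_width))
  cat("  UL:", paste(sprintf("%s=%.1f", names(x$UL), x$UL), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.stirq_limits <- function(x, ...) {
  tibble::tibble(muscle = names(x$UL), UL = unname(x$UL), LL = x$LL)
}

#' Serialize reference limits
#' @param limits a `stirq_limits`.
#' @param path JSON file path.
#' @return `write_reference_limits()` the path invisibly;
#'   `read_reference_limits()` a `stirq_limits`.
#' @export
write_reference_limits <- function(limits, path) {
  x <- unclass(limits)
  x$UL <- as.list(x$UL)   # keep muscle names (atomic vectors drop them)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_limits
#' @export
read_reference_limits <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$UL <- unlist(x$UL)
  structure(x, class = "stirq_limits")
}

#' Fat-infiltration and muscle-edema grades of one muscle
#'
#' FFG is the fraction of ROI pixels strictly below LL (residual suppressed
#' fat is dark on STIR), MEG the fraction strictly above the muscle's UL
#' (edema is bright). Values are computed per side and averaged, consistent
#' with the side-averaging used for the radiomic features.
#'
#' @param subject a cohort subject on the same intensity scale as the
#'   healthy-control cohort the limits came from.
#' @param muscle one of [calf_muscles()].
#' @param limits a `stirq_limits`.
#' @param slice_index slice to use (default mid slice).
#' @return Tibble with one row: `muscle`, `FFG`, `MEG` (fractions in [0, 1]).
#' @export
compute_ffg_meg <- function(subject, muscle, limits,
                            slice_index = mid_slice(subject)) {
  ul <- limits$UL[[muscle]]
  sides <- purrr::compact(purrr::map(roi_sides(), function(sd) {
    px <- tryCatch(roi_pixels(subject, slice_index, muscle, sd),
                   error = function(e) numeric(0))
    if (length(px) == 0) return(NULL)
    c(ffg = mean(px < limits$LL), meg = mean(px > ul))
  }))
  if (length(sides) == 0) {
    abort(sprintf("empty ROI for muscle %s on subject %s", muscle,
                  subject$subject_id),
          class = "stirq_wf3_error")
  }
  v <- Reduce(`+`, sides) / length(sides)
  tibble::tibble(muscle = muscle, FFG = v[["ffg"]], MEG = v[["meg"]])
}

#' Per-muscle WF3 covariate tables
#'
#' For each muscle, two single-covariate datasets with one row per subject:
#' `(FFG, FF_pp)` for the fat-fraction target and `(MEG, wT2_ms)` for the
#' water-T2 target.
#'
#' @param cohort a `stirq_cohort` with ground truth.
#' @param limits a `stirq_limits`.
#' @param slice_selector function(subject) -> slice index.
#' @return Named list (per muscle) of lists with elements `FF` and `wT2`,
#'   each a tibble.
#' @export
build_wf3_tables <- function(cohort, limits, slice_selector = mid_slice) {
  rows <- purrr::map_dfr(cohort, function(s) {
    if (is.null(s$ground_truth)) {
      warn(sprintf("subject %s has no ground truth; excluded", s$subject_id))
      return(NULL)
    }
    purrr::map_dfr(calf_muscles(), function(m) {
      compute_ffg_meg(s, m, limits, slice_selector(s))
    }) |>
      dplyr::left_join(s$ground_truth, by = "muscle") |>
      dplyr::mutate(subject_id = s$subject_id, .before = 1)
  })
  if (nrow(rows) == 0) abort("no subject with ground truth",
                             class = "stirq_wf3_error")
  split(rows, rows$muscle)[calf_muscles()] |>
    purrr::map(function(tab) {
      list(
        FF = dplyr::select(tab, "subject_id", "FFG", "FF_pp"),
        wT2 = dplyr::select(tab, "subject_id", "MEG", "wT2_ms")
      )
    })
}
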