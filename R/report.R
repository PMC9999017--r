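#' Per-muscle volumes of a cohort
#'
#' Slab volume of each muscle ROI (left/right mean) on the selected slice,
#' in mL.
#'
#' @param cohort a `stirq_cohort`.
#' @param slice_selector function(subject) -> slice index.
#' @return Tibble: subject_id, muscle, volume_mL.
#' @export
muscle_volumes <- function(cohort, slice_selector = mid_slice) {
  purrr::map_dfr(cohort, function(s) {
    k <- slice_selector(s)
    mask <- s$masks[[k]]
    sl <- s$slices[[k]]
    lt <- s$label_table
    purrr::map_dfr(calf_muscles(), function(m) {
      vols <- purrr::map_dbl(roi_sides(), function(sd) {
        lab <- lt$label[lt$muscle == m & !is.na(lt$side) & lt$side == sd]
        n <- if (length(lab) == 1) sum(mask == lab) else 0
        n * sl$pixel_spacing^2 * sl$slice_thickness / 1000
      })
      vols <- vols[vols > 0]
      tibble::tibble(subject_id = s$subject_id, muscle = m,
                     volume_mL = mean(vols))
    })
  })
}

#' Muscle-wise coefficients of variation
#'
#' The CV (population SD / mean) of ground-truth FF, wT2 and muscle volume
#' across subjects, per muscle -- the variability ranges on which the models
#' are evaluated.
#'
#' @param cohort a `stirq_cohort` with ground truth.
#' @param slice_selector function(subject) -> slice index.
#' @return Tibble: muscle, CV_FF, CV_wT2, CV_volume, mean_volume_mL.
#' @export
muscle_cv_summary <- function(cohort, slice_selector = mid_slice) {
  gt <- ground_truth_table(cohort)
  vols <- muscle_volumes(cohort, slice_selector)
  dplyr::left_join(gt, vols, by = c("subject_id", "muscle")) |>
    dplyr::group_by(.data$muscle) |>
    dplyr::summarise(
      CV_FF = coefficient_of_variation(.data$FF_pp),
      CV_wT2 = coefficient_of_variation(.data$wT2_ms),
      CV_volume = coefficient_of_variation(.data$volume_mL),
      mean_volume_mL = mean(.data$volume_mL),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$muscle, calf_muscles()))
}

#' Correlation screen between KNN error and cohort variability
#'
#' Pearson and Spearman correlations (with two-sided p-values) between the
#' per-muscle KNN mean MAE and the per-muscle CV of volume, the CV of the
#' matching ground truth, and the mean volume: the pairings Vol-FF, Vol-wT2,
#' FF-FF, wT2-wT2, MeanVol-FF, MeanVol-wT2.
#'
#' @param study a `stirq_study` that includes KNN results.
#' @param cohort the cohort the study ran on (for ground truth and volumes).
#' @param workflow which workflow's KNN errors to screen (default: the
#'   first one in the study).
#' @param slice_selector function(subject) -> slice index.
#' @return Tibble: pairing, method, estimate, p_value.
#' @export
correlation_screen <- function(study, cohort, workflow = NULL,
                               slice_selector = mid_slice) {
  cells <- tidy(study) |> dplyr::filter(.data$model == "KNN")
  if (is.null(workflow)) workflow <- cells$workflow[1]
  cells <- dplyr::filter(cells, .data$workflow == !!workflow)
  if (nrow(cells) == 0) {
    abort("study has no KNN results for the requested workflow",
          class = "stirq_pipeline_error")
  }
  cvs <- muscle_cv_summary(cohort, slice_selector)
  knn <- cells |>
    dplyr::select("target", "muscle", "mean_mae") |>
    tidyr::pivot_wider(names_from = "target", values_from = "mean_mae")
  d <- dplyr::left_join(cvs, knn, by = "muscle")
  pairings <- list(
    `Vol-FF` = c("CV_volume", "FF"), `Vol-wT2` = c("CV_volume", "wT2"),
    `FF-FF` = c("CV_FF", "FF"), `wT2-wT2` = c("CV_wT2", "wT2"),
    `MeanVol-FF` = c("mean_volume_mL", "FF"),
    `MeanVol-wT2` = c("mean_volume_mL", "wT2")
  )
  purrr::imap_dfr(pairings, function(pair, name) {
    if (!pair[2] %in% names(d)) return(NULL)
    res <- tryCatch(correlate(d[[pair[1]]], d[[pair[2]]]),
                    stirq_regress_error = function(e) {
                      warn(sprintf("correlation %s undefined (%s); reporting NA",
                                   name, conditionMessage(e)))
                      tibble::tibble(method = c("pearson", "spearman"),
                                     estimate = NA_real_, p_value = NA_real_)
                    })
    dplyr::mutate(res, pairing = name, .before = 1)
  })
}

#' Write the study's summary files
#'
#' Emits, under `dir`:
#' * `results_<workflow>_<target>.csv` -- muscles x models, cells
#'   `"mean (sd)"` over folds;
#' * `results_folds.csv` -- the tidy fold-level results;
#' * `cv_table.csv` -- muscle-wise CVs of FF, wT2 and volume;
#' * `correlations_<workflow>.csv` -- the KNN correlation screen.
#'
#' Every file starts with a `#` header carrying the run's configuration
#' hash and seed for provenance.
#'
#' @param study a `stirq_study`.
#' @param cohort the cohort it ran on.
#' @param dir output directory (created if missing).
#' @param slice_selector function(subject) -> slice index.
#' @return Invisibly, the paths written.
#' @export
summarize_study <- function(study, cohort, dir, slice_selector = mid_slice) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- sprintf("# stirq run config=%s seed=%s",
                    rlang::hash(study$meta), study$meta$seed %||% "NA")
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    writeLines(header, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  paths <- character(0)
  cells <- tidy(study)
  for (wf in unique(cells$workflow)) {
    for (tg in unique(cells$target)) {
      wide <- cells |>
        dplyr::filter(.data$workflow == wf, .data$target == tg) |>
        dplyr::mutate(cell = sprintf("%.2f (%.2f)", .data$mean_mae,
                                     .data$sd_mae)) |>
        dplyr::select("muscle", "model", "cell") |>
        tidyr::pivot_wider(names_from = "model", values_from = "cell") |>
        dplyr::arrange(match(.data$muscle, calf_muscles()))
      paths <- c(paths, write_with_header(
        wide, file.path(dir, sprintf("results_%s_%s.csv", wf, tg))))
    }
  }
  paths <- c(paths, write_with_header(study$results,
                                      file.path(dir, "results_folds.csv")))
  cvs <- muscle_cv_summary(cohort, slice_selector)
  paths <- c(paths, write_with_header(cvs, file.path(dir, "cv_table.csv")))
  if ("KNN" %in% cells$model) {
    for (wf in unique(cells$workflow)) {
      screen <- correlation_screen(study, cohort, workflow = wf,
                                   slice_selector = slice_selector)
      paths <- c(paths, write_with_header(
        screen, file.path(dir, sprintf("correlations_%s.csv", wf))))
    }
  }
  invisible(paths)
}

#' Mean performance per model across muscles
#'
#' Companion plot to [autoplot.stirq_study()]: the muscle-averaged mean MAE
#' for each model and workflow.
#'
#' @param study a `stirq_study`.
#' @return A ggplot object.
#' @export
plot_model_summary <- function(study) {
  g <- glance(study)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$model, y = .data$mean_mae,
                                  fill = .data$workflow)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean MAE (muscle average)",
                  title = "Model-wise prediction performance") +
    ggplot2::theme_minimal()
}
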