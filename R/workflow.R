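#' Run one feature workflow end to end
#'
#' The three workflows share the cohort, the CV fold partition (same seed,
#' so model and workflow comparisons are paired across folds) and the seven
#' models; they differ in the covariates handed to the models:
#' * **WF1**: the 56 radiomic features reduced to `n_components` principal
#'   components;
#' * **WF2**: the feature subset minimizing the information imbalance
#'   towards the target;
#' * **WF3**: the single healthy-reference covariate (FFG for the FF target,
#'   MEG for wT2).
#'
#' With `fit_scope = "fold"` (default) the PCA and the imbalance selection
#' are re-fit inside each training fold, so no test-fold information leaks
#' into the reduction; `"global"` fits them once on the full table.
#'
#' @param wf_id 1, 2 or 3.
#' @param fshd diseased `stirq_cohort` with ground truth.
#' @param hc healthy-control cohort (required for WF3 unless `limits` given).
#' @param targets subset of `c("FF", "wT2")`.
#' @param models model names to run (default all seven).
#' @param seed seed for fold assignment and stochastic models.
#' @param k folds (default 5).
#' @param n_components principal components for WF1.
#' @param max_subset_size imbalance search cap for WF2.
#' @param fit_scope `"fold"` or `"global"` (WF1/WF2 reduction fitting).
#' @param limits optional precomputed `stirq_limits` for WF3.
#' @param slice_selector function(subject) -> slice index.
#' @param G gray levels for quantization (WF1/WF2).
#' @param normalize histogram-match both cohorts to the first HC mid slice
#'   before any computation (default FALSE: phantom cohorts are generated on
#'   a single common intensity scale).
#' @return A `stirq_study` containing the fold-level results tibble
#'   (`workflow`, `target`, `muscle`, `model`, `fold`, `mae`) and metadata.
#' @export
run_workflow <- function(wf_id, fshd, hc = NULL, targets = c("FF", "wT2"),
                         models = model_names(), seed = 1L, k = 5L,
                         n_components = 6L, max_subset_size = 5L,
                         fit_scope = c("fold", "global"), limits = NULL,
                         slice_selector = mid_slice, G = 64L,
                         normalize = FALSE) {
  fit_scope <- match.arg(fit_scope)
  stopifnot(wf_id %in% 1:3)
  targets <- match.arg(targets, several.ok = TRUE)

  if (normalize) {
    cfg <- histogram_match_config()
    if (is.null(hc)) {
      abort("normalize = TRUE needs the healthy-control cohort as reference",
            class = "stirq_pipeline_error")
    }
    ref <- find_reference_slice(list(hc), cfg)
    hc <- normalize_cohort(hc, cfg)
    fshd <- normalize_cohort(fshd, cfg, reference = ref$slice)
  }

  if (wf_id == 3) {
    if (is.null(limits)) {
      if (is.null(hc)) {
        abort("workflow 3 needs a healthy-control cohort (or precomputed limits)",
              class = "stirq_pipeline_error")
      }
      limits <- compute_reference_limits(hc)
    }
    wf3_tabs <- build_wf3_tables(fshd, limits, slice_selector)
  } else {
    feat_tabs <- build_feature_tables(fshd, slice_selector, G = G)
  }

  target_col <- c(FF = "FF_pp", wT2 = "wT2_ms")

  results <- purrr::map_dfr(targets, function(tg) {
    purrr::map_dfr(calf_muscles(), function(m) {
      if (wf_id == 3) {
        tab <- wf3_tabs[[m]][[tg]]
        x <- as.matrix(tab[, if (tg == "FF") "FFG" else "MEG"])
        y <- tab[[target_col[[tg]]]]
        transform <- NULL
      } else {
        tab <- feat_tabs[[m]]
        x <- as.matrix(tab[, feature_catalog()])
        y <- tab[[target_col[[tg]]]]
        if (wf_id == 1) {
          if (fit_scope == "fold") {
            transform <- function(x_tr, y_tr, x_te) {
              fit <- suppressWarnings(fit_pca(x_tr, n_components))
              list(train = project_pca(fit, x_tr), test = project_pca(fit, x_te))
            }
          } else {
            fit <- suppressWarnings(fit_pca(x, n_components))
            x <- project_pca(fit, x)
            transform <- NULL
          }
        } else {
          if (fit_scope == "fold") {
            transform <- function(x_tr, y_tr, x_te) {
              sel <- select_subset_by_imbalance(x_tr, y_tr, max_subset_size)
              list(train = x_tr[, sel$subset, drop = FALSE],
                   test = x_te[, sel$subset, drop = FALSE])
            }
          } else {
            sel <- select_subset_by_imbalance(scale(x), y, max_subset_size)
            x <- x[, sel$subset, drop = FALSE]
            transform <- NULL
          }
        }
      }
      purrr::map_dfr(models, function(mod) {
        cv <- cross_validate(x, y, model_spec(mod, seed = seed), k = k,
                             seed = seed, transform = transform)
        tibble::tibble(workflow = paste0("WF", wf_id), target = tg,
                       muscle = m, model = mod,
                       fold = seq_along(cv$fold_maes), mae = cv$fold_maes)
      })
    })
  })

  new_study(results, meta = list(seed = seed, k = k, wf = wf_id,
                                 fit_scope = fit_scope,
                                 normalize = normalize))
}

new_study <- function(results, meta = list()) {
  structure(list(results = results, meta = meta), class = "stirq_study")
}

#' Combine study fragments
#' @param ... `stirq_study` objects (e.g. one per workflow).
#' @return A single `stirq_study` with stacked results.
#' @export
combine_studies <- function(...) {
  frags <- list(...)
  new_study(purrr::map_dfr(frags, "results"),
            meta = frags[[1]]$meta)
}

#' @method print stirq_study
#' @export
print.stirq_study <- function(x, ...) {
  cat(sprintf("<stirq_study> %s; targets %s; %d muscle x model cells\n",
              paste(unique(x$results$workflow), collapse = "+"),
              paste(unique(x$results$target), collapse = "+"),
              nrow(dplyr::distinct(x$results, .data$workflow, .data$target,
                                   .data$muscle, .data$model))))
  invisible(x)
}

#' Per-cell summary of a study
#'
#' One row per workflow x target x muscle x model with the mean MAE over the
#' k folds and its across-fold sample SD (the "mean (sd)" cells of the
#' result tables).
#'
#' @param x a `stirq_study`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.stirq_study <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$workflow, .data$target, .data$muscle, .data$model) |>
    dplyr::summarise(mean_mae = mean(.data$mae), sd_mae = sd(.data$mae),
                     n_folds = dplyr::n(), .groups = "drop")
}

#' Model-level summary of a study
#'
#' Mean MAE per workflow x target x model, averaged over the six muscles.
#'
#' @param x a `stirq_study`.
#' @param ... unused.
#' @return A tibble.
#' @export
glance.stirq_study <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$workflow, .data$target, .data$model) |>
    dplyr::summarise(sd_across_muscles = sd(.data$mean_mae),
                     mean_mae = mean(.data$mean_mae),
                     .groups = "drop") |>
    dplyr::select("workflow", "target", "model", "mean_mae",
                  "sd_across_muscles")
}

#' @export
autoplot.stirq_study <- function(object, ...) {
  cells <- tidy(object)
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$muscle, y = .data$mean_mae,
                               fill = .data$workflow)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~ .data$target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean MAE over folds",
                  title = "Prediction error per muscle and workflow",
                  subtitle = "box = distribution over the seven models") +
    ggplot2::theme_minimal()
}
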