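#' Mean absolute error
#'
#' `MAE = (1/N) * sum_i |y_i - yhat_i|`.
#'
#' @param y observed values.
#' @param y_hat predictions of the same length.
#' @return A single non-negative number.
#' @export
#' @examples
#' mae(c(0, 10), c(10, 0))
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1) {
    abort("y and y_hat must have equal length >= 1",
          class = "stirq_regress_error")
  }
  mean(abs(y - y_hat))
}

#' Coefficient of variation
#'
#' `CV = sigma / mu` with the population (n) standard deviation.
#'
#' @param values non-empty numeric vector with non-zero mean.
#' @return A single number.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) == 0) abort("empty input", class = "stirq_regress_error")
  m <- mean(values)
  if (m == 0) abort("coefficient of variation undefined for zero mean",
                    class = "stirq_regress_error")
  sqrt(mean((values - m)^2)) / m
}

#' Pearson and Spearman correlation screen
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Tibble with one row per method: `method`, `estimate`, `p_value`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3", class = "stirq_regress_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
          class = "stirq_regress_error")
  }
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(
    method = c("pearson", "spearman"),
    estimate = c(unname(pe$estimate), unname(sp$estimate)),
    p_value = c(pe$p.value, sp$p.value)
  )
}

# seeded disjoint cover of 1..n into k contiguous shuffled folds whose sizes
# differ by at most one
make_folds <- function(n, k, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  split(idx, rep(seq_len(k), times = sizes))
}

#' k-fold cross-validated mean absolute error
#'
#' Rows are shuffled with the given seed and cut into `k` folds of
#' near-equal size (the same `n`, `k`, `seed` always give the same
#' partition, so different models and workflows are compared on paired
#' folds). For each fold the model is fit on the remaining folds and scored
#' on the held-out fold with [mae()]. Columns of `x` are standardized inside
#' the loop with training-fold statistics only; an optional `transform`
#' (e.g. a PCA or feature-subset selector) is likewise fit on the training
#' fold only.
#'
#' @param x matrix/data frame of covariates.
#' @param y numeric target.
#' @param spec a [model_spec()].
#' @param k number of folds (default 5).
#' @param seed seed for the fold shuffle.
#' @param transform optional `function(x_train, y_train, x_test)` returning
#'   `list(train = , test = )`, applied after standardization.
#' @return A `cv_result`: `fold_maes` (k values), `mean_mae` (their mean),
#'   `sd_mae` (sample SD across folds), `predictions` (tibble: row, fold,
#'   observed, predicted), `model`, `k`, `seed`.
#' @export
#' @examples
#' cv <- cross_validate(matrix(1:20), 2 * (1:20), model_spec("LR"), seed = 1)
#' cv$mean_mae < 1e-8
cross_validate <- function(x, y, spec, k = 5L, seed = 1L, transform = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) abort(sprintf("need at least k = %d rows, got %d", k, n),
                   class = "stirq_regress_error")
  folds <- make_folds(n, k, seed)
  preds <- purrr::imap_dfr(folds, function(test_idx, fold_name) {
    train_idx <- setdiff(seq_len(n), test_idx)
    mu <- colMeans(x[train_idx, , drop = FALSE])
    sg <- apply(x[train_idx, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, mu, "-"), 2, sg, "/")
    x_tr <- std(x[train_idx, , drop = FALSE])
    x_te <- std(x[test_idx, , drop = FALSE])
    if (!is.null(transform)) {
      tr <- transform(x_tr, y[train_idx], x_te)
      x_tr <- as.matrix(tr$train)
      x_te <- as.matrix(tr$test)
    }
    fold_spec <- spec
    fold_spec$seed <- spec$seed + as.integer(fold_name)
    y_hat <- fit_predict(fold_spec, x_tr, y[train_idx], x_te)
    tibble::tibble(row = test_idx, fold = as.integer(fold_name),
                   observed = y[test_idx], predicted = y_hat)
  })
  fold_maes <- preds |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(mae = mae(.data$observed, .data$predicted),
                     .groups = "drop") |>
    dplyr::pull(.data$mae)
  structure(list(
    fold_maes = fold_maes,
    mean_mae = mean(fold_maes),
    sd_mae = sd(fold_maes),
    predictions = preds,
    model = spec$name, k = k, seed = seed
  ), class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold: mean MAE %.3f (SD %.3f)\n",
              x$model, x$k, x$mean_mae, x$sd_mae))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_maes), mae = x$fold_maes)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(model = x$model, k = x$k, mean_mae = x$mean_mae,
                 sd_mae = x$sd_mae)
}
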