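#' Principal-component reduction of a feature table
#'
#' Features are z-scored with center/scale estimated from the fitting rows
#' only (zero-variance features are dropped with a warning), then decomposed
#' with [stats::prcomp()]. `project_pca()` applies a fitted model's
#' center/scale/loadings to new rows.
#'
#' @param x a data frame or matrix of feature columns (numeric only).
#' @param n_components number of components to retain (default 6, which on
#'   the study's feature tables retains about 90% of the variance).
#' @return `fit_pca()` returns a `stirq_pca` with `loadings`
#'   (features x components, orthonormal), `explained_variance_ratio`
#'   (over all components, non-increasing, summing to 1), `center`, `scale`
#'   and `features`. `project_pca()` returns a matrix of scores with
#'   `n_components` columns.
#' @export
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' fit <- fit_pca(m, n_components = 2)
#' dim(project_pca(fit, m))
fit_pca <- function(x, n_components = 6L) {
  x <- as.matrix(x)
  if (nrow(x) < n_components) {
    abort("fewer rows than requested components", class = "stirq_reduce_error")
  }
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d zero-variance feature(s) before PCA: %s",
                 sum(!keep), paste(colnames(x)[!keep], collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$rotation))
  structure(list(
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance_ratio = evr,
    center = pc$center, scale = pc$scale,
    features = colnames(x), n_components = k
  ), class = "stirq_pca")
}

#' @rdname fit_pca
#' @param model a fitted `stirq_pca`.
#' @param newdata rows to project (must contain the fitted features).
#' @export
project_pca <- function(model, newdata) {
  x <- as.matrix(newdata)[, model$features, drop = FALSE]
  x <- sweep(x, 2, model$center, "-")
  x <- sweep(x, 2, model$scale, "/")
  x %*% model$loadings
}

#' @export
glance.stirq_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    cum_variance_retained = sum(x$explained_variance_ratio[seq_len(x$n_components)]),
    n_features = length(x$features)
  )
}

#' @export
tidy.stirq_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance_ratio),
                 explained_variance_ratio = x$explained_variance_ratio)
}

# pairwise Euclidean rank structure for one space; ranks start at 1 for the
# nearest non-self neighbour, ties broken by ascending point index
rank_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  ranks <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others], others)]
    ranks[i, ord] <- seq_len(n - 1)
  }
  ranks
}

#' Information imbalance between two spaces
#'
#' Estimates `Delta(A -> B) = (2/N) * mean_i rank_B(nn_A(i))`: for each point
#' find its nearest non-self neighbour under Euclidean distance in space A,
#' look up that neighbour's distance rank from the same point in space B, and
#' average. Low values mean neighbourhoods in A predict neighbourhoods in B.
#' The lower bound is `2/N` (every nearest neighbour in A is also nearest in
#' B). Ties in either space are broken by ascending point index, so the
#' estimate is reproducible on discretized data.
#'
#' @param A matrix/data frame of coordinates in the predictor space (rows =
#'   points); a vector is treated as one column.
#' @param B coordinates in the target space (typically the 1-D biomarker).
#' @return A single number `>= 2/N`.
#' @export
#' @examples
#' information_imbalance(c(0, 1, 10), c(0, 10, 1))  # 4/3
information_imbalance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (nrow(B) != n) abort("A and B must have the same number of rows",
                          class = "stirq_reduce_error")
  if (n < 3) abort("information imbalance needs at least 3 points",
                   class = "stirq_reduce_error")
  if (all(B == B[1])) abort("constant target: ranks in B are undefined",
                            class = "stirq_reduce_error")
  dA <- as.matrix(dist(A))
  rB <- rank_matrix(B)
  nn_rank_b <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(dA[i, others], others)][1]
    as.numeric(rB[i, nn])
  }, numeric(1))
  2 * mean(nn_rank_b) / n
}

#' Feature-subset selection by minimal information imbalance
#'
#' Searches for the feature subset whose Euclidean space has minimal
#' information imbalance towards the (1-D) target: exhaustively over all
#' subsets of size 1 and 2, then greedy forward (adding the single feature
#' that most reduces the imbalance) up to `max_size`. Features are z-scored
#' before distance computation. Returns the subset attaining the minimum of
#' the whole size-vs-imbalance curve.
#'
#' @param x data frame/matrix of candidate features.
#' @param target numeric target vector.
#' @param max_size largest subset size explored (default 5).
#' @return A `stirq_imbalance` list: `subset` (feature names), `delta`
#'   (its imbalance), `N`, and `curve` (tibble: size, delta, subset).
#' @export
select_subset_by_imbalance <- function(x, target, max_size = 5L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  max_size <- min(max_size, ncol(x))
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  x <- x[, keep, drop = FALSE]
  z <- scale(x)
  n <- nrow(z)
  feats <- colnames(z)

  # fast evaluation path: squared-difference matrix per feature (distances of
  # a subset are element-wise sums, and ranks only need squared distances)
  # and the target's rank matrix, both computed once
  dsq <- lapply(feats, function(f) as.matrix(dist(z[, f]))^2)
  names(dsq) <- feats
  rB <- rank_matrix(as.matrix(target))
  delta_of <- function(members) {
    D <- Reduce(`+`, dsq[members])
    diag(D) <- Inf
    nn <- max.col(-D, ties.method = "first")
    2 * mean(rB[cbind(seq_len(n), nn)]) / n
  }

  curve <- tibble::tibble(size = integer(), delta = numeric(),
                          subset = character())
  best_of_size <- list()

  singles <- vapply(feats, function(f) delta_of(f), numeric(1))
  k1 <- which.min(singles)
  best_of_size[[1]] <- feats[k1]
  curve <- dplyr::add_row(curve, size = 1L, delta = singles[[k1]],
                          subset = feats[k1])

  if (max_size >= 2 && length(feats) >= 2) {
    pairs <- utils::combn(feats, 2, simplify = FALSE)
    deltas <- vapply(pairs, delta_of, numeric(1))
    k2 <- which.min(deltas)
    best_of_size[[2]] <- pairs[[k2]]
    curve <- dplyr::add_row(curve, size = 2L, delta = deltas[k2],
                            subset = paste(pairs[[k2]], collapse = "+"))
  }

  size <- length(best_of_size)
  while (size < max_size) {
    current <- best_of_size[[size]]
    candidates <- setdiff(feats, current)
    if (length(candidates) == 0) break
    deltas <- vapply(candidates, function(f) delta_of(c(current, f)),
                     numeric(1))
    k <- which.min(deltas)
    size <- size + 1L
    best_of_size[[size]] <- c(current, candidates[k])
    curve <- dplyr::add_row(curve, size = size, delta = deltas[[k]],
                            subset = paste(best_of_size[[size]], collapse = "+"))
  }

  best <- which.min(curve$delta)
  structure(list(
    subset = best_of_size[[curve$size[best]]],
    delta = curve$delta[best],
    N = n, curve = curve
  ), class = "stirq_imbalance")
}

#' @method print stirq_imbalance
#' @export
print.stirq_imbalance <- function(x, ...) {
  cat(sprintf("<stirq_imbalance> Delta = %.4f (N = %d) with {%s}\n",
              x$delta, x$N, paste(x$subset, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.stirq_imbalance <- function(x, ...) x$curve

#' @export
autoplot.stirq_imbalance <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$size, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "feature-subset size",
                  y = expression(Delta(A %->% B)),
                  title = "Optimized information imbalance by subset size") +
    ggplot2::theme_minimal()
}
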