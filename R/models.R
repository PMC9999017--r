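#' Regression model specifications
#'
#' The seven models compared in the study, with fixed, documented
#' hyperparameters (there is no tuning):
#' * `LR` ordinary least squares;
#' * `Ridge` L2-penalized least squares, penalty `alpha = 1` on the
#'   sum-of-squares objective, intercept unpenalized (closed form);
#' * `Lasso` L1-penalized, `lambda = 0.01` on the mean-squared objective
#'   (glmnet);
#' * `TREE` regression tree, max depth 5, no complexity pruning (rpart);
#' * `RF` random forest, 100 trees, seeded (randomForest);
#' * `KNN` k-nearest-neighbour mean with `k_nn = 5`, Euclidean distance,
#'   distance ties broken by training-row index;
#' * `SVM` eps-regression, radial kernel, `C = 1`, `epsilon = 0.1` (e1071).
#'
#' Inputs are expected column-standardized (the CV engine standardizes with
#' training-fold statistics).
#'
#' @param name one of `"LR"`, `"Ridge"`, `"Lasso"`, `"TREE"`, `"RF"`,
#'   `"KNN"`, `"SVM"`.
#' @param seed integer seed applied before fitting stochastic models.
#' @param k_nn,ridge_alpha,lasso_lambda,tree_max_depth,rf_ntree,svm_cost,svm_epsilon
#'   hyperparameter overrides.
#' @return A `model_spec` list.
#' @export
#' @examples
#' model_spec("KNN")$k_nn
model_spec <- function(name, seed = 1L, k_nn = 5L, ridge_alpha = 1,
                       lasso_lambda = 0.01, tree_max_depth = 5L,
                       rf_ntree = 100L, svm_cost = 1, svm_epsilon = 0.1) {
  if (!name %in% model_names()) {
    abort(sprintf("unknown model '%s'; must be one of %s", name,
                  paste(model_names(), collapse = ", ")),
          class = "stirq_regress_error")
  }
  structure(list(name = name, seed = as.integer(seed), k_nn = as.integer(k_nn),
                 ridge_alpha = ridge_alpha, lasso_lambda = lasso_lambda,
                 tree_max_depth = as.integer(tree_max_depth),
                 rf_ntree = as.integer(rf_ntree), svm_cost = svm_cost,
                 svm_epsilon = svm_epsilon),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
model_names <- function() c("LR", "Ridge", "Lasso", "TREE", "RF", "KNN", "SVM")

#' Fit a model on training rows and predict test rows
#'
#' @param spec a [model_spec()].
#' @param x_train,x_test numeric matrices (columns already standardized).
#' @param y_train numeric target.
#' @return Numeric predictions, one per test row.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (!inherits(spec, "model_spec")) {
    abort("spec must be a model_spec", class = "stirq_regress_error")
  }
  set.seed(spec$seed)
  switch(spec$name,
    LR = {
      fit <- stats::lm.fit(cbind(1, x_train), y_train)
      as.vector(cbind(1, x_test) %*% fit$coefficients)
    },
    Ridge = ridge_predict(x_train, y_train, x_test, spec$ridge_alpha),
    Lasso = lasso_predict(x_train, y_train, x_test, spec$lasso_lambda),
    TREE = {
      df <- as.data.frame(x_train); df$.y <- y_train
      if (nrow(df) < 2) return(rep(mean(y_train), nrow(x_test)))
      fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                          control = rpart::rpart.control(
                            maxdepth = spec$tree_max_depth, minsplit = 2,
                            minbucket = 1, cp = 0, xval = 0))
      unname(predict(fit, newdata = as.data.frame(x_test)))
    },
    RF = {
      fit <- randomForest::randomForest(x = x_train, y = y_train,
                                        ntree = spec$rf_ntree)
      unname(predict(fit, newdata = x_test))
    },
    KNN = knn_predict(x_train, y_train, x_test, spec$k_nn),
    SVM = {
      fit <- e1071::svm(x = x_train, y = y_train, type = "eps-regression",
                        kernel = "radial", cost = spec$svm_cost,
                        epsilon = spec$svm_epsilon, scale = FALSE)
      unname(predict(fit, newdata = x_test))
    }
  )
}

# ridge with unpenalized intercept: minimizes ||y - b0 - X b||^2 + a ||b||^2
ridge_predict <- function(x_train, y_train, x_test, alpha) {
  xc <- scale(x_train, center = TRUE, scale = FALSE)
  yc <- y_train - mean(y_train)
  p <- ncol(xc)
  beta <- solve(crossprod(xc) + alpha * diag(p), crossprod(xc, yc))
  b0 <- mean(y_train) - as.vector(colMeans(x_train) %*% beta)
  as.vector(x_test %*% beta) + b0
}

# lasso via glmnet at a fixed lambda; glmnet needs >= 2 columns, and for a
# single covariate the column is duplicated -- the L1 objective and the
# predictions are invariant to how the coefficient splits across duplicates
lasso_predict <- function(x_train, y_train, x_test, lambda) {
  dup <- ncol(x_train) == 1
  if (dup) {
    x_train <- cbind(x_train, x_train)
    x_test <- cbind(x_test, x_test)
  }
  fit <- glmnet::glmnet(x_train, y_train, alpha = 1, lambda = lambda,
                        standardize = FALSE)
  as.vector(predict(fit, newx = x_test, s = lambda))
}

# mean target of the k nearest training rows (Euclidean); distance ties are
# broken by ascending training-row index
knn_predict <- function(x_train, y_train, x_test, k) {
  k <- min(k, nrow(x_train))
  apply(x_test, 1, function(row) {
    d <- sqrt(colSums((t(x_train) - row)^2))
    mean(y_train[order(d, seq_along(d))[seq_len(k)]])
  })
}
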