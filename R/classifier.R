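#' RBF-SVM hyperparameter configuration
#'
#' Bundle of the cost parameter C and kernel width gamma for the
#' radial-basis-function SVM classifier.
#'
#' @param cost Positive real, the soft-margin cost C.
#' @param gamma Positive real, the RBF kernel width.
#' @return Object of class `"svm_config"`.
#' @export
svm_config <- function(cost, gamma) {
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0)
    stop("'cost' must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a single positive number")
  structure(list(cost = as.numeric(cost), gamma = as.numeric(gamma)),
            class = "svm_config")
}

#' @export
print.svm_config <- function(x, ...) {
  cat(sprintf("RBF-SVM config: C = %g (2^%.3g), gamma = %g (2^%.3g)\n",
              x$cost, log2(x$cost), x$gamma, log2(x$gamma)))
  invisible(x)
}

#' Default LIBSVM-style hyperparameter grids
#'
#' The coarse grid recommended in the LIBSVM guide: C = 2^-5, 2^-3, ...,
#' 2^15 (11 values) and gamma = 2^-15, 2^-13, ..., 2^3 (10 values).
#'
#' @name svm_grids
#' @export
default_cost_grid <- function() 2^seq(-5L, 15L, 2L)

#' @rdname svm_grids
#' @export
default_gamma_grid <- function() 2^seq(-15L, 3L, 2L)

#' Grid-search RBF-SVM hyperparameters by cross-validation
#'
#' Evaluates every (C, gamma) pair on a stratified k-fold CV overall
#' accuracy and returns the best configuration. Ties prefer the smaller C,
#' then the smaller gamma (the simpler model).
#'
#' @param data A [pssm_dataset()].
#' @param cost_grid,gamma_grid Positive numeric grids; defaults are the
#'   LIBSVM coarse grids ([default_cost_grid()], [default_gamma_grid()]).
#' @param folds CV folds (default 5); must not exceed the smallest class
#'   size.
#' @param seed Integer seed for the fold assignment.
#' @param features Optional column subset to tune on (default all).
#' @return The winning [svm_config()], with attribute `"cv_table"` holding
#'   the full (cost, gamma, accuracy) table.
#' @export
grid_search <- function(data, cost_grid = default_cost_grid(),
                        gamma_grid = default_gamma_grid(),
                        folds = 5L, seed = 1L, features = NULL) {
  stopifnot(inherits(data, "pssm_dataset"))
  if (length(cost_grid) == 0L || length(gamma_grid) == 0L)
    stop("hyperparameter grids must be non-empty")
  if (any(cost_grid <= 0) || any(gamma_grid <= 0))
    stop("grid values must be positive")
  if (folds < 2L) stop("'folds' must be at least 2")
  y <- droplevels(data$labels)
  if (folds > min(table(y)))
    stop("fold count (", folds, ") exceeds the smallest class size (",
         min(table(y)), ")")
  x <- if (is.null(features)) data$x else data$x[, features, drop = FALSE]
  fold_id <- stratified_folds(y, folds, seed)
  grid <- expand.grid(gamma = sort(gamma_grid), cost = sort(cost_grid))
  grid <- grid[order(grid$cost, grid$gamma), c("cost", "gamma")]
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (!any(!tr)) next
      fit <- e1071::svm(x[tr, , drop = FALSE], droplevels(y[tr]),
                        kernel = "radial", cost = grid$cost[i],
                        gamma = grid$gamma[i], scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    acc[i] <- correct / nrow(x)
  }
  best <- which.max(acc)  # grid sorted by (cost, gamma): ties -> simpler model
  out <- svm_config(grid$cost[best], grid$gamma[best])
  attr(out, "cv_table") <- cbind(grid, accuracy = acc)
  out
}

#' Train a multiclass RBF-SVM
#'
#' Fits a one-vs-one multiclass SVM with the radial kernel on the selected
#' feature columns. Features are used as-is (no internal rescaling): the
#' GapDPC features from sigmoid-scaled profiles are already bounded.
#'
#' @param data A [pssm_dataset()] with at least two classes.
#' @param config An [svm_config()].
#' @param features Integer indices of the columns to train on (default
#'   all).
#' @return Object of class `"pssm_svm"`: the fitted SVM plus the feature
#'   indices, class levels, source dimensionality and config.
#' @export
svm_train <- function(data, config, features = NULL) {
  stopifnot(inherits(data, "pssm_dataset"), inherits(config, "svm_config"))
  y <- droplevels(data$labels)
  if (nlevels(y) < 2L) stop("training needs at least 2 classes")
  d <- ncol(data$x)
  if (is.null(features)) features <- seq_len(d)
  features <- as.integer(features)
  if (any(features < 1L | features > d))
    stop("feature index out of range 1..", d)
  fit <- e1071::svm(data$x[, features, drop = FALSE], y,
                    kernel = "radial", cost = config$cost,
                    gamma = config$gamma, scale = FALSE)
  structure(list(fit = fit, features = features, classes = levels(y),
                 d_source = d, config = config),
            class = "pssm_svm")
}

#' @export
print.pssm_svm <- function(x, ...) {
  cat("RBF-SVM classifier:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), ")\n")
  cat("  trained on", length(x$features), "of", x$d_source, "features;",
      x$fit$tot.nSV, "support vectors\n")
  print(x$config)
  invisible(x)
}

#' Predict structural classes
#'
#' @param object A `"pssm_svm"` from [svm_train()].
#' @param newdata Numeric matrix (or single vector) whose width equals
#'   either the training source dimensionality (columns are subset to the
#'   model's features) or the number of selected features directly.
#' @param ... Unused.
#' @return Factor of predicted class labels, one per row.
#' @export
predict.pssm_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == object$d_source) {
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != length(object$features)) {
    stop("feature dimension mismatch: expected ", object$d_source,
         " (full) or ", length(object$features),
         " (selected) columns, got ", ncol(newdata))
  }
  pred <- predict(object$fit, newdata)
  factor(as.character(pred), levels = object$classes)
}

MODEL_FORMAT <- "pssmclass-model-v1"

#' Persist and restore a trained classifier
#'
#' Serializes the fitted SVM together with its feature indices, class
#' order and configuration under a version tag; loading refuses files
#' whose tag does not match the current format.
#'
#' @param model A `"pssm_svm"`.
#' @param file Path.
#' @return `save_model` returns `file` invisibly; `load_model` the model.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "pssm_svm"))
  saveRDS(list(format = MODEL_FORMAT, model = model), file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  obj <- readRDS(file)
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop("not a ", MODEL_FORMAT, " file: found tag '",
         if (is.list(obj)) obj$format else class(obj)[1], "'")
  obj$model
}
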