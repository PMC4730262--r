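#' Fit the full structural-class prediction pipeline
#'
#' One-call fit of the complete method: rank the GapDPC features by
#' SVM-RFE, keep the top K, grid-search the RBF-SVM hyperparameters (C,
#' gamma) by stratified cross-validation, and train the final one-vs-one
#' multiclass classifier. Returns a model object with `print`, `summary`
#' and `predict` methods; prediction accepts either feature matrices or
#' scaled PSSM profiles (features are then extracted with the same
#' `max_gap` the training data used).
#'
#' @param data A [pssm_dataset()], typically from [extract_dataset()].
#' @param K Number of top-ranked features to keep; `NULL` keeps all
#'   columns and skips ranking.
#' @param rfe_step,c_linear Passed to [rank_features()].
#' @param tune Grid-search (C, gamma) (default `TRUE`); otherwise C = 1,
#'   gamma = 1/K.
#' @param cost_grid,gamma_grid,folds Passed to [grid_search()].
#' @param seed Integer seed for all fold assignments.
#' @param ranking Optional precomputed [rank_features()] result to reuse.
#' @param config Optional fixed [svm_config()], bypassing tuning.
#' @param features Optional explicit feature subset, bypassing ranking.
#' @return Object of class `"pssmclass"`.
#' @examples
#' syn <- make_feature_dataset(n_per_class = 12, d = 40, n_informative = 6,
#'                             effect = 2.5, seed = 7)
#' fit <- pssmclass(syn$data, K = 10, tune = FALSE)
#' fit
#' table(truth = syn$data$labels, predicted = predict(fit, syn$data$x))
#' @export
pssmclass <- function(data, K = NULL, rfe_step = 0.1, c_linear = 1,
                      tune = TRUE, cost_grid = default_cost_grid(),
                      gamma_grid = default_gamma_grid(), folds = 5L,
                      seed = 1L, ranking = NULL, config = NULL,
                      features = NULL) {
  stopifnot(inherits(data, "pssm_dataset"))
  if (is.null(ranking) && !is.null(K) && is.null(features))
    ranking <- rank_features(data, step = rfe_step, cost = c_linear)
  rp <- resolve_pipeline(data, K, ranking, features, config, tune,
                         rfe_step, c_linear, cost_grid, gamma_grid,
                         folds, seed)
  model <- svm_train(data, rp$config, rp$features)
  structure(list(model = model, ranking = rp$ranking,
                 features = rp$features, config = rp$config,
                 classes = model$classes, K = K,
                 max_gap = attr(data, "max_gap"),
                 n = nrow(data$x), d = ncol(data$x), seed = seed,
                 call = match.call()),
            class = "pssmclass")
}

#' @export
print.pssmclass <- function(x, ...) {
  cat("Structural-class predictor (GapDPC + SVM-RFE + RBF-SVM)\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  trained on", x$n, "proteins;", length(x$features), "of", x$d,
      "features", if (!is.null(x$K)) sprintf("(top K = %d by SVM-RFE)", x$K),
      "\n")
  print(x$config)
  invisible(x)
}

#' @export
summary.pssmclass <- function(object, ...) {
  print(object)
  if (!is.null(object$ranking)) {
    top <- utils::head(object$ranking$order, 10L)
    cat("Top-ranked features:\n")
    print(decode_feature_index(top), row.names = FALSE)
  }
  invisible(object)
}

#' @export
predict.pssmclass <- function(object, newdata, ...) {
  if (inherits(newdata, "pssm_profile")) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) &&
      inherits(newdata[[1]], "pssm_profile")) {
    mg <- object$max_gap
    if (is.null(mg))
      stop("model was not trained on GapDPC features with a recorded ",
           "max_gap; supply a feature matrix instead")
    newdata <- t(vapply(newdata, feature_vector, numeric(object$d),
                        max_gap = mg))
  }
  if (inherits(newdata, "pssm_dataset")) newdata <- newdata$x
  predict(object$model, newdata, ...)
}
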