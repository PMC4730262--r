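# Stratified fold assignment: per class, shuffled near-equal fold labels,
# so per-fold class proportions differ by at most one sample.
stratified_folds <- function(labels, folds, seed) {
  labels <- factor(labels)
  n <- length(labels)
  folds <- as.integer(folds)
  if (folds == n) return(seq_len(n))  # leave-one-out
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

#' One-vs-rest confusion counts
#'
#' Cross-tabulates true against predicted labels and derives, for every
#' class j, the one-vs-rest counts TP_j, TN_j, FP_j, FN_j together with the
#' class sizes |C_j|. These are the raw ingredients of per-class accuracy,
#' Matthews correlation and overall accuracy.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Optional class set; labels outside it are an error.
#'   Defaults to the sorted union of observed labels.
#' @return Object of class `"confusion_counts"`: list with the k x k
#'   confusion `table` (rows = truth), vectors `tp`, `tn`, `fp`, `fn`,
#'   `sizes`, the `classes` and total `n`.
#' @export
confusion_counts <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth (", length(truth), ") and predicted (", length(predicted),
         ") lengths differ")
  if (length(truth) == 0L) stop("empty label vectors")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(c(truth, predicted), classes)
  if (length(bad))
    stop("label(s) outside the class set: ", paste(unique(bad), collapse = ", "))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  tab <- table(truth = tf, predicted = pf)
  tp <- diag(tab)
  sizes <- rowSums(tab)
  fn <- sizes - tp
  fp <- colSums(tab) - tp
  tn <- sum(tab) - tp - fn - fp
  structure(list(table = tab, tp = as.numeric(tp), tn = as.numeric(tn),
                 fp = as.numeric(fp), fn = as.numeric(fn),
                 sizes = as.numeric(sizes), classes = classes,
                 n = length(truth)),
            class = "confusion_counts")
}

#' Per-class and overall accuracy, and Matthews correlation
#'
#' `class_accuracy` is TP_j / |C_j| per class (NA when the class has no
#' members: an empty class has no defined sensitivity). `class_mcc` is the
#' per-class one-vs-rest Matthews correlation coefficient
#' \deqn{MCC_j = \frac{TP_j TN_j - FP_j FN_j}{\sqrt{(TP_j+FP_j)(TP_j+FN_j)(TN_j+FP_j)(TN_j+FN_j)}},}
#' with the standard convention MCC = 0 when any factor of the denominator
#' vanishes. `overall_accuracy` is the pooled sum of TP over n.
#'
#' @param counts A [confusion_counts()].
#' @return Named numeric vector (per class) or single number.
#' @export
class_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  acc <- ifelse(counts$sizes > 0, counts$tp / counts$sizes, NA_real_)
  names(acc) <- counts$classes
  acc
}

#' @rdname class_accuracy
#' @export
class_mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(denom2 > 0, (tp * tn - fp * fn) / sqrt(denom2), 0)
  names(mcc) <- counts$classes
  mcc
}

#' @rdname class_accuracy
#' @export
overall_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sum(counts$tp) / counts$n
}

# Assemble an eval_report from truth/prediction vectors.
make_eval_report <- function(truth, predicted, classes, protocol) {
  cc <- confusion_counts(truth, predicted, classes)
  structure(list(confusion = cc$table, counts = cc,
                 accuracy = class_accuracy(cc), mcc = class_mcc(cc),
                 overall = overall_accuracy(cc), n = cc$n,
                 protocol = protocol),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  p <- x$protocol
  cat(sprintf("%s evaluation, n = %d%s\n",
              switch(p$protocol, jackknife = "Jackknife (leave-one-out)",
                     kfold = sprintf("Stratified %d-fold CV", p$folds),
                     p$protocol),
              x$n,
              if (isTRUE(p$nested)) " [nested selection/tuning]" else ""))
  df <- data.frame(n = x$counts$sizes,
                   accuracy = round(x$accuracy, digits),
                   MCC = round(x$mcc, digits))
  rownames(df) <- x$counts$classes
  print(df)
  cat(sprintf("Overall accuracy: %.*f\n", digits, x$overall))
  if (length(p$flagged))
    cat("Degenerate training folds (a class absent) for:",
        paste(p$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes confusion counts, per-class metrics, overall accuracy and the
#' full protocol descriptor (seeds, configuration, nesting) as JSON.
#'
#' @param report An `"eval_report"`.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_eval_json <- function(report, file) {
  stopifnot(inherits(report, "eval_report"))
  p <- report$protocol
  p$config <- if (!is.null(p$config)) unclass(p$config)
  out <- list(
    protocol = p,
    n = report$n,
    classes = report$counts$classes,
    confusion = as.vector(t(unclass(report$confusion))),
    class_sizes = report$counts$sizes,
    tp = report$counts$tp, tn = report$counts$tn,
    fp = report$counts$fp, fn = report$counts$fn,
    accuracy = as.list(report$accuracy),
    mcc = as.list(report$mcc),
    overall_accuracy = report$overall)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}

# Resolve the selection + configuration stage of the pipeline on `data`.
resolve_pipeline <- function(data, K, ranking, features, config, tune,
                             rfe_step, c_linear, cost_grid, gamma_grid,
                             tune_folds, seed) {
  if (is.null(features)) {
    if (is.null(K)) {
      features <- seq_len(ncol(data$x))
    } else {
      if (is.null(ranking))
        ranking <- rank_features(data, step = rfe_step, cost = c_linear)
      features <- select_top_k(ranking, K)
    }
  }
  if (is.null(config)) {
    config <- if (tune) {
      grid_search(data, cost_grid, gamma_grid, folds = tune_folds,
                  seed = seed, features = features)
    } else {
      svm_config(1, 1 / length(features))
    }
  }
  list(features = features, config = config, ranking = ranking)
}

#' Jackknife (leave-one-out) evaluation of the full pipeline
#'
#' Each protein is predicted by an RBF-SVM trained on the other n - 1. By
#' default the pipeline follows the classical (optimistic) protocol: the
#' SVM-RFE ranking, the top-K cut and the (C, gamma) configuration are
#' fixed once on the full dataset and only the SVM is refit per left-out
#' sample. `nested = TRUE` instead re-runs ranking, selection and
#' (optionally) tuning inside every fold, giving an unbiased but much more
#' expensive estimate. The protocol actually used is recorded in the
#' report.
#'
#' @param data A [pssm_dataset()] with n >= number of classes + 1.
#' @param K Number of top-ranked features to use; `NULL` (with `features`
#'   `NULL`) uses all columns and skips ranking.
#' @param features Explicit feature subset, overriding `K`/`ranking`.
#' @param ranking Optional precomputed [rank_features()] result.
#' @param config Optional fixed [svm_config()]; when `NULL`, tuned by
#'   [grid_search()] if `tune = TRUE`, else C = 1, gamma = 1/K.
#' @param tune Grid-search (C, gamma) instead of using the default config.
#' @param nested Re-run selection (and tuning if `tune`) inside every
#'   training fold.
#' @param rfe_step,c_linear Passed to [rank_features()].
#' @param cost_grid,gamma_grid,tune_folds Passed to [grid_search()].
#' @param seed Integer seed controlling all fold assignments.
#' @return An `"eval_report"`.
#' @export
jackknife <- function(data, K = NULL, features = NULL, ranking = NULL,
                      config = NULL, tune = FALSE, nested = FALSE,
                      rfe_step = 0.1, c_linear = 1,
                      cost_grid = default_cost_grid(),
                      gamma_grid = default_gamma_grid(),
                      tune_folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "pssm_dataset"))
  y <- droplevels(data$labels)
  n <- nrow(data$x)
  if (nlevels(y) < 2L) stop("evaluation needs at least 2 classes")
  if (n < nlevels(y) + 1L)
    stop("jackknife needs n >= number of classes + 1")
  counts <- table(y)
  if (nested && tune && any(counts < 2L))
    stop("nested stratified tuning impossible: class(es) with a single member")
  fold_id <- seq_len(n)
  res <- run_cv_protocol(data, y, fold_id, K, features, ranking, config,
                         tune, nested, rfe_step, c_linear, cost_grid,
                         gamma_grid, tune_folds, seed)
  protocol <- c(list(protocol = "jackknife", n = n, seed = seed), res$meta)
  make_eval_report(as.character(y), res$pred, levels(y), protocol)
}

#' Stratified k-fold evaluation of the full pipeline
#'
#' k-fold analogue of [jackknife()]: folds are stratified by class and
#' seeded; `folds = n` reduces to the jackknife.
#'
#' @inheritParams jackknife
#' @param folds Number of folds (default 5), 2..n.
#' @return An `"eval_report"`.
#' @export
kfold <- function(data, folds = 5L, K = NULL, features = NULL,
                  ranking = NULL, config = NULL, tune = FALSE,
                  nested = FALSE, rfe_step = 0.1, c_linear = 1,
                  cost_grid = default_cost_grid(),
                  gamma_grid = default_gamma_grid(),
                  tune_folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "pssm_dataset"))
  y <- droplevels(data$labels)
  n <- nrow(data$x)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) stop("'folds' must be in 2..n")
  if (nlevels(y) < 2L) stop("evaluation needs at least 2 classes")
  fold_id <- stratified_folds(y, folds, seed)
  res <- run_cv_protocol(data, y, fold_id, K, features, ranking, config,
                         tune, nested, rfe_step, c_linear, cost_grid,
                         gamma_grid, tune_folds, seed)
  protocol <- c(list(protocol = "kfold", folds = folds, n = n, seed = seed),
                res$meta)
  make_eval_report(as.character(y), res$pred, levels(y), protocol)
}

# Shared CV engine: train on each fold complement, predict the fold.
run_cv_protocol <- function(data, y, fold_id, K, features, ranking, config,
                            tune, nested, rfe_step, c_linear, cost_grid,
                            gamma_grid, tune_folds, seed) {
  n <- nrow(data$x)
  if (!nested) {
    rp <- resolve_pipeline(data, K, ranking, features, config, tune,
                           rfe_step, c_linear, cost_grid, gamma_grid,
                           tune_folds, seed)
  }
  pred <- character(n)
  flagged <- character(0)
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    train_data <- subset_dataset(data, !test)
    if (nested) {
      rp <- resolve_pipeline(train_data, K, NULL, features, config, tune,
                             rfe_step, c_linear, cost_grid, gamma_grid,
                             tune_folds, seed)
    }
    ytr <- droplevels(train_data$labels)
    if (nlevels(ytr) < nlevels(y))
      flagged <- c(flagged, data$ids[test])
    model <- svm_train(train_data, rp$config, rp$features)
    pred[test] <- as.character(predict(model, data$x[test, , drop = FALSE]))
  }
  list(pred = pred,
       meta = list(K = if (is.null(K)) NA_integer_ else K,
                   n_features = length(rp$features), nested = nested,
                   tune = tune, config = rp$config, flagged = flagged))
}
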