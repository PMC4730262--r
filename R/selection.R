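#' Rank features by SVM recursive feature elimination
#'
#' Classic SVM-RFE: repeatedly fit a linear-kernel SVM on the surviving
#' features, score every feature by its squared weight, drop the weakest
#' `step` features, and record the elimination order. The rank of a feature
#' is the reverse of when it was eliminated (last survivor = rank 1).
#'
#' With more than two classes the weight criterion is the sum of squared
#' per-feature weights over all one-vs-one binary classifiers, the pairwise
#' analogue of the original two-class w^2 criterion. Ties favour the lower
#' original index (it is kept longer), so a dataset of identical columns
#' ranks 1, 2, ..., d.
#'
#' @param data A [pssm_dataset()] with at least two classes.
#' @param step Features removed per round: a fraction in (0, 1) of the
#'   surviving set (default 0.1, floor, minimum 1) or an integer count.
#'   `step = 1` is the original one-at-a-time elimination.
#' @param cost Cost parameter C of the linear ranking SVM (default 1).
#' @param standardize Center and scale columns to unit variance before
#'   ranking. Off by default: sigmoid-scaled GapDPC features are already
#'   bounded.
#' @return An object of class `"feature_ranking"`: list with `order`
#'   (permutation of 1..d, best feature first), `scores` (squared-weight
#'   importance at each feature's elimination round), `d`, `step`, `cost`.
#' @references Guyon, I. et al. Gene selection for cancer classification
#'   using support vector machines. Machine Learning 46, 389-422 (2002).
#' @export
rank_features <- function(data, step = 0.1, cost = 1, standardize = FALSE) {
  stopifnot(inherits(data, "pssm_dataset"))
  y <- droplevels(data$labels)
  if (nlevels(y) < 2L) stop("feature ranking needs at least 2 classes")
  counts <- table(y)
  if (any(counts < 2L))
    warning("class(es) with fewer than 2 members (",
            paste(names(counts)[counts < 2L], collapse = ", "),
            "); ranking may be unstable")
  x <- data$x
  d <- ncol(x)
  if (d < 1L) stop("dataset has no features")
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant columns
  }
  if (step <= 0) stop("'step' must be positive")

  pairs <- utils::combn(levels(y), 2L, simplify = FALSE)
  surviving <- seq_len(d)
  eliminated <- integer(0)        # filled worst-first
  scores <- numeric(d)
  while (length(surviving) > 0L) {
    w2 <- numeric(length(surviving))
    for (pr in pairs) {
      rows <- y %in% pr
      fit <- e1071::svm(x[rows, surviving, drop = FALSE],
                        droplevels(y[rows]), kernel = "linear",
                        cost = cost, scale = FALSE)
      w <- as.vector(crossprod(fit$coefs, fit$SV))
      w2 <- w2 + w * w
    }
    n_elim <- if (step < 1) max(1L, floor(step * length(surviving)))
              else min(as.integer(step), length(surviving))
    # ascending score; among ties eliminate the higher original index first.
    # Scores are rounded to 10 significant digits so that exact ties are not
    # broken by solver-level floating-point jitter.
    ord <- order(signif(w2, 10L), -surviving)
    drop_pos <- ord[seq_len(n_elim)]
    scores[surviving[drop_pos]] <- w2[drop_pos]
    eliminated <- c(eliminated, surviving[drop_pos])
    surviving <- surviving[-drop_pos]
  }
  structure(list(order = rev(eliminated), scores = scores, d = d,
                 step = step, cost = cost, standardize = standardize),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("SVM-RFE feature ranking over", x$d, "features",
      sprintf("(step = %s, linear C = %g)\n", format(x$step), x$cost))
  top <- utils::head(x$order, 10L)
  cat("  top features:", paste(top, collapse = ", "),
      if (x$d > 10L) "...", "\n")
  invisible(x)
}

#' Select the top-K ranked features
#'
#' Returns the first K entries of a [rank_features()] ordering, sorted
#' ascending so the result slices feature matrices with stable column
#' order.
#'
#' @param ranking A `"feature_ranking"`.
#' @param k Number of features to keep, 1 <= k <= d.
#' @return Sorted integer vector of K feature indices.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("'k' must be a positive integer")
  if (k > ranking$d)
    stop("k = ", k, " exceeds the number of ranked features (", ranking$d, ")")
  sort(ranking$order[seq_len(k)])
}

#' Cross-validated accuracy over a grid of top-K sizes
#'
#' For each K in `k_grid`, trains the RBF-kernel SVM on the top-K ranked
#' features and measures overall accuracy by stratified k-fold
#' cross-validation (same seeded fold assignment for every K, so the curve
#' reflects K alone). The canonical sweep is K = 10, 20, ..., 500.
#'
#' @param data A [pssm_dataset()].
#' @param ranking A `"feature_ranking"` for the same feature space.
#' @param k_grid Integer vector of K values (default `seq(10, 500, 10)`).
#' @param folds Number of CV folds (default 5); must not exceed the
#'   smallest class size.
#' @param seed Integer seed for the fold assignment.
#' @param cost,gamma RBF-SVM hyperparameters used at every K; `gamma =
#'   NULL` uses 1/K.
#' @return A data frame of class `"k_sweep"` with columns `k` and
#'   `accuracy`, and attribute `best_k` (the smallest K attaining the
#'   maximum accuracy).
#' @export
sweep_top_k <- function(data, ranking, k_grid = seq(10L, 500L, 10L),
                        folds = 5L, seed = 1L, cost = 1, gamma = NULL) {
  stopifnot(inherits(data, "pssm_dataset"), inherits(ranking, "feature_ranking"))
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0L) stop("'k_grid' is empty")
  if (max(k_grid) > ncol(data$x))
    stop("largest K (", max(k_grid), ") exceeds feature count (",
         ncol(data$x), ")")
  if (folds < 2L) stop("'folds' must be at least 2")
  if (folds > min(table(droplevels(data$labels))))
    stop("fold count (", folds, ") exceeds the smallest class size (",
         min(table(droplevels(data$labels))), ")")
  fold_id <- stratified_folds(data$labels, folds, seed)
  acc <- vapply(k_grid, function(k) {
    feats <- select_top_k(ranking, k)
    g <- if (is.null(gamma)) 1 / length(feats) else gamma
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (!any(!tr)) next
      fit <- e1071::svm(data$x[tr, feats, drop = FALSE],
                        droplevels(data$labels[tr]),
                        kernel = "radial", cost = cost, gamma = g,
                        scale = FALSE)
      pred <- predict(fit, data$x[!tr, feats, drop = FALSE])
      correct <- correct + sum(as.character(pred) ==
                               as.character(data$labels[!tr]))
    }
    correct / nrow(data$x)
  }, numeric(1))
  out <- data.frame(k = k_grid, accuracy = acc)
  class(out) <- c("k_sweep", "data.frame")
  attr(out, "best_k") <- k_grid[which.max(acc)]
  out
}

#' @export
plot.k_sweep <- function(x, ...) {
  plot(x$k, x$accuracy, type = "b", pch = 16, xlab = "top K features",
       ylab = "overall accuracy (CV)", ...)
  graphics::abline(v = attr(x, "best_k"), lty = 2, col = "grey40")
  invisible(x)
}

#' Write a feature ranking as TSV
#'
#' Columns: rank (1 = best), flat feature index, decoded name
#' `g{g}_{aa_i}{aa_j}`, and the squared-weight importance recorded at the
#' feature's elimination round.
#'
#' @param ranking A `"feature_ranking"`.
#' @param file Path.
#' @return `file`, invisibly; `read_ranking_tsv` returns a
#'   `"feature_ranking"`.
#' @export
write_ranking_tsv <- function(ranking, file) {
  stopifnot(inherits(ranking, "feature_ranking"))
  dec <- decode_feature_index(ranking$order)
  df <- data.frame(rank = seq_len(ranking$d), flat_index = ranking$order,
                   name = dec$name,
                   importance = num_format(ranking$scores[ranking$order]))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  ord <- df$flat_index[order(df$rank)]
  scores <- numeric(length(ord))
  scores[df$flat_index] <- as.numeric(df$importance)
  structure(list(order = ord, scores = scores, d = length(ord),
                 step = NA, cost = NA, standardize = NA),
            class = "feature_ranking")
}
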