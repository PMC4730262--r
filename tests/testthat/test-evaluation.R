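test_that("confusion counts match a hand-enumerated example", {
  # truth (a,a,b,b) vs predicted (a,b,b,b): class a has TP=1 FN=1 FP=0 TN=2
  cc <- confusion_counts(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_identical(cc$classes, c("a", "b"))
  expect_equal(cc$tp, c(1, 2))
  expect_equal(cc$fn, c(1, 0))
  expect_equal(cc$fp, c(0, 1))
  expect_equal(cc$tn, c(2, 1))
  expect_equal(cc$sizes, c(2, 2))
  expect_equal(unname(class_accuracy(cc)), c(0.5, 1))
  # MCC for class a: (1*2 - 0*1) / sqrt(1 * 2 * 2 * 3) = 2 / sqrt(12)
  expect_equal(unname(class_mcc(cc))[1], 2 / sqrt(12))
  expect_equal(unname(class_mcc(cc))[1], 0.5773502691896258)
  expect_equal(overall_accuracy(cc), 3 / 4)
})

test_that("perfect, inverted and degenerate predictions hit metric extremes", {
  y <- rep(c("x", "y"), each = 6)
  perf <- confusion_counts(y, y)
  expect_equal(unname(class_accuracy(perf)), c(1, 1))
  expect_equal(unname(class_mcc(perf)), c(1, 1))
  expect_equal(overall_accuracy(perf), 1)
  inv <- confusion_counts(y, rev(y))
  expect_equal(unname(class_mcc(inv)), c(-1, -1))
  expect_equal(overall_accuracy(inv), 0)
  # single observed class with matching predictions: TP = n, MCC = 0 by the
  # zero-denominator convention, absent class accuracy is reported missing
  single <- confusion_counts(rep("x", 5), rep("x", 5), classes = c("x", "y"))
  expect_equal(single$tp[1], 5)
  expect_equal(unname(class_mcc(single)), c(0, 0))
  expect_true(is.na(class_accuracy(single)["y"]))
  expect_equal(unname(class_accuracy(single))[1], 1)
})

test_that("confusion counts validate inputs and satisfy identities", {
  expect_error(confusion_counts(c("a", "b"), c("a")), "lengths differ")
  expect_error(confusion_counts("a", "z", classes = c("a", "b")),
               "outside the class set")
  set.seed(71)
  classes <- c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cc <- confusion_counts(truth, pred, classes)
    expect_equal(cc$tp + cc$fn, cc$sizes)          # TP_j + FN_j = |C_j|
    expect_equal(sum(cc$sizes), n)
    expect_true(all(c(cc$tp, cc$tn, cc$fp, cc$fn) >= 0))
    mcc <- class_mcc(cc)
    expect_true(all(mcc >= -1 & mcc <= 1))
    expect_equal(overall_accuracy(cc), sum(diag(cc$table)) / n)
  }
})

test_that("MCC of label-permuted predictions is centred on zero", {
  set.seed(2024)
  n <- 200
  truth <- sample(c("a", "b"), n, replace = TRUE)
  pred_base <- sample(c("a", "b"), n, replace = TRUE)
  m <- replicate(1000, {
    class_mcc(confusion_counts(truth, sample(pred_base)))[1]
  })
  expect_lt(abs(mean(m)), 0.05)
})

test_that("jackknife on strongly separated synthetic data is near-perfect", {
  syn <- make_feature_dataset(n_per_class = 10, d = 20, n_informative = 6,
                              effect = 6, n_classes = 3, seed = 42)
  rep <- jackknife(syn$data, config = svm_config(4, 0.05))
  expect_s3_class(rep, "eval_report")
  expect_gte(rep$overall, 0.95)
  expect_equal(rep$n, 30)
  # Eq. 9 consistency: overall equals pooled TP over n, recomputed here
  expect_equal(rep$overall, sum(diag(rep$confusion)) / rep$n)
  expect_identical(rep$protocol$protocol, "jackknife")
})

test_that("jackknife with one sample per class flags degenerate folds", {
  x <- matrix(rnorm(8 * 5), 8, 5)
  labs <- c("a", "a", "b", "b", "c", "c", "d", "d")
  d8 <- pssm_dataset(x, labs)
  rep <- jackknife(d8, config = svm_config(1, 0.2))
  expect_equal(rep$n, 8)
  # every leave-one-out fold drops one sample of a 2-member class: no flags
  expect_length(rep$protocol$flagged, 0)
  d4 <- pssm_dataset(x[1:4, ], c("a", "b", "c", "d"))
  expect_error(jackknife(d4, config = svm_config(1, 0.2)), "classes \\+ 1")
  d5 <- pssm_dataset(x[1:5, ], c("a", "a", "b", "c", "d"))
  rep5 <- jackknife(d5, config = svm_config(1, 0.2))
  # leaving out a singleton-class sample trains without that class
  expect_length(rep5$protocol$flagged, 3)
  expect_error(jackknife(pssm_dataset(x, rep("a", 8))), "2 classes")
})

test_that("kfold is stratified, seeded, and reduces to jackknife at folds = n", {
  syn <- make_feature_dataset(n_per_class = 8, d = 15, n_informative = 5,
                              effect = 4, n_classes = 2, seed = 7)
  cfg <- svm_config(2, 0.2)
  r1 <- kfold(syn$data, folds = 4, seed = 1, config = cfg)
  r1b <- kfold(syn$data, folds = 4, seed = 1, config = cfg)
  expect_identical(r1$confusion, r1b$confusion)     # same seed, same folds
  expect_gte(r1$overall, 0.9)
  rn <- kfold(syn$data, folds = 16, seed = 3, config = cfg)
  rj <- jackknife(syn$data, config = cfg)
  expect_identical(rn$confusion, rj$confusion)      # limiting case
})

test_that("stratified folds keep per-fold class proportions within one", {
  set.seed(9)
  labels <- factor(rep(c("a", "b", "c"), times = c(12, 9, 6)))
  for (seed in 1:5) {
    fid <- pssmclass:::stratified_folds(labels, 3, seed)
    tab <- table(labels, fid)
    expect_true(all(apply(tab, 1, function(r) diff(range(r)) <= 1)))
  }
  # different seeds reshuffle membership
  expect_false(identical(pssmclass:::stratified_folds(labels, 3, 1),
                         pssmclass:::stratified_folds(labels, 3, 2)))
})

test_that("a feature-blind majority classifier matches its exact jackknife value", {
  # leave-one-out majority vote is computable in closed form: a sample is
  # predicted correctly iff its class remains the strict majority without it
  labels <- c(rep("big", 12), rep("small", 6))
  n <- length(labels)
  loo_majority_correct <- sum(vapply(seq_len(n), function(i) {
    tab <- table(labels[-i])
    names(tab)[which.max(tab)] == labels[i]
  }, logical(1)))
  # constant features force the SVM into the same prior-driven behaviour
  x <- matrix(0.5, n, 3) + matrix(rnorm(3 * n, sd = 1e-8), n, 3)
  rep <- jackknife(pssm_dataset(x, labels), config = svm_config(1, 1))
  expect_equal(rep$overall, loo_majority_correct / n)
})

test_that("evaluation reports serialize to JSON with protocol metadata", {
  syn <- make_feature_dataset(n_per_class = 6, d = 10, n_informative = 4,
                              effect = 3, n_classes = 2, seed = 3)
  rep <- kfold(syn$data, folds = 3, seed = 5, config = svm_config(1, 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall_accuracy, rep$overall)
  expect_equal(back$protocol$seed, 5)
  expect_equal(back$n, 12)
  expect_equal(sum(back$tp), sum(rep$counts$tp))
  expect_output(print(rep), "Overall accuracy")
})
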