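# Benchmark harness: baselines, folds, ROC/AUC, cross-validation, summary.

test_that("ZeroR predicts the training majority with ties to label 0", {
  d <- make_gaussian_dataset(30, 20, seed = 1)
  m <- zeror_fit(d)
  expect_identical(m$majority, 1L)
  p <- zeror_predict(m, d$X)
  expect_true(all(p$label == 1L))

  tie <- make_gaussian_dataset(10, 10, seed = 2)
  expect_identical(zeror_fit(tie)$majority, 0L)

  one_class <- labeled_dataset(matrix(rnorm(20), 10), rep(1L, 10))
  expect_identical(zeror_fit(one_class)$majority, 1L)
  expect_error(zeror_fit(labeled_dataset(matrix(0, 0, 2), integer(0))), "empty")
})

test_that("OneR finds a perfectly separating feature", {
  set.seed(3)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(rnorm(n), ifelse(y == 1, 5, 0) + runif(n), rnorm(n))
  d <- labeled_dataset(X, y)
  m <- oner_fit(d)
  expect_identical(m$feature, 2L)
  expect_equal(m$train_accuracy, 100)
  p <- oner_predict(m, X)
  expect_identical(p$label, y)
})

test_that("OneR ties go to the lowest feature index", {
  y <- rep(c(0L, 1L), each = 30)
  sep <- ifelse(y == 1, 5, 0)
  d <- labeled_dataset(cbind(sep, sep), y)
  expect_identical(oner_fit(d)$feature, 1L)
})

test_that("OneR on label-independent features stays near the baseline", {
  set.seed(17)
  d <- labeled_dataset(matrix(rnorm(400 * 10), 400), rep(c(0L, 1L), 200))
  bt <- run_cv(d, c("ZeroR", "OneR"), cv_config(seed = 4))
  acc <- bt$results$accuracy
  expect_lt(abs(acc[2] - acc[1]), 5)
})

test_that("all-constant features fall back to the majority class", {
  d <- labeled_dataset(matrix(1, 20, 3), rep(c(0L, 1L), c(8, 12)))
  m <- oner_fit(d)
  expect_true(is.na(m$feature))
  p <- oner_predict(m, d$X)
  expect_true(all(p$label == 1L))
})

test_that("ROC curves are monotone with exact endpoints and correct AUC", {
  set.seed(9)
  y <- rep(c(0L, 1L), 500)
  s <- rnorm(1000)
  r <- roc_curve(s, y)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  # permutation expectation
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  # rank-statistic oracle
  expect_equal(r$auc, auc_rank_oracle(s, y), tolerance = 1e-12)

  # perfect separation and score negation
  y2 <- rep(c(0L, 1L), each = 20)
  s2 <- y2 + runif(40, -0.4, 0.4)
  expect_equal(roc_curve(s2, y2)$auc, 1)
  expect_equal(roc_curve(-s2, y2)$auc, 1 - roc_curve(s2, y2)$auc)
  expect_equal(roc_curve(-s, y)$auc, 1 - r$auc, tolerance = 1e-12)

  expect_error(roc_curve(s2, rep(1L, 40)), "both classes")
})

test_that("tied scores and the pROC cross-check agree", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rep(c(0L, 1L), 50)
  s <- round(rnorm(100), 1) # many ties
  ours <- roc_curve(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(weighted_auc(s, y), ours, tolerance = 1e-12)
})

test_that("stratified folds partition the data with balanced class ratios", {
  y <- rep(c(0L, 1L), c(149, 171))
  folds <- make_folds(y, cv_config(k = 10, seed = 3))
  expect_identical(sort(unique(folds)), 1:10)
  sizes <- tabulate(folds, 10)
  expect_lte(diff(range(sizes)), 1L)
  pos_per_fold <- vapply(1:10, function(f) sum(y[folds == f] == 1L), 1L)
  expect_lte(diff(range(pos_per_fold)), 1L)
  expect_identical(sum(sizes), 320L)
  expect_error(make_folds(rep(0L, 5), cv_config(k = 10)), "exceed")
})

test_that("ZeroR cross-validation equals the majority fraction on study-sized data", {
  d <- make_gaussian_dataset(171, 149, seed = 6)
  bt <- run_cv(d, "ZeroR", cv_config(k = 10, seed = 1))
  expect_equal(bt$results$accuracy, 100 * 171 / 320)
  expect_equal(round(bt$results$accuracy, 2), 53.44)
  expect_equal(bt$results$auc, 0.5, tolerance = 0.05)
})

test_that("cross-validation is reproducible and rejects unknown classifiers", {
  d <- make_gaussian_dataset(30, 30, shift = 2, seed = 8)
  cv <- cv_config(k = 5, seed = 2)
  b1 <- run_cv(d, c("ZeroR", "OneR", "NaiveBayes", "KNN"), cv)
  b2 <- run_cv(d, c("ZeroR", "OneR", "NaiveBayes", "KNN"), cv)
  expect_identical(b1$results, b2$results)
  expect_identical(b1$folds, b2$folds)
  expect_error(run_cv(d, "MegaNet", cv), "unknown classifier")
  expect_error(run_cv(make_gaussian_dataset(3, 3), "ZeroR", cv_config(k = 10)),
               "exceed")
})

test_that("separated classes are classified nearly perfectly by every family", {
  d <- make_gaussian_dataset(40, 40, shift = 4, seed = 10)
  bt <- suppressWarnings(
    run_cv(d, c("Logistic", "C45Tree", "RandomForest", "SVM", "MLP", "BayesNet"),
           cv_config(k = 5, seed = 3)))
  expect_true(all(bt$results$accuracy > 90))
  expect_true(all(bt$results$auc > 0.95))
})

test_that("the summary appends the rounded non-baseline average row", {
  df <- data.frame(classifier = c("ZeroR", "A", "B", "C"),
                   accuracy = c(50, 80.005, 70.001, 90.002),
                   auc = c(0.5, 0.8, 0.7, 0.9))
  s <- summarize_benchmark(df)
  avg <- s[s$classifier == "Average", ]
  expect_equal(avg$accuracy, round(mean(df$accuracy[-1]), 2))
  expect_equal(avg$auc, round(mean(df$auc[-1]), 3))
  # single non-baseline row: average equals that row
  s1 <- summarize_benchmark(data.frame(classifier = "A", accuracy = 81.239,
                                       auc = 0.7))
  expect_equal(s1$accuracy[s1$classifier == "Average"], 81.24)
})

test_that("benchmark CSV export writes the table and per-classifier ROC files", {
  d <- make_gaussian_dataset(20, 20, shift = 3, seed = 12)
  bt <- run_cv(d, c("ZeroR", "OneR"), cv_config(k = 5, seed = 1))
  dir <- withr::local_tempdir()
  write_benchmark_csv(bt, dir)
  expect_true(file.exists(file.path(dir, "benchmark.csv")))
  expect_true(all(file.exists(file.path(dir, c("roc_ZeroR.csv", "roc_OneR.csv")))))
  tab <- read.csv(file.path(dir, "benchmark.csv"))
  expect_identical(tab$classifier, c("ZeroR", "OneR", "Average"))
})
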