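# Classification benchmark: native ZeroR/OneR baselines, stratified k-fold
# cross-validation, pooled out-of-fold accuracy, ROC curves and class-weighted
# AUC, and the Table-style summary with an average row.

#' Cross-validation configuration
#' @param k number of folds (default 10, i.e. 90% training / 10% testing).
#' @param stratified preserve the class ratio within each fold.
#' @param seed integer seed for the fold assignment.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k = 10L, stratified = TRUE, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  structure(list(k = as.integer(k), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Assign cross-validation folds
#'
#' Returns a fold index (1..k) per instance. Stratified assignment shuffles
#' each class separately and deals its members round-robin across folds, so
#' fold sizes differ by at most one and per-fold class ratios match the global
#' ratio within one instance.
#'
#' @param y 0/1 label vector.
#' @param cv a [cv_config()].
#' @return Integer vector of fold ids, same length as `y`.
#' @export
make_folds <- function(y, cv = cv_config()) {
  n <- length(y)
  if (cv$k > n) stop(sprintf("k = %d folds exceed dataset size %d", cv$k, n),
                     call. = FALSE)
  rng <- .seeded_rng(cv$seed)
  folds <- integer(n)
  if (cv$stratified) {
    # one continuous round-robin across the (shuffled) classes: per-class
    # counts differ by <= 1 AND total fold sizes differ by <= 1
    pos <- 0L
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[order(rng$runif(length(idx)))]
      folds[idx] <- ((pos + seq_along(idx) - 1L) %% cv$k) + 1L
      pos <- pos + length(idx)
    }
  } else {
    idx <- order(rng$runif(n))
    folds[idx] <- rep_len(seq_len(cv$k), n)
  }
  folds
}

# ---- baselines (native implementations) -------------------------------------

#' Fit the ZeroR majority-class baseline
#'
#' Predicts the class that occurs most often in the training set for every
#' instance, ignoring all features; ties favour label 0.
#'
#' @param train a `labeled_dataset`.
#' @return An object of class `zeror_model`.
#' @export
zeror_fit <- function(train) {
  if (!length(train$y)) stop("empty training set", call. = FALSE)
  n1 <- sum(train$y == 1L)
  n0 <- length(train$y) - n1
  majority <- if (n1 > n0) 1L else 0L
  structure(list(majority = majority,
                 score = n1 / length(train$y)),
            class = "zeror_model")
}

#' Predict with a ZeroR model
#' @param model a `zeror_model`.
#' @param X feature matrix (only the row count is used).
#' @return List with `label` (constant majority label) and `score` (constant
#'   training prevalence of class 1, so ROC analysis is well defined).
#' @export
zeror_predict <- function(model, X) {
  n <- nrow(X)
  list(label = rep(model$majority, n), score = rep(model$score, n))
}

#' Fit the OneR single-feature rule
#'
#' For each feature, discretises the training values into equal-frequency
#' bins (merging adjacent bins until each holds at least `min_bucket`
#' instances), assigns each bin its majority label, and scores the training
#' error; the feature with minimum error wins, ties going to the lowest
#' feature index. Constant features are skipped; if every feature is
#' degenerate the rule falls back to the majority class.
#'
#' @param train a `labeled_dataset`.
#' @param bins initial number of equal-frequency bins.
#' @param min_bucket minimum instances per bin (default 6).
#' @return An object of class `oner_model` recording the winning feature
#'   index, its bin edges and per-bin labels/scores.
#' @export
oner_fit <- function(train, bins = 10L, min_bucket = 6L) {
  if (length(unique(train$y)) < 2L)
    stop("OneR requires at least two classes in the training data", call. = FALSE)
  n <- length(train$y)
  best <- list(err = Inf, feature = NA_integer_)
  for (j in seq_len(ncol(train$X))) {
    x <- train$X[, j]
    if (length(unique(x)) < 2L) next
    edges <- .ef_edges(x, bins, min_bucket)
    bin <- findInterval(x, edges, all.inside = TRUE)
    err <- 0
    lab <- integer(length(edges) - 1L)
    sc <- numeric(length(edges) - 1L)
    for (b in seq_along(lab)) {
      yb <- train$y[bin == b]
      if (!length(yb)) { lab[b] <- NA_integer_; sc[b] <- NA_real_; next }
      n1 <- sum(yb == 1L)
      lab[b] <- if (n1 > length(yb) - n1) 1L else 0L
      sc[b] <- n1 / length(yb)
      err <- err + min(n1, length(yb) - n1)
    }
    if (err < best$err) {
      best <- list(err = err, feature = j, edges = edges,
                   bin_label = lab, bin_score = sc)
    }
  }
  if (is.na(best$feature)) {
    maj <- zeror_fit(train)
    return(structure(list(feature = NA_integer_, fallback = maj),
                     class = "oner_model"))
  }
  maj <- zeror_fit(train)
  best$fallback <- maj
  best$train_accuracy <- 100 * (1 - best$err / n)
  structure(best, class = "oner_model")
}

# equal-frequency bin edges with a minimum bucket size; outer edges at +-Inf
.ef_edges <- function(x, bins, min_bucket) {
  bins <- max(1L, min(bins, floor(length(x) / max(1L, min_bucket))))
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7)
  edges <- unique(qs)
  if (length(edges) < 2L) edges <- range(x)
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  edges
}

#' Predict with a OneR rule
#' @param model an `oner_model`.
#' @param X feature matrix.
#' @return List with `label` and `score` (bin prevalence of class 1).
#' @export
oner_predict <- function(model, X) {
  n <- nrow(X)
  if (is.na(model$feature)) {
    p <- zeror_predict(model$fallback, X)
    return(p)
  }
  bin <- findInterval(X[, model$feature], model$edges, all.inside = TRUE)
  lab <- model$bin_label[bin]
  sc <- model$bin_score[bin]
  # empty training bins fall back to the majority class
  miss <- is.na(lab)
  lab[miss] <- model$fallback$majority
  sc[miss] <- model$fallback$score
  list(label = lab, score = sc)
}

# ---- ROC / AUC --------------------------------------------------------------

#' ROC curve and AUC by threshold sweep
#'
#' Standard convention: false-positive rate on x, true-positive rate on y,
#' one point per distinct score threshold, including (0,0) and (1,1); AUC by
#' trapezoidal integration (equal scores handled by the diagonal segment,
#' equivalent to the rank/Mann-Whitney statistic).
#'
#' @param scores numeric class-1 scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return List with `fpr`, `tpr` (non-decreasing, endpoints included) and
#'   `auc` in `[0, 1]`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # aggregate ties so equal scores produce one ROC vertex
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Class-weighted AUC
#'
#' One-vs-rest AUC per class, averaged with class-prevalence weights. For a
#' binary problem the class-0 ROC (scoring by `1 - score`) is the mirror image
#' of the class-1 ROC, so both per-class AUCs coincide and the weighted
#' average equals the plain AUC; the function computes the weighted form
#' regardless.
#'
#' @param scores class-1 scores.
#' @param labels 0/1 labels.
#' @return Weighted AUC in `[0, 1]`.
#' @export
weighted_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  auc1 <- roc_curve(scores, labels)$auc
  auc0 <- roc_curve(-scores, 1L - labels)$auc
  w1 <- mean(labels == 1L)
  w1 * auc1 + (1 - w1) * auc0
}

# ---- cross-validation harness ----------------------------------------------

#' Names of the supported classifiers
#' @return Character vector of recognised classifier names.
#' @export
classifier_names <- function() {
  c("ZeroR", "OneR", "NaiveBayes", "BayesNet", "Logistic", "C45Tree",
    "RandomForest", "SVM", "MLP", "KNN")
}

#' Run the cross-validated classifier benchmark
#'
#' For each named classifier: assign (stratified) folds, train on k-1 folds,
#' score the held-out fold, pool the out-of-fold predictions, and report
#' overall accuracy (%), class-weighted AUC and the pooled ROC curve. The
#' fold assignment is shared across classifiers and fully determined by the
#' seed, so deterministic classifiers reproduce exactly on re-run.
#'
#' @param data a `labeled_dataset`.
#' @param classifiers character vector of classifier names
#'   (see [classifier_names()]), or a list of `classifier_spec`-style lists
#'   with `name` and optional `hyperparameters`.
#' @param cv a [cv_config()].
#' @return An object of class `benchmark_table`: list with `results` (a data
#'   frame of classifier, accuracy, auc), `roc` (named list of ROC point
#'   sets), `per_fold` (named list of per-fold accuracies), `folds`.
#' @export
run_cv <- function(data, classifiers = classifier_names(), cv = cv_config()) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (cv$k > length(data$y))
    stop(sprintf("k = %d folds exceed dataset size %d", cv$k, length(data$y)),
         call. = FALSE)
  specs <- lapply(classifiers, function(s) {
    if (is.character(s)) list(name = s, hyperparameters = list()) else s
  })
  for (sp in specs)
    if (!sp$name %in% classifier_names())
      stop(sprintf("unknown classifier '%s'", sp$name), call. = FALSE)

  folds <- make_folds(data$y, cv)
  n <- length(data$y)
  acc <- numeric(length(specs)); auc <- numeric(length(specs))
  roc_list <- list(); fold_acc <- list()

  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    pred_label <- integer(n); pred_score <- numeric(n)
    pf <- numeric(cv$k)
    for (f in seq_len(cv$k)) {
      te <- folds == f
      train <- labeled_dataset(data$X[!te, , drop = FALSE], data$y[!te])
      fit <- .fit_classifier(sp, train, seed = cv$seed + 1000L * ci + f)
      p <- .predict_classifier(sp$name, fit, data$X[te, , drop = FALSE])
      pred_label[te] <- p$label; pred_score[te] <- p$score
      pf[f] <- 100 * mean(p$label == data$y[te])
    }
    acc[ci] <- 100 * mean(pred_label == data$y)
    auc[ci] <- weighted_auc(pred_score, data$y)
    roc_list[[sp$name]] <- roc_curve(pred_score, data$y)[c("fpr", "tpr")]
    fold_acc[[sp$name]] <- pf
  }

  structure(list(results = data.frame(classifier = vapply(specs, `[[`, "", "name"),
                                      accuracy = acc, auc = auc,
                                      stringsAsFactors = FALSE),
                 roc = roc_list, per_fold = fold_acc, folds = folds),
            class = "benchmark_table")
}

.fit_classifier <- function(sp, train, seed = 1L) {
  hp <- sp$hyperparameters %||% list()
  X <- train$X; y <- train$y
  yf <- factor(y, levels = c(0, 1))
  # drop zero-variance columns for fitters that cannot handle them
  keep <- apply(X, 2L, function(v) length(unique(v)) > 1L)
  switch(sp$name,
    ZeroR = zeror_fit(train),
    OneR = oner_fit(train, bins = hp$bins %||% 10L,
                    min_bucket = hp$min_bucket %||% 6L),
    NaiveBayes = list(keep = keep,
                      fit = e1071::naiveBayes(X[, keep, drop = FALSE], yf)),
    BayesNet = {
      .bayesnet_warn()
      list(keep = keep, fit = e1071::naiveBayes(X[, keep, drop = FALSE], yf))
    },
    Logistic = {
      # ridge-regularised logistic regression (p > n safe)
      glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                     lambda = hp$lambda %||% 1e-2)
    },
    C45Tree = {
      df <- data.frame(X); df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = hp$cp %||% 0.01,
                                                  minsplit = hp$minsplit %||% 20L))
    },
    RandomForest = {
      set.seed(seed)
      randomForest::randomForest(X, yf, ntree = hp$ntree %||% 100L)
    },
    SVM = e1071::svm(X, yf, kernel = hp$kernel %||% "radial",
                     cost = hp$cost %||% 1, probability = TRUE, scale = .svm_scale(X)),
    MLP = {
      set.seed(seed)
      sc <- .col_scale(X)
      list(scale = sc,
           fit = nnet::nnet(.apply_scale(X, sc), class.ind2(yf),
                            size = hp$size %||% 10L, decay = hp$decay %||% 0.01,
                            maxit = hp$maxit %||% 200L, trace = FALSE,
                            MaxNWts = 100000L, softmax = TRUE))
    },
    KNN = {
      sc <- .col_scale(X)
      list(X = .apply_scale(X, sc), y = yf, k = hp$k %||% 1L, scale = sc)
    }
  )
}

.predict_classifier <- function(name, fit, Xte) {
  switch(name,
    ZeroR = zeror_predict(fit, Xte),
    OneR = oner_predict(fit, Xte),
    NaiveBayes = ,
    BayesNet = {
      pr <- stats::predict(fit$fit, Xte[, fit$keep, drop = FALSE], type = "raw")
      list(label = as.integer(pr[, "1"] >= 0.5), score = pr[, "1"])
    },
    Logistic = {
      p <- as.numeric(stats::predict(fit, Xte, type = "response"))
      list(label = as.integer(p >= 0.5), score = p)
    },
    C45Tree = {
      pr <- stats::predict(fit, data.frame(Xte), type = "prob")
      list(label = as.integer(pr[, "1"] >= 0.5), score = pr[, "1"])
    },
    RandomForest = {
      pr <- stats::predict(fit, Xte, type = "prob")
      list(label = as.integer(pr[, "1"] >= 0.5), score = pr[, "1"])
    },
    SVM = {
      pr <- attr(stats::predict(fit, Xte, probability = TRUE), "probabilities")
      list(label = as.integer(pr[, "1"] >= 0.5), score = pr[, "1"])
    },
    MLP = {
      pr <- stats::predict(fit$fit, .apply_scale(Xte, fit$scale))
      list(label = as.integer(pr[, 2] >= 0.5), score = pr[, 2])
    },
    KNN = {
      pr <- class::knn(fit$X, .apply_scale(Xte, fit$scale), fit$y,
                       k = fit$k, prob = TRUE)
      conf <- attr(pr, "prob")
      lab <- as.integer(as.character(pr))
      score <- ifelse(lab == 1L, conf, 1 - conf)
      list(label = lab, score = score)
    }
  )
}

class.ind2 <- function(f) {
  m <- matrix(0, length(f), 2, dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

.col_scale <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
.apply_scale <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")
.svm_scale <- function(X) apply(X, 2L, function(v) stats::sd(v) > 0)

.bayesnet_env <- new.env()
.bayesnet_warn <- function() {
  if (!isTRUE(.bayesnet_env$warned)) {
    warning("BayesNet degrades to NaiveBayes (no Bayesian-network backend configured)",
            call. = FALSE)
    .bayesnet_env$warned <- TRUE
  }
}

#' Summarise a benchmark table with an average row
#'
#' Appends the unweighted mean accuracy (rounded to 2 decimals) and mean AUC
#' (3 decimals) over the non-baseline rows (every classifier except ZeroR),
#' matching the conventional results-table layout.
#'
#' @param table a `benchmark_table`, or a data frame with `classifier`,
#'   `accuracy` and optionally `auc` columns.
#' @return A data frame with one row per classifier plus an `"Average"` row.
#' @export
summarize_benchmark <- function(table) {
  df <- if (inherits(table, "benchmark_table")) table$results else as.data.frame(table)
  if (!nrow(df)) stop("benchmark table is empty", call. = FALSE)
  non_base <- df[df$classifier != "ZeroR", , drop = FALSE]
  if (!nrow(non_base)) non_base <- df
  avg <- data.frame(classifier = "Average",
                    accuracy = round(mean(non_base$accuracy), 2),
                    stringsAsFactors = FALSE)
  if ("auc" %in% names(df)) avg$auc <- round(mean(non_base$auc), 3)
  out <- df
  out$accuracy <- round(out$accuracy, 2)
  if ("auc" %in% names(out)) out$auc <- round(out$auc, 3)
  rbind(out, avg[names(out)])
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("<benchmark_table>\n")
  print(summarize_benchmark(x), row.names = FALSE)
  invisible(x)
}

#' Export benchmark results and ROC point sets as CSV
#' @param table a `benchmark_table`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_benchmark_csv <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summarize_benchmark(table),
                   file.path(dir, "benchmark.csv"), row.names = FALSE)
  for (nm in names(table$roc)) {
    r <- table$roc[[nm]]
    utils::write.csv(data.frame(fpr = r$fpr, tpr = r$tpr),
                     file.path(dir, sprintf("roc_%s.csv", nm)), row.names = FALSE)
  }
  invisible(dir)
}
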