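#' Supported classifier families
#'
#' `gb` gradient-boosted trees (xgboost), `lr` one-vs-rest ridge logistic
#' regression (glmnet, alpha = 0), `svm_linear`/`svm_poly`/`svm_rbf`
#' support vector machines (e1071), `rf` random forest and `et`
#' extremely-randomized trees (ranger), `nb` naive Bayes (e1071), `knn`
#' k-nearest neighbours (class).
#'
#' @return Character vector of family codes.
#' @export
model_families <- function() {
  c("gb", "lr", "svm_linear", "svm_poly", "svm_rbf", "rf", "et", "nb", "knn")
}

#' Default hyperparameter grids
#'
#' Small per-family grids for the grid-search/CV harness. The study printed
#' no grids, so these are package defaults chosen for coverage at modest
#' cost.
#'
#' @param family Family code, see [model_families()].
#' @param p Number of features (used for kernel/mtry defaults).
#' @return data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(family, p = 100) {
  switch(family,
    gb = expand.grid(max_depth = c(3, 6), eta = c(0.1, 0.3), nrounds = 150),
    lr = data.frame(lambda = c(1e-3, 1e-2)),
    svm_linear = data.frame(cost = c(0.1, 1)),
    svm_poly = data.frame(cost = 1, degree = c(2, 3)),
    svm_rbf = data.frame(cost = c(1, 10), gamma = 1 / p),
    rf = data.frame(num_trees = 300, mtry = floor(sqrt(p))),
    et = data.frame(num_trees = 300, mtry = floor(sqrt(p))),
    nb = data.frame(laplace = 0),
    knn = data.frame(k = c(5, 15)),
    stop("unknown family: ", family)
  )
}

# families fit on standardized features
scaled_family <- function(family) family %in% c("lr", "svm_linear", "svm_poly",
                                                "svm_rbf", "knn")

# stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

fit_family <- function(family, x, y, params, seed) {
  K <- nlevels(y)
  switch(family,
    gb = {
      yi <- as.integer(y) - 1L
      obj <- if (K > 2) "multi:softmax" else "binary:logistic"
      pars <- list(objective = obj, max_depth = params$max_depth,
                   eta = params$eta, nthread = 1, seed = seed,
                   verbosity = 0)
      if (K > 2) pars$num_class <- K
      dtrain <- xgboost::xgb.DMatrix(x, label = yi)
      list(fit = xgboost::xgb.train(params = pars, data = dtrain,
                                    nrounds = params$nrounds))
    },
    lr = {
      # one-vs-rest ridge-penalized binomial fits, one per class
      fits <- lapply(levels(y), function(cl)
        glmnet::glmnet(x, as.numeric(y == cl), family = "binomial",
                       alpha = 0, lambda = params$lambda,
                       standardize = FALSE))
      names(fits) <- levels(y)
      list(fit = fits)
    },
    svm_linear = list(fit = e1071::svm(x, y, kernel = "linear",
                                       cost = params$cost, scale = FALSE)),
    svm_poly = list(fit = e1071::svm(x, y, kernel = "polynomial",
                                     cost = params$cost,
                                     degree = params$degree, scale = FALSE)),
    svm_rbf = list(fit = e1071::svm(x, y, kernel = "radial",
                                    cost = params$cost, gamma = params$gamma,
                                    scale = FALSE)),
    rf = {
      d <- data.frame(x, check.names = FALSE); d$.y <- y
      list(fit = ranger::ranger(dependent.variable.name = ".y", data = d,
                                num.trees = params$num_trees,
                                mtry = min(params$mtry, ncol(x)),
                                seed = seed, num.threads = 1))
    },
    et = {
      d <- data.frame(x, check.names = FALSE); d$.y <- y
      list(fit = ranger::ranger(dependent.variable.name = ".y", data = d,
                                num.trees = params$num_trees,
                                mtry = min(params$mtry, ncol(x)),
                                splitrule = "extratrees",
                                num.random.splits = 1,
                                replace = FALSE, sample.fraction = 1,
                                seed = seed, num.threads = 1))
    },
    nb = list(fit = e1071::naiveBayes(x, y, laplace = params$laplace)),
    knn = list(fit = list(train = x, y = y, k = params$k)),
    stop("unknown family: ", family)
  )
}

predict_family <- function(family, fit, x, lv) {
  switch(family,
    gb = {
      p <- predict(fit, xgboost::xgb.DMatrix(x))
      if (length(lv) > 2) factor(lv[p + 1], levels = lv)
      else factor(lv[(p > 0.5) + 1], levels = lv)
    },
    lr = {
      probs <- vapply(lv, function(cl)
        as.numeric(predict(fit[[cl]], x, type = "response")), numeric(nrow(x)))
      if (nrow(x) == 1) probs <- matrix(probs, nrow = 1)
      factor(lv[max.col(probs, ties.method = "last")], levels = lv)
    },
    svm_linear = , svm_poly = , svm_rbf = {
      factor(as.character(predict(fit, x)), levels = lv)
    },
    rf = , et = {
      factor(as.character(
        predict(fit, data.frame(x, check.names = FALSE),
                num.threads = 1)$predictions), levels = lv)
    },
    nb = factor(as.character(
      predict(fit, x, threshold = 1e-3, eps = 1e-3)), levels = lv),
    knn = factor(as.character(
      class::knn(fit$train, x, fit$y, k = fit$k)), levels = lv),
    stop("unknown family: ", family)
  )
}

#' Train a classifier with grid search and stratified k-fold CV
#'
#' Exhaustively scores every grid row by stratified k-fold cross-validation
#' accuracy, refits the best configuration (ties go to the first row) on
#' the full training data, and returns the fitted record. Deterministic
#' given the seed.
#'
#' @param x Numeric feature matrix (training cases x features).
#' @param y Label vector: triage categories 1-4 or exacerbation 0/1.
#' @param family Family code, see [model_families()].
#' @param task `"triage"` or `"exacerbation"` (bookkeeping).
#' @param grid data.frame of hyperparameter combinations; defaults to
#'   [default_grid()].
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `copd_model`: family, task, `hyperparameters`
#'   (best row), `cv_results` (per-combination fold accuracies), fitted
#'   model, preprocessing info and class levels.
#' @export
train_and_tune <- function(x, y, family, task = "triage", grid = NULL,
                           folds = 5, seed = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("degenerate labels: fewer than two classes present")
  if (any(table(y) == 0)) stop("degenerate labels: empty class")
  if (is.null(grid)) grid <- default_grid(family, ncol(x))
  if (nrow(grid) == 0) stop("empty grid")

  # drop zero-variance columns; standardize for scale-sensitive families
  keep <- which(apply(x, 2, function(v) max(v) - min(v)) > 0)
  ctr <- scl <- NULL
  xt <- x[, keep, drop = FALSE]
  if (scaled_family(family)) {
    ctr <- colMeans(xt); scl <- apply(xt, 2, sd)
    xt <- scale(xt, ctr, scl)
  }

  fold <- stratified_folds(y, folds, seed)
  cv <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fit_family(family, xt[tr, , drop = FALSE], droplevels(y[tr]),
                        grid[g, , drop = FALSE], seed = seed + f)
      pred <- predict_family(family, fit$fit, xt[!tr, , drop = FALSE],
                             levels(droplevels(y[tr])))
      cv[g, f] <- 100 * mean(as.character(pred) == as.character(y[!tr]))
    }
  }
  best <- which.max(rowMeans(cv))
  final <- fit_family(family, xt, y, grid[best, , drop = FALSE], seed = seed)
  structure(list(
    family = family, task = task,
    hyperparameters = grid[best, , drop = FALSE],
    grid = grid, cv_results = cv, cv_accuracy = rowMeans(cv)[best],
    fit = final$fit, levels = levels(y),
    keep = keep, center = ctr, scale = scl,
    feature_names = colnames(x)[keep], seed = seed),
    class = "copd_model")
}

#' Predict labels for new cases
#'
#' @param object A `copd_model` from [train_and_tune()].
#' @param newx Feature matrix with the training columns.
#' @param ... Unused.
#' @return Vector of predicted labels on the original coding (integers for
#'   triage/exacerbation labels).
#' @export
predict.copd_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)[, object$keep, drop = FALSE]
  if (scaled_family(object$family))
    newx <- scale(newx, object$center, object$scale)
  pred <- predict_family(object$family, object$fit, newx, object$levels)
  out <- as.character(pred)
  if (all(!is.na(suppressWarnings(as.numeric(object$levels)))))
    out <- as.numeric(out)
  out
}

#' Select the best model per family and the overall top two
#'
#' Scores each trained record against the validation consensus by
#' classification accuracy (percent of predictions matching consensus) and
#' returns the comparison table, the best record per family, and the
#' overall top two — the out-of-sample selection protocol of the study.
#'
#' @param records List of `copd_model` objects for one task.
#' @param validation_features Feature matrix of the validation cases.
#' @param validation_consensus Consensus labels of the validation cases.
#' @return List with `table` (data.frame family, cv_accuracy,
#'   validation_accuracy, sorted descending), `per_family` (named list of
#'   best records) and `top2` (list of the two best records).
#' @export
select_top_models <- function(records, validation_features,
                              validation_consensus) {
  if (length(records) == 0) stop("nothing to select")
  tasks <- unique(vapply(records, `[[`, "", "task"))
  if (length(tasks) != 1) stop("records span multiple tasks")
  acc <- vapply(records, function(r) {
    p <- predict(r, validation_features)
    100 * mean(p == validation_consensus)
  }, 0)
  fam <- vapply(records, `[[`, "", "family")
  tab <- data.frame(family = fam,
                    cv_accuracy = vapply(records, `[[`, 0, "cv_accuracy"),
                    validation_accuracy = acc, stringsAsFactors = FALSE)
  ord <- order(-tab$validation_accuracy)
  per_family <- lapply(split(seq_along(records), fam), function(ix)
    records[[ix[which.max(acc[ix])]]])
  list(table = tab[ord, ], per_family = per_family,
       top2 = records[ord[seq_len(min(2, length(records)))]])
}

#' Gradient-boosting feature importance: expected fraction of samples
#'
#' For each tree of the fitted ensemble, each feature's contribution is the
#' fraction of training samples passing through the nodes that split on it
#' (node cover divided by the tree's root cover); the importance is the
#' average of that fraction across all trees, normalized to sum to one.
#' Computed from the dumped tree structure, not from a library importance
#' accessor.
#'
#' @param model A `copd_model` with `family == "gb"`.
#' @return data.frame `feature`, `score`, sorted non-increasing; scores sum
#'   to 1. Features never split on score 0.
#' @export
importance_gb <- function(model) {
  if (!inherits(model, "copd_model") || model$family != "gb")
    stop("importance_gb requires a fitted gradient-boosting copd_model")
  if (is.null(model$fit)) stop("not fitted")
  tr <- xgboost::xgb.model.dt.tree(model = model$fit)
  tr <- as.data.frame(tr)
  split_rows <- tr$Feature != "Leaf"
  # root is the first node of each tree in the dump
  roots <- tr[!duplicated(tr$Tree), ]
  root_by_tree <- setNames(roots$Cover, roots$Tree)
  sp <- tr[split_rows, , drop = FALSE]
  frac <- sp$Cover / root_by_tree[as.character(sp$Tree)]
  per_tree_feature <- tapply(frac, list(sp$Tree, sp$Feature), sum)
  per_tree_feature[is.na(per_tree_feature)] <- 0
  n_trees <- length(unique(tr$Tree))
  avg <- colSums(per_tree_feature) / n_trees
  score <- setNames(numeric(length(model$feature_names)), model$feature_names)
  score[names(avg)] <- avg
  if (sum(score) > 0) score <- score / sum(score)
  out <- data.frame(feature = names(score), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score), ]
}

# average, over the binary models (columns), of each feature's rank by
# absolute coefficient effect (rank 1 = largest magnitude; ties averaged)
avg_coef_ranks <- function(B) {
  ranks <- apply(abs(B), 2, function(b) rank(-b, ties.method = "average"))
  if (nrow(B) == 1) ranks <- matrix(ranks, nrow = 1)
  rowMeans(ranks)
}

#' Logistic-regression feature importance: average one-vs-rest rank
#'
#' In each one-vs-rest binary model, features are ranked by the magnitude
#' of their coefficient effect (features are standardized at training time,
#' so magnitudes are scale-comparable); the final score is the average rank
#' across the binary models (four for triage, one for exacerbation). Lower
#' average rank = more important.
#'
#' @param model A `copd_model` with `family == "lr"`.
#' @return data.frame `feature`, `avg_rank`, `score` (= max rank + 1 -
#'   avg_rank, so higher is more important and sorting by `score`
#'   non-increasing equals sorting by `avg_rank` non-decreasing).
#' @export
importance_lr <- function(model) {
  if (!inherits(model, "copd_model") || model$family != "lr")
    stop("requires one-vs-rest: importance_lr needs an 'lr' copd_model")
  if (is.null(model$fit)) stop("not fitted")
  B <- vapply(model$fit, function(f) as.numeric(coef(f))[-1],  # drop intercept
              numeric(length(model$feature_names)))
  if (length(model$feature_names) == 1) B <- matrix(B, nrow = 1)
  avg <- avg_coef_ranks(B)
  out <- data.frame(feature = model$feature_names, avg_rank = avg,
                    score = length(avg) + 1 - avg, stringsAsFactors = FALSE)
  out[order(out$avg_rank), ]
}
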