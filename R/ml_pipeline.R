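#' Stratified fold assignment
#'
#' Partitions patients into `k` folds whose sizes differ by at most one and
#' whose per-fold positive counts differ by at most one, so every fold
#' carries (nearly) the cohort prevalence. With 3,743 patients and k = 5 the
#' folds have 748 or 749 patients each at close to 11.7% IgAN. The
#' assignment is a deterministic function of `seed`.
#'
#' @param labels Logical vector of gold-standard labels.
#' @param k Number of folds (>= 2; defaults to 5).
#' @param seed Integer seed; sets the R RNG.
#' @return Integer vector of fold indices in `1:k`, aligned to `labels`,
#'   with attributes `k` and `seed`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.logical(labels)
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L) stop("`k` must be >= 2")
  if (k > n) stop("`k` must not exceed the number of patients")
  npos <- sum(labels)
  if (npos < k) stop("need at least `k` positive labels for stratification")
  if (n - npos < k) stop("need at least `k` negative labels for stratification")
  per_fold <- function(m) m %/% k + (seq_len(k) <= m %% k)
  sizes <- per_fold(n)
  pos_counts <- per_fold(npos)
  neg_counts <- sizes - pos_counts
  set.seed(seed)
  fold <- integer(n)
  fold[sample(which(labels))]  <- rep.int(seq_len(k), pos_counts)
  fold[sample(which(!labels))] <- rep.int(seq_len(k), neg_counts)
  structure(fold, k = k, seed = seed)
}

#' Hyperparameter set for the gradient-boosted classifier
#'
#' @param eta Learning rate in (0, 1].
#' @param rounds Number of boosting rounds (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @param colsample_bytree Column subsample ratio per tree in (0, 1].
#' @return A list of class `boost_params`.
#' @export
boost_params <- function(eta, rounds, max_depth, colsample_bytree) {
  if (eta <= 0 || eta > 1) stop("`eta` must be in (0, 1]")
  rounds <- as.integer(rounds); max_depth <- as.integer(max_depth)
  if (rounds < 1L) stop("`rounds` must be >= 1")
  if (max_depth < 1L) stop("`max_depth` must be >= 1")
  if (colsample_bytree <= 0 || colsample_bytree > 1) {
    stop("`colsample_bytree` must be in (0, 1]")
  }
  structure(list(eta = eta, rounds = rounds, max_depth = max_depth,
                 colsample_bytree = colsample_bytree),
            class = "boost_params")
}

#' Default hyperparameter search ranges
#'
#' Conventional desk-scale ranges for the four tuned hyperparameters:
#' learning rate `eta` log-uniform on \[0.01, 0.3\], boosting `rounds`
#' uniform on \[50, 500\], `max_depth` on \[2, 9\], and `colsample_bytree`
#' on \[0.4, 1.0\].
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_search_ranges <- function() {
  list(eta = c(0.01, 0.3), rounds = c(50L, 500L),
       max_depth = c(2L, 9L), colsample_bytree = c(0.4, 1.0))
}

#' Train a gradient-boosted tree classifier
#'
#' Fits an XGBoost model with the binary-logistic objective on a feature
#' matrix, single-threaded and seeded so that identical inputs give
#' identical models.
#'
#' @param train A `feature_matrix` containing both classes.
#' @param params A `boost_params` object.
#' @param seed Integer seed.
#' @return An object of class `igan_booster` wrapping the fitted model and
#'   its feature list.
#' @export
train_booster <- function(train, params, seed = 1L) {
  stopifnot(inherits(train, "feature_matrix"), inherits(params, "boost_params"))
  y <- as.numeric(train$labels)
  if (all(y == 0) || all(y == 1)) stop("training data must contain both classes")
  dtrain <- xgboost::xgb.DMatrix(train$values, label = y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = params$eta,
                  max_depth = params$max_depth,
                  colsample_bytree = params$colsample_bytree,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = params$rounds, verbose = 0
  )
  structure(list(model = bst, feature_names = train$feature_names,
                 params = params, seed = as.integer(seed)),
            class = "igan_booster")
}

#' Predict IgAN scores for a feature matrix
#'
#' @param object An `igan_booster`.
#' @param newdata A `feature_matrix` with the same feature list the model
#'   was trained on.
#' @return Numeric vector of predicted probabilities.
#' @export
predict_scores <- function(object, newdata) {
  stopifnot(inherits(object, "igan_booster"), inherits(newdata, "feature_matrix"))
  if (!identical(object$feature_names, newdata$feature_names)) {
    stop("feature mismatch: `newdata` was built with a different feature list")
  }
  stats::predict(object$model,
                 xgboost::xgb.DMatrix(newdata$values, nthread = 1))
}

#' Feature importance by split count (F score)
#'
#' Counts how many tree splits use each feature, the "F score" reported for
#' gradient-boosted models. Absolute values are not comparable across models
#' trained on different folds; only the within-model ranking is meaningful.
#'
#' @param object An `igan_booster`.
#' @param top Number of features to keep (descending; ties alphabetical).
#' @return Data frame with columns `feature` and `f_score`.
#' @export
importance_fscore <- function(object, top = 10L) {
  stopifnot(inherits(object, "igan_booster"))
  tr <- xgboost::xgb.model.dt.tree(model = object$model)
  feats <- tr$Feature[tr$Feature != "Leaf"]
  if (length(feats) == 0L) {
    return(data.frame(feature = character(0), f_score = integer(0)))
  }
  tab <- table(feats)
  out <- data.frame(feature = names(tab), f_score = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$f_score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}

sample_params <- function(ranges) {
  lo <- log(ranges$eta[1]); hi <- log(ranges$eta[2])
  boost_params(
    eta = exp(stats::runif(1, lo, hi)),
    rounds = sample(seq.int(ranges$rounds[1], ranges$rounds[2]), 1L),
    max_depth = sample(seq.int(ranges$max_depth[1], ranges$max_depth[2]), 1L),
    colsample_bytree = stats::runif(1, ranges$colsample_bytree[1],
                                    ranges$colsample_bytree[2])
  )
}

#' Seeded random search for booster hyperparameters
#'
#' Draws `budget` candidate hyperparameter sets from the search ranges
#' (learning rate sampled log-uniformly) and scores each by mean held-out
#' AUC over an inner stratified `inner_k`-fold split of the training data,
#' so tuning never sees the outer test fold. Returns the best candidate;
#' the whole search is a deterministic function of `(train, budget, seed)`.
#'
#' @param train A `feature_matrix` with both classes.
#' @param budget Number of candidate sets (>= 1).
#' @param seed Integer seed.
#' @param ranges Search ranges, see [default_search_ranges()].
#' @param inner_k Inner folds for the tuning objective (default 3).
#' @return A `boost_params` with attribute `inner_auc` (the winning mean
#'   inner AUC).
#' @export
tune_params <- function(train, budget = 50L, seed = 1L,
                        ranges = default_search_ranges(), inner_k = 3L) {
  stopifnot(inherits(train, "feature_matrix"))
  budget <- as.integer(budget)
  if (budget < 1L) stop("`budget` must be >= 1")
  y <- train$labels
  if (all(y) || !any(y)) stop("training labels are degenerate (one class)")
  set.seed(seed)
  candidates <- replicate(budget, sample_params(ranges), simplify = FALSE)
  folds <- stratified_folds(y, k = inner_k, seed = seed)
  scores <- vapply(seq_along(candidates), function(i) {
    aucs <- vapply(seq_len(inner_k), function(f) {
      fit <- train_booster(fm_subset(train, folds != f), candidates[[i]],
                           seed = seed)
      held <- fm_subset(train, folds == f)
      roc_curve(predict_scores(fit, held), held$labels)$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(scores)
  structure(candidates[[best]], inner_auc = scores[best])
}

#' Stratified k-fold cross-validated boosting over a feature matrix
#'
#' For each of `k` stratified folds: tunes hyperparameters on the k - 1
#' training folds (see [tune_params()]), trains the booster, scores the
#' held-out fold, and computes the fold ROC/AUC. Test-fold rows are withheld
#' from tuning and training by construction. Fold AUCs are summarized as
#' mean +/- sample SD and each fold contributes its top-10 split-count
#' feature importances.
#'
#' @param matrix A `feature_matrix`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; drives fold assignment, tuning, and training.
#' @param budget Tuning trials per fold.
#' @param ranges Hyperparameter search ranges.
#' @return An object of class `cv_report`: list with `fold_auc`, `auc_mean`,
#'   `auc_sd`, `params` (per fold), `importance` (per fold), `roc` (per
#'   fold `roc_result`), `k`, `seed`, `budget`, `pattern`, `n_features`.
#' @export
cross_validate <- function(matrix, k = 5L, seed = 1L, budget = 50L,
                           ranges = default_search_ranges()) {
  stopifnot(inherits(matrix, "feature_matrix"))
  folds <- stratified_folds(matrix$labels, k = k, seed = seed)
  fold_fit <- lapply(seq_len(k), function(f) {
    train <- fm_subset(matrix, folds != f)
    test  <- fm_subset(matrix, folds == f)
    pars  <- tune_params(train, budget = budget, seed = seed + f,
                         ranges = ranges)
    fit   <- train_booster(train, pars, seed = seed + f)
    roc   <- roc_curve(predict_scores(fit, test), test$labels)
    list(params = pars, roc = roc, importance = importance_fscore(fit))
  })
  aucs <- vapply(fold_fit, function(x) x$roc$auc, numeric(1))
  summ <- auc_mean_sd(aucs)
  structure(
    list(fold_auc = aucs, auc_mean = summ$mean, auc_sd = summ$sd,
         params = lapply(fold_fit, `[[`, "params"),
         importance = lapply(fold_fit, `[[`, "importance"),
         roc = lapply(fold_fit, `[[`, "roc"),
         k = as.integer(k), seed = as.integer(seed),
         budget = as.integer(budget), pattern = matrix$pattern,
         n_features = feature_count(matrix)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: pattern (%s), %d-fold, %d features, budget %d>\n",
              x$pattern, x$k, x$n_features, x$budget))
  cat(sprintf("  AUC %.3f +/- %.3f  (folds: %s)\n", x$auc_mean, x$auc_sd,
              paste(sprintf("%.3f", x$fold_auc), collapse = " ")))
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return Invisibly, the report.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  out <- list(
    pattern = report$pattern, k = report$k, seed = report$seed,
    budget = report$budget, n_features = report$n_features,
    fold_auc = report$fold_auc, auc_mean = report$auc_mean,
    auc_sd = report$auc_sd,
    params = lapply(report$params, unclass),
    importance = report$importance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
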