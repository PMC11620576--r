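# small separable feature matrix built directly, avoiding cohort machinery
make_fm <- function(n = 300, p = 5, seed = 1, signal = 2.5, prev = 0.3) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lab <- runif(n) < plogis(qlogis(prev) + signal * (x[, 1] + x[, 2] - 1))
  lab[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  structure(list(patient_ids = sprintf("P%03d", seq_len(n)),
                 feature_names = colnames(x), values = x,
                 labels = lab, pattern = "a"),
            class = "feature_matrix")
}

test_that("stratified folds balance sizes and positives for any n and k", {
  set.seed(31)
  for (case in list(c(60, 2), c(57, 3), c(101, 5), c(260, 4))) {
    n <- case[1]; k <- case[2]
    lab <- runif(n) < 0.3
    lab[seq_len(k)] <- TRUE; lab[k + seq_len(k)] <- FALSE
    fold <- stratified_folds(lab, k = k, seed = 7)
    expect_setequal(unique(fold), seq_len(k))
    sizes <- tabulate(fold, k)
    expect_lte(max(sizes) - min(sizes), 1L)
    pos <- tabulate(fold[lab], k)
    expect_lte(max(pos) - min(pos), 1L)
  }
  expect_error(stratified_folds(c(TRUE, FALSE), k = 5), "exceed|at least")
})

test_that("fold assignment is deterministic in the seed", {
  lab <- rep(c(TRUE, FALSE, FALSE, FALSE), 50)
  expect_identical(stratified_folds(lab, 5, seed = 3),
                   stratified_folds(lab, 5, seed = 3))
  expect_false(identical(as.integer(stratified_folds(lab, 5, seed = 3)),
                         as.integer(stratified_folds(lab, 5, seed = 4))))
})

test_that("hyperparameter objects are validated", {
  p <- boost_params(0.1, 100, 4, 0.8)
  expect_s3_class(p, "boost_params")
  expect_error(boost_params(0, 100, 4, 0.8), "eta")
  expect_error(boost_params(0.1, 0, 4, 0.8), "rounds")
  expect_error(boost_params(0.1, 100, 4, 1.2), "colsample")
})

test_that("a perfectly separating feature is learned to training AUC 1", {
  n <- 80
  fm <- make_fm(n, p = 3, seed = 2)
  fm$values[, 1] <- as.numeric(fm$labels)
  fit <- train_booster(fm, boost_params(0.3, 50, 2, 1), seed = 5)
  expect_equal(roc_curve(predict_scores(fit, fm), fm$labels)$auc, 1.0)
})

test_that("training and prediction are reproducible bit for bit", {
  fm <- make_fm(200, seed = 3)
  p <- boost_params(0.1, 60, 3, 0.7)
  f1 <- train_booster(fm, p, seed = 9)
  f2 <- train_booster(fm, p, seed = 9)
  expect_identical(predict_scores(f1, fm), predict_scores(f2, fm))
})

test_that("prediction refuses a mismatched feature list", {
  fm <- make_fm(120, seed = 4)
  fit <- train_booster(fm, boost_params(0.2, 30, 3, 1), seed = 1)
  other <- fm
  other$feature_names <- rev(other$feature_names)
  expect_error(predict_scores(fit, other), "feature mismatch")
})

test_that("random search respects its ranges and is seed-deterministic", {
  fm <- make_fm(250, seed = 5)
  rg <- list(eta = c(0.05, 0.2), rounds = c(10L, 40L),
             max_depth = c(2L, 4L), colsample_bytree = c(0.5, 1))
  p1 <- tune_params(fm, budget = 4, seed = 11, ranges = rg)
  p2 <- tune_params(fm, budget = 4, seed = 11, ranges = rg)
  expect_equal(unclass(p1)[names(unclass(p1))], unclass(p2)[names(unclass(p2))],
               ignore_attr = TRUE)
  expect_gte(p1$eta, rg$eta[1]); expect_lte(p1$eta, rg$eta[2])
  expect_gte(p1$rounds, rg$rounds[1]); expect_lte(p1$rounds, rg$rounds[2])
  expect_gte(p1$max_depth, rg$max_depth[1]); expect_lte(p1$max_depth, rg$max_depth[2])
  expect_gte(p1$colsample_bytree, rg$colsample_bytree[1])
  # budget 1 returns the single sampled point
  expect_s3_class(tune_params(fm, budget = 1, seed = 2, ranges = rg),
                  "boost_params")
  # on separable data the winning inner AUC is high
  sep <- make_fm(250, seed = 6)
  sep$values[, 1] <- as.numeric(sep$labels)
  expect_gte(attr(tune_params(sep, budget = 2, seed = 3, ranges = rg),
                  "inner_auc"), 0.95)
})

test_that("cross-validation returns one AUC per fold and is reproducible", {
  fm <- make_fm(300, seed = 7)
  rg <- list(eta = c(0.05, 0.3), rounds = c(10L, 40L),
             max_depth = c(2L, 4L), colsample_bytree = c(0.5, 1))
  cv1 <- cross_validate(fm, k = 3, seed = 13, budget = 2, ranges = rg)
  cv2 <- cross_validate(fm, k = 3, seed = 13, budget = 2, ranges = rg)
  expect_length(cv1$fold_auc, 3L)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_equal(cv1$auc_mean, mean(cv1$fold_auc))
  expect_equal(cv1$auc_sd, sd(cv1$fold_auc))
  # informative features give clearly better-than-chance held-out AUC
  expect_gt(cv1$auc_mean, 0.7)
  # importance lists are at most 10 rows, sorted by split count
  for (imp in cv1$importance) {
    expect_lte(nrow(imp), 10L)
    expect_true(!is.unsorted(rev(imp$f_score)))
  }
  # the report serializes to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv1, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$fold_auc, cv1$fold_auc, tolerance = 1e-12)
  expect_equal(parsed$k, 3L)
})
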