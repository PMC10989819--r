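test_that("every family separates a linearly separable toy perfectly", {
  d <- separable_data()
  for (fam in c("nn", "svm_linear", "svm_rbf", "random_forest", "knn")) {
    spec <- classifier_spec(fam, seed = 4)
    model <- fit_classifier(spec, d$X, d$y)
    scores <- predict(model, d$X)
    expect_equal(roc_auc(d$y, scores)$auc, 1,
                 info = paste("family", fam))
  }
})

test_that("training is deterministic given the seed and rejects bad input", {
  d <- separable_data()
  for (fam in c("nn", "random_forest", "knn")) {
    spec <- classifier_spec(fam, seed = 9)
    s1 <- predict(fit_classifier(spec, d$X, d$y), d$X)
    s2 <- predict(fit_classifier(spec, d$X, d$y), d$X)
    expect_identical(s1, s2, info = fam)
  }
  expect_error(fit_classifier(classifier_spec("nn"), d$X, rep(1, 20)),
               "single class")
  bad <- d$X; bad[1, 1] <- NA
  expect_error(fit_classifier(classifier_spec("nn"), bad, d$y), "non-finite")
})

test_that("stratified folds partition samples with near-equal sizes", {
  y <- c(rep(1L, 183), rep(0L, 185))
  folds <- make_folds(y, 5, seed = 1)
  expect_identical(sort(as.integer(table(folds)), decreasing = TRUE),
                   c(74L, 74L, 74L, 73L, 73L))
  # stratification: per-class fold counts differ by at most one
  for (cls in 0:1) {
    counts <- table(folds[y == cls])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_identical(make_folds(y, 5, seed = 1), folds)
})

test_that("cross-validation scores every sample exactly once out-of-fold", {
  d <- separable_data(n = 40, seed = 2)
  res <- crossval_evaluate(classifier_spec("random_forest", seed = 1),
                           d$X, d$y, n_folds = 5, seed = 3)
  expect_false(any(is.na(res$oof_scores)))
  expect_length(res$oof_scores, 40)
  expect_setequal(res$folds, 1:5)
  auc <- res$summary$mean[res$summary$metric == "auc"]
  expect_gt(auc, 0.95)
  expect_error(crossval_evaluate(classifier_spec("knn"), d$X, d$y,
                                 n_folds = 25), "at least n_folds")
})

test_that("label permutation drives every family to chance-level AUC", {
  d <- xor_data(n = 200, seed = 5)
  set.seed(99)
  yperm <- sample(d$y)
  for (fam in c("nn", "svm_linear", "random_forest")) {
    auc <- cv_auc(classifier_spec(fam, seed = 2), d$X, yperm, seed = 13)
    expect_gt(auc, 0.35)
    expect_lt(auc, 0.65)
  }
})

test_that("holdout split moves round(fraction * controls) half-up, disjointly", {
  split <- make_holdout_split(external_case_ids = sprintf("d2_%03d", 1:100),
                              control_ids = sprintf("ctl_%03d", 1:185),
                              train_case_ids = sprintf("cas_%03d", 1:183),
                              control_fraction = 0.3, seed = 1)
  expect_identical(split$n_test_controls, 56)
  expect_length(intersect(split$train_ids, split$test_ids), 0)

  s2 <- make_holdout_split(letters[1:4], paste0("c", 1:10),
                           control_fraction = 0.5, seed = 2)
  expect_identical(s2$n_test_controls, 5)
  s3 <- make_holdout_split(letters[1:4], paste0("c", 1:10),
                           control_fraction = 0.5, seed = 2)
  expect_identical(s2$test_ids, s3$test_ids)
  expect_error(make_holdout_split("a", "c1", control_fraction = 0.05),
               "zero held-out")
})
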