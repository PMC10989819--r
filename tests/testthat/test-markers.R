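test_that("ranking is a permutation with zero importance for constants", {
  set.seed(21)
  X <- cbind(signal = c(rnorm(30, 2), rnorm(30, -2)),
             noise = rnorm(60),
             flat = rep(0.5, 60))
  y <- rep(c(1L, 0L), each = 30)
  rk <- rank_features(X, y, n_trees = 100, n_permutations = 3, seed = 1)
  expect_setequal(rk$feature, colnames(X))
  expect_identical(rk$feature[1], "signal")
  expect_equal(rk$importance[rk$feature == "flat"], 0)
  expect_true(all(diff(rk$importance) <= 1e-12))
  expect_identical(rank_features(X, y, n_trees = 100, n_permutations = 3,
                                 seed = 1), rk)
})

test_that("pure-noise features get importances centred on zero", {
  set.seed(31)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rep(c(0L, 1L), 40)
  rk <- rank_features(X, y, n_trees = 200, n_permutations = 5, seed = 2)
  expect_lt(abs(mean(rk$importance)), 2 * sd(rk$importance))
})

test_that("planted markers are recovered near the top of the ranking", {
  co <- generate_cohort(cohort_config(n_case = 60, n_control = 60,
                                      n_features = 60, n_markers = 6,
                                      effect_size = 1.5, seed = 8))
  rk <- rank_features(co$profile$values, co$metadata$label,
                      n_trees = 300, n_permutations = 5, seed = 8)
  expect_gte(sum(co$truth$marker_ids %in% rk$feature[1:12]), 5)
})

test_that("topk sweep shares folds across k and picks the smallest tied k", {
  d <- separable_data(n = 60, seed = 3)
  X <- cbind(d$X, matrix(rnorm(60 * 8), 60, 8))
  colnames(X) <- paste0("f", 1:10)
  rk <- rank_features(X, d$y, n_trees = 100, n_permutations = 2, seed = 1)
  quick_nn <- nn_spec(epochs = 40)
  sw <- topk_sweep(rk, X, d$y, k_grid = c(2, 4, 6), spec = quick_nn,
                   n_folds = 3, seed = 5)
  # separable signal sits in the first two ranked features: AUC ties at 1
  # across the grid and the smallest k must win
  expect_equal(max(sw$mean_auc), 1)
  expect_identical(sw$selected_k, 2L)
  expect_identical(sw$markers, rk$feature[1:2])
  expect_error(topk_sweep(rk, X, d$y, k_grid = integer(0)), "empty")
  expect_error(topk_sweep(rk, X, d$y, k_grid = c(5, 200)), "exceeds")
})

test_that("marker evaluation transfers between independently drawn cohorts", {
  cc1 <- cohort_config(n_case = 60, n_control = 60, n_features = 40,
                       n_markers = 6, effect_size = 1.5, seed = 11,
                       structure_seed = 100)
  cc2 <- cohort_config(n_case = 60, n_control = 60, n_features = 40,
                       n_markers = 6, effect_size = 1.5, seed = 12,
                       structure_seed = 100)
  train <- generate_cohort(cc1); test <- generate_cohort(cc2)
  markers <- train$truth$marker_ids
  m <- evaluate_markers(markers,
                        train$profile$values, train$metadata$label,
                        test$profile$values, test$metadata$label,
                        spec = nn_spec(epochs = 80))
  expect_gt(m[["auc"]], 0.7)
  expect_error(
    evaluate_markers(c(markers, "sp999"),
                     train$profile$values, train$metadata$label,
                     test$profile$values, test$metadata$label),
    "sp999")
})

test_that("nested evaluation scores held-out folds with refit selection", {
  co <- generate_cohort(cohort_config(n_case = 50, n_control = 50,
                                      n_features = 30, n_markers = 5,
                                      effect_size = 1.5, seed = 13))
  ne <- nested_sweep_evaluate(co$profile$values, co$metadata$label,
                              k_grid = c(5, 10), spec = nn_spec(epochs = 60),
                              outer_folds = 3, n_folds = 3,
                              n_trees = 100, n_permutations = 2, seed = 13)
  expect_length(ne$outer_auc, 3)
  expect_true(all(ne$selected_k %in% c(5, 10)))
  expect_gt(ne$mean_auc, 0.7)
})
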