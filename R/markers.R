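# Marker selection: random-forest importance ranking and the top-k sweep
# scored by the neural network's cross-validated AUC.

#' Rank features by random-forest mean decrease accuracy
#'
#' Fits `n_permutations` independent random forests and averages their
#' out-of-bag permutation importances (Breiman's mean decrease accuracy: for
#' each tree, the drop in accuracy on that tree's out-of-bag samples when a
#' feature's values are permuted, averaged over trees). Averaging over
#' independent replicates smooths the permutation noise of a single forest.
#' A constant feature can never change a prediction and gets importance
#' exactly zero. Ties are broken lexicographically by feature id so the
#' ranking is reproducible.
#'
#' @param X numeric feature matrix (samples in rows; column names used as
#'   feature ids, generated when absent).
#' @param y binary labels with both classes present.
#' @param n_trees trees per forest.
#' @param n_permutations number of independent forest replicates averaged.
#' @param seed integer seed.
#' @return a data.frame of class `importance_ranking` with columns `feature`
#'   and `importance`, ordered by decreasing importance.
#' @export
rank_features <- function(X, y, n_trees = 500L, n_permutations = 10L,
                          seed = 1L) {
  check_finite_matrix(X)
  y <- check_binary_labels(y)
  n_trees <- check_count(n_trees, "n_trees")
  n_permutations <- check_count(n_permutations, "n_permutations")
  ids <- feature_names(X)
  colnames(X) <- ids
  yf <- factor(y, levels = c(0L, 1L))
  imp <- matrix(0, ncol(X), n_permutations, dimnames = list(ids, NULL))
  for (r in seq_len(n_permutations)) {
    rf <- ranger::ranger(x = X, y = yf, num.trees = n_trees,
                         importance = "permutation",
                         seed = as.integer(stage_seed(seed, r)),
                         num.threads = 1L)
    imp[, r] <- rf$variable.importance[ids]
  }
  score <- rowMeans(imp)
  ord <- order(-score, ids)
  structure(data.frame(feature = ids[ord], importance = score[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> %d features; top 5:\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Top-k sweep: cross-validated NN AUC over ranked feature prefixes
#'
#' For each `k` in `k_grid`, evaluates the neural network by stratified
#' cross-validation on the top-k features of the ranking. The fold
#' assignment is computed once and shared across all `k`, so the curve
#' varies only with the feature set. The selected marker set is the top-k
#' prefix at the `k` with the highest mean AUC; on ties the smallest such
#' `k` wins (parsimony).
#'
#' @param ranking an [rank_features()] result.
#' @param X,y the feature matrix and labels the ranking was computed on.
#' @param k_grid integer vector of prefix sizes; the default
#'   `seq(5, 60, by = 5)` is the species-level grid, `seq(5, 100, by = 5)`
#'   suits gene-level profiles. All values must be at most `ncol(X)`.
#' @param spec an [nn_spec()] for the classifier.
#' @param n_folds,seed cross-validation settings.
#' @return a list of class `sweep_result`: `k_grid`, `mean_auc`, `sd_auc`,
#'   `selected_k`, `markers` (feature ids) and the shared `folds`.
#' @export
topk_sweep <- function(ranking, X, y, k_grid = seq(5L, 60L, by = 5L),
                       spec = nn_spec(), n_folds = 5L, seed = 1L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  if (!length(k_grid)) stop("k_grid must not be empty", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (max(k_grid) > ncol(X)) {
    stop("k_grid exceeds the number of features (", ncol(X), ")",
         call. = FALSE)
  }
  colnames(X) <- feature_names(X)
  y <- check_binary_labels(y)
  folds <- make_folds(y, n_folds, seed)
  mean_auc <- sd_auc <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    feats <- ranking$feature[seq_len(k_grid[i])]
    res <- crossval_evaluate(spec, X[, feats, drop = FALSE], y,
                             n_folds = n_folds, seed = seed, folds = folds)
    mean_auc[i] <- res$summary$mean[res$summary$metric == "auc"]
    sd_auc[i] <- res$summary$sd[res$summary$metric == "auc"]
  }
  best <- k_grid[which.max(mean_auc)]  # which.max takes the first maximum
  structure(list(k_grid = k_grid, mean_auc = mean_auc, sd_auc = sd_auc,
                 selected_k = best,
                 markers = ranking$feature[seq_len(best)], folds = folds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> peak mean AUC %.3f at k = %d\n",
              max(x$mean_auc), x$selected_k))
  invisible(x)
}

#' Plot the AUC-versus-k curve of a top-k sweep
#' @param x a `sweep_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, ...) {
  plot(x$k_grid, x$mean_auc, type = "b", pch = 16,
       xlab = "top-k features", ylab = "mean CV AUC", ...)
  points(x$selected_k, max(x$mean_auc), col = "red", pch = 19, cex = 1.4)
  invisible(x)
}

#' Nested (unbiased) evaluation of the marker-selection procedure
#'
#' The plain [topk_sweep()] reports the peak of a curve whose folds also
#' chose `k`, so its peak AUC is optimistically biased as an estimate of
#' generalization. Here the entire selection procedure — importance ranking
#' followed by the top-k sweep — is repeated inside each outer training
#' fold, and the markers chosen there are scored on the held-out outer
#' fold. The mean outer AUC estimates how well the *procedure* (not one
#' fixed marker set) generalizes.
#'
#' @inheritParams topk_sweep
#' @param outer_folds number of outer cross-validation folds.
#' @param n_trees,n_permutations passed to [rank_features()] inside each
#'   outer training fold.
#' @return list with `outer_auc` (per outer fold), `mean_auc`,
#'   `selected_k` (per outer fold) and `folds`.
#' @export
nested_sweep_evaluate <- function(X, y, k_grid = seq(5L, 60L, by = 5L),
                                  spec = nn_spec(), outer_folds = 5L,
                                  n_folds = 5L, n_trees = 500L,
                                  n_permutations = 10L, seed = 1L) {
  colnames(X) <- feature_names(X)
  y <- check_binary_labels(y)
  folds <- make_folds(y, outer_folds, seed)
  outer_auc <- numeric(outer_folds)
  ks <- integer(outer_folds)
  for (f in seq_len(outer_folds)) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]
    fold_seed <- as.integer(stage_seed(seed, 100L + f))
    rk <- rank_features(Xtr, y[!te], n_trees = n_trees,
                        n_permutations = n_permutations, seed = fold_seed)
    sw <- topk_sweep(rk, Xtr, y[!te], k_grid = k_grid, spec = spec,
                     n_folds = n_folds, seed = fold_seed)
    ks[f] <- sw$selected_k
    m <- evaluate_markers(sw$markers, Xtr, y[!te],
                          X[te, , drop = FALSE], y[te], spec = spec)
    outer_auc[f] <- m[["auc"]]
  }
  list(outer_auc = outer_auc, mean_auc = mean(outer_auc), selected_k = ks,
       folds = folds)
}

#' Train on one cohort restricted to markers, evaluate on another
#'
#' @param markers character vector of marker feature ids; every marker must
#'   be present in both feature matrices.
#' @param train_X,train_y training cohort.
#' @param test_X,test_y evaluation cohort.
#' @param spec a [classifier_spec()] or [nn_spec()].
#' @param threshold score threshold for the hard-label metrics.
#' @return named numeric vector: accuracy, precision, recall, f1, auc.
#' @export
evaluate_markers <- function(markers, train_X, train_y, test_X, test_y,
                             spec = nn_spec(), threshold = 0.5) {
  colnames(train_X) <- feature_names(train_X)
  colnames(test_X) <- feature_names(test_X)
  for (nm in list(colnames(train_X), colnames(test_X))) {
    missing <- setdiff(markers, nm)
    if (length(missing)) {
      stop("marker feature absent from data: ", missing[1L], call. = FALSE)
    }
  }
  Xtr <- train_X[, markers, drop = FALSE]
  Xte <- test_X[, markers, drop = FALSE]
  z <- standardize_train_test(Xtr, Xte)
  model <- fit_classifier(spec, z$train, check_binary_labels(train_y))
  scores <- predict(model, z$test)
  score_metrics(as.integer(test_y), scores, threshold = threshold)
}
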