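# One training/scoring contract over the five classifier families, plus the
# stratified cross-validation harness and the external-cohort holdout split.

#' Specification of a classifier
#'
#' Wraps the five families evaluated by the package behind one contract:
#' every fitted model scores new samples with a case-likeness score (higher =
#' more case-like).
#'
#' @param family one of `"nn"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"random_forest"`, `"knn"`.
#' @param cost SVM regularization strength (both kernels).
#' @param gamma RBF kernel width; default `1 / (n_features * var(X))`,
#'   computed at fit time.
#' @param n_trees random-forest tree count.
#' @param k neighbour count for k-nearest-neighbours.
#' @param nn an [nn_spec()] used when `family = "nn"`.
#' @param seed integer seed.
#' @export
classifier_spec <- function(family = c("nn", "svm_linear", "svm_rbf",
                                       "random_forest", "knn"),
                            cost = 1, gamma = NULL, n_trees = 500L, k = 5L,
                            nn = nn_spec(), seed = 1L) {
  family <- match.arg(family)
  check_scalar_number(cost, "cost", min = 1e-12)
  if (!is.null(gamma)) check_scalar_number(gamma, "gamma", min = 1e-12)
  n_trees <- check_count(n_trees, "n_trees")
  k <- check_count(k, "k")
  structure(list(family = family, cost = cost, gamma = gamma,
                 n_trees = n_trees, k = k, nn = nn, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()] or an [nn_spec()] (taken as
#'   `family = "nn"`).
#' @param X numeric feature matrix (samples in rows). Callers are expected to
#'   standardize features; [crossval_evaluate()] does this per fold.
#' @param y binary labels (1 = case, 0 = control), both classes present.
#' @return a fitted model of class `micromark_model`; score new data with
#'   [predict.micromark_model()].
#' @export
fit_classifier <- function(spec, X, y) {
  if (inherits(spec, "nn_spec")) spec <- classifier_spec("nn", nn = spec,
                                                         seed = spec$seed)
  stopifnot(inherits(spec, "classifier_spec"))
  check_finite_matrix(X)
  y <- check_binary_labels(y)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- switch(
    spec$family,
    nn = {
      sp <- spec$nn
      sp$loss <- "cross_entropy"
      nn_train(X, y, sp)
    },
    svm_linear = with_seed(spec$seed,
      e1071::svm(x = X, y = yf, kernel = "linear", cost = spec$cost,
                 scale = FALSE)),
    svm_rbf = {
      gamma <- if (is.null(spec$gamma)) 1 / (ncol(X) * max(var(as.vector(X)),
                                                           1e-12))
               else spec$gamma
      with_seed(spec$seed,
        e1071::svm(x = X, y = yf, kernel = "radial", cost = spec$cost,
                   gamma = gamma, scale = FALSE))
    },
    random_forest = ranger::ranger(
      x = X, y = yf, num.trees = spec$n_trees, probability = TRUE,
      seed = spec$seed, num.threads = 1L),
    knn = list(X = X, y = yf, k = spec$k)  # lazy learner: store the data
  )
  structure(list(family = spec$family, fit = fit, spec = spec),
            class = "micromark_model")
}

#' Score samples with a fitted classifier
#'
#' @param object a `micromark_model` from [fit_classifier()].
#' @param newdata numeric matrix on the same feature scale used for fitting.
#' @param ... unused.
#' @return numeric vector of case-likeness scores (higher = more case-like);
#'   probabilities for the NN, random forest and KNN, decision values for the
#'   SVMs.
#' @export
predict.micromark_model <- function(object, newdata, ...) {
  check_finite_matrix(newdata, "newdata")
  switch(
    object$family,
    nn = nn_forward(object$fit, newdata),
    svm_linear = ,
    svm_rbf = {
      dv <- attr(predict(object$fit, newdata, decision.values = TRUE),
                 "decision.values")
      # e1071 orients decision values toward the first level of its column
      # label ("0/1" means positive favours class 0)
      first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
      if (first == "1") dv[, 1L] else -dv[, 1L]
    },
    random_forest = predict(object$fit, data = newdata,
                            num.threads = 1L)$predictions[, "1"],
    knn = {
      res <- with_seed(object$spec$seed,
        class::knn(train = object$fit$X, test = newdata, cl = object$fit$y,
                   k = object$fit$k, prob = TRUE))
      p <- attr(res, "prob")
      ifelse(res == "1", p, 1 - p)
    }
  )
}

#' Stratified cross-validation folds
#'
#' Random folds stratified by label: each class is shuffled and dealt into
#' folds of as-equal-as-possible size, so fold sizes differ by at most one
#' overall and per class.
#'
#' @param y binary label vector.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments in `1..n_folds`.
#' @export
make_folds <- function(y, n_folds = 5L, seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  y <- as.integer(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      sizes <- rep(length(idx) %/% n_folds, n_folds)
      extra <- length(idx) %% n_folds
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      folds[idx] <- rep.int(seq_len(n_folds), sizes)
    }
  })
  folds
}

# Center/scale columns by training-fold statistics; constant columns pass
# through unscaled.
standardize_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sds <- apply(Xtr, 2L, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  list(train = scale(Xtr, center = mu, scale = sds),
       test = scale(Xte, center = mu, scale = sds))
}

#' Cross-validated evaluation of a classifier
#'
#' Stratified k-fold cross-validation. Feature standardization statistics
#' (per-feature center and scale) are computed on the training folds only and
#' applied to the held-out fold. Hard-label metrics use a score threshold of
#' 0.5 for probabilistic scorers (0 for the margin-based SVMs); AUC is
#' threshold-free. Every sample is scored exactly once out-of-fold.
#'
#' @param spec a [classifier_spec()] or [nn_spec()].
#' @param X numeric feature matrix.
#' @param y binary labels; each class must have at least `n_folds` members.
#' @param n_folds number of folds (default 5).
#' @param seed seed for the fold assignment and per-fold model seeds.
#' @param folds optional pre-computed fold assignment (overrides `seed` for
#'   the partition); used to share identical folds across runs.
#' @param standardize set `FALSE` to skip per-fold feature standardization.
#' @return a list of class `cv_result`: `folds`, `per_fold` (named metric
#'   vectors), `summary` (from [aggregate_folds()]), and `oof_scores` aligned
#'   to the rows of `X`.
#' @export
crossval_evaluate <- function(spec, X, y, n_folds = 5L, seed = 1L,
                              folds = NULL, standardize = TRUE) {
  if (inherits(spec, "nn_spec")) spec <- classifier_spec("nn", nn = spec,
                                                         seed = spec$seed)
  check_finite_matrix(X)
  y <- check_binary_labels(y)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (min(table(y)) < n_folds) {
    stop("each class needs at least n_folds = ", n_folds, " samples",
         call. = FALSE)
  }
  if (is.null(folds)) folds <- make_folds(y, n_folds, seed)
  threshold <- if (spec$family %in% c("svm_linear", "svm_rbf")) 0 else 0.5
  oof <- rep(NA_real_, length(y))
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      z <- standardize_train_test(Xtr, Xte)
      Xtr <- z$train; Xte <- z$test
    }
    sp <- spec
    sp$seed <- as.integer(stage_seed(seed, f))
    if (sp$family == "nn") sp$nn$seed <- sp$seed
    model <- fit_classifier(sp, Xtr, y[!te])
    scores <- predict(model, Xte)
    oof[te] <- scores
    per_fold[[f]] <- score_metrics(y[te], scores, threshold = threshold)
  }
  structure(list(folds = folds, per_fold = per_fold,
                 summary = aggregate_folds(per_fold), oof_scores = oof,
                 family = spec$family),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds\n", x$family, max(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Mean cross-validated AUC of a classifier (convenience wrapper)
#' @inheritParams crossval_evaluate
#' @export
cv_auc <- function(spec, X, y, n_folds = 5L, seed = 1L, folds = NULL) {
  r <- crossval_evaluate(spec, X, y, n_folds = n_folds, seed = seed,
                         folds = folds)
  r$summary$mean[r$summary$metric == "auc"]
}

#' Train/test split with held-out controls for an external case cohort
#'
#' Emulates evaluating on an external cohort that contains only cases: a
#' fraction of the training cohort's controls (rounded half-up) is sampled
#' without replacement and moved to the test set alongside all external case
#' samples; the remaining controls and the original cases form the training
#' set. Train and test sample sets are disjoint.
#'
#' @param external_case_ids sample ids of the external (test) cases.
#' @param control_ids sample ids of the control pool.
#' @param train_case_ids sample ids of the original training cases.
#' @param control_fraction fraction of controls moved to the test set.
#' @param seed integer seed.
#' @return list with `train_ids`, `test_ids`, `test_control_ids` and
#'   `n_test_controls`.
#' @export
make_holdout_split <- function(external_case_ids, control_ids,
                               train_case_ids = character(0),
                               control_fraction = 0.3, seed = 1L) {
  check_scalar_number(control_fraction, "control_fraction", 1e-12, 1 - 1e-12)
  control_ids <- as.character(control_ids)
  n_move <- floor(control_fraction * length(control_ids) + 0.5)  # half-up
  if (n_move < 1) {
    stop("control_fraction yields zero held-out controls", call. = FALSE)
  }
  moved <- with_seed(seed, sample(control_ids, n_move))
  list(train_ids = c(as.character(train_case_ids),
                     setdiff(control_ids, moved)),
       test_ids = c(as.character(external_case_ids), moved),
       test_control_ids = moved,
       n_test_controls = n_move)
}
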