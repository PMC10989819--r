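# Neural-network regression of clinical covariates on marker abundances,
# with out-of-fold predictions and Pearson correlation against the truth.

#' Cross-validated NN regression of a covariate
#'
#' Uses the same dense architecture as the classifier but with a single
#' linear output node and mean-square-error loss. Samples with a missing
#' covariate value are dropped (listwise, with a message). Within each fold
#' the features and the covariate are standardized on the training folds
#' only; predictions are mapped back to the covariate's original units.
#' Every retained sample is predicted exactly once out-of-fold.
#'
#' @param X numeric marker matrix (samples in rows).
#' @param covariate numeric vector aligned to the rows of `X`; may contain
#'   `NA`.
#' @param spec an [nn_spec()]; its loss is forced to `"mse"`.
#' @param n_folds,seed cross-validation settings.
#' @return a list with `predicted` (aligned to the rows of `X`, `NA` where
#'   the covariate was missing), `used` (logical row mask) and `folds`.
#' @export
crossval_regress <- function(X, covariate, spec = nn_spec(loss = "mse"),
                             n_folds = 5L, seed = 1L) {
  check_finite_matrix(X)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  used <- is.finite(covariate)
  if (sum(!used)) {
    message("dropping ", sum(!used), " sample(s) with missing covariate")
  }
  if (sum(used) < 2L * n_folds) {
    stop("need at least ", 2L * n_folds, " samples with a finite covariate",
         call. = FALSE)
  }
  cv <- covariate[used]
  if (sd(cv) == 0) stop("covariate is constant", call. = FALSE)
  Xu <- X[used, , drop = FALSE]
  spec$loss <- "mse"
  # fold assignment stratified over the covariate's order so every fold
  # spans its range
  folds <- integer(length(cv))
  with_seed(seed, {
    ord <- order(cv)
    for (s0 in seq(1L, length(cv), by = n_folds)) {
      grp <- ord[s0:min(s0 + n_folds - 1L, length(cv))]
      folds[grp] <- sample(seq_len(n_folds))[seq_along(grp)]
    }
  })
  pred <- rep(NA_real_, length(cv))
  for (f in seq_len(n_folds)) {
    te <- folds == f
    z <- standardize_train_test(Xu[!te, , drop = FALSE],
                                Xu[te, , drop = FALSE])
    mu <- mean(cv[!te]); sc <- sd(cv[!te])
    if (sc == 0) sc <- 1
    sp <- spec
    sp$seed <- as.integer(stage_seed(seed, f))
    fit <- nn_train(z$train, (cv[!te] - mu) / sc, sp)
    pred[te] <- nn_forward(fit, z$test) * sc + mu
  }
  out <- rep(NA_real_, length(covariate))
  out[used] <- pred
  list(predicted = out, used = used, folds = folds)
}

#' Pearson correlation between predicted and real values
#'
#' Two-sided p-value from the exact t-transform with `n - 2` degrees of
#' freedom.
#'
#' @param predicted,real numeric vectors (pairs with a missing value are
#'   dropped); at least 3 complete pairs, neither vector constant.
#' @return list with `r`, `p` and `n`.
#' @export
correlate_predictions <- function(predicted, real) {
  ok <- is.finite(predicted) & is.finite(real)
  x <- predicted[ok]; y <- real[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation is undefined for a constant vector", call. = FALSE)
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Regress every covariate on the marker profile
#'
#' @param X numeric marker matrix.
#' @param metadata metadata data.frame containing the covariate columns.
#' @param covariates character vector of covariate column names.
#' @inheritParams crossval_regress
#' @return list of class `regression_results`; one entry per covariate with
#'   `covariate`, `predicted`, `r`, `p`, `n`.
#' @export
regress_covariates <- function(X, metadata,
                               covariates = c("fbg", "bmi", "age", "weight"),
                               spec = nn_spec(loss = "mse"), n_folds = 5L,
                               seed = 1L) {
  covariates <- intersect(covariates, colnames(metadata))
  if (!length(covariates)) stop("no requested covariate found", call. = FALSE)
  res <- lapply(seq_along(covariates), function(i) {
    cv <- covariates[i]
    cr <- crossval_regress(X, metadata[[cv]], spec = spec, n_folds = n_folds,
                           seed = as.integer(stage_seed(seed, i)))
    stat <- correlate_predictions(cr$predicted, metadata[[cv]])
    list(covariate = cv, predicted = cr$predicted, r = stat$r, p = stat$p,
         n = stat$n)
  })
  names(res) <- covariates
  structure(res, class = "regression_results")
}

#' @export
print.regression_results <- function(x, ...) {
  cat("<regression_results>\n")
  for (r in x) cat(sprintf("  %-7s r = %6.3f, p = %.3g (n = %d)\n",
                           r$covariate, r$r, r$p, r$n))
  invisible(x)
}

#' Order covariates by strength of association
#'
#' Ascending p-value, ties broken by descending absolute correlation; the
#' first entry is the leading factor.
#'
#' @param results a [regress_covariates()] result (or list of comparable
#'   entries).
#' @return data.frame with `covariate`, `r`, `p`, `n` in rank order.
#' @export
rank_covariates <- function(results) {
  if (!length(results)) stop("no regression results given", call. = FALSE)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(covariate = r$covariate, r = r$r, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$p, -abs(df$r)), , drop = FALSE]
  rownames(df) <- NULL
  df
}
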