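# High-level fitting interface: run the whole marker-discovery workflow on a
# paired cohort and return one inspectable object.

#' Fit the full marker-discovery workflow
#'
#' Runs, in order: random-forest importance ranking ([rank_features()]), the
#' top-k NN cross-validated AUC sweep that defines the marker set
#' ([topk_sweep()]), cross-validated evaluation of the marker set for the
#' requested classifier families, directed interaction-network inference on
#' the markers with the row-variance refinement ([infer_adjacency()],
#' [refine_adjacency()], [top_edges()], [hub_report()]), NN regression of
#' each covariate on the markers ([regress_covariates()]), per-feature
#' Kruskal-Wallis testing, and quantile stratification over the leading
#' covariate ([stratify_profile()]).
#'
#' All stage seeds are fanned out deterministically from `seed`.
#'
#' @param profile an [abundance_profile()].
#' @param metadata a metadata data.frame (see [read_sample_metadata()]).
#' @param k_grid prefix sizes for the marker sweep.
#' @param nn an [nn_spec()] used for the sweep, evaluation and regression.
#' @param families classifier families evaluated on the selected markers.
#' @param covariates covariate columns to regress and stratify on; the
#'   stratification covariate is the top-ranked one.
#' @param n_folds cross-validation folds.
#' @param n_trees_rank,n_permutations ranking parameters.
#' @param n_edges how many network edges to keep.
#' @param hub_thresholds partner-count thresholds for the hub report.
#' @param seed master seed.
#' @return an object of class `micromark_fit`.
#' @export
micromark_fit <- function(profile, metadata, k_grid = seq(5L, 60L, by = 5L),
                          nn = nn_spec(),
                          families = c("nn", "svm_linear", "svm_rbf",
                                       "random_forest", "knn"),
                          covariates = c("fbg", "bmi", "age", "weight"),
                          n_folds = 5L, n_trees_rank = 500L,
                          n_permutations = 10L, n_edges = 100L,
                          hub_thresholds = c(5L, 10L), seed = 1L) {
  paired <- align_cohort(profile, metadata)
  X <- paired$profile$values
  y <- paired$y

  ranking <- rank_features(X, y, n_trees = n_trees_rank,
                           n_permutations = n_permutations,
                           seed = stage_seed(seed, 1L))
  sweep <- topk_sweep(ranking, X, y, k_grid = k_grid, spec = nn,
                      n_folds = n_folds, seed = stage_seed(seed, 2L))
  markers <- sweep$markers
  Xm <- X[, markers, drop = FALSE]

  cv <- lapply(families, function(fam) {
    spec <- if (fam == "nn") classifier_spec("nn", nn = nn)
            else classifier_spec(fam)
    crossval_evaluate(spec, Xm, y, n_folds = n_folds,
                      seed = stage_seed(seed, 3L), folds = sweep$folds)
  })
  names(cv) <- families

  adj <- infer_adjacency(Xm, seed = stage_seed(seed, 4L))
  refined <- refine_adjacency(adj)
  edges <- top_edges(refined, n = n_edges)
  hubs <- hub_report(edges, thresholds = hub_thresholds)

  covariates <- intersect(covariates, colnames(paired$metadata))
  regression <- if (length(covariates)) {
    regress_covariates(Xm, paired$metadata, covariates = covariates,
                       spec = nn, n_folds = n_folds,
                       seed = stage_seed(seed, 5L))
  } else NULL
  cov_ranking <- if (!is.null(regression)) rank_covariates(regression)

  kw <- kruskal_wallis_per_feature(Xm, y)
  stratified <- if (!is.null(cov_ranking) && nrow(cov_ranking)) {
    lead <- cov_ranking$covariate[1L]
    tryCatch(
      stratify_profile(subset_features(paired$profile, markers),
                       paired$metadata[[lead]], y),
      error = function(e) {
        warning("stratification skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  } else NULL

  # final model on all samples for scoring new profiles
  mu <- colMeans(Xm)
  sds <- apply(Xm, 2L, sd); sds[sds == 0] <- 1
  nn_final <- nn
  nn_final$seed <- as.integer(stage_seed(seed, 6L))
  final_model <- fit_classifier(classifier_spec("nn", nn = nn_final),
                                scale(Xm, mu, sds), y)

  structure(list(ranking = ranking, sweep = sweep, markers = markers,
                 cv = cv, adjacency = adj, refined = refined, edges = edges,
                 hubs = hubs, regression = regression,
                 covariate_ranking = cov_ranking, kruskal_wallis = kw,
                 stratified = stratified, final_model = final_model,
                 scaling = list(center = mu, scale = sds),
                 n_samples = length(y), seed = seed),
            class = "micromark_fit")
}

#' @export
print.micromark_fit <- function(x, ...) {
  nn_auc <- x$cv$nn$summary
  cat("<micromark_fit>\n")
  cat(sprintf("  samples: %d, features ranked: %d\n", x$n_samples,
              nrow(x$ranking)))
  cat(sprintf("  selected markers: %d (peak mean CV AUC %.3f)\n",
              length(x$markers), max(x$sweep$mean_auc)))
  if (!is.null(nn_auc)) {
    cat(sprintf("  NN marker-set CV AUC: %.3f +/- %.3f\n",
                nn_auc$mean[nn_auc$metric == "auc"],
                nn_auc$sd[nn_auc$metric == "auc"]))
  }
  cat(sprintf("  network: %d edges kept\n", nrow(x$edges)))
  if (!is.null(x$covariate_ranking)) {
    cat(sprintf("  leading covariate: %s (r = %.3f, p = %.3g)\n",
                x$covariate_ranking$covariate[1L], x$covariate_ranking$r[1L],
                x$covariate_ranking$p[1L]))
  }
  invisible(x)
}

#' @export
summary.micromark_fit <- function(object, ...) {
  cat("Marker-discovery workflow summary\n")
  cat("=================================\n")
  print(object)
  cat("\nAUC-vs-k curve:\n")
  print(data.frame(k = object$sweep$k_grid,
                   mean_auc = round(object$sweep$mean_auc, 4),
                   sd_auc = round(object$sweep$sd_auc, 4)))
  cat("\nClassifier comparison on the marker set (mean CV AUC):\n")
  for (fam in names(object$cv)) {
    s <- object$cv[[fam]]$summary
    cat(sprintf("  %-14s %.3f\n", fam, s$mean[s$metric == "auc"]))
  }
  sig <- sum(object$kruskal_wallis$class != "not-significant")
  cat(sprintf("\nMarkers with significant marginal shift: %d of %d\n",
              sig, length(object$markers)))
  if (!is.null(object$covariate_ranking)) {
    cat("\nCovariate association ranking:\n")
    print(object$covariate_ranking)
  }
  invisible(object)
}

#' Plot the marker sweep curve of a fitted workflow
#' @param x a `micromark_fit`.
#' @param ... passed on to [plot.sweep_result()].
#' @export
plot.micromark_fit <- function(x, ...) {
  plot(x$sweep, main = "NN cross-validated AUC vs top-k features", ...)
}

#' Score new samples with the fitted marker model
#'
#' Applies the final neural network (trained on all paired samples,
#' restricted to the selected markers, using the training cohort's
#' standardization) to a new profile.
#'
#' @param object a `micromark_fit`.
#' @param newdata an [abundance_profile()] or numeric matrix containing all
#'   marker features.
#' @param ... unused.
#' @return named vector of case-probability scores.
#' @export
predict.micromark_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "abundance_profile")) newdata$values
       else newdata
  missing <- setdiff(object$markers, colnames(X))
  if (length(missing)) {
    stop("marker feature absent from new data: ", missing[1L], call. = FALSE)
  }
  Xm <- scale(X[, object$markers, drop = FALSE],
              center = object$scaling$center, scale = object$scaling$scale)
  scores <- predict(object$final_model, Xm)
  names(scores) <- rownames(X)
  scores
}
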