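# Covariate-quantile stratification of marker abundances and per-feature
# Kruskal-Wallis case/control testing.

#' Quantile bin boundaries and assignments
#'
#' Boundaries come from linear-interpolation quantiles (the common
#' statistical convention, `quantile(type = 7)`). Values are assigned to
#' half-open intervals `[b_{k-1}, b_k)`, with the first interval open below
#' and the last closed above, so every value lands in exactly one bin.
#'
#' @param values numeric vector (at least 4 finite values, not all equal).
#' @param probs strictly increasing probabilities in (0, 1); the default
#'   quartile probabilities give bins Q1..Q4.
#' @return list with `boundaries`, integer `assignments` (1-based bin
#'   index, `NA` for missing values) and `labels` (`"Q1"`, ...).
#' @export
quantile_bins <- function(values, probs = c(0.25, 0.5, 0.75)) {
  finite <- values[is.finite(values)]
  if (length(finite) < 4L) stop("need at least 4 finite values", call. = FALSE)
  if (any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1)) {
    stop("probs must be strictly increasing within (0, 1)", call. = FALSE)
  }
  if (max(finite) == min(finite)) {
    stop("all values are identical; no quantile bins possible", call. = FALSE)
  }
  boundaries <- unname(quantile(finite, probs = probs, type = 7))
  if (any(diff(boundaries) <= 0)) {
    stop("quantile boundaries are not strictly increasing; ",
         "reduce the number of bins", call. = FALSE)
  }
  assignments <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  assignments[ok] <- findInterval(values[ok], boundaries,
                                  left.open = FALSE) + 1L
  labels <- paste0("Q", seq_len(length(probs) + 1L))
  list(boundaries = boundaries, assignments = assignments, labels = labels)
}

#' Mean abundance of each feature within each bin
#'
#' @param profile an [abundance_profile()].
#' @param assignments integer bin assignment per sample (from
#'   [quantile_bins()]); every bin in `1..max` must be non-empty.
#' @return feature-by-bin matrix of arithmetic means.
#' @export
binned_means <- function(profile, assignments) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (length(assignments) != length(profile$sample_ids)) {
    stop("assignments length must match the number of samples", call. = FALSE)
  }
  bins <- seq_len(max(assignments, na.rm = TRUE))
  out <- matrix(NA_real_, length(profile$feature_ids), length(bins),
                dimnames = list(profile$feature_ids, paste0("Q", bins)))
  for (b in bins) {
    rows <- which(assignments == b)
    if (!length(rows)) stop("bin Q", b, " is empty", call. = FALSE)
    out[, b] <- colMeans(profile$values[rows, , drop = FALSE])
  }
  out
}

#' Min-max normalize each row to `[0, 1]`
#'
#' Rows are mapped by `(x - min) / (max - min)`, so every non-constant row
#' attains both 0 and 1; a constant row carries no pattern and maps to all
#' zeros with a warning. Invariant under positive affine transforms of a
#' row.
#'
#' @param m numeric matrix.
#' @export
minmax_rows <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    rng <- range(m[i, ])
    if (rng[1L] == rng[2L]) {
      warning("row ", if (!is.null(rownames(m))) rownames(m)[i] else i,
              " is constant; normalized to zero", call. = FALSE)
      out[i, ] <- 0
    } else {
      out[i, ] <- (m[i, ] - rng[1L]) / (rng[2L] - rng[1L])
    }
  }
  out
}

#' Per-feature Kruskal-Wallis case/control test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value
#' (1 degree of freedom for two groups). Each feature is classed
#' `higher-in-case` or `higher-in-control` when `p < alpha` by the sign of
#' the case-minus-control mean-rank difference, otherwise
#' `not-significant`. A feature constant across all samples has `H = 0`,
#' `p = 1`.
#'
#' @param profile an [abundance_profile()] (or a numeric matrix).
#' @param labels binary labels (1 = case), both groups with at least 2
#'   samples.
#' @param alpha significance level (default 0.05; no multiple-testing
#'   correction, matching raw per-feature coloring. Apply
#'   [stats::p.adjust()] to the `p` column for a corrected view.)
#' @return data.frame with `feature`, `H`, `p`, `class`.
#' @export
kruskal_wallis_per_feature <- function(profile, labels, alpha = 0.05) {
  values <- if (inherits(profile, "abundance_profile")) profile$values
            else profile
  labels <- as.integer(labels)
  if (min(table(labels)) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  g <- factor(labels, levels = c(0L, 1L))
  ids <- if (!is.null(colnames(values))) colnames(values)
         else sprintf("f%03d", seq_len(ncol(values)))
  H <- p <- numeric(ncol(values))
  cls <- character(ncol(values))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    if (max(x) == min(x)) {
      H[j] <- 0; p[j] <- 1; cls[j] <- "not-significant"
      next
    }
    kt <- kruskal.test(x, g)
    H[j] <- unname(kt$statistic)
    p[j] <- kt$p.value
    if (p[j] < alpha) {
      r <- rank(x)
      dr <- mean(r[labels == 1L]) - mean(r[labels == 0L])
      cls[j] <- if (dr > 0) "higher-in-case" else "higher-in-control"
    } else {
      cls[j] <- "not-significant"
    }
  }
  data.frame(feature = ids, H = H, p = p, class = cls,
             stringsAsFactors = FALSE)
}

#' Stratify marker abundances over covariate quantiles
#'
#' The full heat-map pipeline: quantile-bin the covariate, average each
#' feature within each bin, min-max normalize each feature row to `[0, 1]`,
#' and attach the per-feature Kruskal-Wallis significance class.
#'
#' @param profile an [abundance_profile()] (typically restricted to the
#'   marker features).
#' @param covariate numeric covariate aligned to the samples.
#' @param labels binary case/control labels aligned to the samples.
#' @param probs quantile probabilities (default quartiles).
#' @param alpha significance level for the per-feature test.
#' @return list of class `stratified_matrix`: `matrix` (feature x bin,
#'   values in `[0, 1]`), `raw_means`, `boundaries`, `labels`,
#'   `assignments`, `significance` (from [kruskal_wallis_per_feature()]).
#' @export
stratify_profile <- function(profile, covariate, labels,
                             probs = c(0.25, 0.5, 0.75), alpha = 0.05) {
  qb <- quantile_bins(covariate, probs = probs)
  keep <- !is.na(qb$assignments)
  prof <- profile
  if (any(!keep)) {
    message("dropping ", sum(!keep), " sample(s) with missing covariate")
    prof <- abundance_profile(profile$values[keep, , drop = FALSE],
                              profile$sample_ids[keep], profile$feature_ids,
                              allow_zero_rows = TRUE)
  }
  means <- binned_means(prof, qb$assignments[keep])
  sig <- kruskal_wallis_per_feature(profile, labels, alpha = alpha)
  structure(list(matrix = minmax_rows(means), raw_means = means,
                 boundaries = qb$boundaries, labels = qb$labels,
                 assignments = qb$assignments, significance = sig),
            class = "stratified_matrix")
}

#' @export
print.stratified_matrix <- function(x, ...) {
  cat(sprintf("<stratified_matrix> %d features x %d bins; boundaries: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(signif(x$boundaries, 4), collapse = ", ")))
  invisible(x)
}

#' Write a stratified matrix as TSV
#'
#' Boundary header line (as a comment), then one row per feature with the
#' normalized bin means and the significance class.
#'
#' @param x a [stratify_profile()] result.
#' @param path output path.
#' @export
write_stratified_tsv <- function(x, path) {
  stopifnot(inherits(x, "stratified_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# quantile boundaries: %s",
                     paste(sprintf("%.12g", x$boundaries), collapse = "\t")),
             con)
  df <- data.frame(feature = rownames(x$matrix),
                   apply(x$matrix, 2L, function(col) sprintf("%.12g", col)),
                   class = x$significance$class[
                     match(rownames(x$matrix), x$significance$feature)],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
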