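# Relative-abundance profiles and sample metadata: construction, IO,
# validation, filtering and alignment.

#' Construct a relative-abundance profile
#'
#' An `abundance_profile` holds a samples-by-features matrix of non-negative
#' relative abundances together with unique sample and feature identifiers.
#' Rows need not sum to one on construction (see [renormalize()]), but every
#' value must be finite and non-negative and no sample row may be all zero.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the row names of `values`.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to the column names of `values`.
#' @param allow_zero_rows accept samples with all-zero abundances. Full
#'   profiles reject them (an unobserved sample is a data error), but a
#'   subset of features can legitimately leave a sample empty.
#' @return an object of class `abundance_profile` with elements `values`
#'   (the matrix, dimnames set), `sample_ids` and `feature_ids`.
#' @export
abundance_profile <- function(values, sample_ids = rownames(values),
                              feature_ids = colnames(values),
                              allow_zero_rows = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample and feature identifiers are required", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values)) {
    stop("identifier lengths do not match the matrix dimensions", call. = FALSE)
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicate sample id: ", dup[1L], call. = FALSE)
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) {
    stop("duplicate feature id: ", dup[1L], call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid abundance at sample '%s', feature '%s': %s",
                 sample_ids[bad[1L, 1L]], feature_ids[bad[1L, 2L]],
                 values[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  if (!allow_zero_rows) {
    zero <- which(rowSums(values) == 0)
    if (length(zero)) {
      stop("sample '", sample_ids[zero[1L]], "' has all-zero abundances",
           call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> %d samples x %d features\n",
              length(x$sample_ids), length(x$feature_ids)))
  rs <- rowSums(x$values)
  cat(sprintf("  row sums: %.4g .. %.4g\n", min(rs), max(rs)))
  invisible(x)
}

#' Read a relative-abundance table from TSV
#'
#' Expects a tab-separated table with one header row of identifiers and one
#' identifier column; the body must be numeric and non-negative. Values are
#' accepted on either the fraction (`[0, 1]`) or percentage (`[0, 100]`)
#' scale: if the median row sum exceeds 10 the table is treated as
#' percentages and divided by 100 (a message records this). Profiles are
#' always returned in the canonical samples-as-rows orientation.
#'
#' @param path path to the TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`;
#'   the latter transposes on read.
#' @return an [abundance_profile()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_as_rows",
                                                 "features_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("table needs an id column and at least one data column",
                           call. = FALSE)
  ids <- as.character(raw[[1L]])
  other_ids <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1L, 1L]], other_ids[bad[1L, 2L]],
                 body[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance at row '%s', column '%s': %s",
                 ids[neg[1L, 1L]], other_ids[neg[1L, 2L]],
                 num[neg[1L, , drop = FALSE]]), call. = FALSE)
  }
  if (orientation == "features_as_rows") {
    values <- t(num)
    sample_ids <- other_ids
    feature_ids <- ids
  } else {
    values <- num
    sample_ids <- ids
    feature_ids <- other_ids
  }
  if (stats::median(rowSums(values)) > 10) {
    message("row sums suggest percentage scale; dividing by 100")
    values <- values / 100
  }
  abundance_profile(values, sample_ids, feature_ids)
}

#' Write a relative-abundance table to TSV
#'
#' Values are written with 15 significant digits so a read/write round trip
#' is the identity to within 1e-12.
#'
#' @inheritParams read_abundance_table
#' @param profile an [abundance_profile()].
#' @export
write_abundance_table <- function(profile, path,
                                  orientation = c("samples_as_rows",
                                                  "features_as_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(profile, "abundance_profile"))
  if (orientation == "samples_as_rows") {
    m <- profile$values
    id_col <- "sample_id"
  } else {
    m <- t(profile$values)
    id_col <- "feature_id"
  }
  out <- data.frame(rownames(m),
                    apply(m, 2L, function(col) sprintf("%.15g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c(id_col, colnames(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalize each sample row to sum to one
#'
#' @param profile an [abundance_profile()].
#' @return the profile with every row divided by its sum. Idempotent.
#' @export
renormalize <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"))
  rs <- rowSums(profile$values)
  zero <- which(rs == 0)
  if (length(zero)) {
    stop("sample '", profile$sample_ids[zero[1L]],
         "' has all-zero abundances and cannot be renormalized", call. = FALSE)
  }
  abundance_profile(profile$values / rs, profile$sample_ids,
                    profile$feature_ids)
}

#' Drop features observed in too few samples
#'
#' Removes features with a nonzero abundance in fewer than `min_samples`
#' samples, preserving the order of surviving features. With
#' `min_samples = 1` the profile is returned unchanged.
#'
#' @param profile an [abundance_profile()].
#' @param min_samples minimum number of samples in which a feature must be
#'   nonzero to be retained.
#' @export
filter_min_prevalence <- function(profile, min_samples) {
  stopifnot(inherits(profile, "abundance_profile"))
  min_samples <- check_count(min_samples, "min_samples", min = 1L)
  keep <- colSums(profile$values > 0) >= min_samples
  if (!any(keep)) {
    stop("no feature is present in at least ", min_samples, " samples",
         call. = FALSE)
  }
  subset_features(profile, profile$feature_ids[keep])
}

#' Subset a profile to a set of features
#'
#' @param profile an [abundance_profile()].
#' @param features character vector of feature ids to keep, in the order
#'   given.
#' @param renormalize if `TRUE`, rows are rescaled to sum to one after the
#'   subset. The default keeps raw relative abundances so subset profiles
#'   remain comparable with the full table.
#' @export
subset_features <- function(profile, features, renormalize = FALSE) {
  stopifnot(inherits(profile, "abundance_profile"))
  missing <- setdiff(features, profile$feature_ids)
  if (length(missing)) {
    stop("unknown feature id: ", missing[1L], call. = FALSE)
  }
  out <- abundance_profile(profile$values[, features, drop = FALSE],
                           profile$sample_ids, features,
                           allow_zero_rows = TRUE)
  if (renormalize) out <- renormalize(out)
  out
}

#' Read per-sample metadata from TSV
#'
#' Requires columns `sample_id` and `label` (0 = control, 1 = case); the
#' covariate columns `fbg` (fasting blood glucose, mmol/L), `bmi` (kg/m^2),
#' `age` (years) and `weight` (kg) are read when present and may contain
#' missing values. Extra columns are ignored with a message.
#'
#' @param path path to the metadata TSV.
#' @return a `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata frame
#'
#' @param df data.frame with at least `sample_id` and `label` columns.
#' @export
validate_metadata <- function(df) {
  known <- c("sample_id", "label", "fbg", "bmi", "age", "weight")
  if (!all(c("sample_id", "label") %in% colnames(df))) {
    stop("metadata needs 'sample_id' and 'label' columns", call. = FALSE)
  }
  extra <- setdiff(colnames(df), known)
  if (length(extra)) {
    message("ignoring metadata columns: ", paste(extra, collapse = ", "))
  }
  df <- df[, intersect(known, colnames(df)), drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id in metadata: ", dup[1L],
                        call. = FALSE)
  if (any(is.na(df$label)) || !all(df$label %in% c(0, 1))) {
    stop("labels must be 0 (control) or 1 (case) with no missing values",
         call. = FALSE)
  }
  df$label <- as.integer(df$label)
  for (cv in intersect(c("fbg", "bmi", "age", "weight"), colnames(df))) {
    v <- df[[cv]]
    if (!is.numeric(v)) stop("covariate '", cv, "' must be numeric",
                             call. = FALSE)
    if (any(!is.na(v) & !is.finite(v))) {
      stop("covariate '", cv, "' contains non-finite values", call. = FALSE)
    }
  }
  df
}

#' Write sample metadata to TSV
#' @param metadata validated metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair a profile with sample metadata
#'
#' Inner-joins on `sample_id`, preserving the profile's sample order.
#' Samples present on only one side are dropped with a message.
#'
#' @param profile an [abundance_profile()].
#' @param metadata a metadata data.frame (see [read_sample_metadata()]).
#' @return a list of class `paired_cohort` with the subset `profile`, the
#'   reordered `metadata`, and the label vector `y`.
#' @export
align_cohort <- function(profile, metadata) {
  stopifnot(inherits(profile, "abundance_profile"))
  metadata <- validate_metadata(metadata)
  shared <- profile$sample_ids[profile$sample_ids %in% metadata$sample_id]
  if (!length(shared)) {
    stop("profile and metadata share no sample ids", call. = FALSE)
  }
  dropped <- c(setdiff(profile$sample_ids, shared),
               setdiff(metadata$sample_id, shared))
  if (length(dropped)) {
    message("dropped ", length(dropped), " unmatched sample(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  prof <- abundance_profile(profile$values[shared, , drop = FALSE],
                            shared, profile$feature_ids)
  md <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  structure(list(profile = prof, metadata = md, y = md$label),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d samples (%d case / %d control), %d features\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0),
              length(x$profile$feature_ids)))
  invisible(x)
}
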