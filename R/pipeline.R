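# Batch pipeline: run the full workflow from a config (list or YAML file),
# write all stage outputs and a run manifest.

#' Run the full workflow from a configuration
#'
#' Validates the configuration (referenced input files must exist) before
#' any computation, then either loads the profile/metadata from TSV or
#' generates a synthetic cohort, fits the workflow with [micromark_fit()],
#' and writes: `markers.json` (ranking, AUC-vs-k curve, selected markers),
#' `cv_metrics.json`, `network_edges.tsv`, `network.graphml`,
#' `regression.json`, `stratified.tsv` and `manifest.json` (package
#' version, seed, parameter echo, per-output MD5 hashes). Outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure. Recognized fields: `seed`; `profile`/`metadata` (input TSV
#'   paths) or `simulate` (arguments for [cohort_config()]); `orientation`;
#'   `out_dir`; and optional parameter blocks `k_grid`, `families`,
#'   `covariates`, `n_folds`, `n_edges`, `nn` (arguments for [nn_spec()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the `micromark_fit` object, invisibly, with the written file
#'   paths attached as attribute `"outputs"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- out_dir %||% config$out_dir %||% stop("config must set out_dir",
                                                   call. = FALSE)

  # validate referenced inputs before any compute
  if (is.null(config$simulate)) {
    for (f in c(config$profile, config$metadata)) {
      if (is.null(f) || !file.exists(f)) {
        stop("input file missing: ", if (is.null(f)) "(unset)" else f,
             call. = FALSE)
      }
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    cc <- do.call(cohort_config,
                  modifyList(config$simulate, list(seed = seed)))
    cohort <- generate_cohort(cc)
    profile <- cohort$profile
    metadata <- cohort$metadata
  } else {
    profile <- read_abundance_table(config$profile,
                                    orientation = config$orientation %||%
                                      "samples_as_rows")
    metadata <- read_sample_metadata(config$metadata)
  }

  nn <- if (is.null(config$nn)) nn_spec() else do.call(nn_spec, config$nn)
  fit <- micromark_fit(
    profile, metadata,
    k_grid = config$k_grid %||% seq(5L, 60L, by = 5L),
    nn = nn,
    families = config$families %||% c("nn", "random_forest"),
    covariates = config$covariates %||% c("fbg", "bmi", "age", "weight"),
    n_folds = config$n_folds %||% 5L,
    n_edges = config$n_edges %||% 100L,
    seed = seed)

  paths <- c(markers = file.path(out_dir, "markers.json"),
             cv = file.path(out_dir, "cv_metrics.json"),
             edges = file.path(out_dir, "network_edges.tsv"),
             graphml = file.path(out_dir, "network.graphml"),
             regression = file.path(out_dir, "regression.json"),
             stratified = file.path(out_dir, "stratified.tsv"),
             manifest = file.path(out_dir, "manifest.json"))

  write_json <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  write_json(list(ranking = as.data.frame(fit$ranking),
                  curve = data.frame(k = fit$sweep$k_grid,
                                     mean_auc = fit$sweep$mean_auc,
                                     sd_auc = fit$sweep$sd_auc),
                  selected_k = fit$sweep$selected_k,
                  markers = fit$markers), paths[["markers"]])
  write_json(lapply(fit$cv, function(r) list(summary = r$summary,
                                             per_fold = r$per_fold)),
             paths[["cv"]])
  export_graph(fit$edges, paths[["edges"]], format = "tsv")
  export_graph(fit$edges, paths[["graphml"]], format = "graphml")
  write_json(if (is.null(fit$regression)) list() else
               lapply(fit$regression, function(r) {
                 r[c("covariate", "r", "p", "n")]
               }), paths[["regression"]])
  if (!is.null(fit$stratified)) {
    write_stratified_tsv(fit$stratified, paths[["stratified"]])
  } else {
    writeLines("# stratification unavailable", paths[["stratified"]])
  }

  hashes <- vapply(paths[setdiff(names(paths), "manifest")],
                   function(p) unname(tools::md5sum(p)), character(1L))
  write_json(list(package = "micromark",
                  version = as.character(utils::packageVersion("micromark")),
                  seed = seed,
                  parameters = config[setdiff(names(config),
                                              c("profile", "metadata"))],
                  outputs = as.list(hashes)),
             paths[["manifest"]])
  attr(fit, "outputs") <- paths
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic cohort to disk
#'
#' Writes the profile TSV, metadata TSV and planted-truth JSON produced by
#' [generate_cohort()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_prefix path prefix for `profile.tsv`, `metadata.tsv`,
#'   `truth.json`.
#' @return named vector of written paths.
#' @export
write_cohort <- function(cohort, out_prefix) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dirname(file.path(out_prefix, "x")), showWarnings = FALSE,
             recursive = TRUE)
  paths <- c(profile = paste0(out_prefix, "profile.tsv"),
             metadata = paste0(out_prefix, "metadata.tsv"),
             truth = paste0(out_prefix, "truth.json"))
  write_abundance_table(cohort$profile, paths[["profile"]])
  write_sample_metadata(cohort$metadata, paths[["metadata"]])
  truth <- cohort$truth
  truth$flat_pairs <- if (nrow(truth$flat_pairs)) {
    apply(truth$flat_pairs, 1L, identity, simplify = FALSE)
  } else list()
  truth$effect_signs <- as.list(truth$effect_signs)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
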