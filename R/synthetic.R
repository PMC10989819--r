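# Synthetic case/control cohorts with planted ground truth.
#
# The generator works on a latent log-abundance scale: marker effects, planted
# directed dependencies and covariate couplings are all defined there, then
# structural zeros are applied and each sample row is closed to sum to one.
# Compositional closure attenuates the realized effect sizes relative to the
# latent ones, which downstream recovery tests take into account.

#' Configuration for a synthetic case/control cohort
#'
#' @param n_case,n_control numbers of case and control samples.
#' @param n_features total number of features (species/genes).
#' @param n_markers number of signal-carrying features.
#' @param frac_flat_markers fraction of markers whose marginal case/control
#'   distributions are identical; their signal enters only through a
#'   label-dependent pairwise interaction (the within-pair correlation flips
#'   sign between groups), so a rank test on either member stays at the null
#'   while the pair is jointly predictive.
#' @param effect_size latent log-scale mean shift applied to cases for each
#'   non-flat marker (sign alternates across markers).
#' @param planted_edges optional data.frame with columns `source`, `target`
#'   (feature indices) and `coef`, realized as directed dependencies on the
#'   latent scale; must form a DAG.
#' @param covariate_spec named list describing how covariates are coupled to
#'   markers; see [default_covariate_spec()]. Covariates are weighted sums of
#'   coupled markers' latent values plus Gaussian noise, mapped to realistic
#'   clinical units, with fasting blood glucose additionally shifted upward
#'   in cases.
#' @param sparsity probability that a feature is structurally zero in a
#'   sample.
#' @param flat_pair_cor magnitude of the within-pair latent correlation used
#'   for flat markers (`+` in cases, `-` in controls).
#' @param seed integer seed; all draws flow from one generator.
#' @param structure_seed optional separate seed for the cohort's structural
#'   draws (feature base means, marker identities, effect signs, covariate
#'   weights). Defaults to `seed`. Two configs sharing a `structure_seed`
#'   but differing in `seed` describe independent sample draws from the
#'   same population, e.g. a train/test pair.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_case = 100, n_control = 100, n_features = 200,
                          n_markers = 20, frac_flat_markers = 0,
                          effect_size = 1, planted_edges = NULL,
                          covariate_spec = default_covariate_spec(),
                          sparsity = 0.3, flat_pair_cor = 0.9, seed = 1,
                          structure_seed = NULL) {
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  n_features <- check_count(n_features, "n_features")
  n_markers <- check_count(n_markers, "n_markers", min = 0L)
  check_scalar_number(frac_flat_markers, "frac_flat_markers", 0, 1)
  check_scalar_number(effect_size, "effect_size", 0)
  check_scalar_number(sparsity, "sparsity", 0, 0.99)
  check_scalar_number(flat_pair_cor, "flat_pair_cor", 0, 0.999)
  if (n_markers > n_features) {
    stop("n_markers exceeds n_features", call. = FALSE)
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("source", "target", "coef") %in% colnames(planted_edges)))
    if (any(planted_edges$source < 1 | planted_edges$source > n_features |
            planted_edges$target < 1 | planted_edges$target > n_features)) {
      stop("planted edge endpoints must be valid feature indices",
           call. = FALSE)
    }
  }
  structure(list(n_case = n_case, n_control = n_control,
                 n_features = n_features, n_markers = n_markers,
                 frac_flat_markers = frac_flat_markers,
                 effect_size = effect_size, planted_edges = planted_edges,
                 covariate_spec = covariate_spec, sparsity = sparsity,
                 flat_pair_cor = flat_pair_cor, seed = as.integer(seed),
                 structure_seed = as.integer(if (is.null(structure_seed))
                   seed else structure_seed)),
            class = "cohort_config")
}

#' Default covariate coupling specification
#'
#' Each covariate is a weighted sum of the latent values of its coupled
#' markers plus Gaussian noise, standardized and mapped to clinical units as
#' `location + scale * value`. Fasting blood glucose (mmol/L) is coupled with
#' the least noise and receives an upward shift in cases; BMI (kg/m^2), age
#' (years) and weight (kg) are progressively noisier.
#'
#' @param n_coupled how many markers each covariate is coupled to.
#' @export
default_covariate_spec <- function(n_coupled = 5) {
  list(
    fbg    = list(n_coupled = n_coupled, noise_sd = 0.5, location = 5.5,
                  scale = 1.2, case_shift = 2.0),
    bmi    = list(n_coupled = n_coupled, noise_sd = 1.0, location = 24,
                  scale = 3.0, case_shift = 0),
    age    = list(n_coupled = n_coupled, noise_sd = 1.5, location = 50,
                  scale = 8.0, case_shift = 0),
    weight = list(n_coupled = n_coupled, noise_sd = 1.2, location = 65,
                  scale = 10.0, case_shift = 0)
  )
}

#' Generate a synthetic case/control cohort
#'
#' Base abundances are log-normal: each feature gets a latent mean drawn once
#' and per-sample Gaussian noise. Non-flat markers receive a latent mean
#' shift of `effect_size` in cases (sign alternating across markers); flat
#' markers are generated in pairs with identical marginals in both groups but
#' a within-pair correlation of `+flat_pair_cor` in cases and
#' `-flat_pair_cor` in controls. Planted edges add `coef * (source - mean)`
#' to their target's latent value in topological order. Structural zeros are
#' applied at rate `sparsity` and rows are closed to sum to one.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements `profile` (an
#'   [abundance_profile()]), `metadata` (sample_id, label, fbg, bmi, age,
#'   weight) and `truth` (marker indices, flat markers and pairs, effect
#'   signs, planted edges, covariate coupling weights).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  n <- cf$n_case + cf$n_control
  p <- cf$n_features
  y <- c(rep(1L, cf$n_case), rep(0L, cf$n_control))
  sample_ids <- sprintf("%s%03d", ifelse(y == 1, "case", "ctrl"),
                        c(seq_len(cf$n_case), seq_len(cf$n_control)))
  feature_ids <- sprintf("sp%03d", seq_len(p))

  # structural draws: shared by every cohort with the same structure_seed
  structure <- with_seed(stage_seed(cf$structure_seed, 911), {
    mu <- rnorm(p, mean = 0, sd = 1.5)
    markers <- sort(sample.int(p, cf$n_markers))
    n_flat <- round(cf$frac_flat_markers * cf$n_markers)
    n_flat <- n_flat - n_flat %% 2L  # flat markers come in pairs
    flat <- if (n_flat > 0) markers[seq_len(n_flat)] else integer(0)
    shifted <- setdiff(markers, flat)
    signs <- setNames(rep_len(c(1, -1), length(shifted)), shifted)
    weights <- lapply(cf$covariate_spec, function(sp) {
      idx <- markers[seq_len(min(sp$n_coupled, length(markers)))]
      setNames(runif(length(idx), 0.5, 1.5), idx)
    })
    list(mu = mu, markers = markers, flat = flat, shifted = shifted,
         signs = signs, weights = weights)
  })

  with_seed(cf$seed, {
    mu <- structure$mu
    markers <- structure$markers
    flat <- structure$flat
    shifted <- structure$shifted
    signs <- structure$signs

    latent <- matrix(rnorm(n * p), n, p)
    latent <- sweep(latent, 2L, mu, "+")

    # marginal shift for non-flat markers (cases only)
    for (j in shifted) {
      latent[y == 1, j] <- latent[y == 1, j] + signs[[as.character(j)]] *
        cf$effect_size
    }

    # flat pairs: same marginals, label-dependent correlation sign
    flat_pairs <- if (n_flat > 0) {
      matrix(flat, ncol = 2L, byrow = TRUE)
    } else matrix(integer(0), 0L, 2L)
    rho <- cf$flat_pair_cor
    for (r in seq_len(nrow(flat_pairs))) {
      a <- flat_pairs[r, 1L]; b <- flat_pairs[r, 2L]
      za <- latent[, a] - mu[a]
      e <- rnorm(n)
      zb <- ifelse(y == 1, rho, -rho) * za + sqrt(1 - rho^2) * e
      latent[, b] <- mu[b] + zb
    }

    # planted directed dependencies, applied in topological order
    if (!is.null(cf$planted_edges) && nrow(cf$planted_edges)) {
      ord <- topological_edge_order(cf$planted_edges, p)
      for (r in ord) {
        src <- cf$planted_edges$source[r]
        tgt <- cf$planted_edges$target[r]
        latent[, tgt] <- latent[, tgt] + cf$planted_edges$coef[r] *
          (latent[, src] - mean(latent[, src]))
      }
    }

    # covariates from coupled markers' latent values
    md <- data.frame(sample_id = sample_ids, label = y,
                     stringsAsFactors = FALSE)
    cov_weights <- list()
    for (cv in names(cf$covariate_spec)) {
      sp <- cf$covariate_spec[[cv]]
      w <- structure$weights[[cv]]
      idx <- as.integer(names(w))
      signal <- as.vector(latent[, idx, drop = FALSE] %*% w)
      signal <- (signal - mean(signal)) / sd(signal)
      value <- signal + rnorm(n, sd = sp$noise_sd)
      value <- sp$location + sp$scale * value + sp$case_shift * (y == 1)
      md[[cv]] <- value
      cov_weights[[cv]] <- setNames(w, feature_ids[idx])
    }

    # structural zeros, then compositional closure
    abund <- exp(latent)
    zero <- matrix(runif(n * p) < cf$sparsity, n, p)
    abund[zero] <- 0
    dead <- which(rowSums(abund) == 0)
    for (s in dead) {  # keep every sample observable
      j <- which.max(latent[s, ])
      abund[s, j] <- exp(latent[s, j])
    }
    abund <- abund / rowSums(abund)

    profile <- abundance_profile(abund, sample_ids, feature_ids)
    truth <- list(markers = markers,
                  marker_ids = feature_ids[markers],
                  flat_markers = flat,
                  flat_pairs = flat_pairs,
                  shifted_markers = shifted,
                  effect_signs = signs,
                  planted_edges = cf$planted_edges,
                  covariate_weights = cov_weights)
    structure(list(profile = profile, metadata = md, truth = truth,
                   config = cf),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d case / %d control, %d features, %d markers (%d flat)\n",
    x$config$n_case, x$config$n_control, x$config$n_features,
    x$config$n_markers, length(x$truth$flat_markers)))
  invisible(x)
}

# Order edge rows so every source precedes its targets; errors on cycles.
topological_edge_order <- function(edges, n_nodes) {
  g <- igraph::graph_from_edgelist(
    cbind(edges$source, edges$target), directed = TRUE)
  if (!igraph::is_dag(g)) {
    stop("planted edge list contains a cycle; a DAG is required",
         call. = FALSE)
  }
  node_order <- as.integer(igraph::topo_sort(g))
  pos <- match(edges$target, node_order)
  order(pos)
}

#' Simulate data from a planted directed network
#'
#' Root features are standard normal; every other feature is the
#' coefficient-weighted sum of its parents plus Gaussian noise with standard
#' deviation `noise_sd`, generated in topological order. Used as a fixture
#' with known ground truth for network-inference recovery tests.
#'
#' @param edges data.frame with columns `source`, `target` (1-based feature
#'   indices) and `coef`; must be a DAG. May have zero rows.
#' @param n_features number of features (columns).
#' @param n_samples number of samples (rows).
#' @param noise_sd noise standard deviation for non-root features.
#' @param seed integer seed.
#' @return numeric matrix `n_samples x n_features` with the edge list
#'   attached as attribute `"edges"`.
#' @export
generate_network_data <- function(edges, n_features, n_samples,
                                  noise_sd = 0.25, seed = 1) {
  n_features <- check_count(n_features, "n_features")
  n_samples <- check_count(n_samples, "n_samples")
  check_scalar_number(noise_sd, "noise_sd", min = 1e-12)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stopifnot(all(c("source", "target", "coef") %in% colnames(edges)))
    if (any(edges$source < 1 | edges$source > n_features |
            edges$target < 1 | edges$target > n_features)) {
      stop("edge endpoints must be in 1..n_features", call. = FALSE)
    }
  }
  with_seed(seed, {
    X <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
    if (nrow(edges)) {
      ord <- topological_edge_order(edges, n_features)
      # regenerate each target as parents %*% coef + noise, in topo order
      topo_targets <- unique(edges$target[ord])
      for (tgt in topo_targets) {
        rows <- edges[edges$target == tgt, , drop = FALSE]
        X[, tgt] <- as.vector(X[, rows$source, drop = FALSE] %*% rows$coef) +
          rnorm(n_samples, sd = noise_sd)
      }
    }
    colnames(X) <- sprintf("f%02d", seq_len(n_features))
    attr(X, "edges") <- edges
    X
  })
}
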