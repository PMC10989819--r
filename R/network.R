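# Directed feature-feature interaction inference: per-target tree-ensemble
# importances, row-variance refinement, top-N edge extraction, hub analysis
# and graph export.

#' Infer a directed adjacency matrix by per-target regression forests
#'
#' For each target feature (scaled to unit variance), a random regression
#' forest predicts it from all other features; entry `M[i, j]` is feature
#' i's total variance-reduction importance in the forest for target j,
#' normalized so each target column sums to one. Candidate features per
#' split default to the square root of the number of predictors. The
#' diagonal is structurally zero; a constant target yields an all-zero
#' column with a warning.
#'
#' @param X numeric sample-by-feature matrix (at least 3 features and 10
#'   samples; column names used as feature ids).
#' @param n_trees trees per target forest.
#' @param candidate_split_fraction fraction of the `p - 1` predictors tried
#'   at each split; default `sqrt(p - 1) / (p - 1)`.
#' @param seed integer seed (fanned out per target).
#' @return a list of class `adjacency` with `feature_ids` and the matrix
#'   `M`.
#' @export
infer_adjacency <- function(X, n_trees = 1000L,
                            candidate_split_fraction = NULL, seed = 1L) {
  check_finite_matrix(X)
  p <- ncol(X)
  if (p < 3L) stop("need at least 3 features", call. = FALSE)
  if (nrow(X) < 10L) stop("need at least 10 samples", call. = FALSE)
  n_trees <- check_count(n_trees, "n_trees")
  ids <- feature_names(X)
  colnames(X) <- ids
  if (is.null(candidate_split_fraction)) {
    candidate_split_fraction <- sqrt(p - 1) / (p - 1)
  }
  check_scalar_number(candidate_split_fraction, "candidate_split_fraction",
                      1e-9, 1)
  mtry <- max(1L, round(candidate_split_fraction * (p - 1)))
  M <- matrix(0, p, p, dimnames = list(ids, ids))
  for (j in seq_len(p)) {
    yj <- X[, j]
    if (sd(yj) == 0) {
      warning("target feature '", ids[j],
              "' is constant; its column is set to zero", call. = FALSE)
      next
    }
    yj <- (yj - mean(yj)) / sd(yj)
    rf <- ranger::ranger(x = X[, -j, drop = FALSE], y = yj,
                         num.trees = n_trees, mtry = mtry,
                         importance = "impurity",
                         seed = as.integer(stage_seed(seed, j)),
                         num.threads = 1L)
    imp <- pmax(rf$variable.importance, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
    M[names(imp), j] <- imp
  }
  diag(M) <- 0
  structure(list(feature_ids = ids, M = M), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d nodes, %d positive entries\n",
              length(x$feature_ids), sum(x$M > 0)))
  invisible(x)
}

#' Row-variance refinement of an adjacency matrix
#'
#' Multiplies each row of the adjacency matrix elementwise by the population
#' variance of that row's off-diagonal entries. Rows belonging to putative
#' hub nodes — many strong outgoing links next to weak ones — have elevated
#' variance and are amplified; a row with all off-diagonal entries equal has
#' zero variance and maps to zero. The diagonal stays zero. The inverse
#' convention (dividing by the row variance) is available behind
#' `mode = "divide"` but is not the default.
#'
#' @param adj an [infer_adjacency()] result (or any `adjacency`).
#' @param mode `"multiply"` (default) or `"divide"`; division treats
#'   zero-variance rows as zero rather than dividing by zero.
#' @return the refined `adjacency`.
#' @export
refine_adjacency <- function(adj, mode = c("multiply", "divide")) {
  stopifnot(inherits(adj, "adjacency"))
  mode <- match.arg(mode)
  M <- adj$M
  p <- nrow(M)
  out <- M
  for (i in seq_len(p)) {
    row <- M[i, -i]
    v <- mean((row - mean(row))^2)  # population variance
    out[i, ] <- if (mode == "multiply") {
      M[i, ] * v
    } else if (v > 0) M[i, ] / v else 0
  }
  diag(out) <- 0
  structure(list(feature_ids = adj$feature_ids, M = out),
            class = "adjacency")
}

#' Extract the strongest directed edges
#'
#' Returns the `n` largest positive off-diagonal entries as an edge list in
#' descending weight order; ties are broken lexicographically by (source,
#' target) id. If fewer positive entries exist, all of them are returned;
#' an all-zero matrix yields an empty edge list with a warning.
#'
#' @param adj an `adjacency`.
#' @param n maximum number of edges (default 100).
#' @return a data.frame of class `edge_list` with columns `source`,
#'   `target`, `weight`, carrying per-node degree tables as attribute
#'   `"degrees"` (directed in/out degree and the number of distinct
#'   partners).
#' @export
top_edges <- function(adj, n = 100L) {
  stopifnot(inherits(adj, "adjacency"))
  n <- check_count(n, "n")
  M <- adj$M
  ids <- adj$feature_ids
  pos <- which(M > 0, arr.ind = TRUE)
  if (!nrow(pos)) {
    warning("adjacency matrix has no positive entries; empty edge list",
            call. = FALSE)
    el <- data.frame(source = character(0), target = character(0),
                     weight = numeric(0), stringsAsFactors = FALSE)
    attr(el, "degrees") <- node_degrees(el, ids)
    class(el) <- c("edge_list", "data.frame")
    return(el)
  }
  el <- data.frame(source = ids[pos[, 1L]], target = ids[pos[, 2L]],
                   weight = M[pos], stringsAsFactors = FALSE)
  el <- el[order(-el$weight, el$source, el$target), , drop = FALSE]
  el <- el[seq_len(min(n, nrow(el))), , drop = FALSE]
  rownames(el) <- NULL
  attr(el, "degrees") <- node_degrees(el, ids)
  class(el) <- c("edge_list", "data.frame")
  el
}

# Per-node degrees over an edge list: directed in/out degree plus the
# number of distinct partners (reciprocal edges count one partner).
node_degrees <- function(edges, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(edges$source, edges$target)))
  out_deg <- table(factor(edges$source, levels = ids))
  in_deg <- table(factor(edges$target, levels = ids))
  partners <- vapply(ids, function(v) {
    length(unique(c(edges$target[edges$source == v],
                    edges$source[edges$target == v])))
  }, integer(1L))
  data.frame(node = ids, out_degree = as.integer(out_deg),
             in_degree = as.integer(in_deg),
             partners = as.integer(partners),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("<edge_list> %d directed edges\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Report hub nodes by connection count
#'
#' A node's connectivity is its number of distinct partners (a reciprocal
#' pair of edges counts as one connection), matching the reading of a
#' species "connecting with" another.
#'
#' @param edges an [top_edges()] edge list.
#' @param thresholds integer vector of minimum partner counts.
#' @return named list (one entry per threshold) of data.frames with `node`
#'   and `partners`, ordered by decreasing connectivity.
#' @export
hub_report <- function(edges, thresholds = c(5L, 10L)) {
  deg <- attr(edges, "degrees")
  if (is.null(deg)) deg <- node_degrees(edges)
  out <- lapply(thresholds, function(th) {
    d <- deg[deg$partners >= th, c("node", "partners"), drop = FALSE]
    d <- d[order(-d$partners, d$node), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- paste0("min_", thresholds)
  out
}

#' Export an edge list as TSV or GraphML
#'
#' TSV has columns `source`, `target`, `weight` with 12 significant digits;
#' GraphML is a directed graph with a `weight` edge attribute and a
#' `partners` node attribute (distinct-partner degree).
#'
#' @param edges an [top_edges()] edge list.
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
export_graph <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(edges, "edge_list"))
  if (format == "tsv") {
    out <- data.frame(source = edges$source, target = edges$target,
                      weight = sprintf("%.12g", edges$weight),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    deg <- attr(edges, "degrees")
    nodes <- if (is.null(deg)) {
      data.frame(name = sort(unique(c(edges$source, edges$target))),
                 partners = NA_integer_)
    } else data.frame(name = deg$node, partners = deg$partners)
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges)[, c("source", "target", "weight")],
      directed = TRUE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
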