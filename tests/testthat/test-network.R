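test_that("a planted chain dominates its target's adjacency column", {
  ch <- data.frame(source = 1L, target = 2L, coef = 1)
  X <- generate_network_data(ch, n_features = 4, n_samples = 1000,
                             noise_sd = 0.1, seed = 1)
  adj <- infer_adjacency(X, n_trees = 300, seed = 1)
  col2 <- adj$M[, 2]
  expect_identical(names(which.max(col2)), "f01")
  expect_equal(unname(diag(adj$M)), rep(0, 4))
  # columns are normalized to sum one (or zero)
  sums <- colSums(adj$M)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
})

test_that("constant targets produce zero columns with a warning", {
  set.seed(2)
  X <- cbind(a = rnorm(30), b = rnorm(30), c = rep(1, 30))
  expect_warning(adj <- infer_adjacency(X, n_trees = 50, seed = 1),
                 "constant")
  expect_equal(unname(adj$M[, "c"]), rep(0, 3))
})

test_that("row-variance refinement matches hand evaluation", {
  M <- matrix(c(0, 0.2, 0.4,
                0.3, 0, 0.3,
                0.1, 0.5, 0), 3L, 3L, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  adj <- structure(list(feature_ids = letters[1:3], M = M),
                   class = "adjacency")
  ref <- refine_adjacency(adj)
  # row a: off-diagonal (0.2, 0.4), population variance 0.01
  expect_equal(unname(ref$M[1, ]), c(0, 0.002, 0.004), tolerance = 1e-12)
  # row b: equal off-diagonal entries -> zero variance -> zero row
  expect_equal(unname(ref$M[2, ]), c(0, 0, 0))
  # scaling a row by c scales its refined row by c^3
  M3 <- M; M3[3, ] <- 2 * M[3, ]
  ref3 <- refine_adjacency(structure(list(feature_ids = letters[1:3],
                                          M = M3), class = "adjacency"))
  expect_equal(unname(ref3$M[3, ]), unname(8 * ref$M[3, ]),
               tolerance = 1e-12)
})

test_that("top_edges ranks, truncates and breaks ties lexicographically", {
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M["a", "b"] <- 0.5; M["b", "c"] <- 0.5; M["a", "c"] <- 0.9
  M["c", "a"] <- 0.1; M["c", "b"] <- 0.05
  adj <- structure(list(feature_ids = c("a", "b", "c"), M = M),
                   class = "adjacency")
  el <- top_edges(adj, n = 100)
  expect_equal(nrow(el), 5)
  expect_equal(el$weight[1], 0.9)
  # tied 0.5 edges: (a,b) before (b,c)
  expect_identical(el$source[2:3], c("a", "b"))
  el2 <- top_edges(adj, n = 2)
  expect_equal(nrow(el2), 2)
  zero <- structure(list(feature_ids = c("a", "b", "c"),
                         M = matrix(0, 3, 3)), class = "adjacency")
  expect_warning(e0 <- top_edges(zero), "no positive")
  expect_equal(nrow(e0), 0)
})

test_that("hub report counts distinct partners, not directed multiplicity", {
  el <- data.frame(
    source = c("h", "h", "h", "x", "y", "z", "p", "q", "r", "s"),
    target = c("x", "y", "z", "h", "h", "h", "h", "p", "q", "r"),
    weight = seq(1, 0.1, length.out = 10), stringsAsFactors = FALSE)
  class(el) <- c("edge_list", "data.frame")
  rep5 <- hub_report(el, thresholds = 5)
  # h: partners x,y,z (reciprocal) + p = 4 distinct -> excluded at 5
  expect_false("h" %in% rep5$min_5$node)
  el2 <- data.frame(source = rep("h", 6), target = paste0("t", 1:6),
                    weight = 1:6, stringsAsFactors = FALSE)
  class(el2) <- c("edge_list", "data.frame")
  rep2 <- hub_report(el2, thresholds = c(5, 10))
  expect_identical(rep2$min_5$node, "h")
  expect_identical(rep2$min_5$partners, 6L)
  expect_equal(nrow(rep2$min_10), 0)
  empty <- el2[0, ]; class(empty) <- c("edge_list", "data.frame")
  expect_equal(nrow(hub_report(empty, 5)$min_5), 0)
})

test_that("graph export round-trips through TSV and GraphML", {
  M <- matrix(runif(25), 5, 5,
              dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  diag(M) <- 0
  adj <- structure(list(feature_ids = paste0("n", 1:5), M = M),
                   class = "adjacency")
  el <- top_edges(adj, 10)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(el, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(back$weight, el$weight, tolerance = 1e-9)
  expect_identical(back$source, el$source)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(el, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::is_directed(g))
  eg <- igraph::as_data_frame(g)
  eg <- eg[order(-eg$weight), ]
  expect_equal(eg$weight, el$weight, tolerance = 1e-9)
})
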