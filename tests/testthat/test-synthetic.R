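test_that("generated cohorts are closed, non-negative and reproducible", {
  cc <- cohort_config(n_case = 30, n_control = 30, n_features = 50,
                      n_markers = 8, seed = 3)
  co <- generate_cohort(cc)
  expect_true(all(co$profile$values >= 0))
  expect_equal(unname(rowSums(co$profile$values)), rep(1, 60),
               tolerance = 1e-9)
  co2 <- generate_cohort(cc)
  expect_identical(co$profile$values, co2$profile$values)
  expect_identical(co$metadata, co2$metadata)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n_features = 10, n_markers = 20), "n_markers")
  expect_error(cohort_config(frac_flat_markers = 1.5), "frac_flat_markers")
})

test_that("non-flat markers shift group means with the planted sign", {
  co <- generate_cohort(cohort_config(n_case = 100, n_control = 100,
                                      n_features = 200, n_markers = 20,
                                      effect_size = 1, seed = 1))
  X <- co$profile$values
  y <- co$metadata$label
  correct <- vapply(co$truth$shifted_markers, function(j) {
    dm <- mean(X[y == 1, j]) - mean(X[y == 0, j])
    sign(dm) == co$truth$effect_signs[[as.character(j)]]
  }, logical(1))
  expect_gte(sum(correct), 18L)
})

test_that("flat markers have matched marginals but label-linked pairing", {
  co <- generate_cohort(cohort_config(n_case = 150, n_control = 150,
                                      n_features = 60, n_markers = 10,
                                      frac_flat_markers = 1, seed = 5))
  y <- co$metadata$label
  X <- co$profile$values
  for (j in co$truth$flat_markers) {
    p <- suppressWarnings(
      stats::wilcox.test(X[y == 1, j], X[y == 0, j])$p.value)
    expect_gt(p, 0.01)
  }
  # within each pair the correlation sign flips between groups; closure and
  # structural zeros attenuate it, so check the log scale on samples where
  # both members are observed
  for (r in seq_len(nrow(co$truth$flat_pairs))) {
    a <- co$truth$flat_pairs[r, 1]; b <- co$truth$flat_pairs[r, 2]
    both <- X[, a] > 0 & X[, b] > 0
    rc <- cor(log(X[y == 1 & both, a]), log(X[y == 1 & both, b]),
              method = "spearman")
    rt <- cor(log(X[y == 0 & both, a]), log(X[y == 0 & both, b]),
              method = "spearman")
    expect_gt(rc, 0.3)
    expect_lt(rt, -0.3)
  }
})

test_that("fbg covariate is shifted upward in cases", {
  co <- generate_cohort(cohort_config(seed = 2))
  md <- co$metadata
  expect_gt(mean(md$fbg[md$label == 1]), mean(md$fbg[md$label == 0]))
})

test_that("network data generator honors planted structure", {
  # no edges: independent columns
  X0 <- generate_network_data(data.frame(source = integer(0),
                                         target = integer(0),
                                         coef = numeric(0)),
                              n_features = 3, n_samples = 2000, seed = 1)
  cors <- cor(X0)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.2)

  # chain 1 -> 2 -> 3, coefficient 1, small noise: corr approx 1/sqrt(1+s^2)
  ch <- data.frame(source = c(1L, 2L), target = c(2L, 3L), coef = 1)
  X1 <- generate_network_data(ch, n_features = 3, n_samples = 1000,
                              noise_sd = 0.1, seed = 2)
  expect_gt(cor(X1[, 1], X1[, 2]), 0.9)
  expect_gt(cor(X1[, 2], X1[, 3]), 0.9)

  cyc <- data.frame(source = c(1L, 2L), target = c(2L, 1L), coef = 1)
  expect_error(generate_network_data(cyc, n_features = 2, n_samples = 10),
               "cycle")
})
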