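test_that("quantile boundaries use linear interpolation; assignment is total", {
  qb <- quantile_bins(1:8)
  expect_equal(qb$boundaries, c(2.75, 4.5, 6.25))
  # a value equal to an interior boundary belongs to the upper bin
  expect_equal(qb$assignments[5], 3L)  # value 5 -> [4.5, 6.25)
  v45 <- quantile_bins(c(1:8, 4.5))
  expect_equal(v45$assignments[9], 3L)
  expect_false(any(is.na(qb$assignments)))
  expect_identical(sort(unique(qb$assignments)), 1:4)

  four <- quantile_bins(c(10, 20, 30, 40))
  expect_equal(as.integer(table(four$assignments)), rep(1L, 4))
  expect_error(quantile_bins(rep(2, 10)), "identical")
})

test_that("binned means are plain arithmetic over bin members", {
  m <- matrix(c(0.1, 0.9,
                0.3, 0.7,
                0.5, 0.5,
                0.7, 0.3), 4L, 2L, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("f1", "f2")))
  prof <- abundance_profile(m)
  bm <- binned_means(prof, c(1L, 1L, 2L, 2L))
  expect_equal(unname(bm["f1", ]), c(0.2, 0.6))
  expect_equal(unname(bm["f2", ]), c(0.8, 0.4))
  expect_error(binned_means(prof, c(1L, 1L, 3L, 3L)), "Q2 is empty")
})

test_that("min-max row normalization maps to [0,1] and handles constants", {
  m <- rbind(a = c(2, 4, 6, 8), b = c(5, 5, 5, 5))
  expect_warning(nm <- minmax_rows(m), "constant")
  expect_equal(unname(nm["a", ]), c(0, 1, 2, 3) / 3)
  expect_equal(unname(nm["b", ]), rep(0, 4))
  # invariance under positive affine transform
  expect_equal(minmax_rows(rbind(10 + 5 * m["a", , drop = FALSE])),
               minmax_rows(m["a", , drop = FALSE]) * 1, ignore_attr = TRUE)
})

test_that("kruskal-wallis per feature matches the rank formula and classes", {
  prof <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f1"))
  out <- kruskal_wallis_per_feature(prof, c(0, 0, 1, 1))
  expect_equal(out$H, 2.4, tolerance = 1e-12)
  expect_identical(out$class, "not-significant")

  # strong shift: significant, higher in the case group
  set.seed(9)
  strong <- matrix(c(rnorm(20, 0), rnorm(20, 5)), 40, 1,
                   dimnames = list(NULL, "up"))
  res <- kruskal_wallis_per_feature(strong, rep(c(0, 1), each = 20))
  expect_identical(res$class, "higher-in-case")

  const <- matrix(1, 10, 1, dimnames = list(NULL, "c1"))
  rc <- kruskal_wallis_per_feature(const, rep(c(0, 1), 5))
  expect_equal(rc$H, 0)
  expect_equal(rc$p, 1)
  expect_error(kruskal_wallis_per_feature(strong, c(1, rep(0, 39))),
               "at least 2")
})

test_that("p-values shrink as the rank separation grows", {
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  labs <- rep(c(0, 1), each = 4)
  weak <- matrix(base[c(1, 3, 5, 7, 2, 4, 6, 8)], 8, 1)
  strongm <- matrix(base, 8, 1)
  pw <- kruskal_wallis_per_feature(weak, labs)$p
  ps <- kruskal_wallis_per_feature(strongm, labs)$p
  expect_lt(ps, pw)
})

test_that("the full stratification pipeline tracks a label-coupled covariate", {
  co <- generate_cohort(cohort_config(n_case = 80, n_control = 80,
                                      n_features = 60, n_markers = 10,
                                      effect_size = 1.5, seed = 6))
  strat <- stratify_profile(
    subset_features(co$profile, co$truth$marker_ids),
    co$metadata$fbg, co$metadata$label)
  expect_true(all(strat$matrix >= 0 & strat$matrix <= 1))
  expect_equal(ncol(strat$matrix), 4)
  expect_true(all(diff(strat$boundaries) > 0))
  # case-enriched markers should peak in the top fbg quartile more often
  # than not: fbg is shifted upward in cases and coupled to the markers
  up <- names(co$truth$effect_signs)[unlist(co$truth$effect_signs) > 0]
  up_ids <- co$profile$feature_ids[as.integer(up)]
  peak_bin <- apply(strat$matrix[up_ids, , drop = FALSE], 1, which.max)
  expect_gte(mean(peak_bin >= 3), 0.6)
})
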