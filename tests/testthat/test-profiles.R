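test_that("read/write round trip is the identity in either orientation", {
  prof <- toy_profile()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(prof, tsv)
  back <- read_abundance_table(tsv)
  expect_identical(back$sample_ids, prof$sample_ids)
  expect_identical(back$feature_ids, prof$feature_ids)
  expect_equal(back$values, prof$values, tolerance = 1e-12)

  write_abundance_table(prof, tsv, orientation = "features_as_rows")
  back2 <- read_abundance_table(tsv, orientation = "features_as_rows")
  expect_equal(back2$values, prof$values, tolerance = 1e-12)
})

test_that("reader rejects malformed tables with located errors", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfA\tfB", "s1\t0.5\t-0.1", "s2\t0.4\t0.6"), tsv)
  expect_error(read_abundance_table(tsv), "fB")

  writeLines(c("sample_id\tfA\tfB", "s1\t0.5\toops", "s2\t0.4\t0.6"), tsv)
  expect_error(read_abundance_table(tsv), "non-numeric")

  writeLines(c("sample_id\tfA\tfB", "s1\t0.5\t0.5", "s1\t0.4\t0.6"), tsv)
  expect_error(read_abundance_table(tsv), "duplicate sample id")
})

test_that("percentage-scale tables are detected and stored as fractions", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfA\tfB", "s1\t60\t40", "s2\t25\t75"), tsv)
  expect_message(prof <- read_abundance_table(tsv), "percentage")
  expect_equal(unname(rowSums(prof$values)), c(1, 1))
})

test_that("renormalize scales rows to one, is idempotent, rejects zero rows", {
  m <- matrix(c(2, 2, 4, 1, 1, 2), 2L, 3L, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  prof <- renormalize(abundance_profile(m))
  expect_equal(unname(prof$values[1L, ]), c(0.25, 0.25, 0.5))
  again <- renormalize(prof)
  expect_equal(again$values, prof$values, tolerance = 1e-12)
  expect_error(abundance_profile(matrix(c(0, 0, 0, 1, 2, 3), 2L, 3L,
                                        byrow = TRUE,
                                        dimnames = list(c("z", "b"), NULL)),
                                 feature_ids = c("f1", "f2", "f3")),
               "all-zero")
})

test_that("prevalence filter drops rare features and keeps order", {
  m <- matrix(c(0.5, 0.0, 0.5,
                0.4, 0.0, 0.6,
                0.3, 0.7, 0.0), 3L, 3L, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("f1", "f2", "f3")))
  prof <- abundance_profile(m)
  filtered <- filter_min_prevalence(prof, 2L)
  expect_identical(filtered$feature_ids, c("f1", "f3"))
  expect_identical(filter_min_prevalence(prof, 1L)$feature_ids,
                   prof$feature_ids)
  expect_error(filter_min_prevalence(prof, 4L), "no feature")
})

test_that("align_cohort inner-joins on sample id in profile order", {
  m <- matrix(runif(9, 0.1, 1), 3L, 3L,
              dimnames = list(c("a", "b", "c"), paste0("f", 1:3)))
  prof <- abundance_profile(m)
  md <- data.frame(sample_id = c("b", "c", "d"), label = c(1L, 0L, 1L))
  expect_message(paired <- align_cohort(prof, md), "dropped 2")
  expect_identical(paired$profile$sample_ids, c("b", "c"))
  expect_identical(paired$metadata$sample_id, c("b", "c"))

  md_all <- data.frame(sample_id = c("c", "a", "b"), label = c(0L, 1L, 1L))
  paired2 <- align_cohort(prof, md_all)
  expect_identical(paired2$profile$sample_ids, c("a", "b", "c"))

  md_none <- data.frame(sample_id = c("x", "y"), label = c(0L, 1L))
  expect_error(align_cohort(prof, md_none), "no sample ids")
})

test_that("metadata validation enforces labels and numeric covariates", {
  md <- data.frame(sample_id = c("a", "b"), label = c(0L, 2L))
  expect_error(validate_metadata(md), "labels")
  md2 <- data.frame(sample_id = c("a", "b"), label = c(0L, 1L),
                    fbg = c(5.1, NA), note = c("x", "y"))
  expect_message(out <- validate_metadata(md2), "ignoring")
  expect_false("note" %in% colnames(out))
})
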