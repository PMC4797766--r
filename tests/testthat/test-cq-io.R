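test_that("wide Cq tables round-trip through write and read", {
  m <- random_cq(8, 4, seed = 3)
  meta <- data.frame(condition = rep(c("healthy", "inflammation"), 4),
                     animal_id = rep(c("a1", "a2"), each = 4))
  cq <- cq_matrix(m, scale = "corrected", sample_meta = meta)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(cq, path)
  back <- read_cq_table(path)
  expect_s3_class(back, "cq_matrix")
  expect_equal(cq_scale(back), "corrected")
  expect_identical(rownames(back), rownames(cq))
  expect_identical(colnames(back), colnames(cq))
  expect_equal(as.matrix(back), as.matrix(cq), tolerance = 1e-6)
  expect_equal(sample_meta(back)$condition, meta$condition)
})

test_that("long layout yields replicate sets that collapse to a matrix", {
  reps <- make_replicates(c("s1", "s2"), c("gA", "gB"),
                          function(s, g, r) 20 + 5 * (g == "gB") + 0.1 * r)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(reps, path, row.names = FALSE, quote = FALSE)
  parsed <- read_cq_table(path)
  expect_s3_class(parsed, "cq_replicates")
  expect_equal(nrow(parsed), 12)  # 2 samples x 2 genes x 3 replicates
  mat <- collapse_replicates(parsed)
  expect_equal(dim(mat), c(2L, 2L))
  expect_equal(unname(as.matrix(mat)[1, ]), c(20.2, 25.2))
})

test_that("replicate collapsing averages good sets and flags noisy ones", {
  reps <- data.frame(
    sample_id = c(rep("s1", 3), rep("s2", 3), "s3"),
    gene = "gA",
    replicate = c(1:3, 1:3, 1),
    cq = c(20.1, 20.2, 20.3, 20.0, 20.0, 21.5, 25.0))
  mat <- collapse_replicates(reps, sd_threshold = 0.5)
  expect_equal(as.matrix(mat)["s1", "gA"], 20.2)
  expect_true(is.na(as.matrix(mat)["s2", "gA"]))  # SD 0.866 >= 0.5
  expect_equal(as.matrix(mat)["s3", "gA"], 25.0)  # singleton kept, SD 0
  flagged <- attr(mat, "flagged")
  expect_equal(flagged$sample_id, "s2")
  expect_equal(flagged$sd, sd1(c(20.0, 20.0, 21.5)), tolerance = 1e-12)
})

test_that("collapsing is invariant to replicate order and monotone in the gate", {
  set.seed(11)
  reps <- make_replicates(paste0("s", 1:6), paste0("g", 1:3),
                          function(s, g, r) 24 + rnorm(1, sd = 0.4))
  shuffled <- reps[sample(nrow(reps)), ]
  a <- collapse_replicates(reps)
  b <- collapse_replicates(shuffled)
  expect_equal(as.matrix(a), as.matrix(b)[rownames(a), colnames(a)])

  thresholds <- c(0.1, 0.3, 0.5, 1)
  n_flagged <- vapply(thresholds, function(th)
    nrow(attr(collapse_replicates(reps, sd_threshold = th), "flagged")),
    numeric(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("malformed Cq tables are rejected with row-level errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,gA\n", path)
  expect_error(read_cq_table(path), "no samples")

  writeLines(c("sample_id,gene,replicate,cq",
               "s1,gA,1,20.0", "s1,gA,1,20.1"), path)
  expect_error(read_cq_table(path), "duplicate")

  writeLines(c("sample_id,gA", "s1,oops"), path)
  expect_error(read_cq_table(path), "non-numeric")

  writeLines(c("sample_id,gA", "s1,46.2"), path)
  expect_error(read_cq_table(path), "outside")
})

test_that("plate-control QC applies the 0.5-cycle gate", {
  passing <- plate_control_qc(c(19.67, 20.0, 20.33))  # SD 0.33
  expect_equal(passing$sd, 0.33, tolerance = 1e-12)
  expect_true(passing$pass)
  expect_true(plate_control_qc(rep(21.4, 5))$pass)
  failing <- plate_control_qc(c(20.0, 21.5))
  expect_equal(failing$sd, sd1(c(20.0, 21.5)), tolerance = 1e-12)
  expect_false(failing$pass)
  expect_error(plate_control_qc(20.0), "insufficient controls")
})

test_that("subsampling is reproducible and preserves genes and order", {
  cq <- cq_matrix(random_cq(60, 13, seed = 5))
  expect_identical(as.matrix(subsample_cq(cq, 60, seed = 1)), as.matrix(cq))
  a <- subsample_cq(cq, 30, seed = 17)
  b <- subsample_cq(cq, 30, seed = 17)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_equal(dim(a), c(30L, 13L))
  expect_identical(colnames(a), colnames(cq))
  # kept rows appear in their original relative order
  expect_false(is.unsorted(match(rownames(a), rownames(cq))))
  expect_error(subsample_cq(cq, 61, seed = 1), "cannot subsample")
})

test_that("incomplete samples are dropped with a warning naming them", {
  m <- random_cq(5, 3, seed = 9)
  m[2, 1] <- NA
  cq <- cq_matrix(m)
  expect_warning(out <- drop_incomplete_samples(cq), "s2")
  expect_equal(nrow(out), 4)
  expect_false(anyNA(as.matrix(out)))
})
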