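test_that("feature tables round-trip through delimited text at full precision", {
  set.seed(42)
  v <- matrix(exp(rnorm(12, 10, 4)), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"),
                              make_bucket_id(c(1.1, 2.3, 3.5, 4.7),
                                             c(100.1, 200.2, 300.3, 400.4))))
  ft <- feature_table(v)
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_feature_table(ft, path)
    back <- read_feature_table(path)
    expect_identical(back$values, ft$values)
    expect_identical(back$bucket_meta$rt, ft$bucket_meta$rt)
    # canonical formatting: a second write is byte-identical
    path2 <- withr::local_tempfile(fileext = ext)
    write_feature_table(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("malformed tables produce descriptive parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,b1,b1", "s1,1,2"), path)
  expect_error(read_feature_table(path), "duplicate bucket ids.*b1")

  writeLines(c("sample_id,b1,b2", "s1,1,2", "s1,3,4"), path)
  expect_error(read_feature_table(path), "duplicate sample ids.*s1")

  writeLines(c("sample_id,b1,b2", "s1,1,oops", "s2,3,4"), path)
  expect_error(read_feature_table(path), "row 1, column 'b2'")

  writeLines(c("sample_id,b1,b2", "s1,1", "s2,3,4"), path)
  expect_error(read_feature_table(path), "malformed feature table")

  m <- matrix(c(1, -2), 1, dimnames = list("s1", c("a", "b")))
  expect_error(feature_table(m), "non-negative")
})

test_that("bucketing follows the half-open floor-index grid", {
  params <- bucketing_params()
  # below the RT range: dropped
  pk <- peak_list(rt = c(0.4, 1.00, 1.05, 1.10),
                  mz = c(100.000, 100.000, 100.002, 100.002),
                  intensity = c(9, 5, 3, 2))
  row <- bucket_peaks(pk, params, analysis_id = "a1")
  md <- row$bucket_meta
  expect_equal(sum(row$values), 5 + 3 + 2)        # 0.4 min peak dropped
  # rt 1.00 and 1.05 share the cell [0.8, 1.1); rt 1.10 starts the next one
  expect_equal(ncol(row$values), 2L)
  expect_equal(sort(unname(row$values[1, ])), c(2, 8))
  expect_equal(sort(md$rt), c(0.95, 1.25))
  expect_equal(unique(md$mz), 60.5 + (7900 + 0.5) * 0.005)

  # a peak exactly on a cell edge belongs to the upper cell
  edge <- bucket_peaks(peak_list(0.8, 100, 1), params)
  expect_equal(edge$bucket_meta$rt, 0.95)

  # out-of-range peaks only: empty row with a warning, not an error
  expect_warning(empty <- bucket_peaks(peak_list(25, 100, 1), params),
                 "no peaks inside")
  expect_equal(ncol(empty$values), 0L)
})

test_that("grid assignment matches a brute-force interval scan", {
  params <- bucketing_params()
  set.seed(7)
  rt <- runif(300, 0.5, 20)
  mz <- runif(300, 60.5, 850.5)
  # include exact representable edges among the probes
  rt[1:5] <- 0.5 + (0:4) * 0.3
  mz[1:5] <- 60.5 + (0:4) * 0.005
  pk <- peak_list(rt, mz, intensity = rep(1, 300))
  row <- bucket_peaks(pk, params)
  expect_equal(sum(row$values), 300)  # conservation of in-range intensity
  idx_rt <- vapply(rt, grid_scan_oracle, integer(1),
                   lo = 0.5, hi = 20, delta = 0.3)
  idx_mz <- vapply(mz, grid_scan_oracle, integer(1),
                   lo = 60.5, hi = 850.5, delta = 0.005)
  expected <- rowsum(rep(1, 300), paste(idx_rt, idx_mz))
  expect_equal(sort(unname(row$values[1, ])),
               sort(unname(expected[, 1])))
})

test_that("bucketing a batch materializes the sparse union of cells", {
  pks <- list(a1 = peak_list(c(1.0, 5.0), c(100, 200), c(2, 3)),
              a2 = peak_list(5.0, 200, 7))
  tab <- bucket_analyses(pks)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(unname(tab$values["a1", ]), c(2, 3))
  expect_equal(sum(tab$values["a2", ] == 0), 1L)  # absent bucket zero-filled
})

test_that("block combination aligns rows and namespaces columns", {
  set.seed(1)
  mk <- function(ids, p, mode) {
    v <- matrix(runif(length(ids) * p), length(ids),
                dimnames = list(ids, make_bucket_id(seq_len(p), 100 + seq_len(p),
                                                    mode = mode)))
    feature_table(v)
  }
  b1 <- mk(c("s1", "s2", "s3"), 4, "ESI+")
  b2 <- mk(c("s3", "s1", "s2"), 3, "ESI-")
  b3 <- mk(c("s2", "s3", "s1"), 5, "ESI-acid")
  all_ <- combine_blocks(list(b1, b2, b3))
  expect_equal(ncol(all_$values), 4 + 3 + 5)
  expect_identical(sample_ids(all_), sample_ids(b1))
  # permuted row order gives the identical combined table
  expect_equal(all_$values["s2", ], combine_blocks(list(b1, b3, b2))$values[
    "s2", c(bucket_ids(b1), bucket_ids(b2), bucket_ids(b3))])

  b_missing <- subset_table(b2, samples = c("s1", "s2"))
  expect_error(combine_blocks(list(b1, b_missing)), "s3")
})
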