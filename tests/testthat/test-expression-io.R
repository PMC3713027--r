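test_that("TSV round-trip preserves shape, ids and values exactly", {
  v <- matrix(c(1.25, 2.5, 3.75, 4, 5.125, 6, 7, 8.0625, 9, 10, 11, 12),
              nrow = 3, dimnames = list(c("sA", "sB", "sC"),
                                        c("p1", "p2", "p3", "p4")))
  m <- ExpressionMatrix(v)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  m2 <- load_expression_matrix(path)
  expect_identical(dim(m2$values), c(3L, 4L))
  expect_identical(rownames(m2$values), rownames(v))
  expect_identical(colnames(m2$values), colnames(v))
  expect_identical(m2$values, v)   # bitwise
})

test_that("duplicate and malformed inputs are hard errors naming the culprit", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tp1\tp1", "s1\t1\t2", "s2\t3\t4"), path)
  expect_error(load_expression_matrix(path), "p1")
  writeLines(c("sample_id\tp1\tp2", "s1\t1\tabc", "s2\t3\t4"), path)
  expect_error(load_expression_matrix(path), "s1.*p2|p2.*s1")
  expect_error(ExpressionMatrix(matrix(1:4, 2,
    dimnames = list(c("a", "a"), c("x", "y")))), "duplicate sample")
})

test_that("filter_probesets keeps single-locus non-control probes and reports counts", {
  v <- matrix(rnorm(10), 2, 5,
              dimnames = list(c("s1", "s2"),
                              c("AFFX-c1", "amb1", "u1", "u2", "u3")))
  m <- ExpressionMatrix(v)
  map <- data.frame(probe_id = c("amb1", "amb1", "u1", "u2", "u3"),
                    gene_id = c("gA", "gB", "gC", "gD", "gE"))
  res <- filter_probesets(m, map)
  expect_identical(probe_ids(res$matrix), c("u1", "u2", "u3"))
  expect_equal(res$report$removed_controls, 1)
  expect_equal(res$report$removed_ambiguous, 1)
  # idempotence
  res2 <- filter_probesets(res$matrix, map)
  expect_identical(res2$matrix$values, res$matrix$values)
  expect_equal(res2$report$removed_controls + res2$report$removed_ambiguous, 0)
  # all informative -> unchanged
  m3 <- ExpressionMatrix(v[, 3:5])
  res3 <- filter_probesets(m3, map)
  expect_identical(res3$matrix$values, m3$values)
  # nothing informative -> error
  expect_error(filter_probesets(ExpressionMatrix(v[, 1, drop = FALSE]), map),
               "no informative probes")
  # unmapped probes are removed as ambiguous, with a warning
  map_missing <- map[map$probe_id != "u3", ]
  expect_warning(res4 <- filter_probesets(m, map_missing), "absent")
  expect_identical(probe_ids(res4$matrix), c("u1", "u2"))
})

test_that("generator-planted ambiguous probes are counted exactly", {
  comp <- generate_compendium(n_groups = 2, samples_per_group = 5,
                              n_genes = 60, modules_per_group = 1,
                              module_size = 5, n_ambiguous = 50,
                              n_control = 7, seed = 3)
  res <- filter_probesets(comp$matrix, comp$probe_map)
  expect_equal(res$report$removed_ambiguous, 50)
  expect_equal(res$report$removed_controls, 7)
})

test_that("quantile normalization equalizes sample distributions to rank means", {
  v <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  colnames(v) <- c("p1", "p2", "p3")
  qn <- quantile_normalize(ExpressionMatrix(v))
  expect_equal(unname(qn$values["s1", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values["s2", ]), c(2.5, 3.5, 4.5))
  # already identical samples are a fixed point
  v2 <- rbind(s1 = c(3, 1, 2), s2 = c(2, 3, 1))
  colnames(v2) <- c("p1", "p2", "p3")
  qn2 <- quantile_normalize(ExpressionMatrix(v2))
  expect_equal(qn2$values, v2)
  # postcondition property on arbitrary input
  set.seed(1)
  m <- expr_from(matrix(rnorm(60), 5, 12))
  qn3 <- quantile_normalize(m)
  sorted <- apply(qn3$values, 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # sample-order invariance (up to reordering)
  perm <- c(3, 1, 5, 2, 4)
  qn4 <- quantile_normalize(expr_from(m$values[perm, ]))
  expect_equal(qn4$values, qn3$values[perm, ])
  expect_warning(quantile_normalize(expr_from(matrix(1:3, 1))), "single")
})

test_that("outlier detection flags a planted aberrant sample by >= 2 of 3 tests", {
  comp <- generate_compendium(n_groups = 1, samples_per_group = 30,
                              n_genes = 150, modules_per_group = 0,
                              module_size = 0, seed = 5)
  qc <- detect_outlier_samples(comp$matrix)
  expect_equal(sum(qc$outlier_samples$is_outlier), 0)
  # plant an aberration: doubled intensities with shuffled ranks
  v <- comp$matrix$values
  set.seed(9)
  v[1, ] <- 2 * sample(v[1, ])
  qc2 <- detect_outlier_samples(ExpressionMatrix(v))
  row1 <- qc2$outlier_samples[1, ]
  expect_true(row1$is_outlier)
  expect_gte(row1$n_failed, 2)
  # flagged-iff rule holds for every sample
  expect_equal(qc2$outlier_samples$is_outlier,
               qc2$outlier_samples$n_failed >= 2)
  # probe-permutation invariance
  qc3 <- detect_outlier_samples(ExpressionMatrix(v[, sample(ncol(v))]))
  expect_equal(qc3$outlier_samples$is_outlier, qc2$outlier_samples$is_outlier)
  expect_error(detect_outlier_samples(expr_from(matrix(rnorm(30), 3))),
               "at least 4")
})
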