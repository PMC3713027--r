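test_that("correlation matrix matches the two-pass Pearson formula", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  m <- expr_from(cbind(x = x, y = y, z = -2 * x + 5))
  sim <- suppressWarnings(correlation_matrix(m))
  expect_equal(diag(sim$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sim$r["x", "z"], -1)
  expect_equal(sim$r["x", "y"], 0.98198051, tolerance = 1e-7)
  expect_equal(sim$r["x", "y"], brute_pearson(x, y), tolerance = 1e-14)
  # 20x20 fixture against the brute-force oracle to 1e-12
  set.seed(3)
  v <- matrix(rnorm(20 * 20), 20, 20)
  sim2 <- correlation_matrix(expr_from(v))
  for (i in 1:5) for (j in 6:10)
    expect_equal(sim2$r[i, j], brute_pearson(v[, i], v[, j]),
                 tolerance = 1e-12)
  expect_error(correlation_matrix(expr_from(matrix(rnorm(8), 2))),
               "at least 3")
  expect_warning(correlation_matrix(expr_from(cbind(rnorm(5), rep(2, 5)))),
                 "zero-variance")
})

test_that("unfolded spacings have mean one and degenerate spectra error out", {
  set.seed(4)
  ev <- sort(rnorm(300))
  unfolded <- unfold_eigenvalues(ev)
  expect_equal(mean(diff(unfolded)), 1, tolerance = 1e-9)
  expect_error(nnsd_chi_square(rnorm(10)), class = "gilnet_too_few_genes")
})

test_that("network edges are exactly the pairs at or above the threshold", {
  set.seed(5)
  m <- expr_from(matrix(rnorm(25 * 12), 25, 12))
  sim <- correlation_matrix(m)
  t <- 0.3
  net <- build_network(sim, t, gil_id = "GX")
  # oracle: full matrix scan
  want <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    if (abs(sim$r[i, j]) >= t) {
      want <- want + 1L
      a <- sort(c(sim$ids[i], sim$ids[j]))
      hit <- net$edges$gene_a == a[1] & net$edges$gene_b == a[2]
      expect_true(any(hit))
      expect_equal(net$edges$r[hit], sim$r[i, j])
    }
  }
  expect_equal(nrow(net$edges), want)
  expect_false(any(net$edges$gene_a == net$edges$gene_b))
  expect_false(any(duplicated(net$edges[, 1:2])))
  expect_true(all(net$edges$abs_r >= t))
  # t above every |r| -> empty network with warning
  expect_warning(empty <- build_network(sim, 0.999), "empty")
  expect_length(empty$nodes, 0)
  # three probes pairwise r ~ 1 -> triangle
  tri <- expr_from(cbind(a = 1:5 + rnorm(5, 0, 1e-3),
                         b = 1:5 + rnorm(5, 0, 1e-3),
                         c = 1:5 + rnorm(5, 0, 1e-3)))
  net_tri <- build_network(correlation_matrix(tri), 0.95)
  expect_equal(nrow(net_tri$edges), 3)
})

test_that("probe collapsing keeps the highest-mean probe per gene", {
  v <- cbind(p1 = c(1, 2, 3), p2 = c(10, 11, 12), p3 = c(5, 5, 6))
  rownames(v) <- c("s1", "s2", "s3")
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("gA", "gA", "gB"))
  g <- collapse_probes_to_genes(ExpressionMatrix(v), map)
  expect_identical(probe_ids(g), c("gA", "gB"))
  expect_equal(unname(g$values[, "gA"]), c(10, 11, 12))
})

test_that("threshold scan fails cleanly on structureless matrices", {
  # identity-like: nothing at or above the scan start
  ids <- sprintf("g%03d", 1:120)
  r <- diag(120) + matrix(runif(120 * 120, -0.2, 0.2), 120)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  s <- structure(list(r = r, ids = ids, n_samples = 40),
                 class = "SimilarityMatrix")
  res <- find_rmt_threshold(s)
  expect_false(res$success)
  expect_equal(res$reason, "no_threshold_found")
})

test_that("scan result on the planted-block fixture is reproducible and monotone in t_start", {
  m <- make_block_matrix(seed = 21, n_blocks = 8, block = 20, n_samples = 30)
  sim <- correlation_matrix(m)
  res <- find_rmt_threshold(sim)
  expect_true(res$success)
  expect_true(all(diff(res$scan$t[res$scan$t %in% seq(0.5, 1, 0.01)]) > 0))
  res2 <- find_rmt_threshold(sim, t_start = min(res$threshold + 0.05, 0.9))
  if (res2$success) expect_gte(res2$threshold, res$threshold)
})

test_that("network summaries report 2E/N to two decimals and multiplicities", {
  tri <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  s <- network_summary(tri)
  expect_equal(s$avg_degree, 2.00)
  expect_equal(s$n_nodes, 3)
  empty <- make_net(character(), character())
  expect_equal(network_summary(empty)$avg_degree, 0)
  # collection redundancy
  one <- collection_summary(list(tri))
  expect_equal(one$node_multiplicity$percent, 100)
  expect_equal(one$edge_multiplicity$percent, 100)
  two <- collection_summary(list(tri, tri))
  expect_equal(two$node_multiplicity$multiplicity, 2)
  expect_equal(two$node_multiplicity$percent, 100)
  expect_equal(two$edge_multiplicity$multiplicity, 2)
  expect_equal(two$total_edges, 6)
  expect_equal(two$distinct_nodes, 3)
})
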