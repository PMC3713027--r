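genome2 <- c(Chr01 = 3e7, Chr02 = 3e7)

test_that("single-marker QTLs are enlarged to a centred 2 Mb interval", {
  qtls <- data.frame(trait = c("t1", "t2"),
                     chrom = c("Chr01", "Chr02"),
                     start = c(4999999, 1000000),
                     end = c(5000001, 6000000))  # lengths 3 bp and 5 Mb
  f <- prepare_features(qtls = qtls, genome = genome2)
  expect_equal(f$start[1], 4000001)
  expect_equal(f$end[1], 6000000)
  expect_equal(f$end[1] - f$start[1] + 1, 2000000)
  expect_equal(f$start[2], 1000000)   # above threshold: unchanged
  expect_equal(f$end[2], 6000000)
  expect_error(prepare_features(qtls = data.frame(trait = "t", chrom = "ChrX",
                                                  start = 1, end = 10),
                                genome = genome2), "ChrX")
})

test_that("GWAS SNPs become 300 kb total-span windows, filtered by p", {
  snps <- data.frame(trait = "t", chrom = "Chr01",
                     pos = c(1000000, 2000000), p = c(1e-6, 1e-3))
  f <- prepare_features(snps = snps, genome = genome2)
  expect_equal(nrow(f), 1)           # p = 1e-3 dropped at snp_p_max = 1e-4
  expect_equal(f$start, 850001)
  expect_equal(f$end, 1150000)
  expect_equal(f$end - f$start + 1, 300000)
  f2 <- prepare_features(snps = snps, genome = genome2,
                         snp_window_per_side = TRUE)
  expect_equal(f2$end - f2$start + 1, 600001)
})

test_that("gene-feature assignment uses closed 1-based intervals (1 bp overlap counts)", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "Chr01",
                      start = c(100, 100), end = c(200, 200), strand = "+")
  feats <- data.frame(feature_id = c("F1", "F2"), type = "QTL", trait = "t",
                      map_label = NA, chrom = "Chr01",
                      start = c(200, 201), end = c(300, 300))
  asn <- assign_genes_to_features(genes, feats)
  expect_true(all(asn$feature_id == "F1"))
  expect_setequal(asn$gene_id, c("gA", "gB"))
  # symmetry oracle: brute-force interval overlap gives identical pairs
  set.seed(8)
  g2 <- data.frame(gene_id = sprintf("g%02d", 1:40), chrom = "Chr01",
                   start = s <- sample.int(1e6, 40), end = s + 5000,
                   strand = "+")
  f2 <- data.frame(feature_id = sprintf("F%02d", 1:15), type = "QTL",
                   trait = "t", map_label = NA, chrom = "Chr01",
                   start = fs <- sample.int(1e6, 15), end = fs + 30000)
  asn2 <- assign_genes_to_features(g2, f2)
  brute <- expand.grid(gi = 1:40, fi = 1:15)
  brute$hit <- with(brute, pmax(g2$start[gi], f2$start[fi]) <=
                      pmin(g2$end[gi], f2$end[fi]))
  want <- sort(paste(g2$gene_id[brute$gi[brute$hit]],
                     f2$feature_id[brute$fi[brute$hit]]))
  expect_identical(sort(paste(asn2$gene_id, asn2$feature_id)), want)
})

test_that("module-trait Fisher p equals the direct hypergeometric tail", {
  # background 1000 genes; 30 trait-assigned; module of 25 containing 10
  bg <- sprintf("g%04d", 1:1000)
  assigned <- bg[c(1:10, 500:519)]
  asn <- data.frame(gene_id = assigned, trait = "t",
                    feature_id = "F1", type = "QTL")
  module <- bg[c(1:10, 100:114)]
  res <- module_trait_fisher(module, "t", asn, bg)
  expect_equal(res$a, 10)
  expect_equal(res$a + res$b, 25)
  expect_equal(res$p, hyper_tail(10, 30, 1000, 25), tolerance = 1e-12)
  expect_equal(res$features_hit, "F1")
  # zero overlap -> p = 1; absent trait warns
  res0 <- module_trait_fisher(bg[200:220], "t", asn, bg)
  expect_equal(res0$p, 1)
  expect_warning(module_trait_fisher(module, "no_such", asn, bg), "absent")
  expect_error(module_trait_fisher(c(module, "zz"), "t", asn, bg), "zz")
  # large-background oracle agreement (N = 2000)
  bg2 <- sprintf("h%04d", 1:2000)
  asn2 <- data.frame(gene_id = bg2[1:80], trait = "t", feature_id = "F1",
                     type = "QTL")
  res2 <- module_trait_fisher(bg2[c(1:12, 1000:1017)], "t", asn2, bg2)
  expect_equal(res2$p, hyper_tail(12, 80, 2000, 30), tolerance = 1e-12)
})

test_that("min_features requires distinct features per gene and per edge", {
  asn <- data.frame(gene_id = c("gA", "gA", "gB"),
                    trait = "t", feature_id = c("F1", "F2", "F1"),
                    type = "QTL")
  bg <- c("gA", "gB", "gC", "gD", sprintf("x%02d", 1:30))
  r1 <- suppressWarnings(module_trait_fisher(c("gA", "gB", "gC"), "t", asn,
                                             bg, min_features = 2))
  expect_equal(r1$overlapping_genes, "gA")
  mod <- structure(list(module_name = "m", gil_id = "G0001",
                        genes = c("gA", "gB", "gC", "gD"),
                        edges = data.frame(gene_a = c("gA", "gB", "gC"),
                                           gene_b = c("gB", "gC", "gD"),
                                           r = 1, abs_r = 1)),
                   class = "LinkCommunityModule")
  f1 <- filter_edges_by_trait(mod, "t", asn, min_features = 1)
  expect_equal(nrow(f1$highlighted), 2)     # edges touching gA or gB
  f3 <- filter_edges_by_trait(mod, "t", asn, min_features = 3)
  expect_equal(nrow(f3$highlighted), 0)
  # monotone: raising min_features never highlights more edges
  counts <- vapply(1:4, function(k)
    nrow(filter_edges_by_trait(mod, "t", asn, min_features = k)$highlighted),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  # brute-force oracle over a 20-edge fixture
  net <- rand_graph(5, n_nodes = 10, n_edges = 20)
  mod2 <- structure(list(module_name = "m2", gil_id = "G0001",
                         genes = net$nodes, edges = net$edges),
                    class = "LinkCommunityModule")
  asn2 <- data.frame(gene_id = sample(net$nodes, 6),
                     trait = "t", feature_id = sprintf("F%d", 1:6),
                     type = "QTL")
  for (k in 1:3) {
    got <- filter_edges_by_trait(mod2, "t", asn2, min_features = k)
    want <- vapply(seq_len(nrow(net$edges)), function(i) {
      fts <- unique(asn2$feature_id[asn2$gene_id %in%
                                      c(net$edges$gene_a[i],
                                        net$edges$gene_b[i])])
      length(fts) >= k
    }, logical(1))
    expect_equal(nrow(got$highlighted), sum(want))
  }
})

test_that("biomarker SNP query respects the 50 kb boundary exactly", {
  genes <- data.frame(gene_id = "gA", chrom = "Chr01",
                      start = 1000000, end = 1005000, strand = "+")
  asn <- data.frame(gene_id = "gA", trait = "t", feature_id = "F1",
                    type = "QTL")
  snps <- data.frame(snp_id = c("in", "edge", "out"),
                     chrom = "Chr01",
                     pos = c(1002000, 1000000 - 50000, 1000000 - 50001))
  res <- biomarker_snps("gA", "t", asn, snps, genes)
  expect_setequal(res$snp_id, c("in", "edge"))
  # planted-marker fixture: exactly the markers within the window return
  set.seed(13)
  marks <- data.frame(snp_id = sprintf("mk%03d", 1:100), chrom = "Chr01",
                      pos = sample.int(3e6, 100))
  res2 <- biomarker_snps("gA", "t", asn, marks, genes)
  want <- marks$snp_id[marks$pos >= 1000000 - 50000 &
                         marks$pos <= 1005000 + 50000]
  expect_setequal(res2$snp_id, want)
  expect_false(any(duplicated(res2$snp_id)))
  expect_true(all(diff(res2$pos) >= 0))
})
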