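test_that("the compendium generator is seed-deterministic and size-checked", {
  a <- generate_compendium(n_groups = 2, samples_per_group = 8, n_genes = 80,
                           modules_per_group = 2, module_size = 10, seed = 42)
  b <- generate_compendium(n_groups = 2, samples_per_group = 8, n_genes = 80,
                           modules_per_group = 2, module_size = 10, seed = 42)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$modules, b$truth$modules)
  expect_error(generate_compendium(n_groups = 2, n_genes = 50,
                                   modules_per_group = 2, module_size = 20),
               "genes")
  # planted modules within a group are disjoint
  g1 <- a$truth$modules[[1]]
  expect_false(any(duplicated(unlist(g1))))
})

test_that("planted within-module correlation matches its analytic target", {
  comp <- generate_compendium(seed = 17)
  g1 <- names(comp$truth$sample_groups)[comp$truth$sample_groups == 1]
  probe_of <- setNames(comp$probe_map$probe_id, comp$probe_map$gene_id)
  within_r <- c(); between_r <- c()
  v <- comp$matrix$values[g1, ]
  mods <- comp$truth$modules[[1]]
  for (mg in mods) {
    cm <- cor(v[, probe_of[mg]])
    within_r <- c(within_r, cm[upper.tri(cm)])
  }
  cb <- cor(v[, probe_of[mods[[1]]]], v[, probe_of[mods[[2]]]])
  between_r <- as.vector(cb)
  expect_gt(mean(within_r), 0.90)
  expect_lt(mean(within_r), 0.98)
  expect_lt(mean(abs(between_r)), 0.2)
  # outside the home group, module genes are uncorrelated noise
  g2 <- names(comp$truth$sample_groups)[comp$truth$sample_groups == 2]
  cm2 <- cor(comp$matrix$values[g2, probe_of[mods[[1]]]])
  expect_lt(mean(abs(cm2[upper.tri(cm2)])), 0.2)
})

test_that("the toy genome is deterministic and trait features cover their targets", {
  comp <- generate_compendium(n_groups = 2, samples_per_group = 8,
                              n_genes = 120, modules_per_group = 2,
                              module_size = 10, seed = 9)
  gt <- generate_genome(comp$truth, chrom_count = 3, seed = 9)
  gt2 <- generate_genome(comp$truth, chrom_count = 3, seed = 9)
  expect_identical(gt$genes, gt2$genes)
  expect_identical(gt$qtls, gt2$qtls)
  # genes do not overlap each other
  for (ch in unique(gt$genes$chrom)) {
    g <- gt$genes[gt$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # every targeted feature covers >= 80% of its module's genes
  feats <- prepare_features(qtls = gt$qtls, snps = gt$gwas_snps,
                            genome = gt$genome)
  asn <- assign_genes_to_features(gt$genes, feats)
  for (i in seq_len(nrow(gt$targeted))) {
    mg <- comp$truth$modules[[gt$targeted$group[i]]][[gt$targeted$module[i]]]
    cov <- mean(mg %in% asn$gene_id[asn$trait == gt$targeted$trait[i]])
    expect_gte(cov, 0.8)
  }
  # written files are byte-identical across runs of the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_files(gt, d1); write_genome_files(gt2, d2)
  for (fn in list.files(d1))
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)), label = fn)
})

test_that("genome files round-trip through the standard readers", {
  comp <- generate_compendium(n_groups = 2, samples_per_group = 8,
                              n_genes = 100, modules_per_group = 2,
                              module_size = 10, seed = 31)
  d <- withr::local_tempdir()
  gt <- generate_genome(comp$truth, seed = 31, dir = d)
  genes <- load_gene_loci(file.path(d, "genes.gff3"))
  expect_setequal(genes$gene_id, gt$genes$gene_id)
  got <- genes[match(gt$genes$gene_id, genes$gene_id), ]
  expect_equal(got$start, gt$genes$start)
  expect_equal(got$end, gt$genes$end)
  snps_tsv <- load_snp_positions(file.path(d, "markers.tsv"))
  snps_vcf <- load_snp_positions(file.path(d, "markers.vcf"))
  expect_equal(snps_tsv, snps_vcf)
  expect_equal(nrow(snps_vcf), nrow(gt$markers))
})

test_that("recovery evaluation scores planted-vs-discovered overlap", {
  comp <- generate_compendium(n_groups = 2, samples_per_group = 8,
                              n_genes = 80, modules_per_group = 2,
                              module_size = 10, seed = 2)
  mk <- function(genes, gil) structure(
    list(module_name = paste0(gil, "_m"), genes = genes,
         edges = data.frame(), gil_id = gil), class = "LinkCommunityModule")
  # discovered exactly equal to planted -> all Jaccard 1
  disc <- list()
  for (g in 1:2) for (mn in names(comp$truth$modules[[g]]))
    disc[[mn]] <- mk(comp$truth$modules[[g]][[mn]], sprintf("G%04d", g))
  ev <- evaluate_recovery(disc, comp$truth)
  expect_equal(ev$mean_jaccard, 1)
  # empty discovery -> all zero
  ev0 <- evaluate_recovery(list(), comp$truth)
  expect_equal(ev0$mean_jaccard, 0)
  # GIL attribution restricts matching to the home group's network
  gil_samples <- split(names(comp$truth$sample_groups),
                       sprintf("G%04d", comp$truth$sample_groups))
  ev2 <- evaluate_recovery(disc, comp$truth, gil_samples = gil_samples)
  expect_equal(ev2$mean_jaccard, 1)
})
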