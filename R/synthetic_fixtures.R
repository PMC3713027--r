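# Deterministic per-stage seed derived from one root seed, so that each
# generation stage is independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483629)
}

#' Generate a synthetic expression compendium with planted modules
#'
#' Samples fall into condition groups; each group carries a set of planted
#' co-expression modules (disjoint gene sets) that are correlated only
#' within their home group. Module genes follow a single-latent-factor
#' model: within the home group, gene value = baseline + group offset +
#' loading * latent(sample) + noise, with the loading chosen so the expected
#' within-module pairwise Pearson correlation is `rho`
#' (loading = noise_sd * sqrt(rho / (1 - rho))). Outside the home group, and
#' for all non-module genes, values are baseline + group offset +
#' independent noise. Group-specific baseline offsets emulate condition
#' signatures (differential expression between conditions), which is what
#' lets sample clustering recover the groups and what dilutes module
#' correlations when all groups are pooled.
#'
#' @param n_groups Number of condition groups (default 4).
#' @param samples_per_group Samples per group (default 40).
#' @param n_genes Number of genes (default 800).
#' @param modules_per_group Planted modules per group (default 5).
#' @param module_size Genes per planted module (default 25).
#' @param rho Expected within-module correlation in the home group
#'   (default 0.95).
#' @param noise_sd Per-gene residual noise standard deviation on the log2
#'   scale (default 0.4, typical residual array noise).
#' @param group_effect_sd Standard deviation of per-gene condition-group
#'   offsets (default 1.5, i.e. typical condition shifts of a few
#'   fold-changes on the log2 scale).
#' @param baseline_mean,baseline_sd Per-gene baseline intensity distribution
#'   (defaults 8 and 1.5, typical of log2 microarray intensities).
#' @param n_ambiguous Extra probes mapping to two loci (default 0).
#' @param n_control Extra control probes with prefix `AFFX-` (default 0).
#' @param seed Root seed; fully determines the output.
#' @return List with `matrix` (an [ExpressionMatrix] of samples x probes),
#'   `probe_map` (data.frame `probe_id`, `gene_id`), and `truth` (a
#'   `CompendiumTruth`: `sample_groups` named integer vector,
#'   `modules` nested list `[[group]][[module]]` of gene ids, `loading`,
#'   `noise_sd`, `rho`, `seed`).
#' @export
generate_compendium <- function(n_groups = 4L, samples_per_group = 40L,
                                n_genes = 800L, modules_per_group = 5L,
                                module_size = 25L, rho = 0.95,
                                noise_sd = 0.4, group_effect_sd = 1.5,
                                baseline_mean = 8, baseline_sd = 1.5,
                                n_ambiguous = 0L, n_control = 0L, seed = 1L) {
  if (!(rho > 0 && rho < 1)) stop("rho must be in (0,1)")
  if (modules_per_group * module_size * n_groups > n_genes)
    stop("planted modules need ", modules_per_group * module_size * n_groups,
         " genes but only ", n_genes, " available")
  n_samples <- n_groups * samples_per_group
  gene_ids <- sprintf("LOCg%04d", seq_len(n_genes))
  sample_id <- sprintf("S%04d", seq_len(n_samples))
  groups <- rep(seq_len(n_groups), each = samples_per_group)
  loading <- noise_sd * sqrt(rho / (1 - rho))

  # planted module gene sets: globally disjoint, drawn from a shuffled pool
  pool <- withr::with_seed(stage_seed(seed, 1L), sample(gene_ids))
  modules <- vector("list", n_groups)
  idx <- 1L
  for (g in seq_len(n_groups)) {
    modules[[g]] <- vector("list", modules_per_group)
    for (m in seq_len(modules_per_group)) {
      modules[[g]][[m]] <- sort(pool[idx:(idx + module_size - 1L)])
      idx <- idx + module_size
    }
    names(modules[[g]]) <- sprintf("grp%d_mod%d", g, seq_len(modules_per_group))
  }

  values <- withr::with_seed(stage_seed(seed, 2L), {
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    offsets <- matrix(stats::rnorm(n_genes * n_groups, 0, group_effect_sd),
                      n_genes, n_groups)
    v <- matrix(stats::rnorm(n_samples * n_genes, 0, noise_sd),
                n_samples, n_genes)
    v <- v + rep(baseline, each = n_samples) + t(offsets[, groups])
    for (g in seq_len(n_groups)) {
      in_g <- which(groups == g)
      for (m in seq_len(modules_per_group)) {
        latent <- stats::rnorm(length(in_g))
        cols <- match(modules[[g]][[m]], gene_ids)
        v[in_g, cols] <- v[in_g, cols] + loading * latent
      }
    }
    v
  })

  probe_of_gene <- sprintf("P%04d_at", seq_len(n_genes))
  probe_map <- data.frame(probe_id = probe_of_gene, gene_id = gene_ids,
                          stringsAsFactors = FALSE)
  colnames(values) <- probe_of_gene
  rownames(values) <- sample_id

  if (n_ambiguous > 0 || n_control > 0) {
    extra <- withr::with_seed(stage_seed(seed, 3L), {
      amb_ids <- if (n_ambiguous > 0) sprintf("PA%03d_at", seq_len(n_ambiguous))
                 else character()
      ctl_ids <- if (n_control > 0) sprintf("AFFX-C%03d", seq_len(n_control))
                 else character()
      ids <- c(amb_ids, ctl_ids)
      ev <- matrix(stats::rnorm(n_samples * length(ids), baseline_mean, 1),
                   n_samples, length(ids), dimnames = list(sample_id, ids))
      amb_map <- if (n_ambiguous > 0)
        data.frame(probe_id = rep(amb_ids, each = 2),
                   gene_id = sample(gene_ids, 2 * n_ambiguous, replace = TRUE),
                   stringsAsFactors = FALSE)
      else NULL
      list(values = ev, map = amb_map)
    })
    values <- cbind(values, extra$values)
    if (!is.null(extra$map)) probe_map <- rbind(probe_map, extra$map)
  }

  truth <- structure(list(
    sample_groups = stats::setNames(groups, sample_id),
    modules = modules, gene_ids = gene_ids, loading = loading,
    noise_sd = noise_sd, rho = rho,
    seed = as.integer(seed)), class = "CompendiumTruth")
  list(matrix = ExpressionMatrix(values), probe_map = probe_map,
       truth = truth)
}

#' Generate a toy genome with planted trait congruence
#'
#' Places every gene of a compendium on a toy genome without overlap. One
#' planted module per condition group (the "targeted" modules, by default
#' the first module of each group) has its genes placed in consecutive
#' positional slots so that a single QTL interval can cover them; that QTL
#' (plus `n_targeted_snps` significant GWAS SNPs inside it) is tagged with a
#' trait named after the group. Additional decoy QTLs with their own traits
#' are placed uniformly at random, as are trait-less marker SNPs for
#' biomarker queries.
#'
#' @param truth A `CompendiumTruth` from [generate_compendium()].
#' @param chrom_count Number of chromosomes (default 5).
#' @param chrom_len Chromosome length in bp (default 3e7).
#' @param targeted_modules Character vector of planted module names (from
#'   `truth$modules`) to make trait-congruent; default the first module of
#'   each group.
#' @param n_random_features Number of decoy QTLs, each with its own trait
#'   (default 10).
#' @param random_feature_size Decoy QTL span in bp (default 2e6).
#' @param n_targeted_snps Significant GWAS SNPs planted inside each targeted
#'   region (default 2).
#' @param n_snp_markers Trait-less marker SNPs scattered uniformly
#'   (default 500).
#' @param seed Root seed.
#' @param dir If non-NULL, write `genes.gff3`, `qtl.tsv`, `gwas_snps.tsv`,
#'   `markers.tsv` and `markers.vcf` there.
#' @return A `GenomeTruth` list: `genes` (gene loci data.frame), `genome`
#'   (named chromosome lengths), `qtls`, `gwas_snps`, `markers` data.frames,
#'   and `targeted` (data.frame trait / module / group).
#' @export
generate_genome <- function(truth, chrom_count = 5L, chrom_len = 3e7,
                            targeted_modules = NULL,
                            n_random_features = 10L,
                            random_feature_size = 2e6,
                            n_targeted_snps = 2L, n_snp_markers = 500L,
                            seed = 1L, dir = NULL) {
  all_modules <- unlist(truth$modules, recursive = FALSE)
  if (is.null(targeted_modules))
    targeted_modules <- vapply(truth$modules,
                               function(g) names(g)[1], character(1))
  missing <- setdiff(targeted_modules, names(all_modules))
  if (length(missing)) stop("unknown module(s): ",
                            paste(missing, collapse = ", "))
  gene_ids <- truth$gene_ids
  n_genes <- length(gene_ids)

  genes_per_chrom <- ceiling(n_genes / chrom_count)
  slot_w <- floor(chrom_len / genes_per_chrom)
  max_gene_len <- min(5000L, slot_w - 2L)
  n_slots <- genes_per_chrom * chrom_count
  genome <- stats::setNames(rep(chrom_len, chrom_count),
                            sprintf("Chr%02d", seq_len(chrom_count)))

  placement <- withr::with_seed(stage_seed(seed, 11L), {
    slot_of <- rep(NA_integer_, n_genes)          # gene index -> global slot
    used <- rep(FALSE, n_slots)
    # reserve consecutive runs for targeted modules, one run per module
    for (mn in targeted_modules) {
      mg <- all_modules[[mn]]
      run_len <- length(mg)
      repeat {
        ch <- sample.int(chrom_count, 1)
        start_slot <- (ch - 1L) * genes_per_chrom +
          sample.int(genes_per_chrom - run_len + 1L, 1)
        run <- start_slot:(start_slot + run_len - 1L)
        if (!any(used[run])) break
      }
      used[run] <- TRUE
      slot_of[match(mg, gene_ids)] <- run
    }
    free <- which(!used)
    rest <- which(is.na(slot_of))
    slot_of[rest] <- sample(free, length(rest))
    starts_in_slot <- sample.int(max(1L, slot_w - max_gene_len - 1L),
                                 n_genes, replace = TRUE)
    lens <- sample(1000:max_gene_len, n_genes, replace = TRUE)
    list(slot_of = slot_of, starts = starts_in_slot, lens = lens)
  })

  slot_of <- placement$slot_of
  chrom_idx <- (slot_of - 1L) %/% genes_per_chrom + 1L
  within <- (slot_of - 1L) %% genes_per_chrom
  start <- within * slot_w + placement$starts
  end <- pmin(start + placement$lens - 1L, chrom_len)
  genes <- data.frame(gene_id = gene_ids,
                      chrom = names(genome)[chrom_idx],
                      start = as.integer(start), end = as.integer(end),
                      strand = "+", stringsAsFactors = FALSE)

  group_of_module <- rep(seq_along(truth$modules),
                         times = lengths(truth$modules))
  names(group_of_module) <- names(all_modules)

  qtl_rows <- list(); snp_rows <- list(); targeted_tab <- list()
  for (mn in targeted_modules) {
    mg <- all_modules[[mn]]
    gi <- genes[genes$gene_id %in% mg, , drop = FALSE]
    trait <- sprintf("trait_group%d", group_of_module[[mn]])
    qtl_rows[[mn]] <- data.frame(
      trait = trait, map_label = "synthetic_map",
      chrom = gi$chrom[1], start = max(1L, min(gi$start) - 1000L),
      end = min(chrom_len, max(gi$end) + 1000L), stringsAsFactors = FALSE)
    if (n_targeted_snps > 0) {
      pos <- withr::with_seed(stage_seed(seed, 13L + match(mn, targeted_modules)),
        sort(sample(min(gi$start):max(gi$end), n_targeted_snps)))
      snp_rows[[mn]] <- data.frame(trait = trait, chrom = gi$chrom[1],
                                   pos = as.integer(pos), p = 1e-6,
                                   stringsAsFactors = FALSE)
    }
    targeted_tab[[mn]] <- data.frame(trait = trait, module = mn,
                                     group = group_of_module[[mn]],
                                     stringsAsFactors = FALSE)
  }

  decoys <- if (n_random_features == 0) NULL else
    withr::with_seed(stage_seed(seed, 12L), {
    ch <- sample.int(chrom_count, n_random_features, replace = TRUE)
    st <- vapply(ch, function(x)
      sample.int(chrom_len - random_feature_size, 1), integer(1))
    data.frame(trait = sprintf("random_trait%02d", seq_len(n_random_features)),
               map_label = "synthetic_map", chrom = names(genome)[ch],
               start = as.integer(st),
               end = as.integer(st + random_feature_size - 1),
               stringsAsFactors = FALSE)
  })
  qtls <- do.call(rbind, c(qtl_rows, list(decoys)))
  rownames(qtls) <- NULL
  qtls$feature_id <- sprintf("QTL%05d", seq_len(nrow(qtls)))

  gwas <- if (length(snp_rows)) {
    g <- do.call(rbind, snp_rows); rownames(g) <- NULL
    g$feature_id <- sprintf("GWAS%05d", seq_len(nrow(g)))
    g
  } else data.frame(trait = character(), chrom = character(),
                    pos = integer(), p = numeric(), feature_id = character())

  markers <- withr::with_seed(stage_seed(seed, 14L), {
    ch <- sample.int(chrom_count, n_snp_markers, replace = TRUE)
    pos <- vapply(ch, function(x) sample.int(chrom_len, 1), integer(1))
    df <- data.frame(snp_id = sprintf("mk%05d", seq_len(n_snp_markers)),
                     chrom = names(genome)[ch], pos = as.integer(pos),
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$pos), , drop = FALSE]
  })
  rownames(markers) <- NULL

  out <- structure(list(genes = genes, genome = genome, qtls = qtls,
                        gwas_snps = gwas, markers = markers,
                        targeted = do.call(rbind, targeted_tab),
                        seed = as.integer(seed)),
                   class = "GenomeTruth")
  if (!is.null(dir)) write_genome_files(out, dir)
  out
}

#' Write the toy genome to standard file formats
#'
#' @param gt A `GenomeTruth` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_files <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- GenomicRanges::GRanges(
    gt$genes$chrom, IRanges::IRanges(gt$genes$start, gt$genes$end),
    strand = gt$genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- gt$genes$gene_id
  S4Vectors::mcols(gr)$source <- "gilnet"
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  data.table::fwrite(gt$qtls, file.path(dir, "qtl.tsv"), sep = "\t")
  data.table::fwrite(gt$gwas_snps, file.path(dir, "gwas_snps.tsv"),
                     sep = "\t")
  data.table::fwrite(gt$markers, file.path(dir, "markers.tsv"), sep = "\t")
  write_snp_vcf(gt$markers, gt$genome, file.path(dir, "markers.vcf"))
  invisible(dir)
}

# Minimal VCFv4.2 writer for point markers (id, chrom, pos only).
write_snp_vcf <- function(markers, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(genome),
                       as.integer(genome)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(markers))
    writeLines(sprintf("%s\t%d\t%s\tA\tG\t.\tPASS\t.", markers$chrom,
                       markers$pos, markers$snp_id), con)
  invisible(path)
}

#' Read SNP positions from TSV or VCF
#'
#' @param path A TSV with columns `snp_id`, `chrom`, `pos`, or a VCF file.
#' @return Data.frame `snp_id`, `chrom`, `pos`.
#' @export
load_snp_positions <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    dt <- data.table::fread(path, skip = "#CHROM", data.table = FALSE)
    data.frame(snp_id = as.character(dt$ID), chrom = as.character(dt[[1]]),
               pos = as.integer(dt$POS), stringsAsFactors = FALSE)
  } else {
    dt <- data.table::fread(path, data.table = FALSE)
    stopifnot(all(c("snp_id", "chrom", "pos") %in% colnames(dt)))
    dt[, c("snp_id", "chrom", "pos")]
  }
}

#' Score recovery of planted modules
#'
#' For each planted module, finds the best-matching discovered module (by
#' Jaccard index of gene sets) among the modules of the network(s) built
#' from that module's home group, and summarizes with the mean best-match
#' Jaccard.
#'
#' @param discovered_modules Named list of `LinkCommunityModule` objects
#'   across all networks.
#' @param truth A `CompendiumTruth`.
#' @param gil_samples Optional named list `gil_id -> sample ids` (e.g. from
#'   the pipeline manifest); when given, each network is attributed to the
#'   condition group contributing most of its samples and planted modules
#'   are only matched against their home group's network(s). Without it,
#'   matching is against all discovered modules.
#' @return List with `per_module` data.frame (`module`, `group`,
#'   `best_match`, `jaccard`) and `mean_jaccard`.
#' @export
evaluate_recovery <- function(discovered_modules, truth,
                              gil_samples = NULL) {
  gil_of_group <- NULL
  if (!is.null(gil_samples)) {
    maj <- vapply(gil_samples, function(s) {
      tab <- table(truth$sample_groups[s])
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
    gil_of_group <- split(names(maj), maj)
  }
  disc_genes <- lapply(discovered_modules, `[[`, "genes")
  disc_gil <- vapply(discovered_modules, `[[`, character(1), "gil_id")
  rows <- list()
  for (g in seq_along(truth$modules)) {
    allowed <- if (is.null(gil_of_group)) seq_along(disc_genes)
      else which(disc_gil %in% gil_of_group[[as.character(g)]])
    for (mn in names(truth$modules[[g]])) {
      planted <- truth$modules[[g]][[mn]]
      if (length(allowed)) {
        js <- vapply(disc_genes[allowed], function(dg)
          jaccard(planted, dg), numeric(1))
        best <- which.max(js)
        rows[[mn]] <- data.frame(module = mn, group = g,
                                 best_match = names(disc_genes[allowed])[best],
                                 jaccard = js[best],
                                 stringsAsFactors = FALSE)
      } else {
        rows[[mn]] <- data.frame(module = mn, group = g,
                                 best_match = NA_character_, jaccard = 0,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  per_module <- do.call(rbind, rows)
  rownames(per_module) <- NULL
  list(per_module = per_module, mean_jaccard = mean(per_module$jaccard))
}
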