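#' Read gene loci from GFF3 or BED
#'
#' Coordinates are normalized to 1-based inclusive (GFF3 convention); BED
#' half-open 0-based intervals are converted on read.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file. GFF3 rows of
#'   type `gene` are used; the `ID` attribute is the gene id.
#' @return Data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
load_gene_loci <- function(path) {
  gr <- rtracklayer::import(path)  # BED 0-based half-open -> 1-based closed
  meta <- S4Vectors::mcols(gr)
  if (!is.null(meta$type)) gr <- gr[meta$type == "gene"]
  meta <- S4Vectors::mcols(gr)
  ids <- if (!is.null(meta$ID)) as.character(meta$ID)
         else if (!is.null(meta$name)) as.character(meta$name)
         else stop("no gene identifiers (ID/name) in ", path)
  df <- data.frame(gene_id = ids,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$start <= df$end))
  df
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         gene_id = genes$gene_id)
}

#' Normalize QTL and GWAS SNP records into genomic trait features
#'
#' QTL intervals shorter than `qtl_enlarge_below` (single-marker QTLs)
#' are replaced by an interval of `qtl_enlarged_size` centred on the
#' original midpoint; SNPs passing `snp_p_max` become windows of total span
#' `snp_window` centred on the SNP position (set
#' `snp_window_per_side = TRUE` to use `snp_window` on each side instead).
#' All intervals are clamped to chromosome bounds.
#'
#' @param qtls Data.frame (`trait`, `chrom`, `start`, `end`, optional
#'   `map_label`, `feature_id`), or NULL.
#' @param snps Data.frame (`trait`, `chrom`, `pos`, `p`, optional
#'   `feature_id`), or NULL.
#' @param genome Named numeric vector of chromosome lengths.
#' @param qtl_enlarge_below QTLs shorter than this are enlarged (default 5).
#' @param qtl_enlarged_size Enlarged QTL span in bp (default 2e6).
#' @param snp_window Total SNP window span in bp (default 3e5).
#' @param snp_p_max Maximum SNP p-value kept (default 1e-4).
#' @param snp_window_per_side Interpret `snp_window` per flank.
#' @return Data.frame of `GeneticFeature` rows: `feature_id`, `type`
#'   (`QTL` / `GWAS_SNP`), `trait`, `map_label`, `chrom`, `start`, `end`.
#' @export
prepare_features <- function(qtls = NULL, snps = NULL, genome,
                             qtl_enlarge_below = 5, qtl_enlarged_size = 2e6,
                             snp_window = 3e5, snp_p_max = 1e-4,
                             snp_window_per_side = FALSE) {
  out <- list()
  check_chrom <- function(chrom, id) {
    bad <- !(chrom %in% names(genome))
    if (any(bad))
      stop("unknown chromosome '", chrom[bad][1], "' for record '",
           id[bad][1], "'")
  }
  if (!is.null(qtls) && nrow(qtls)) {
    if (is.null(qtls$feature_id))
      qtls$feature_id <- sprintf("QTL%05d", seq_len(nrow(qtls)))
    if (is.null(qtls$map_label)) qtls$map_label <- NA_character_
    check_chrom(qtls$chrom, qtls$feature_id)
    len <- qtls$end - qtls$start + 1
    small <- len < qtl_enlarge_below
    mid <- floor((qtls$start + qtls$end) / 2)
    half <- floor(qtl_enlarged_size / 2)
    qtls$start[small] <- mid[small] - half + 1
    qtls$end[small] <- mid[small] + half
    cl <- unname(genome[qtls$chrom])
    qtls$start <- pmax(1, qtls$start)
    qtls$end <- pmin(cl, qtls$end)
    out$qtl <- data.frame(feature_id = qtls$feature_id, type = "QTL",
                          trait = qtls$trait, map_label = qtls$map_label,
                          chrom = qtls$chrom, start = qtls$start,
                          end = qtls$end, stringsAsFactors = FALSE)
  }
  if (!is.null(snps) && nrow(snps)) {
    if (is.null(snps$feature_id))
      snps$feature_id <- sprintf("SNP%05d", seq_len(nrow(snps)))
    snps <- snps[!is.na(snps$p) & snps$p <= snp_p_max, , drop = FALSE]
    if (nrow(snps)) {
      check_chrom(snps$chrom, snps$feature_id)
      half <- if (snp_window_per_side) snp_window else floor(snp_window / 2)
      start <- snps$pos - half + (if (snp_window_per_side) 0 else 1)
      end <- snps$pos + half
      cl <- unname(genome[snps$chrom])
      out$snp <- data.frame(feature_id = snps$feature_id, type = "GWAS_SNP",
                            trait = snps$trait, map_label = NA_character_,
                            chrom = snps$chrom,
                            start = pmax(1, start), end = pmin(cl, end),
                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_id = character(), type = character(),
                      trait = character(), map_label = character(),
                      chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign traits to genes by interval overlap
#'
#' A gene inherits a feature's trait when their intervals (1-based,
#' inclusive) overlap by at least one base.
#'
#' @param genes Gene loci data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param features `GeneticFeature` data.frame from [prepare_features()].
#' @return Assignment data.frame: `gene_id`, `trait`, `feature_id`, `type`.
#' @export
assign_genes_to_features <- function(genes, features) {
  if (nrow(features) == 0 || nrow(genes) == 0)
    return(data.frame(gene_id = character(), trait = character(),
                      feature_id = character(), type = character()))
  gr_genes <- genes_to_granges(genes)
  gr_feat <- GenomicRanges::GRanges(features$chrom,
                                    IRanges::IRanges(features$start,
                                                     features$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_feat, minoverlap = 1L)
  data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
             trait = features$trait[S4Vectors::subjectHits(hits)],
             feature_id = features$feature_id[S4Vectors::subjectHits(hits)],
             type = features$type[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

trait_overlapping_genes <- function(trait, assignments,
                                    feature_types = c("QTL", "GWAS_SNP"),
                                    min_features = 1L) {
  a <- assignments[assignments$trait == trait &
                     assignments$type %in% feature_types, , drop = FALSE]
  if (nrow(a) == 0) return(list(genes = character(), table = a))
  nfeat <- tapply(a$feature_id, a$gene_id, function(f) length(unique(f)))
  list(genes = names(nfeat)[nfeat >= min_features], table = a)
}

#' Fisher's test of module-trait overlap
#'
#' A module gene "overlaps" the trait when it is assigned at least
#' `min_features` distinct genetic features of that trait (restricted to the
#' allowed feature types). The 2x2 table (in module vs not) x (overlapping
#' vs not) over the background is scored with a one-sided Fisher exact test
#' (hypergeometric upper tail); this p is a false-positive guide, not a
#' causal claim.
#'
#' @param module A `LinkCommunityModule` or character vector of gene ids.
#' @param trait Trait name (opaque string).
#' @param assignments Data.frame from [assign_genes_to_features()].
#' @param background Background gene universe (must contain the module).
#' @param feature_types Allowed feature types (default both).
#' @param min_features Minimum distinct features per overlapping gene.
#' @return A `TraitOverlapResult` list: `module_name`, `trait`,
#'   `feature_types`, `overlapping_genes`, `features_hit`, counts `a`, `b`,
#'   `c`, `d`, and `p`.
#' @export
module_trait_fisher <- function(module, trait, assignments, background,
                                feature_types = c("QTL", "GWAS_SNP"),
                                min_features = 1L) {
  genes <- if (inherits(module, "LinkCommunityModule")) module$genes
           else unique(module)
  name <- if (inherits(module, "LinkCommunityModule") &&
              nzchar(module$module_name)) module$module_name else "module"
  offenders <- setdiff(genes, background)
  if (length(offenders))
    stop("module genes outside the background: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  ov <- trait_overlapping_genes(trait, assignments, feature_types,
                                min_features)
  overlapping <- intersect(ov$genes, background)
  if (nrow(ov$table) == 0)
    warning("trait '", trait, "' absent from assignments")
  a <- length(intersect(genes, overlapping))
  b <- length(genes) - a
  c_ <- length(overlapping) - a
  d <- length(background) - length(genes) - c_
  p <- if (length(overlapping) == 0) 1 else
    stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  feats <- unique(ov$table$feature_id[ov$table$gene_id %in%
                                        intersect(genes, overlapping)])
  structure(list(module_name = name, trait = trait,
                 feature_types = feature_types,
                 min_features = min_features,
                 overlapping_genes = intersect(genes, overlapping),
                 features_hit = feats,
                 a = a, b = b, c = c_, d = d, p = p),
            class = "TraitOverlapResult")
}

#' @export
print.TraitOverlapResult <- function(x, ...) {
  cat(sprintf(
    "TraitOverlapResult %s x '%s': %d/%d module genes overlap %d features, p = %.3g\n",
    x$module_name, x$trait, x$a, x$a + x$b, length(x$features_hit), x$p))
  invisible(x)
}

#' Highlight module edges overlapping a trait's features
#'
#' An edge is highlighted when the union of its two endpoints' assigned
#' features for the trait contains at least `min_features` distinct
#' features. Raising `min_features` can only shrink the highlighted set.
#'
#' @param module A `LinkCommunityModule` (its `edges` are used).
#' @param trait Trait name.
#' @param assignments Data.frame from [assign_genes_to_features()].
#' @param feature_types Allowed feature types.
#' @param min_features Minimum distinct features per edge (default 1).
#' @return List with data.frames `highlighted` and `other`, partitioning the
#'   module's edges; `highlighted` carries an `n_features` column.
#' @export
filter_edges_by_trait <- function(module, trait, assignments,
                                  feature_types = c("QTL", "GWAS_SNP"),
                                  min_features = 1L) {
  e <- module$edges
  a <- assignments[assignments$trait == trait &
                     assignments$type %in% feature_types, , drop = FALSE]
  feats_of <- split(a$feature_id, a$gene_id)
  n_features <- vapply(seq_len(nrow(e)), function(i) {
    length(unique(c(feats_of[[e$gene_a[i]]], feats_of[[e$gene_b[i]]])))
  }, integer(1))
  hi <- n_features >= min_features
  highlighted <- e[hi, , drop = FALSE]
  highlighted$n_features <- n_features[hi]
  rownames(highlighted) <- NULL
  other <- e[!hi, , drop = FALSE]
  rownames(other) <- NULL
  list(highlighted = highlighted, other = other)
}

#' Nominate proximal biomarker SNPs for a trait-overlapping module
#'
#' Returns every known SNP lying within `window` bp of the interval of any
#' module gene that overlaps the trait's genetic features (distance 0 when
#' the SNP falls inside the gene), deduplicated and sorted by chromosome
#' then position.
#'
#' @param module A `LinkCommunityModule` or gene id vector.
#' @param trait Trait name.
#' @param assignments Data.frame from [assign_genes_to_features()].
#' @param snp_positions Data.frame (`snp_id`, `chrom`, `pos`) of known SNPs.
#' @param genes Gene loci data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param window Maximum distance in bp (default 5e4).
#' @param feature_types,min_features Passed to the overlap definition.
#' @return Data.frame of candidate SNPs: `snp_id`, `chrom`, `pos`.
#' @export
biomarker_snps <- function(module, trait, assignments, snp_positions, genes,
                           window = 5e4,
                           feature_types = c("QTL", "GWAS_SNP"),
                           min_features = 1L) {
  mod_genes <- if (inherits(module, "LinkCommunityModule")) module$genes
               else unique(module)
  if (anyDuplicated(snp_positions$snp_id))
    stop("duplicate SNP ids in snp_positions")
  ov <- trait_overlapping_genes(trait, assignments, feature_types,
                                min_features)
  target <- genes[genes$gene_id %in% intersect(mod_genes, ov$genes), ,
                  drop = FALSE]
  if (nrow(target) == 0 || nrow(snp_positions) == 0)
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer()))
  gr_target <- GenomicRanges::GRanges(
    target$chrom,
    IRanges::IRanges(pmax(1, target$start - window), target$end + window))
  gr_snp <- GenomicRanges::GRanges(snp_positions$chrom,
                                   IRanges::IRanges(snp_positions$pos,
                                                    snp_positions$pos))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_target)
  res <- snp_positions[unique(S4Vectors::queryHits(hits)), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), c("snp_id", "chrom", "pos")]
  rownames(res) <- NULL
  res
}
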