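#' Read a flat annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `source` (GO / InterPro / KEGG / phenotype) and `label`.
#' @return Annotation data.frame with unique (gene, term) pairs.
#' @export
load_annotations <- function(path) {
  ann <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% colnames(ann)))
    stop("annotation table needs columns 'gene_id' and 'term_id'")
  if (!"source" %in% colnames(ann)) ann$source <- "GO"
  if (!"label" %in% colnames(ann)) ann$label <- ann$term_id
  ann[!duplicated(ann[, c("gene_id", "term_id")]), , drop = FALSE]
}

#' Fisher's exact term over-representation in a gene set
#'
#' For every annotation term with at least one annotated gene in the module,
#' tests the 2x2 table (in module vs not) x (has term vs not) against the
#' genomic background with a one-sided (enrichment) Fisher exact test, i.e.
#' the hypergeometric upper tail. Raw p-values below `alpha` are reported
#' (no multiple-testing cutoff, but a Benjamini-Hochberg column is included
#' for information).
#'
#' @param module_genes Character vector of module gene ids (must be a subset
#'   of the background).
#' @param ann Annotation data.frame (`gene_id`, `term_id`, optional `source`,
#'   `label`).
#' @param background Background gene universe; default: all genes with at
#'   least one annotation in `ann`.
#' @param alpha Raw p-value cutoff (default 0.01).
#' @return Data.frame of enriched terms sorted by ascending p: `term_id`,
#'   `source`, `label`, `k` (module genes with term), `n` (module size),
#'   `K` (background genes with term), `N` (background size), `p`, `bh`.
#' @export
fisher_enrichment <- function(module_genes, ann, background = NULL,
                              alpha = 0.01) {
  if (is.null(background)) background <- unique(ann$gene_id)
  module_genes <- unique(module_genes)
  offenders <- setdiff(module_genes, background)
  if (length(offenders))
    stop("module genes outside the background: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(module_genes)
  terms <- split(ann$gene_id, ann$term_id)
  k <- vapply(terms, function(g) sum(g %in% module_genes), integer(1))
  K <- lengths(terms)
  keep <- k >= 1
  if (!any(keep))
    return(data.frame(term_id = character(), source = character(),
                      label = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      bh = numeric()))
  k <- k[keep]; K <- K[keep]
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  meta <- ann[!duplicated(ann$term_id), c("term_id", "source", "label")]
  res <- data.frame(term_id = names(k), stringsAsFactors = FALSE)
  res <- merge(res, meta, by = "term_id", sort = FALSE)
  res$k <- k[res$term_id]; res$n <- n
  res$K <- K[res$term_id]; res$N <- N
  res$p <- p[res$term_id]
  res$bh <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$p < alpha, , drop = FALSE]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enrich every module of a collection
#'
#' @param modules Named list of `LinkCommunityModule` objects (or plain gene
#'   sets).
#' @param ann Annotation data.frame.
#' @param background Background universe (default: annotated genes).
#' @param alpha Raw p cutoff (default 0.01).
#' @return Named list (by module) of enrichment data.frames.
#' @export
enrich_modules <- function(modules, ann, background = NULL, alpha = 0.01) {
  if (is.null(background)) background <- unique(ann$gene_id)
  lapply(modules, function(m) {
    genes <- if (inherits(m, "LinkCommunityModule")) m$genes else m
    fisher_enrichment(intersect(genes, background), ann,
                      background = background, alpha = alpha)
  })
}
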