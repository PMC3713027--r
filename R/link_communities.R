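#' Similarity between two adjacent edges
#'
#' For edges e1 = (i, k) and e2 = (j, k) sharing exactly one node k, the
#' similarity is the Jaccard index of the closed neighbourhoods of the
#' non-shared endpoints: S = |n+(i) n n+(j)| / |n+(i) u n+(j)| with
#' n+(x) = x together with its neighbours. Similarity is undefined for
#' non-adjacent edge pairs (they are simply never merged directly).
#'
#' @param net A `GILNetwork`.
#' @param e1,e2 Length-2 character vectors naming the edge endpoints.
#' @return Similarity in \[0, 1\].
#' @export
edge_similarity <- function(net, e1, e2) {
  shared <- intersect(e1, e2)
  if (length(shared) != 1)
    stop("edges must share exactly one node")
  i <- setdiff(e1, shared); j <- setdiff(e2, shared)
  nb <- edge_adjacency_sets(net)
  ni <- c(i, nb[[i]]); nj <- c(j, nb[[j]])
  length(intersect(ni, nj)) / length(union(ni, nj))
}

# closed-neighbourhood building block: named list node -> neighbours
edge_adjacency_sets <- function(net) {
  e <- net$edges
  split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
}

#' Partition density of an edge partition
#'
#' D = (2/M) * sum_c m_c (m_c - (n_c - 1)) / ((n_c - 2)(n_c - 1)) over edge
#' communities c with m_c edges and n_c induced nodes; communities with two
#' nodes (single edges, trees of one link) contribute 0. D is 1 when every
#' community is a clique and 0 when every edge sits alone.
#'
#' @param net A `GILNetwork` (or anything with an `edges` data.frame).
#' @param membership Integer/character vector, one community label per edge
#'   (in `net$edges` row order), covering all edges.
#' @return Partition density D.
#' @export
partition_density <- function(net, membership) {
  e <- net$edges
  M <- nrow(e)
  if (M == 0 || length(membership) != M)
    stop("membership must label every edge of a non-empty network")
  contrib <- vapply(split(seq_len(M), membership), function(rows) {
    m_c <- length(rows)
    n_c <- length(unique(c(e$gene_a[rows], e$gene_b[rows])))
    if (n_c <= 2) return(0)
    m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))
  }, numeric(1))
  2 / M * sum(contrib)
}

# Dense single-linkage dendrogram over edges: dissimilarity 1 - S for
# adjacent edge pairs, 1 otherwise. Exact, suitable for the network sizes
# this package targets (a guard refuses matrices that would not fit).
edge_dendrogram <- function(net, max_edges = 20000L) {
  e <- net$edges
  M <- nrow(e)
  if (M > max_edges)
    stop("network has ", M, " edges; raise max_edges to cluster it densely")
  nodes <- net$nodes
  a <- match(e$gene_a, nodes); b <- match(e$gene_b, nodes)
  # neighbour index sets per node (by node index)
  nb <- vector("list", length(nodes))
  for (k in seq_len(M)) {
    nb[[a[k]]] <- c(nb[[a[k]]], b[k])
    nb[[b[k]]] <- c(nb[[b[k]]], a[k])
  }
  closed <- lapply(seq_along(nodes), function(i) c(i, nb[[i]]))
  sizes <- lengths(closed)
  d <- matrix(1, M, M)
  inc <- split(rep(seq_len(M), 2L), factor(c(a, b), levels = seq_along(nodes)))
  for (node in seq_along(nodes)) {
    es <- inc[[node]]
    if (length(es) < 2) next
    for (x in seq_len(length(es) - 1)) {
      for (y in seq((x + 1), length(es))) {
        e1 <- es[x]; e2 <- es[y]
        i <- if (a[e1] == node) b[e1] else a[e1]
        j <- if (a[e2] == node) b[e2] else a[e2]
        inter <- length(intersect(closed[[i]], closed[[j]]))
        s <- inter / (sizes[i] + sizes[j] - inter)
        dd <- 1 - s
        if (dd < d[e1, e2]) { d[e1, e2] <- dd; d[e2, e1] <- dd }
      }
    }
  }
  stats::hclust(stats::as.dist(d), method = "single")
}

#' Detect overlapping link-community modules
#'
#' Clusters the network's edges by single-linkage on adjacent-edge
#' similarity, cuts the dendrogram at the height maximizing the partition
#' density (ties broken toward the lowest height, i.e. the finest
#' partition), and reports every edge cluster with at least `min_edges`
#' edges as a module. Because communities are sets of edges, a gene may
#' belong to several modules; no edge belongs to more than one.
#'
#' @param net A `GILNetwork`.
#' @param min_edges Minimum edges per reported module (default 2).
#' @return List of `LinkCommunityModule` objects (fields `module_name` --
#'   empty until [name_modules()] -- `edges`, `genes`, `gil_id`), with
#'   attributes `cut_height`, `partition_density`, `profile` (data.frame of
#'   candidate heights and their D).
#' @export
detect_link_communities <- function(net, min_edges = 2L) {
  M <- nrow(net$edges)
  if (M == 0) return(list())
  if (M == 1) {
    # a single edge is an unclustered singleton under min_edges = 2
    if (min_edges <= 1) {
      mod <- new_module(net, 1L)
      return(structure(list(mod), cut_height = 0, partition_density = 0,
                       profile = data.frame(height = 0, D = 0)))
    }
    return(structure(list(), cut_height = 0, partition_density = 0,
                     profile = data.frame(height = 0, D = 0)))
  }
  hc <- edge_dendrogram(net)
  heights <- sort(unique(c(0, hc$height[hc$height < 1])))
  profile <- data.frame(height = heights, D = NA_real_)
  best <- NULL
  for (hi in seq_along(heights)) {
    mem <- stats::cutree(hc, h = heights[hi])
    D <- partition_density(net, mem)
    profile$D[hi] <- D
    if (is.null(best) || D > best$D + 1e-12) best <- list(D = D, mem = mem,
                                                          h = heights[hi])
  }
  mem <- best$mem
  keep_groups <- names(which(table(mem) >= min_edges))
  mods <- lapply(keep_groups, function(g) new_module(net, which(mem == g)))
  # deterministic order: descending edge count, ties by smallest gene id
  ord <- order(-vapply(mods, function(m) nrow(m$edges), integer(1)),
               vapply(mods, function(m) min(m$genes), character(1)))
  structure(mods[ord], cut_height = best$h, partition_density = best$D,
            profile = profile)
}

new_module <- function(net, edge_rows) {
  e <- net$edges[edge_rows, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(module_name = "", edges = e,
                 genes = sort(unique(c(e$gene_a, e$gene_b))),
                 gil_id = net$gil_id),
            class = "LinkCommunityModule")
}

#' @export
print.LinkCommunityModule <- function(x, ...) {
  cat(sprintf("LinkCommunityModule %s: %d genes, %d edges (GIL %s)\n",
              if (nzchar(x$module_name)) x$module_name else "<unnamed>",
              length(x$genes), nrow(x$edges), x$gil_id))
  invisible(x)
}

#' Name modules by the collection naming schema
#'
#' Names follow `{collection_tag}_{gil_id}_LCM{nnnn}` with a 1-based,
#' zero-padded index in the deterministic module order (descending edge
#' count, ties by lexicographically smallest gene id).
#'
#' @param collection_tag Collection label, e.g. `"OsK25v1.0"`.
#' @param gil_id Network identifier, e.g. `"G0011"`.
#' @param modules List of `LinkCommunityModule` objects.
#' @return The modules with `module_name` filled in, as a named list.
#' @export
name_modules <- function(collection_tag, gil_id, modules) {
  ord <- order(-vapply(modules, function(m) nrow(m$edges), integer(1)),
               vapply(modules, function(m) min(m$genes), character(1)))
  modules <- modules[ord]
  for (i in seq_along(modules))
    modules[[i]]$module_name <- sprintf("%s_%s_LCM%04d", collection_tag,
                                        gil_id, i)
  stats::setNames(modules,
                  vapply(modules, `[[`, character(1), "module_name"))
}

#' Export modules as a (module, gene) TSV
#' @param modules Named list of `LinkCommunityModule` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- do.call(rbind, lapply(modules, function(m)
    data.frame(module_name = m$module_name, gene_id = m$genes,
               stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(module_name = character(),
                                    gene_id = character())
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
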