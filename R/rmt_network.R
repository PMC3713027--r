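#' All-pairs Pearson similarity matrix
#'
#' Correlates every pair of probes (or genes, after collapsing) across the
#' samples of one group. Zero-variance probes cannot be correlated and are
#' dropped with a warning.
#'
#' @param m An [ExpressionMatrix] with at least 3 samples.
#' @return A `SimilarityMatrix` list: `r` (symmetric correlation matrix with
#'   unit diagonal), `ids`, `n_samples`.
#' @export
correlation_matrix <- function(m) {
  v <- m$values
  if (nrow(v) < 3) stop("need at least 3 samples for correlation")
  vars <- apply(v, 2, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance probes dropped")
    v <- v[, vars > 0, drop = FALSE]
  }
  r <- stats::cor(v)
  diag(r) <- 1
  structure(list(r = r, ids = colnames(v), n_samples = nrow(v)),
            class = "SimilarityMatrix")
}

#' Collapse probes to one value per gene
#'
#' Where several single-locus probes interrogate the same gene, the probe
#' with the highest mean intensity is kept and renamed to the gene id, so
#' that network nodes are genes.
#'
#' @param m An [ExpressionMatrix] of single-locus probes.
#' @param map Probe map data.frame (`probe_id`, `gene_id`).
#' @return An [ExpressionMatrix] whose columns are gene ids.
#' @export
collapse_probes_to_genes <- function(m, map) {
  probes <- probe_ids(m)
  map <- map[map$probe_id %in% probes, , drop = FALSE]
  multi <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(multi))
    stop("ambiguous probes must be filtered before collapsing: ",
         paste(utils::head(multi, 3), collapse = ", "))
  missing <- setdiff(probes, map$probe_id)
  if (length(missing))
    stop("probes absent from map: ", paste(utils::head(missing, 3), collapse = ", "))
  gene_of <- stats::setNames(map$gene_id, map$probe_id)[probes]
  means <- colMeans(m$values)
  ord <- order(-means)  # highest mean first within each gene
  keep_probe <- probes[ord][!duplicated(gene_of[ord])]
  keep_probe <- keep_probe[order(match(keep_probe, probes))]
  v <- m$values[, keep_probe, drop = FALSE]
  colnames(v) <- unname(gene_of[keep_probe])
  ExpressionMatrix(v, m$metadata)
}

# ---- nearest-neighbour spacing machinery -----------------------------------

#' Chi-square statistic of spacings against the Poisson (exponential) law
#'
#' Bins unit-mean spacings on \[0, 3\] (spacings above 3 pooled into the last
#' bin) and compares observed counts with the counts expected under the
#' exponential density e^(-s), the nearest-neighbour spacing law of a
#' non-random (modular) spectrum.
#'
#' @param spacings Numeric vector of spacings; rescaled to mean 1 internally.
#' @param n_bins Number of histogram bins on \[0, 3\] (default 60).
#' @return The chi-square statistic (df = `n_bins` - 1 under the null).
#' @export
poisson_spacing_statistic <- function(spacings, n_bins = 60L) {
  spacings <- spacings[is.finite(spacings)]
  if (length(spacings) < 2) stop("need at least 2 spacings")
  s <- spacings / mean(spacings)
  breaks <- seq(0, 3, length.out = n_bins + 1L)
  idx <- pmin(findInterval(s, breaks, rightmost.closed = TRUE), n_bins)
  idx[s >= 3] <- n_bins  # pool the tail
  obs <- tabulate(idx, nbins = n_bins)
  p <- exp(-breaks[-length(breaks)]) - exp(-breaks[-1])
  p[n_bins] <- p[n_bins] + exp(-3)  # pooled tail mass
  expd <- length(s) * p
  sum((obs - expd)^2 / expd)
}

#' Unfold a spectrum to unit mean spacing
#'
#' Maps eigenvalues through a smooth monotone cubic spline fit to the
#' empirical cumulative spectral function, so that local fluctuations in
#' spacing are measured against the local eigenvalue density. Knots are
#' placed at every `knot_every`-th distinct eigenvalue (at least
#' `min_knots`). Eigenvalues closer than `dedup_tol` are collapsed first;
#' exact degeneracies otherwise spike the spacing distribution at zero.
#'
#' @param eigenvalues Numeric vector (any order).
#' @param knot_every Spline knot spacing in eigenvalue rank (default 10).
#' @param min_knots Minimum number of knots (default 5).
#' @param dedup_tol Collapse eigenvalues closer than this (default 1e-6).
#' @return Sorted vector of unfolded eigenvalues (mean spacing 1).
#' @export
unfold_eigenvalues <- function(eigenvalues, knot_every = 10L, min_knots = 5L,
                               dedup_tol = 1e-6) {
  ev <- sort(eigenvalues)
  keep <- c(TRUE, diff(ev) > dedup_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < min_knots + 1L) stop("too few distinct eigenvalues to unfold")
  n_knots <- max(min_knots, ceiling(n / knot_every))
  kidx <- unique(round(seq(1, n, length.out = n_knots)))
  cdf <- (seq_len(n) - 0.5) / n
  sp <- stats::splinefun(ev[kidx], cdf[kidx], method = "hyman")
  unfolded <- n * sp(ev)
  d <- diff(unfolded)
  d <- d / mean(d)
  cumsum(c(0, d))
}

#' NNSD chi-square statistic of a spectrum
#'
#' Deduplicates and unfolds the eigenvalues, then scores the
#' nearest-neighbour spacing distribution against the Poisson law with
#' [poisson_spacing_statistic()]. Errors with condition class
#' `gilnet_too_few_genes` when fewer than `min_eigenvalues` distinct
#' eigenvalues remain.
#'
#' @param eigenvalues Numeric vector of eigenvalues.
#' @param n_bins Histogram bins (default 60).
#' @param min_eigenvalues Minimum distinct eigenvalues (default 100).
#' @param dedup_tol Degeneracy tolerance (default 1e-6).
#' @return Chi-square statistic.
#' @export
nnsd_chi_square <- function(eigenvalues, n_bins = 60L, min_eigenvalues = 100L,
                            dedup_tol = 1e-6) {
  ev <- sort(eigenvalues)
  ev <- ev[c(TRUE, diff(ev) > dedup_tol)]
  if (length(ev) < min_eigenvalues)
    stop(structure(class = c("gilnet_too_few_genes", "error", "condition"),
                   list(message = sprintf(
                     "only %d distinct eigenvalues (< %d)",
                     length(ev), min_eigenvalues), call = sys.call())))
  unfolded <- unfold_eigenvalues(ev, dedup_tol = dedup_tol)
  poisson_spacing_statistic(diff(unfolded), n_bins = n_bins)
}

# Threshold the similarity matrix at t and keep genes with >= 1 surviving
# off-diagonal entry. Returns the reduced matrix (unit diagonal) or NULL.
threshold_matrix <- function(r, t, signed = FALSE) {
  a <- r
  mask <- if (signed) a < t else abs(a) < t
  a[mask] <- 0
  diag(a) <- 1
  keep <- rowSums(a != 0) > 1  # diagonal always non-zero
  if (!any(keep)) return(NULL)
  a[keep, keep, drop = FALSE]
}

#' Scan for the RMT threshold of a similarity matrix
#'
#' Raises the correlation cutoff from `t_start` in `t_step` increments; at
#' each cutoff, entries below it are zeroed, genes with no surviving
#' off-diagonal entry are dropped, and the eigenvalue NNSD of the surviving
#' matrix is tested against the Poisson law. The chosen threshold is the
#' smallest cutoff (after `refine_step` refinement between the last
#' rejecting and first accepting coarse cutoffs) at which the chi-square
#' statistic falls at or below the critical value at significance `p`. The
#' scan fails as a data outcome (not an error) when no cutoff accepts before
#' the grid is exhausted or the surviving genes drop below
#' `min_eigenvalues`.
#'
#' @param s A `SimilarityMatrix` from [correlation_matrix()].
#' @param t_start,t_step,refine_step Scan grid (defaults 0.50, 0.01, 0.001).
#' @param p Significance level of the NNSD chi-square test (default 0.001).
#' @param n_bins Histogram bins for the NNSD test (default 60).
#' @param min_eigenvalues Minimum surviving genes for a testable NNSD
#'   (default 100).
#' @param signed Threshold signed correlations instead of absolute values.
#' @return An `RMTScanResult` list: `threshold` (chosen cutoff or `NA`),
#'   `success`, `reason` (`NA`, `"no_threshold_found"` or `"too_few_genes"`),
#'   `scan` (data.frame of t, surviving genes, distinct eigenvalues,
#'   chi-square, decision), `critical_value`, `p`.
#' @export
find_rmt_threshold <- function(s, t_start = 0.50, t_step = 0.01,
                               refine_step = 0.001, p = 0.001, n_bins = 60L,
                               min_eigenvalues = 100L, signed = FALSE) {
  crit <- stats::qchisq(1 - p, df = n_bins - 1)
  scan <- data.frame(t = numeric(), n_genes = integer(),
                     n_eigenvalues = integer(), chi2 = numeric(),
                     decision = character())
  eval_t <- function(t) {
    a <- threshold_matrix(s$r, t, signed = signed)
    n_genes <- if (is.null(a)) 0L else nrow(a)
    if (is.null(a) || n_genes < min_eigenvalues)
      return(list(t = t, n_genes = n_genes, n_eigenvalues = n_genes,
                  chi2 = NA_real_, decision = "too_few_genes"))
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(ev)
    ev <- ev[c(TRUE, diff(ev) > 1e-6)]
    if (length(ev) < min_eigenvalues)
      return(list(t = t, n_genes = n_genes, n_eigenvalues = length(ev),
                  chi2 = NA_real_, decision = "too_few_genes"))
    chi2 <- poisson_spacing_statistic(diff(unfold_eigenvalues(ev)),
                                      n_bins = n_bins)
    list(t = t, n_genes = n_genes, n_eigenvalues = length(ev), chi2 = chi2,
         decision = if (chi2 <= crit) "accept" else "reject")
  }
  add <- function(rec) {
    scan[nrow(scan) + 1L, ] <<- rec[c("t", "n_genes", "n_eigenvalues",
                                      "chi2", "decision")]
    rec
  }
  finish <- function(threshold, reason) {
    structure(list(threshold = threshold, success = !is.na(threshold),
                   reason = reason, scan = scan, critical_value = crit,
                   p = p), class = "RMTScanResult")
  }

  ts <- seq(t_start, 0.99 + 1e-9, by = t_step)
  had_enough <- FALSE
  prev_t <- NA_real_
  for (t in ts) {
    rec <- add(eval_t(t))
    if (rec$decision == "too_few_genes") {
      return(finish(NA_real_,
                    if (had_enough) "too_few_genes" else "no_threshold_found"))
    }
    had_enough <- TRUE
    if (rec$decision == "accept") {
      chosen <- t
      if (!is.na(prev_t) && refine_step > 0 && refine_step < t_step) {
        for (rt in seq(prev_t + refine_step, t - refine_step / 2,
                       by = refine_step)) {
          rrec <- add(eval_t(rt))
          if (rrec$decision == "accept") { chosen <- rt; break }
          if (rrec$decision == "too_few_genes") break
        }
      }
      return(finish(chosen, NA_character_))
    }
    prev_t <- t
  }
  finish(NA_real_, if (had_enough) "no_threshold_found" else "no_threshold_found")
}

#' Extract the thresholded co-expression network
#'
#' Builds the graph whose edges are the gene pairs with correlation
#' magnitude at or above the threshold (the correlation sign is kept on the
#' edge). Genes left without any edge are excluded from the node set. When
#' `map` is supplied, probe ids are relabelled to their single gene locus
#' first.
#'
#' @param s A `SimilarityMatrix`.
#' @param t Threshold in (0, 1).
#' @param map Optional probe map for relabelling probe ids to genes.
#' @param gil_id Network identifier (e.g. `"G0002"`).
#' @param signed Keep only correlations >= t instead of |r| >= t.
#' @return A `GILNetwork` list: `gil_id`, `nodes`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `r`, `abs_r`), `threshold`, `n_samples`.
#' @export
build_network <- function(s, t, map = NULL, gil_id = "G0001", signed = FALSE) {
  if (!(t > 0 && t < 1)) stop("threshold must be in (0,1)")
  ids <- s$ids
  if (!is.null(map)) {
    mm <- map[map$probe_id %in% ids, , drop = FALSE]
    multi <- unique(mm$probe_id[duplicated(mm$probe_id)])
    if (length(multi)) stop("ambiguous probes in map: collapse first")
    gene_of <- stats::setNames(mm$gene_id, mm$probe_id)
    ids <- ifelse(ids %in% names(gene_of), unname(gene_of[ids]), ids)
    if (anyDuplicated(ids))
      stop("multiple probes map to one gene: run collapse_probes_to_genes first")
  }
  r <- s$r
  sel <- if (signed) r >= t else abs(r) >= t
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no edge survives threshold ", t, ": empty network")
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), abs_r = numeric())
  } else {
    a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    rv <- r[idx]
    o <- order(a, b)
    edges <- data.frame(gene_a = a[o], gene_b = b[o], r = rv[o],
                        abs_r = abs(rv[o]), stringsAsFactors = FALSE)
  }
  structure(list(gil_id = gil_id,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, threshold = t, n_samples = s$n_samples),
            class = "GILNetwork")
}

#' @export
print.GILNetwork <- function(x, ...) {
  cat(sprintf("GILNetwork %s: %d nodes, %d edges, threshold %.3f\n",
              x$gil_id, length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Convert a GILNetwork to an igraph graph
#' @param net A `GILNetwork`.
#' @return An undirected `igraph` graph with edge attributes `r`, `abs_r`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Per-network summary statistics
#'
#' @param net A `GILNetwork`.
#' @return List with node count `n_nodes`, edge count `n_edges`, average
#'   degree `avg_degree` = 2E/N rounded to 2 decimals, and the degree
#'   distribution table.
#' @export
network_summary <- function(net) {
  N <- length(net$nodes); E <- nrow(net$edges)
  if (N == 0)
    return(list(n_nodes = 0L, n_edges = 0L, avg_degree = 0,
                degree_distribution = table(integer())))
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  list(n_nodes = N, n_edges = E, avg_degree = round(2 * E / N, 2),
       degree_distribution = table(as.integer(deg)))
}

#' Node and edge redundancy across a network collection
#'
#' Counts how many networks each gene (and each gene pair) appears in.
#' Node fractions are relative to the number of distinct genes; edge
#' fractions are relative to the summed edge count over networks, matching
#' the convention in which per-layer edges are the units.
#'
#' @param nets List of `GILNetwork` objects.
#' @return List with `node_multiplicity` and `edge_multiplicity` data.frames
#'   (multiplicity, count, percent), `distinct_nodes`, `total_edges`.
#' @export
collection_summary <- function(nets) {
  if (length(nets) == 0) stop("need at least one network")
  node_lists <- lapply(nets, `[[`, "nodes")
  edge_keys <- lapply(nets, function(n)
    paste(n$edges$gene_a, n$edges$gene_b, sep = "\r"))
  node_mult <- table(table(unlist(node_lists)))
  edge_mult <- table(table(unlist(edge_keys)))
  distinct_nodes <- length(unique(unlist(node_lists)))
  total_edges <- sum(lengths(edge_keys))
  nm <- data.frame(multiplicity = as.integer(names(node_mult)),
                   count = as.integer(node_mult))
  nm$percent <- round(100 * nm$count / distinct_nodes)
  em <- data.frame(multiplicity = as.integer(names(edge_mult)),
                   count = as.integer(edge_mult))
  em$percent <- round(100 * em$count / max(total_edges, 1))
  list(node_multiplicity = nm, edge_multiplicity = em,
       distinct_nodes = distinct_nodes, total_edges = total_edges)
}

#' Write a network as a TSV edge list
#' @param net A `GILNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  data.table::fwrite(net$edges, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#' @param net A `GILNetwork`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
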