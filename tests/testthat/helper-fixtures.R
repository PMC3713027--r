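# Shared fixture builders and independent oracles.

# samples x genes matrix of planted correlation blocks over iid noise
make_block_matrix <- function(seed, n_blocks = 20L, block = 30L,
                              n_samples = 40L, rho = 0.95, noise_sd = 0.1,
                              n_noise_genes = 0L) {
  set.seed(seed)
  n_genes <- n_blocks * block + n_noise_genes
  v <- matrix(rnorm(n_samples * n_genes, 0, noise_sd), n_samples, n_genes)
  loading <- noise_sd * sqrt(rho / (1 - rho))
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * block + 1L):(b * block)
    v[, cols] <- v[, cols] + loading * rnorm(n_samples)
  }
  colnames(v) <- sprintf("g%04d", seq_len(n_genes))
  rownames(v) <- sprintf("s%03d", seq_len(n_samples))
  ExpressionMatrix(v)
}

block_gene_sets <- function(n_blocks = 20L, block = 30L) {
  lapply(seq_len(n_blocks), function(b)
    sprintf("g%04d", ((b - 1L) * block + 1L):(b * block)))
}

# GILNetwork from a bare edge list (unit weights unless given)
make_net <- function(a, b, r = NULL, gil_id = "G0001", threshold = 0.5) {
  if (is.null(r)) r <- rep(1, length(a))
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order(a, b)
  edges <- data.frame(gene_a = a[o], gene_b = b[o], r = r[o],
                      abs_r = abs(r[o]), stringsAsFactors = FALSE)
  structure(list(gil_id = gil_id, nodes = sort(unique(c(a, b))),
                 edges = edges, threshold = threshold, n_samples = NA_integer_),
            class = "GILNetwork")
}

# random connected-ish simple graph with at most max_edges edges
rand_graph <- function(seed, n_nodes = 10L, n_edges = 20L) {
  set.seed(seed)
  pairs <- t(combn(sprintf("n%02d", seq_len(n_nodes)), 2))
  sel <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  make_net(pairs[sel, 1], pairs[sel, 2])
}

# independent hypergeometric upper-tail oracle by direct log-space summation
hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  if (length(xs) == 0 || k > min(K, n)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# brute-force two-pass Pearson correlation
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force closed-neighbourhood similarity of two adjacent edges
brute_edge_similarity <- function(edges, e1, e2) {
  nbh <- function(x) {
    n <- c(edges$gene_b[edges$gene_a == x], edges$gene_a[edges$gene_b == x])
    unique(c(x, n))
  }
  shared <- intersect(e1, e2)
  i <- setdiff(e1, shared); j <- setdiff(e2, shared)
  length(intersect(nbh(i), nbh(j))) / length(union(nbh(i), nbh(j)))
}

# brute-force partition density from the defining formula
brute_partition_density <- function(edges, membership) {
  M <- nrow(edges)
  total <- 0
  for (g in unique(membership)) {
    rows <- which(membership == g)
    m_c <- length(rows)
    n_c <- length(unique(c(edges$gene_a[rows], edges$gene_b[rows])))
    if (n_c > 2)
      total <- total + m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))
  }
  2 / M * total
}

# Independent max-partition-density oracle: single-linkage clusters at cut
# height h are the connected components of the graph on edges linked when
# their dissimilarity (1 - brute-force similarity) is <= h.
oracle_best_partition_density <- function(net) {
  e <- net$edges
  M <- nrow(e)
  sims <- c()
  links <- list()
  for (x in seq_len(M - 1)) for (y in (x + 1):M) {
    e1 <- c(e$gene_a[x], e$gene_b[x]); e2 <- c(e$gene_a[y], e$gene_b[y])
    if (length(intersect(e1, e2)) == 1) {
      s <- brute_edge_similarity(e, e1, e2)
      sims <- c(sims, s)
      links[[length(links) + 1L]] <- c(x, y, s)
    }
  }
  heights <- sort(unique(c(0, 1 - sims)))
  heights <- heights[heights < 1]
  best <- 0
  lk <- do.call(rbind, links)
  for (h in heights) {
    g <- igraph::make_empty_graph(n = M, directed = FALSE)
    if (!is.null(lk)) {
      keep <- (1 - lk[, 3]) <= h
      if (any(keep))
        g <- igraph::add_edges(g, t(lk[keep, 1:2, drop = FALSE]))
    }
    mem <- igraph::components(g)$membership
    best <- max(best, brute_partition_density(e, mem))
  }
  best
}

expr_from <- function(v) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("s%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("p%02d", seq_len(ncol(v)))
  ExpressionMatrix(v)
}
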