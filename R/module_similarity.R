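#' Jaccard index of two gene sets
#'
#' @param a,b Non-empty character vectors.
#' @return |a n b| / |a u b| in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty set")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Cohen's kappa between two term sets over a universe
#'
#' Treats each set as a binary presence vector over the term universe and
#' computes chance-corrected agreement: kappa = (P_o - P_e) / (1 - P_e)
#' with P_o the observed agreement (co-presence + co-absence) and P_e the
#' agreement expected from the marginal presence rates. kappa is 1 for
#' identical vectors (including the degenerate P_e = 1 case) and negative
#' for systematic disagreement.
#'
#' @param terms_a,terms_b Term sets (subsets of `universe`).
#' @param universe Term universe (>= 2 terms).
#' @return kappa in \[-1, 1\].
#' @export
kappa_score <- function(terms_a, terms_b, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N < 2) stop("universe must contain at least 2 terms")
  extra <- setdiff(union(terms_a, terms_b), universe)
  if (length(extra))
    stop("terms outside the universe: ", paste(utils::head(extra, 5),
                                               collapse = ", "))
  va <- universe %in% terms_a
  vb <- universe %in% terms_b
  n11 <- sum(va & vb); n10 <- sum(va & !vb)
  n01 <- sum(!va & vb); n00 <- sum(!va & !vb)
  po <- (n11 + n00) / N
  pe <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / N^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    return(if (identical(va, vb)) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Pairwise module co-similarity scores
#'
#' For every unordered pair of modules with at least `size_min` genes,
#' computes the Jaccard index of their gene sets and Cohen's kappa of their
#' enriched-term sets. The kappa universe is, by default, the union of terms
#' enriched in at least one module of the whole collection
#' (`universe = "collection"`); `universe = "pairwise"` restricts it to the
#' union of terms enriched in either member of the pair. Modules with no
#' enriched terms get `NA` kappa (they stay in the table for Jaccard).
#'
#' @param modules Named list of `LinkCommunityModule` objects.
#' @param enriched Named list (same names) of enrichment data.frames from
#'   [enrich_modules()].
#' @param size_min Minimum module size in genes (default 30).
#' @param universe `"collection"` (default) or `"pairwise"`.
#' @return Data.frame with columns `module_a`, `module_b`, `jaccard`,
#'   `kappa`, `same_gil`.
#' @export
pairwise_scores <- function(modules, enriched, size_min = 30L,
                            universe = c("collection", "pairwise")) {
  universe <- match.arg(universe)
  sizes <- vapply(modules, function(m) length(m$genes), integer(1))
  qualifying <- names(modules)[sizes >= size_min]
  empty <- data.frame(module_a = character(), module_b = character(),
                      jaccard = numeric(), kappa = numeric(),
                      same_gil = logical())
  if (length(qualifying) < 2) {
    warning("fewer than 2 modules with >= ", size_min, " genes")
    return(empty)
  }
  term_sets <- lapply(enriched[qualifying], function(e)
    if (is.null(e) || nrow(e) == 0) character() else e$term_id)
  coll_universe <- unique(unlist(lapply(enriched, function(e)
    if (is.null(e) || nrow(e) == 0) character() else e$term_id)))
  pairs <- utils::combn(qualifying, 2)
  res <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    ma <- pairs[1, i]; mb <- pairs[2, i]
    ta <- term_sets[[ma]]; tb <- term_sets[[mb]]
    uni <- if (universe == "collection") coll_universe else union(ta, tb)
    kap <- if (length(ta) == 0 || length(tb) == 0 || length(uni) < 2)
      NA_real_ else kappa_score(ta, tb, uni)
    res[[i]] <- data.frame(
      module_a = ma, module_b = mb,
      jaccard = jaccard(modules[[ma]]$genes, modules[[mb]]$genes),
      kappa = kap,
      same_gil = modules[[ma]]$gil_id == modules[[mb]]$gil_id,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlation between compositional and functional similarity
#'
#' Ordinary least squares of the Jaccard index on kappa over all pairs with
#' a defined kappa, reporting R-squared and the slope-test p-value.
#'
#' @param scores Data.frame from [pairwise_scores()].
#' @return List with `r_squared`, `p`, `slope`, `n_pairs`, and the fitted
#'   `lm` object.
#' @export
similarity_correlation <- function(scores) {
  s <- scores[!is.na(scores$kappa), , drop = FALSE]
  if (nrow(s) < 3) stop("need at least 3 pairs with defined kappa")
  if (stats::var(s$kappa) == 0) stop("kappa has zero variance")
  fit <- stats::lm(jaccard ~ kappa, data = s)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p = sm$coefficients["kappa", "Pr(>|t|)"],
       slope = sm$coefficients["kappa", "Estimate"],
       n_pairs = nrow(s), fit = fit)
}

#' Build the module meta-network
#'
#' Modules become nodes; an edge joins every pair with kappa >= `kappa_min`
#' AND Jaccard >= `jaccard_min` (both bounds inclusive). Pairs with
#' undefined kappa never form edges.
#'
#' @param scores Data.frame from [pairwise_scores()].
#' @param kappa_min Kappa threshold (default 0.5).
#' @param jaccard_min Jaccard threshold (default 0.3).
#' @return A `MetaNetwork` list: `edges` (the passing score rows), `nodes`,
#'   and a `summary` with edge counts and within-/cross-GIL percentages
#'   (whole percent).
#' @export
build_meta_network <- function(scores, kappa_min = 0.5, jaccard_min = 0.3) {
  pass <- !is.na(scores$kappa) & scores$kappa >= kappa_min &
    scores$jaccard >= jaccard_min
  edges <- scores[pass, , drop = FALSE]
  rownames(edges) <- NULL
  n_within <- sum(edges$same_gil)
  n_total <- nrow(edges)
  structure(list(
    edges = edges,
    nodes = sort(unique(c(edges$module_a, edges$module_b))),
    kappa_min = kappa_min, jaccard_min = jaccard_min,
    summary = list(
      n_edges = n_total,
      n_within_gil = n_within,
      n_cross_gil = n_total - n_within,
      pct_within_gil = if (n_total) round(100 * n_within / n_total) else NA,
      pct_cross_gil = if (n_total) round(100 * (n_total - n_within) / n_total)
                      else NA)),
    class = "MetaNetwork")
}
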