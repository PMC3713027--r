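#' Rule-of-thumb cluster count
#'
#' The common heuristic k = floor(sqrt(n/2)) for n samples, floored at 1.
#'
#' @param n Number of samples (>= 2).
#' @return Integer k.
#' @export
rule_of_thumb_k <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("n must be a single number >= 2")
  max(1L, as.integer(floor(sqrt(n / 2))))
}

#' K-means clustering of expression samples
#'
#' Groups samples (points) by their probe intensity profiles (coordinates)
#' so that the within-group sum of squares is minimized, using the
#' Hartigan-Wong algorithm with seeded multiple restarts. Deterministic for
#' a given seed.
#'
#' @param m An [ExpressionMatrix].
#' @param k Number of clusters (<= number of samples).
#' @param seed Integer seed recorded in the result.
#' @param restarts Number of random restarts (best WCSS kept).
#' @return A `ClusterAssignment` list: `assignment` (named integer vector of
#'   0-based cluster indices per sample), `k`, `inertia` (total within-cluster
#'   sum of squares), `seed`.
#' @export
kmeans_cluster <- function(m, k, seed = 1L, restarts = 10L) {
  n <- nrow(m$values)
  if (k > n) stop("k (", k, ") exceeds sample count (", n, ")")
  fit <- withr::with_seed(seed, {
    res <- NULL
    for (attempt in 1:5) {
      res <- tryCatch(
        stats::kmeans(m$values, centers = k, nstart = restarts,
                      iter.max = 100L, algorithm = "Hartigan-Wong"),
        error = function(e) NULL)
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(fit)) stop("k-means failed to converge after restarts")
  # relabel clusters deterministically by first appearance in sample order
  first_seen <- unique(fit$cluster)
  relabel <- match(fit$cluster, first_seen) - 1L
  assignment <- stats::setNames(relabel, sample_ids(m))
  structure(list(assignment = assignment, k = as.integer(k),
                 inertia = fit$tot.withinss, seed = as.integer(seed)),
            class = "ClusterAssignment")
}

#' Partition a compendium into per-cluster sub-matrices
#'
#' Splits the expression matrix by cluster assignment. Clusters with fewer
#' than `min_size` samples are reported as `too_few_arrays` and yield no
#' sub-matrix (no network is attempted for them downstream).
#'
#' @param m An [ExpressionMatrix] covering all assigned samples.
#' @param a A `ClusterAssignment` from [kmeans_cluster()].
#' @param min_size Minimum samples per kept cluster (default 25).
#' @return A list with `groups` (named list of [ExpressionMatrix], one per
#'   kept cluster, names `G0001`, `G0002`, ... by ascending cluster index)
#'   and `manifest` (a `GroupManifest`: per-cluster member ids and status
#'   `kept` or `too_few_arrays`).
#' @export
partition_compendium <- function(m, a, min_size = 25L) {
  ids <- sample_ids(m)
  if (!all(ids %in% names(a$assignment)))
    stop("assignment does not cover all samples")
  cl <- a$assignment[ids]
  clusters <- sort(unique(as.integer(a$assignment)))
  groups <- list()
  manifest <- list(min_size = as.integer(min_size), clusters = list())
  for (ci in clusters) {
    gid <- sprintf("G%04d", ci + 1L)
    members <- ids[cl == ci]
    status <- if (length(members) >= min_size) "kept" else "too_few_arrays"
    manifest$clusters[[gid]] <- list(cluster = ci, members = members,
                                     status = status)
    if (status == "kept") {
      keep <- ids %in% members
      meta <- if (is.null(m$metadata)) NULL else
        m$metadata[keep, , drop = FALSE]
      groups[[gid]] <- ExpressionMatrix(m$values[keep, , drop = FALSE], meta)
    }
  }
  class(manifest) <- "GroupManifest"
  list(groups = groups, manifest = manifest)
}
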