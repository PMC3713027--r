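#' Construct an expression matrix object
#'
#' Container for a samples-by-probesets intensity matrix on the log2 scale,
#' with optional per-sample metadata. Row names are sample identifiers,
#' column names are probeset (or gene) identifiers.
#'
#' @param values Numeric matrix, samples in rows, probes in columns. Must
#'   carry unique, non-empty dimnames and contain only finite values.
#' @param metadata Optional data.frame of per-sample annotations; row order
#'   must match the matrix rows.
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and probe column names")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  dup_p <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_p))
    stop("duplicate probe identifiers: ", paste(dup_p, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at sample '%s', probe '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != nrow(values))
      stop("metadata rows must match sample count")
  }
  structure(list(values = values, metadata = metadata),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d samples x %d probes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(m) rownames(m$values)

#' Probe identifiers of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of probe ids.
#' @export
probe_ids <- function(m) colnames(m$values)

#' Read an expression matrix from TSV
#'
#' The expected layout is probes as columns: a header row of probe ids and a
#' first column of sample ids. Use `transposed = TRUE` for the probes-as-rows
#' layout. Duplicated identifiers or non-numeric cells are hard errors.
#'
#' @param path Path to a tab-separated file.
#' @param transposed Logical; set `TRUE` when probes are rows.
#' @param log2_transform Apply `log2(x + 1)` after reading (for matrices on
#'   the raw intensity scale).
#' @return An [ExpressionMatrix].
#' @export
load_expression_matrix <- function(path, transposed = FALSE,
                                   log2_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  ids <- as.character(dt[[1]])
  header <- colnames(dt)[-1]
  if (anyDuplicated(header))
    stop("duplicate column identifiers: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      v <- suppressWarnings(as.numeric(body[[j]]))
      bad <- which(is.na(v) & !is.na(body[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                     ids[bad[1]], colnames(body)[j], body[[j]][bad[1]]))
      body[[j]] <- v
    }
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  if (transposed) values <- t(values)
  if (log2_transform) values <- log2(values + 1)
  ExpressionMatrix(values)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [load_expression_matrix()] (probes as columns, full precision).
#'
#' @param m An [ExpressionMatrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(sample_id = sample_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' One row per (probe, gene) mapping; probes mapping to several loci appear
#' on several rows and are treated as ambiguous downstream.
#'
#' @param path TSV with columns `probe_id` and `gene_id` (header required).
#' @return A data.frame with columns `probe_id`, `gene_id`.
#' @export
load_probe_map <- function(path) {
  pm <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% colnames(pm)))
    stop("probe map must have columns 'probe_id' and 'gene_id'")
  if (any(!nzchar(pm$gene_id))) stop("empty gene identifiers in probe map")
  unique(pm[, c("probe_id", "gene_id")])
}

#' Remove control and ambiguous probesets
#'
#' Keeps exactly the probes that map to a single gene locus and do not match
#' a control-probe prefix. Probes present in the matrix but absent from the
#' map are removed as ambiguous, with a warning. The operation is idempotent.
#'
#' @param m An [ExpressionMatrix].
#' @param map Probe map data.frame (`probe_id`, `gene_id`), one row per
#'   mapping; see [load_probe_map()].
#' @param control_patterns Character vector of probe-id prefixes marking
#'   control probes (default `"AFFX"`).
#' @return A list with elements `matrix` (filtered [ExpressionMatrix]) and
#'   `report` (a `QCReport` list: `removed_controls`, `removed_ambiguous`
#'   counts plus the id vectors `control_ids`, `ambiguous_ids`).
#' @export
filter_probesets <- function(m, map, control_patterns = "AFFX") {
  probes <- probe_ids(m)
  is_control <- rep(FALSE, length(probes))
  for (p in control_patterns) is_control <- is_control | startsWith(probes, p)
  n_loci <- table(map$probe_id[map$probe_id %in% probes])
  ambiguous <- probes[!is_control & probes %in% names(n_loci)[n_loci > 1]]
  unmapped <- probes[!is_control & !(probes %in% map$probe_id)]
  if (length(unmapped))
    warning(length(unmapped),
            " probes absent from the map; removed as ambiguous")
  ambiguous <- c(ambiguous, unmapped)
  keep <- !is_control & !(probes %in% ambiguous)
  if (!any(keep)) stop("no informative probes")
  report <- list(
    removed_controls = sum(is_control),
    removed_ambiguous = length(ambiguous),
    control_ids = probes[is_control],
    ambiguous_ids = ambiguous,
    outlier_samples = data.frame()
  )
  class(report) <- "QCReport"
  list(matrix = ExpressionMatrix(m$values[, keep, drop = FALSE], m$metadata),
       report = report)
}

#' Quantile-normalize samples
#'
#' Forces every sample's intensity distribution to the cross-sample mean
#' distribution: after normalization each sample's sorted value vector is
#' identical and the value at rank r is the mean over samples of their rank-r
#' values. Delegates to `limma::normalizeQuantiles`.
#'
#' @param m An [ExpressionMatrix] with at least 2 samples.
#' @return A quantile-normalized [ExpressionMatrix].
#' @export
quantile_normalize <- function(m) {
  if (nrow(m$values) < 2) {
    warning("single sample: returned unchanged")
    return(m)
  }
  # limma normalizes columns (arrays); our samples are rows
  v <- t(limma::normalizeQuantiles(t(m$values)))
  dimnames(v) <- dimnames(m$values)
  ExpressionMatrix(v, m$metadata)
}

#' Flag outlier samples by three distributional tests
#'
#' Each sample is scored by (T1) its mean Euclidean distance to all other
#' samples, (T2) the Kolmogorov-Smirnov statistic between its intensity
#' distribution and the pooled distribution of all samples, and (T3) one
#' minus its median Pearson correlation with the other samples. A test flags
#' a sample whose statistic exceeds Q3 + 1.5 IQR of that statistic across
#' samples; a sample is an outlier iff at least two of the three tests flag
#' it.
#'
#' @param m An [ExpressionMatrix] with at least 4 samples.
#' @return A `QCReport` list whose `outlier_samples` data.frame has one row
#'   per sample with logical columns `t1`, `t2`, `t3`, the number of failed
#'   tests and the final `is_outlier` call.
#' @export
detect_outlier_samples <- function(m) {
  v <- m$values
  n <- nrow(v)
  if (n < 4) stop("need at least 4 samples for IQR fences")
  d <- as.matrix(stats::dist(v))
  t1 <- rowSums(d) / (n - 1)
  pooled <- sort(as.vector(v))
  t2 <- apply(v, 1, function(x) {
    suppressWarnings(stats::ks.test(x, pooled)$statistic)
  })
  cm <- stats::cor(t(v))
  diag(cm) <- NA
  t3 <- 1 - apply(cm, 1, stats::median, na.rm = TRUE)
  fence <- function(s) s > stats::quantile(s, 0.75) + 1.5 * stats::IQR(s)
  f1 <- fence(t1); f2 <- fence(t2); f3 <- fence(t3)
  n_failed <- f1 + f2 + f3
  tab <- data.frame(sample_id = sample_ids(m), t1 = f1, t2 = f2, t3 = f3,
                    n_failed = n_failed, is_outlier = n_failed >= 2,
                    row.names = NULL)
  report <- list(removed_controls = 0L, removed_ambiguous = 0L,
                 control_ids = character(), ambiguous_ids = character(),
                 outlier_samples = tab)
  class(report) <- "QCReport"
  report
}

#' Drop the samples a QC report flags as outliers
#'
#' @param m An [ExpressionMatrix].
#' @param report A `QCReport` from [detect_outlier_samples()].
#' @return The matrix restricted to non-outlier samples.
#' @export
remove_outlier_samples <- function(m, report) {
  bad <- report$outlier_samples$sample_id[report$outlier_samples$is_outlier]
  keep <- !(sample_ids(m) %in% bad)
  meta <- if (is.null(m$metadata)) NULL else m$metadata[keep, , drop = FALSE]
  ExpressionMatrix(m$values[keep, , drop = FALSE], meta)
}
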