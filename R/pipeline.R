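#' Default run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline with the
#' collection defaults: minimum 25 arrays per group, NNSD test at p = 0.001,
#' enrichment alpha 0.01, module-similarity size minimum 30, meta-network
#' thresholds kappa >= 0.5 and Jaccard >= 0.3, 2 Mb enlargement of
#' single-marker QTLs, 300 kb GWAS SNP windows at p <= 1e-4, and a 50 kb
#' biomarker window.
#'
#' @param ... Named overrides of any default.
#' @return A `RunConfig` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    k = "auto", seed = 1L, restarts = 10L, min_size = 25L,
    control_patterns = "AFFX", quantile_normalize = TRUE,
    t_start = 0.50, t_step = 0.01, refine_step = 0.001, rmt_p = 0.001,
    n_bins = 60L, min_eigenvalues = 100L, signed = FALSE,
    min_edges = 2L, collection_tag = "SYNv1.0",
    enrichment_alpha = 0.01, size_min = 30L,
    kappa_min = 0.5, jaccard_min = 0.3,
    qtl_enlarge_below = 5, qtl_enlarged_size = 2e6,
    snp_window = 3e5, snp_p_max = 1e-4, trait_min_features = 1L,
    biomarker_window = 5e4)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return A `RunConfig` (for `read_config`); `path` invisibly for
#'   `write_config`.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg A `RunConfig`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full layered-network pipeline
#'
#' Preprocess (probe filtering, quantile normalization, outlier removal),
#' K-means sample grouping, per-group re-QC and RMT-thresholded network
#' construction, link-community module discovery, optional functional
#' enrichment, module co-similarity and meta-network, and optional
#' QTL/GWAS trait integration. Per-group failures (too few arrays, no RMT
#' threshold) are recorded in the summary table without aborting the other
#' groups.
#'
#' @param m An [ExpressionMatrix] (samples x probes).
#' @param probe_map Probe map data.frame (`probe_id`, `gene_id`).
#' @param config A `RunConfig` from [default_config()].
#' @param annotations Optional annotation data.frame for enrichment.
#' @param genes Optional gene loci data.frame for trait integration.
#' @param genome Optional named chromosome-length vector.
#' @param qtls,snps Optional QTL / GWAS SNP tables (see
#'   [prepare_features()]).
#' @param out_dir Optional directory for per-stage TSV/GraphML exports.
#' @return A `gil_run` list: `networks`, `modules` (flat named list),
#'   `modules_by_gil`, `enrichment`, `scores`, `meta_network`,
#'   `trait_results`, `assignments`, `summary` (per-GIL table shaped like a
#'   collection summary: input arrays, outliers, edges, nodes, threshold,
#'   average degree, modules, status), `manifest`, `config`.
#' @export
run_pipeline <- function(m, probe_map, config = default_config(),
                         annotations = NULL, genes = NULL, genome = NULL,
                         qtls = NULL, snps = NULL, out_dir = NULL) {
  filt <- filter_probesets(m, probe_map, config$control_patterns)
  mx <- filt$matrix
  if (isTRUE(config$quantile_normalize)) mx <- quantile_normalize(mx)
  qc <- detect_outlier_samples(mx)
  mx <- remove_outlier_samples(mx, qc)

  k <- if (identical(config$k, "auto")) rule_of_thumb_k(nrow(mx$values))
       else as.integer(config$k)
  assignment <- kmeans_cluster(mx, k, seed = config$seed,
                               restarts = config$restarts)
  part <- partition_compendium(mx, assignment, min_size = config$min_size)

  networks <- list(); modules_by_gil <- list()
  summary_rows <- list()
  for (gid in names(part$manifest$clusters)) {
    info <- part$manifest$clusters[[gid]]
    row <- data.frame(gil_id = gid, input_arrays = length(info$members),
                      outlier_arrays = NA_integer_, edges = NA_integer_,
                      nodes = NA_integer_, threshold = NA_real_,
                      avg_degree = NA_real_, modules = NA_integer_,
                      status = info$status, stringsAsFactors = FALSE)
    if (info$status == "too_few_arrays") {
      summary_rows[[gid]] <- row
      next
    }
    res <- tryCatch({
      gm <- part$groups[[gid]]
      gqc <- detect_outlier_samples(gm)
      gm <- remove_outlier_samples(gm, gqc)
      n_out <- sum(gqc$outlier_samples$is_outlier)
      if (nrow(gm$values) < config$min_size) {
        row$outlier_arrays <- n_out
        row$status <- "too_few_arrays"
        list(row = row)
      } else {
        gm <- collapse_probes_to_genes(gm, probe_map)
        sim <- correlation_matrix(gm)
        scan <- find_rmt_threshold(
          sim, t_start = config$t_start, t_step = config$t_step,
          refine_step = config$refine_step, p = config$rmt_p,
          n_bins = config$n_bins, min_eigenvalues = config$min_eigenvalues,
          signed = config$signed)
        row$outlier_arrays <- n_out
        if (!scan$success) {
          row$status <- paste0("failed_rmt_", scan$reason)
          list(row = row)
        } else {
          net <- build_network(sim, scan$threshold, gil_id = gid,
                               signed = config$signed)
          mods <- detect_link_communities(net, min_edges = config$min_edges)
          mods <- name_modules(config$collection_tag, gid, mods)
          ns <- network_summary(net)
          row$edges <- ns$n_edges; row$nodes <- ns$n_nodes
          row$threshold <- scan$threshold
          row$avg_degree <- ns$avg_degree
          row$modules <- length(mods)
          row$status <- "ok"
          list(row = row, net = net, mods = mods)
        }
      }
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      list(row = row)
    })
    summary_rows[[gid]] <- res$row
    if (!is.null(res$net)) {
      networks[[gid]] <- res$net
      modules_by_gil[[gid]] <- res$mods
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  modules <- do.call(c, unname(modules_by_gil))
  if (is.null(modules)) modules <- list()

  enrichment <- NULL; scores <- NULL; meta <- NULL
  if (!is.null(annotations) && length(modules)) {
    enrichment <- enrich_modules(modules, annotations,
                                 alpha = config$enrichment_alpha)
    scores <- tryCatch(
      pairwise_scores(modules, enrichment, size_min = config$size_min),
      warning = function(w) NULL)
    if (!is.null(scores) && nrow(scores))
      meta <- build_meta_network(scores, kappa_min = config$kappa_min,
                                 jaccard_min = config$jaccard_min)
  }

  assignments <- NULL; trait_results <- NULL
  if (!is.null(genes) && !is.null(genome) &&
      (!is.null(qtls) || !is.null(snps)) && length(modules)) {
    features <- prepare_features(
      qtls, snps, genome, qtl_enlarge_below = config$qtl_enlarge_below,
      qtl_enlarged_size = config$qtl_enlarged_size,
      snp_window = config$snp_window, snp_p_max = config$snp_p_max)
    assignments <- assign_genes_to_features(genes, features)
    background <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
    traits <- unique(features$trait)
    trait_results <- list()
    for (mod in modules) {
      mg <- intersect(mod$genes, background)
      for (tr in traits) {
        r <- suppressWarnings(module_trait_fisher(
          mg, tr, assignments, background,
          min_features = config$trait_min_features))
        r$module_name <- mod$module_name
        trait_results[[paste(mod$module_name, tr, sep = "|")]] <- r
      }
    }
  }

  run <- structure(list(
    networks = networks, modules = modules,
    modules_by_gil = modules_by_gil, enrichment = enrichment,
    scores = scores, meta_network = meta, trait_results = trait_results,
    assignments = assignments, summary = summary, qc = qc,
    filter_report = filt$report, assignment = assignment,
    manifest = part$manifest, config = config), class = "gil_run")
  if (!is.null(out_dir)) export_run(run, out_dir)
  run
}

#' Export a pipeline run to a directory
#'
#' Writes the collection summary, per-network edge lists and GraphML files,
#' module membership tables, pairwise scores and the serialized
#' configuration.
#'
#' @param run A `gil_run`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
export_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(run$summary, file.path(out_dir, "collection_summary.tsv"),
                     sep = "\t")
  write_config(run$config, file.path(out_dir, "config.yml"))
  for (gid in names(run$networks)) {
    write_network_tsv(run$networks[[gid]],
                      file.path(out_dir, paste0(gid, "_edges.tsv")))
    write_network_graphml(run$networks[[gid]],
                          file.path(out_dir, paste0(gid, ".graphml")))
  }
  if (length(run$modules))
    write_modules_tsv(run$modules, file.path(out_dir, "modules.tsv"))
  if (!is.null(run$scores))
    data.table::fwrite(run$scores, file.path(out_dir, "module_scores.tsv"),
                       sep = "\t")
  if (!is.null(run$trait_results)) {
    tr <- do.call(rbind, lapply(run$trait_results, function(r)
      data.frame(module_name = r$module_name, trait = r$trait,
                 overlapping = r$a, module_size = r$a + r$b,
                 features_hit = length(r$features_hit), p = r$p,
                 stringsAsFactors = FALSE)))
    rownames(tr) <- NULL
    data.table::fwrite(tr, file.path(out_dir, "trait_overlap.tsv"),
                       sep = "\t")
  }
  invisible(out_dir)
}

#' Summarize a network collection
#'
#' Arithmetic summaries of a per-network summary table: mean (1 decimal)
#' and median (midpoint of the two central sorted values for even counts)
#' of modules per constructed network and of input arrays over all groups,
#' plus totals. Average degree is recomputed from edges and nodes to 2
#' decimals. Accepts either a `gil_run` or a bare summary data.frame with
#' the same columns.
#'
#' @param x A `gil_run` or summary data.frame (`gil_id`, `input_arrays`,
#'   `edges`, `nodes`, `modules`, `status`, ...).
#' @return List of summary statistics.
#' @export
summarize_collection <- function(x) {
  df <- if (inherits(x, "gil_run")) x$summary else as.data.frame(x)
  if (nrow(df) == 0) stop("empty run")
  ok <- df[df$status == "ok", , drop = FALSE]
  med <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n == 0) return(NA_real_)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  list(
    n_groups = nrow(df),
    n_constructed = nrow(ok),
    n_failed = nrow(df) - nrow(ok),
    total_edges = sum(ok$edges),
    total_modules = sum(ok$modules),
    mean_modules_per_gil = round(mean(ok$modules), 1),
    median_modules_per_gil = med(ok$modules),
    mean_input_arrays = round(mean(df$input_arrays), 1),
    median_input_arrays = med(df$input_arrays),
    avg_degree = round(2 * ok$edges / ok$nodes, 2),
    threshold_range = range(ok$threshold))
}
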