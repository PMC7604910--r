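# File-based pipeline: manifest in, partition + diagnostics out, with a
# provenance record sufficient to reproduce the run.

#' Pipeline configuration
#'
#' Collects every tunable of the file-based pipeline. Defaults follow the
#' method's standard settings: 3.5 angstrom resolution cutoff, 20
#' equal-volume scaling shells, reciprocal-space comparison, bounded-Pearson
#' minimum overlap of 10 observations.
#'
#' @param manifest Path to a TSV manifest (`dataset_id`, `reflections`,
#'   optional `model` paths), or a manifest tibble.
#' @param out_dir Output directory.
#' @param k Number of clusters at the root split.
#' @param mode `"reciprocal"` or `"realspace"`.
#' @param d_min,n_bins,min_common,axes,weight_axes,seed See
#'   [cluster_datasets()].
#' @param twin_ops Optional indexing remappings (see [resolve_indexing()]);
#'   `NULL` skips indexing resolution.
#' @param symmetry_ops Optional coordinate-frame operators (see
#'   [collapse_symmetry()]); `NULL` skips the collapse.
#' @param outlier_threshold MADs above the median for outlier-model removal;
#'   `NULL` skips removal (real-space input required).
#' @param subcluster_k When non-`NULL`, each root cluster with at least
#'   `2 * min_cluster_size` members is subclustered once into this many
#'   children.
#' @param subcluster_mode Mode for the subclustering pass (default: same as
#'   `mode`).
#' @param average_policy `"recalculate"` or `"inherit"`, for subclustering.
#' @param min_cluster_size Minimum acceptable cluster size (default 2).
#' @param assignment_path Optional explicit assignment file (manual
#'   workflow); overrides k-means at the root.
#' @param write_plots Also write a correlation-matrix raster and embedding
#'   plot as PNG (default `FALSE`).
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, out_dir, k, mode = "reciprocal",
                       d_min = 3.5, n_bins = 20, min_common = 10,
                       axes = NULL, weight_axes = FALSE, seed = 1L,
                       twin_ops = NULL, symmetry_ops = NULL,
                       outlier_threshold = NULL,
                       subcluster_k = NULL, subcluster_mode = NULL,
                       average_policy = "recalculate",
                       min_cluster_size = 2L,
                       assignment_path = NULL, write_plots = FALSE) {
  structure(list(manifest = manifest, out_dir = out_dir, k = k, mode = mode,
                 d_min = d_min, n_bins = n_bins, min_common = min_common,
                 axes = axes, weight_axes = weight_axes,
                 seed = as.integer(seed),
                 twin_ops = twin_ops, symmetry_ops = symmetry_ops,
                 outlier_threshold = outlier_threshold,
                 subcluster_k = subcluster_k,
                 subcluster_mode = subcluster_mode,
                 average_policy = average_policy,
                 min_cluster_size = min_cluster_size,
                 assignment_path = assignment_path,
                 write_plots = write_plots),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Fields mirror [run_config()]; unknown fields raise an error.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading the file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "xtalclust_config_error")
  do.call(run_config, vals)
}

#' Read a multi-data set from a manifest
#'
#' @param manifest Manifest path or tibble with columns `dataset_id`,
#'   `reflections` (file paths) and optionally `model` (PDB paths).
#' @return A [multidataset()].
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- readr::read_tsv(manifest, col_types = readr::cols())
  refl <- purrr::map2(manifest$reflections, manifest$dataset_id,
                      function(p, id) read_reflections(p, dataset_id = id))
  models <- NULL
  if ("model" %in% names(manifest) && !anyNA(manifest$model)) {
    models <- purrr::map2(manifest$model, manifest$dataset_id,
                          function(p, id) read_model(p, dataset_id = id))
  }
  multidataset(refl, models)
}

#' Run the end-to-end clustering pipeline
#'
#' Sequence: read manifest, resolution cutoff, optional indexing-ambiguity
#' resolution, optional outlier-model removal, optional symmetry collapse,
#' scaling, correlation matrix, SVD, embedding, assignment, optional one
#' level of subclustering — then writes the partition files, the assignment
#' table, the tree document, the embedding and matrix TSVs, any reports, and
#' a `provenance.json` capturing every effective parameter and the seed.
#' All file output is deterministic: identical configuration and seed give
#' byte-identical files.
#'
#' @param config A [run_config()].
#' @return The `mds_clustering` fit, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  msg <- function(...) message("[xtalclust] ", sprintf(...))

  mds <- if (inherits(config$manifest, "multidataset")) config$manifest
         else read_manifest(config$manifest)
  check_min_n(mds, 2L)
  msg("loaded %d data sets", n_datasets(mds))
  mds <- apply_resolution_cutoff(mds, d_min = config$d_min)

  if (!is.null(config$twin_ops)) {
    res <- resolve_indexing(mds, config$twin_ops)
    mds <- res$data
    readr::write_tsv(res$report, file.path(out_dir, "indexing_report.tsv"))
    msg("indexing resolved in %d iteration(s)", res$iterations)
  }
  if (!is.null(config$outlier_threshold)) {
    res <- remove_outliers(mds, threshold_mads = config$outlier_threshold)
    readr::write_tsv(res$scores, file.path(out_dir, "outlier_report.tsv"))
    if (length(res$removed))
      msg("removed %d outlier model(s): %s", length(res$removed),
          paste(res$removed, collapse = ", "))
    mds <- res$kept
    check_min_n(mds, 2L)
  }
  if (!is.null(config$symmetry_ops)) {
    res <- collapse_symmetry(mds, config$symmetry_ops)
    mds <- res$data
    readr::write_tsv(res$report, file.path(out_dir, "symmetry_report.tsv"))
  }

  fit <- cluster_datasets(mds, k = config$k, mode = config$mode,
                          d_min = config$d_min, n_bins = config$n_bins,
                          min_common = config$min_common,
                          axes = config$axes,
                          weight_axes = config$weight_axes,
                          method = if (is.null(config$assignment_path))
                            "kmeans" else "file",
                          assignment_path = config$assignment_path,
                          seed = config$seed)
  if (!is.null(config$subcluster_k)) {
    for (node in vapply(fit$tree$children, `[[`, character(1), "id")) {
      fit <- subcluster(fit, node, k = config$subcluster_k,
                        mode = config$subcluster_mode,
                        average_policy = config$average_policy,
                        min_cluster_size = config$min_cluster_size,
                        seed = config$seed)
    }
  }

  write_partition(fit$tree, out_dir)
  readr::write_tsv(as_tibble(fit$projection),
                   file.path(out_dir, "embedding.tsv"))
  readr::write_tsv(tidy(fit$matrix), file.path(out_dir, "matrix.tsv"))
  if (!is.null(fit$shells)) {
    scales <- dplyr::bind_rows(purrr::map2(
      fit$data$reflections, fit$data$dataset_id,
      function(rs, id) {
        tb <- attr(rs, "shell_scales")
        if (is.null(tb)) NULL else dplyr::mutate(tb, dataset_id = id,
                                                 .before = 1)
      }))
    readr::write_tsv(scales, file.path(out_dir, "shell_scales.tsv"))
  }
  if (isTRUE(config$write_plots)) {
    ggplot2::ggsave(file.path(out_dir, "matrix.png"),
                    autoplot(reorder_matrix(fit$matrix, fit$tree)),
                    width = 6, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "embedding.png"), autoplot(fit),
                    width = 6, height = 5, dpi = 150)
  }
  prov <- list(tool = "xtalclust",
               version = as.character(utils::packageVersion("xtalclust")),
               seed = config$seed,
               parameters = config[setdiff(names(config),
                                           c("manifest", "out_dir"))],
               n_datasets = n_datasets(mds))
  prov$parameters <- prov$parameters[!vapply(prov$parameters, is.null,
                                             logical(1))]
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  msg("wrote partition for %d terminal cluster(s) to %s",
      length(tree_leaves(fit$tree)), out_dir)
  invisible(fit)
}
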