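# In-memory clustering driver: cutoff -> average -> scale -> matrix -> SVD
# -> embedding -> assignment, producing a cluster tree that can be grown by
# recursive subclustering.

#' Cluster a multi-data set
#'
#' Runs the full in-memory pipeline on a multi-data set: resolution cutoff,
#' average-set construction, equal-volume-shell scaling (reciprocal mode),
#' bounded-correlation matrix, SVD, 3-D embedding on the chosen axes, and
#' deterministic cluster assignment. The result holds the cluster tree
#' (root plus one child per cluster) and every intermediate object, and can
#' be refined with [subcluster()].
#'
#' @param mds A [multidataset()] (N >= 2).
#' @param k Number of clusters at the root split. Choosing `k` is a user
#'   decision, as in a manual workflow; a silhouette-style suggestion is not
#'   auto-applied.
#' @param mode `"reciprocal"` (amplitude differences) or `"realspace"`
#'   (C-alpha differences).
#' @param d_min Resolution cutoff in angstroms (default 3.5).
#' @param n_bins Number of equal-volume scaling shells (default 20).
#' @param min_common Minimum shared observations per pair (default 10).
#' @param axes Three SVD axis indices for the embedding (default the three
#'   largest-weight axes).
#' @param weight_axes Multiply embedding columns by their singular values
#'   (default `FALSE`).
#' @param scale Scale amplitudes in resolution shells before correlating
#'   (default `TRUE`; reciprocal mode only).
#' @param method Assignment method, `"kmeans"` or `"file"`.
#' @param assignment_path Assignment TSV for `method = "file"`.
#' @param seed Integer seed for the k-means starts.
#' @return An `mds_clustering` object: list with `tree`, `matrix`, `svd`,
#'   `projection`, `assignment`, `average`, `shells`, `params`, `data` (the
#'   processed multidataset).
#' @export
cluster_datasets <- function(mds, k, mode = c("reciprocal", "realspace"),
                             d_min = 3.5, n_bins = 20, min_common = 10L,
                             axes = NULL, weight_axes = FALSE, scale = TRUE,
                             method = c("kmeans", "file"),
                             assignment_path = NULL, seed = 1L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  check_min_n(mds, 2L)
  mds <- apply_resolution_cutoff(mds, d_min = d_min)
  shells <- NULL
  avg_refl <- NULL
  avg_coord <- NULL
  if (mode == "reciprocal" && scale) {
    scaled <- scale_multidataset(mds, n_bins = n_bins)
    mds <- scaled$data
    avg_refl <- scaled$average
    shells <- scaled$shells
  } else if (mode == "reciprocal") {
    avg_refl <- average_amplitudes(mds)
  } else {
    avg_coord <- average_coordinates(mds)
  }
  average <- if (mode == "reciprocal") avg_refl else avg_coord
  cm <- build_matrix(mds, mode = mode, average = average,
                     min_common = min_common)
  sv <- svd_decompose(cm)
  proj <- project_axes(sv, axes = axes, weight = weight_axes)
  assignment <- assign_clusters(proj, method = method, k = k, seed = seed,
                                path = assignment_path)
  used_axes <- attr(proj, "axes")
  children <- lapply(sort(unique(assignment$cluster)), function(cl)
    new_tree_node(id = as.character(cl),
                  members = assignment$dataset_id[assignment$cluster == cl],
                  mode = mode, axes = used_axes,
                  average_policy = "recalculated"))
  tree <- new_cluster_tree(new_tree_node(
    id = "root", members = mds$dataset_id, mode = mode, axes = used_axes,
    average_policy = "recalculated", children = children))
  structure(list(tree = tree, matrix = cm, svd = sv, projection = proj,
                 assignment = assignment,
                 average = list(reciprocal = avg_refl, realspace = avg_coord),
                 shells = shells,
                 params = list(k = k, mode = mode, d_min = d_min,
                               n_bins = n_bins, min_common = min_common,
                               axes = used_axes, weight_axes = weight_axes,
                               scale = scale, seed = as.integer(seed)),
                 data = mds),
            class = "mds_clustering")
}

#' @export
print.mds_clustering <- function(x, ...) {
  cat(sprintf("<multi-data-set clustering: N = %d, mode = %s, k = %s>\n",
              n_datasets(x$data), x$params$mode, x$params$k))
  print(x$tree)
  invisible(x)
}

#' Subcluster a tree node
#'
#' Reruns the matrix / SVD / embedding / assignment chain on the members of
#' one terminal node, in either comparison mode, using averages either
#' recalculated over the subset (sharpening differences local to it) or
#' inherited from the parent run. Children are appended with full
#' provenance. Subsets smaller than `2 * min_cluster_size` are marked
#' complete instead, with a warning.
#'
#' @param fit An `mds_clustering` from [cluster_datasets()].
#' @param node Terminal node id to split (e.g. `"1"`, or `"1.2"` after a
#'   previous subclustering).
#' @param k Number of subclusters.
#' @param mode Comparison mode for this node; defaults to the parent run's
#'   mode. Mixed-mode trees (reciprocal first, real-space below) are the
#'   normal way to chase conformational substructure.
#' @param average_policy `"recalculate"` (default) or `"inherit"`.
#' @param axes,weight_axes,min_common,seed As in [cluster_datasets()];
#'   defaults inherited from the parent run.
#' @param min_cluster_size Minimum acceptable cluster size (default 2).
#' @return The updated `mds_clustering`.
#' @export
subcluster <- function(fit, node, k, mode = NULL,
                       average_policy = c("recalculate", "inherit"),
                       axes = NULL, weight_axes = NULL, min_common = NULL,
                       seed = NULL, min_cluster_size = 2L) {
  average_policy <- match.arg(average_policy)
  nd <- tree_find(fit$tree, node)
  if (is.null(nd))
    abort(sprintf("no tree node '%s'", node), class = "xtalclust_config_error")
  if (isTRUE(nd$complete))
    abort(sprintf("node '%s' is marked complete", node),
          class = "xtalclust_config_error")
  if (length(nd$children))
    abort(sprintf("node '%s' already has children", node),
          class = "xtalclust_config_error")
  mode <- mode %||% fit$params$mode
  min_common <- min_common %||% fit$params$min_common
  weight_axes <- weight_axes %||% fit$params$weight_axes
  seed <- seed %||% fit$params$seed
  if (length(nd$members) < 2L * min_cluster_size) {
    warn(sprintf("node '%s' has only %d members; marking complete",
                 node, length(nd$members)))
    nd$complete <- TRUE
    fit$tree <- tree_replace(fit$tree, node, nd)
    return(fit)
  }
  sub <- mds_subset(fit$data, nd$members)
  average <- if (average_policy == "recalculate") {
    if (mode == "reciprocal") average_amplitudes(sub) else average_coordinates(sub)
  } else {
    inherited <- fit$average[[mode]]
    if (is.null(inherited))
      abort(sprintf("no inherited %s average available; use average_policy = 'recalculate'",
                    mode),
            class = "xtalclust_config_error")
    inherited
  }
  cm <- build_matrix(sub, mode = mode, average = average,
                     min_common = min_common)
  sv <- svd_decompose(cm)
  proj <- project_axes(sv, axes = axes, weight = weight_axes)
  assignment <- assign_clusters(proj, method = "kmeans", k = k, seed = seed)
  used_axes <- attr(proj, "axes")
  nd$children <- lapply(sort(unique(assignment$cluster)), function(cl)
    new_tree_node(id = paste0(node, ".", cl),
                  members = assignment$dataset_id[assignment$cluster == cl],
                  mode = mode, axes = used_axes,
                  average_policy = if (average_policy == "recalculate")
                    "recalculated" else "inherited"))
  fit$tree <- tree_replace(fit$tree, node, nd)
  fit
}

#' Assignment table of a clustering
#'
#' @param x An `mds_clustering`.
#' @param ... Unused.
#' @return Tibble with `dataset_id`, `cluster_path` (terminal node of the
#'   tree) and the embedding coordinates `s1`, `s2`, `s3`.
#' @method tidy mds_clustering
#' @export
tidy.mds_clustering <- function(x, ...) {
  dplyr::left_join(tidy(x$tree), as_tibble(x$projection), by = "dataset_id")
}

#' One-row summary of a clustering
#'
#' @param x An `mds_clustering`.
#' @param ... Unused.
#' @return Tibble with the data-set count, number of terminal clusters, the
#'   three leading singular-value weights, and the mean within- and
#'   between-cluster correlation coefficients at the root split.
#' @method glance mds_clustering
#' @export
glance.mds_clustering <- function(x, ...) {
  M <- unclass(x$matrix)
  lab <- x$assignment$cluster[match(rownames(M), x$assignment$dataset_id)]
  same <- outer(lab, lab, `==`) & upper.tri(M)
  diff <- !outer(lab, lab, `==`) & upper.tri(M)
  tibble(n_datasets = nrow(M),
         n_clusters = length(tree_leaves(x$tree)),
         w1 = x$svd$W[1], w2 = x$svd$W[2], w3 = x$svd$W[3],
         mean_within = if (any(same)) mean(M[same]) else NA_real_,
         mean_between = if (any(diff)) mean(M[diff]) else NA_real_)
}
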