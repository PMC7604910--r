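# Cluster trees: a recursive partition of dataset ids with per-node
# provenance (comparison mode, SVD axes used, average policy, complete flag).

new_tree_node <- function(id, members, mode = NA_character_,
                          axes = integer(0),
                          average_policy = NA_character_,
                          complete = FALSE, children = list()) {
  structure(list(id = id, members = members, mode = mode,
                 axes = axes, average_policy = average_policy,
                 complete = complete, children = children),
            class = "tree_node")
}

new_cluster_tree <- function(root) structure(root, class = c("cluster_tree", "tree_node"))

# Depth-first list of terminal nodes (no children).
tree_leaves <- function(node) {
  if (length(node$children) == 0) return(list(node))
  unlist(lapply(node$children, tree_leaves), recursive = FALSE)
}

# Locate a node by its path id; returns NULL when absent.
tree_find <- function(node, id) {
  if (identical(node$id, id)) return(node)
  for (ch in node$children) {
    hit <- tree_find(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# Replace a node (matched by id) with `value`, preserving tree class.
tree_replace <- function(node, id, value) {
  if (identical(node$id, id)) {
    value$id <- node$id
    cls <- class(node)
    node[names(value)] <- value
    class(node) <- cls
    return(node)
  }
  node$children <- lapply(node$children, tree_replace, id = id, value = value)
  node
}

tree_to_list <- function(node) {
  list(id = node$id,
       members = as.list(sort(node$members)),
       mode = node$mode,
       axes = as.list(node$axes),
       average_policy = node$average_policy,
       complete = node$complete,
       children = lapply(node$children, tree_to_list))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster tree>\n")
  print_node <- function(node, indent) {
    cat(sprintf("%s%s: %d data sets%s%s\n", strrep("  ", indent),
                node$id, length(node$members),
                if (!is.na(node$mode)) paste0(" [", node$mode, "]") else "",
                if (isTRUE(node$complete)) " (complete)" else ""))
    for (ch in node$children) print_node(ch, indent + 1)
  }
  print_node(x, 0)
  invisible(x)
}

#' Flatten a cluster tree to an assignment table
#'
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @return Tibble with `dataset_id` and `cluster_path` (the terminal node id),
#'   sorted by `dataset_id`.
#' @method tidy cluster_tree
#' @export
tidy.cluster_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  out <- dplyr::bind_rows(lapply(leaves, function(leaf) {
    if (length(leaf$members) == 0) return(NULL)
    tibble(dataset_id = leaf$members, cluster_path = leaf$id)
  }))
  dplyr::arrange(out, .data$dataset_id)
}

#' Mark a tree node as requiring no further subdivision
#'
#' A node marked complete is never subclustered; completeness is recorded in
#' the exported tree document.
#'
#' @param fit A clustering result from [cluster_datasets()].
#' @param node Node id (e.g. `"1"` or `"1.2"`).
#' @return The updated fit.
#' @export
mark_complete <- function(fit, node) {
  nd <- tree_find(fit$tree, node)
  if (is.null(nd))
    abort(sprintf("no tree node '%s'", node), class = "xtalclust_config_error")
  if (length(nd$children))
    abort(sprintf("node '%s' already has children", node),
          class = "xtalclust_config_error")
  nd$complete <- TRUE
  fit$tree <- tree_replace(fit$tree, node, nd)
  fit
}
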