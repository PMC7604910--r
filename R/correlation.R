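# Difference series, bounded Pearson coefficients, the N x N correlation
# matrix and its SVD embedding.
#
# Every pairwise comparison is made between *difference* series — deviations
# of each data set from the multi-data-set average, taken over the
# reflections (or C-alpha atoms) present in both members of the pair.
# Correlating differences rather than absolute values exposes subtle
# concerted variation that absolute-value correlations bury in the noise.

#' Difference series of two reflection sets
#'
#' Over the Miller indices recorded in both data sets (and present in the
#' average), returns the paired deviations `F - F_avg` in a shared index
#' order.
#'
#' @param rs_m,rs_n Two [reflection_set()]s, normally scaled.
#' @param avg [average_amplitudes()] of the multi-data set.
#' @return Tibble with columns `h`, `k`, `l`, `v_m`, `v_n`.
#' @export
diff_series_reciprocal <- function(rs_m, rs_n, avg) {
  am <- as_tibble(rs_m); an <- as_tibble(rs_n)
  j <- dplyr::inner_join(am, an, by = c("h", "k", "l"),
                         suffix = c("_m", "_n"))
  j <- dplyr::inner_join(j, as_tibble(avg)[, c("h", "k", "l", "F_avg")],
                         by = c("h", "k", "l"))
  j <- dplyr::arrange(j, .data$h, .data$k, .data$l)
  tibble(h = j$h, k = j$k, l = j$l,
         v_m = j$F_m - j$F_avg, v_n = j$F_n - j$F_avg)
}

#' Difference series of two coordinate models
#'
#' Over the atoms modelled in both data sets (and in the average), each atom
#' contributes its x, y, z deviations from the average position
#' consecutively, giving series of length three times the common atom count.
#'
#' @param cm_m,cm_n Two [coordinate_model()]s.
#' @param avg [average_coordinates()] of the multi-data set.
#' @return Tibble with columns `atom_key`, `comp` (`"x"`, `"y"`, `"z"`),
#'   `v_m`, `v_n`.
#' @export
diff_series_realspace <- function(cm_m, cm_n, avg) {
  am <- as_tibble(cm_m); an <- as_tibble(cm_n)
  j <- dplyr::inner_join(am, an, by = "atom_key", suffix = c("_m", "_n"))
  j <- dplyr::inner_join(j, as_tibble(avg)[, c("atom_key", "x", "y", "z")],
                         by = "atom_key", suffix = c("", "_avg"))
  j <- dplyr::arrange(j, .data$atom_key)
  tibble(atom_key = rep(j$atom_key, each = 3),
         comp = rep(c("x", "y", "z"), times = nrow(j)),
         v_m = as.vector(rbind(j$x_m - j$x, j$y_m - j$y, j$z_m - j$z)),
         v_n = as.vector(rbind(j$x_n - j$x, j$y_n - j$y, j$z_n - j$z)))
}

#' Bounded Pearson correlation coefficient
#'
#' The textbook Pearson coefficient of two equal-length series, bounded to
#' `[0, 1]` by clamping negative values to zero: a pair whose deviations from
#' the average anti-correlate carries no evidence of shared behaviour and is
#' treated the same as an uncorrelated pair. Degenerate inputs (fewer than
#' `min_n` values, or zero variance in either series) return 0 with a
#' warning rather than an undefined value.
#'
#' @param v_m,v_n Numeric vectors of equal length.
#' @param min_n Minimum series length (default 2).
#' @return A single value in `[0, 1]`.
#' @export
pearson_bounded <- function(v_m, v_n, min_n = 2L) {
  if (length(v_m) != length(v_n))
    abort("series lengths differ", class = "xtalclust_contract_error")
  if (length(v_m) < min_n) {
    warn(sprintf("series too short (%d < %d); returning 0",
                 length(v_m), min_n))
    return(0)
  }
  if (stats::sd(v_m) == 0 || stats::sd(v_n) == 0) {
    warn("zero variance in a difference series; returning 0")
    return(0)
  }
  max(0, stats::cor(v_m, v_n))
}

#' Pairwise bounded-correlation matrix of a multi-data set
#'
#' Builds the symmetric N x N matrix whose off-diagonal entries are the
#' bounded Pearson coefficients of per-pair difference series (reciprocal
#' space: scaled amplitudes; real space: C-alpha positions) and whose
#' diagonal is exactly zero. Pairs sharing fewer than `min_common`
#' observations, or with zero variance, are set to 0 with a warning.
#'
#' @param mds A [multidataset()] (scaled, for reciprocal mode).
#' @param mode `"reciprocal"` (amplitude differences) or `"realspace"`
#'   (C-alpha differences).
#' @param average The matching [average_amplitudes()] or
#'   [average_coordinates()]; computed from `mds` when `NULL`.
#' @param min_common Minimum number of shared observations per pair
#'   (default 10; a common-atom count of `min_common / 3` in real space).
#' @return A `correlation_matrix`: a numeric matrix with dataset ids as
#'   dimnames.
#' @export
build_matrix <- function(mds, mode = c("reciprocal", "realspace"),
                         average = NULL, min_common = 10L) {
  mode <- match.arg(mode)
  check_min_n(mds, 2L)
  D <- difference_matrix(mds, mode, average)
  obs <- !is.na(D)
  counts <- crossprod(obs)
  suppressWarnings(M <- stats::cor(D, use = "pairwise.complete.obs"))
  degenerate <- is.na(M)
  if (any(degenerate[upper.tri(degenerate)]))
    warn("zero-variance difference series for some pairs; coefficients set to 0")
  M[degenerate] <- 0
  thin <- counts < min_common
  if (any(thin[upper.tri(thin)])) {
    warn(sprintf("%d pair(s) share fewer than %d observations; coefficients set to 0",
                 sum(thin[upper.tri(thin)]), min_common))
    M[thin] <- 0
  }
  M <- pmax(M, 0)
  diag(M) <- 0
  M <- (M + t(M)) / 2  # enforce exact symmetry
  new_correlation_matrix(M, mds$dataset_id)
}

# N-column matrix of deviations from the average, NA where unobserved.
# Correlating its columns pairwise-complete is identical to per-pair
# difference-series Pearson, because the average is subtracted per row.
difference_matrix <- function(mds, mode, average = NULL) {
  ids <- mds$dataset_id
  if (mode == "reciprocal") {
    avg <- average %||% average_amplitudes(mds)
    key_avg <- paste(avg$h, avg$k, avg$l)
    D <- matrix(NA_real_, nrow(avg), length(ids),
                dimnames = list(NULL, ids))
    for (i in seq_along(ids)) {
      s <- mds$reflections[[i]]
      idx <- match(paste(s$h, s$k, s$l), key_avg)
      ok <- !is.na(idx)
      D[idx[ok], i] <- s$F[ok] - avg$F_avg[idx[ok]]
    }
  } else {
    avg <- average %||% average_coordinates(mds)
    D <- matrix(NA_real_, 3 * nrow(avg), length(ids),
                dimnames = list(NULL, ids))
    for (i in seq_along(ids)) {
      m <- mds$model[[i]]
      if (is.null(m))
        abort(sprintf("data set '%s' has no coordinate model", ids[i]),
              class = "xtalclust_config_error")
      idx <- match(m$atom_key, avg$atom_key)
      ok <- !is.na(idx)
      rows <- rbind(3 * idx[ok] - 2, 3 * idx[ok] - 1, 3 * idx[ok])
      D[as.vector(rows), i] <- as.vector(rbind(m$x[ok] - avg$x[idx[ok]],
                                               m$y[ok] - avg$y[idx[ok]],
                                               m$z[ok] - avg$z[idx[ok]]))
    }
  }
  D
}

new_correlation_matrix <- function(M, labels) {
  dimnames(M) <- list(labels, labels)
  structure(M, class = c("correlation_matrix", "matrix", "array"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation matrix: %d x %d, mean off-diagonal %.3f>\n",
              nrow(x), ncol(x),
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' Long-format view of a correlation matrix
#'
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `dataset_m`, `dataset_n`, `coefficient`.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  labels <- rownames(x)
  tibble(dataset_m = rep(labels, times = ncol(x)),
         dataset_n = rep(labels, each = nrow(x)),
         coefficient = as.vector(unclass(x)))
}

#' Singular value decomposition of a correlation matrix
#'
#' Decomposes M = U W V' with singular values sorted descending. Because M
#' is symmetric, U and V columns agree up to sign; heavily weighted axes
#' capture concerted variation shared by groups of data sets, and the ratios
#' between weights (not their absolute values) indicate how many axes carry
#' structure. Column signs are canonicalized (largest-magnitude entry of each
#' U column made positive) so repeated runs are bitwise identical.
#'
#' @param cm A `correlation_matrix` from [build_matrix()].
#' @return An `svd_axes` object: `U`, `W` (vector), `V`, `labels`.
#' @export
svd_decompose <- function(cm) {
  M <- unclass(cm)
  if (!all(is.finite(M)))
    abort("correlation matrix has non-finite entries",
          class = "xtalclust_contract_error")
  s <- svd(M)
  for (j in seq_len(ncol(s$u))) {
    i_star <- which.max(abs(s$u[, j]))
    if (s$u[i_star, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  structure(list(U = s$u, W = s$d, V = s$v, labels = rownames(cm)),
            class = "svd_axes")
}

#' @export
print.svd_axes <- function(x, ...) {
  cat(sprintf("<SVD of %d x %d correlation matrix; top weights: %s>\n",
              length(x$W), length(x$W),
              paste(sprintf("%.3f", head(x$W, 5)), collapse = ", ")))
  invisible(x)
}

#' Project data sets onto chosen SVD axes
#'
#' Forms the N x 3 embedding whose rows are the rows of U restricted to the
#' chosen axes — each data set's association with the three selected
#' variation axes. By default the three largest-weight axes are used, raw
#' (unweighted) U columns; set `weight = TRUE` to multiply each column by its
#' singular value.
#'
#' @param svd An `svd_axes` from [svd_decompose()].
#' @param axes Integer vector of three distinct axis indices (1-based, in
#'   descending-weight order); default `c(1, 2, 3)`.
#' @param weight Multiply columns by their singular values (default
#'   `FALSE`).
#' @return An `axis_projection` tibble: `dataset_id`, `s1`, `s2`, `s3`.
#' @export
project_axes <- function(svd, axes = NULL, weight = FALSE) {
  axes <- as.integer(axes %||% 1:3)
  if (length(axes) != 3 || anyDuplicated(axes) ||
      any(axes < 1) || any(axes > length(svd$W)))
    abort("axes must be three distinct indices within range",
          class = "xtalclust_config_error")
  S <- svd$U[, axes, drop = FALSE]
  if (weight) S <- sweep(S, 2, svd$W[axes], `*`)
  out <- tibble(dataset_id = svd$labels,
                s1 = S[, 1], s2 = S[, 2], s3 = S[, 3])
  structure(out, axes = axes, weighted = weight,
            class = c("axis_projection", class(out)))
}

#' Reorder a correlation matrix by cluster
#'
#' Permutes rows and columns so that the members of each terminal cluster of
#' a tree are contiguous, in tree order, for visual block structure.
#'
#' @param cm A `correlation_matrix`.
#' @param tree A `cluster_tree` whose terminal clusters cover the matrix
#'   labels.
#' @return The permuted `correlation_matrix`, with the cluster block sizes
#'   attached as attribute `"blocks"` (named integer vector in display
#'   order).
#' @export
reorder_matrix <- function(cm, tree) {
  leaves <- tree_leaves(tree)
  order_ids <- unlist(lapply(leaves, function(l) sort(l$members)),
                      use.names = FALSE)
  if (!setequal(order_ids, rownames(cm)) ||
      length(order_ids) != nrow(cm))
    abort("tree terminal clusters do not cover the matrix labels",
          class = "xtalclust_consistency_error")
  perm <- match(order_ids, rownames(cm))
  out <- new_correlation_matrix(unclass(cm)[perm, perm, drop = FALSE],
                                order_ids)
  blocks <- vapply(leaves, function(l) length(l$members), integer(1))
  names(blocks) <- vapply(leaves, `[[`, character(1), "id")
  attr(out, "blocks") <- blocks[blocks > 0]
  out
}
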