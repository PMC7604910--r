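# Average-set construction and equal-volume resolution-shell scaling.
#
# The average amplitude set holds, per Miller index, the mean over the data
# sets that recorded it; missing observations simply do not contribute. The
# scaling step divides reciprocal space into shells of equal volume and, per
# data set and shell, multiplies amplitudes by k = sum(F_avg) / sum(F) over
# the commonly recorded reflections, removing global isotropic B-factor
# differences to first order.

#' Apply a high-resolution cutoff
#'
#' Removes reflections with d-spacing below `d_min`, computed from each data
#' set's own unit cell via the full metric tensor. The default of 3.5
#' angstroms balances clustering speed against discriminating power; the
#' subtle concerted differences the method targets live at low resolution.
#'
#' @param x A [reflection_set()] or [multidataset()].
#' @param d_min Resolution cutoff in angstroms (reflections with d >= d_min
#'   are kept).
#' @return Object of the same type with out-of-range reflections removed.
#' @export
apply_resolution_cutoff <- function(x, d_min = 3.5) {
  if (d_min <= 0)
    abort("d_min must be positive", class = "xtalclust_config_error")
  UseMethod("apply_resolution_cutoff")
}

#' @export
apply_resolution_cutoff.refl_tbl <- function(x, d_min = 3.5) {
  cell <- attr(x, "unit_cell")
  if (is.null(cell))
    abort(sprintf("data set '%s' has no unit cell; cannot compute d-spacings",
                  attr(x, "dataset_id")),
          class = "xtalclust_config_error")
  d <- d_spacing(x$h, x$k, x$l, cell)
  refl_like(x[d >= d_min, , drop = FALSE], x)
}

#' @export
apply_resolution_cutoff.multidataset <- function(x, d_min = 3.5) {
  x$reflections <- lapply(x$reflections, apply_resolution_cutoff, d_min = d_min)
  x
}

#' Average amplitudes over a multi-data set
#'
#' For every Miller index recorded anywhere, the mean amplitude over the data
#' sets that recorded it, together with the observation count.
#'
#' @param x A [multidataset()] or list of [reflection_set()] objects.
#' @return An `avg_refl` tibble with columns `h`, `k`, `l`, `F_avg`, `n_obs`.
#' @export
average_amplitudes <- function(x) {
  sets <- if (inherits(x, "multidataset")) x$reflections else x
  if (length(sets) == 0)
    return(structure(tibble(h = integer(), k = integer(), l = integer(),
                            F_avg = numeric(), n_obs = integer()),
                     class = c("avg_refl", class(tibble()))))
  all <- dplyr::bind_rows(lapply(sets, function(s) as_tibble(s)[, c("h", "k", "l", "F")]))
  out <- all |>
    dplyr::group_by(.data$h, .data$k, .data$l) |>
    dplyr::summarise(F_avg = mean(.data$F), n_obs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$h, .data$k, .data$l)
  structure(out, class = c("avg_refl", class(out)))
}

#' Average C-alpha coordinates over a multi-data set
#'
#' Componentwise mean position per atom key over the models that contain it.
#'
#' @param x A [multidataset()] or list of [coordinate_model()] objects.
#' @return An `avg_coord` tibble with columns `atom_key`, `x`, `y`, `z`,
#'   `n_obs`.
#' @export
average_coordinates <- function(x) {
  models <- if (inherits(x, "multidataset")) x$model else x
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0)
    return(structure(tibble(atom_key = character(), x = numeric(),
                            y = numeric(), z = numeric(), n_obs = integer()),
                     class = c("avg_coord", class(tibble()))))
  all <- dplyr::bind_rows(lapply(models, function(m)
    as_tibble(m)[, c("atom_key", "x", "y", "z")]))
  out <- all |>
    dplyr::group_by(.data$atom_key) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$atom_key)
  structure(out, class = c("avg_coord", class(out)))
}

#' Equal-volume resolution shells
#'
#' Divides reciprocal space into `n_bins` concentric spherical shells of
#' equal volume, centred on the origin, with the outer radius equal to the
#' largest reciprocal radius |s| = 1/d of any recorded reflection across the
#' multi-data set. Equal volumes imply the cube-root boundary law
#' r_b = r_max * (b / n_bins)^(1/3).
#'
#' @param x A [multidataset()] or list of [reflection_set()] objects (each
#'   needs a unit cell).
#' @param n_bins Number of shells (default 20).
#' @return A `shell_binning` object: `n_bins`, `r_max` and the `n_bins + 1`
#'   boundary radii (1/angstrom) starting at 0.
#' @export
build_shells <- function(x, n_bins = 20) {
  if (n_bins < 1)
    abort("n_bins must be >= 1", class = "xtalclust_config_error")
  sets <- if (inherits(x, "multidataset")) x$reflections else x
  r_max <- 0
  n_total <- 0L
  for (s in sets) {
    if (nrow(s) == 0) next
    cell <- attr(s, "unit_cell")
    if (is.null(cell))
      abort(sprintf("data set '%s' has no unit cell", attr(s, "dataset_id")),
            class = "xtalclust_config_error")
    r_max <- max(r_max, recip_radius(s$h, s$k, s$l, cell))
    n_total <- n_total + nrow(s)
  }
  if (n_total == 0L)
    abort("no reflections recorded in any data set",
          class = "xtalclust_config_error")
  structure(list(n_bins = as.integer(n_bins), r_max = r_max,
                 boundaries = r_max * ((0:n_bins) / n_bins)^(1 / 3)),
            class = "shell_binning")
}

#' @export
print.shell_binning <- function(x, ...) {
  cat(sprintf("<%d equal-volume resolution shells, outer radius %.4f 1/A (d_min %.2f A)>\n",
              x$n_bins, x$r_max, 1 / x$r_max))
  invisible(x)
}

# Shell index for reciprocal radii; intervals [r_{b-1}, r_b), final closed.
shell_assign <- function(r, shells) {
  idx <- findInterval(r, shells$boundaries, left.open = FALSE)
  pmin(pmax(idx, 1L), shells$n_bins)
}

#' Scale one data set against the average in resolution shells
#'
#' Per shell, over the reflections recorded in both the data set and the
#' average, a scale factor `k = sum(F_avg) / sum(F)` is derived and every
#' amplitude of the data set in that shell is multiplied by `k`. After
#' scaling, each shell's amplitude sum over the common subset equals that of
#' the average, which removes a global isotropic B factor to within
#' within-shell curvature. Shells with no common reflections keep `k = 1`
#' (with a warning when the data set has reflections there).
#'
#' @param rs A [reflection_set()] (within the resolution cutoff).
#' @param avg An [average_amplitudes()] table built over the multi-data set.
#' @param shells A [build_shells()] binning.
#' @return The scaled reflection set, with the per-shell scale table attached
#'   as attribute `"shell_scales"` (tibble: `bin`, `r_lo`, `r_hi`,
#'   `n_common`, `k`).
#' @export
scale_dataset <- function(rs, avg, shells) {
  cell <- attr(rs, "unit_cell")
  if (is.null(cell))
    abort(sprintf("data set '%s' has no unit cell", attr(rs, "dataset_id")),
          class = "xtalclust_config_error")
  n_bins <- shells$n_bins
  scale_tbl <- tibble(bin = seq_len(n_bins),
                      r_lo = shells$boundaries[seq_len(n_bins)],
                      r_hi = shells$boundaries[seq_len(n_bins) + 1],
                      n_common = 0L, k = 1)
  if (nrow(rs) == 0) {
    out <- refl_like(rs, rs)
    attr(out, "shell_scales") <- scale_tbl
    return(out)
  }
  df <- as_tibble(rs)
  df$bin <- shell_assign(recip_radius(df$h, df$k, df$l, cell), shells)
  df <- dplyr::left_join(df, as_tibble(avg)[, c("h", "k", "l", "F_avg")],
                         by = c("h", "k", "l"))
  for (b in unique(df$bin)) {
    sel <- df$bin == b
    common <- sel & !is.na(df$F_avg)
    n_common <- sum(common)
    if (n_common == 0) {
      warn(sprintf("data set '%s': shell %d has no reflections in common with the average; k = 1",
                   attr(rs, "dataset_id"), b))
      next
    }
    denom <- sum(df$F[common])
    if (denom == 0)
      abort(sprintf("data set '%s': shell %d amplitude sum is zero; cannot scale",
                    attr(rs, "dataset_id"), b),
            class = "xtalclust_degenerate_shell_error")
    k <- sum(df$F_avg[common]) / denom
    df$F[sel] <- df$F[sel] * k
    scale_tbl$n_common[b] <- n_common
    scale_tbl$k[b] <- k
  }
  out <- refl_like(df[, c("h", "k", "l", "F")], rs)
  attr(out, "shell_scales") <- scale_tbl
  out
}

#' Scale every data set of a multi-data set
#'
#' Convenience wrapper implementing the default pipeline order: build the
#' reference average, scale each data set against it, then optionally
#' recompute the average from the scaled sets so that first-order B-factor
#' bias is also removed from the reference.
#'
#' When the average is built internally, each data set's amplitudes are first
#' divided by their own mean (and the grand mean scale restored), so that a
#' data set recorded on an arbitrarily different overall scale contributes
#' with the same weight as every other: the reference — and hence the whole
#' downstream correlation matrix — is invariant under per-data-set positive
#' rescaling, up to floating point.
#'
#' @param mds A [multidataset()], already within the resolution cutoff.
#' @param average Optional precomputed [average_amplitudes()]; built from
#'   `mds` (with per-set mean normalization) when `NULL`.
#' @param shells Optional precomputed [build_shells()]; built when `NULL`.
#' @param n_bins Shell count used when `shells` is `NULL`.
#' @param refresh_average Recompute the average from the scaled sets
#'   (default `TRUE`).
#' @return List with elements `data` (scaled multidataset), `average`
#'   (refreshed or input average) and `shells`.
#' @export
scale_multidataset <- function(mds, average = NULL, shells = NULL,
                               n_bins = 20, refresh_average = TRUE) {
  if (is.null(average)) {
    g <- vapply(mds$reflections, function(rs)
      if (nrow(rs) > 0) mean(rs$F) else 1, numeric(1))
    grand <- mean(g[g > 0])
    normalized <- purrr::map2(mds$reflections, g, function(rs, gn) {
      if (gn <= 0) return(rs)
      refl_like(tibble(h = rs$h, k = rs$k, l = rs$l,
                       F = rs$F * (grand / gn)), rs)
    })
    average <- average_amplitudes(normalized)
  }
  shells <- shells %||% build_shells(mds, n_bins = n_bins)
  mds$reflections <- lapply(mds$reflections, scale_dataset,
                            avg = average, shells = shells)
  if (refresh_average) average <- average_amplitudes(mds)
  list(data = mds, average = average, shells = shells)
}
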