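# Synthetic multi-data sets with planted cluster structure.
#
# The generator emulates the heterogeneity phenomena the clustering method
# targets: cluster-specific concerted amplitude perturbations, per-data-set
# global isotropic B factors, unit-cell drift, missing observations,
# rigid-body coordinate shifts between clusters, per-atom noise and dropout,
# and optional indexing flips. It is the test bed for every pipeline stage;
# it is not a physical diffraction simulation.

#' Specify a synthetic multi-data set
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: three planted clusters of 20 data sets each, 10% concerted
#' amplitude perturbation against 5% observation noise (signal-to-noise 2),
#' isotropic B factors spread over 0-30 A^2, 10% missing observations, and
#' a tetragonal-like cell in which the `k,h,-l` indexing flip is available.
#'
#' @param n_clusters Number of planted clusters; defaults to `length(sizes)`
#'   when `sizes` is given, else 3.
#' @param sizes Per-cluster data-set counts; default 20 each.
#' @param n_reflections Reflections per complete data set.
#' @param n_atoms C-alpha atoms per complete model.
#' @param base_cell Six-number base unit cell (a = b by default so index
#'   flips are geometrically valid).
#' @param cell_jitter SD of per-data-set cell-length drift (angstrom).
#' @param amplitude_perturbation Scale of the cluster-specific concerted
#'   amplitude perturbation, as a fraction of the base amplitude.
#' @param noise_sd Per-observation noise: fractional for amplitudes,
#'   angstroms for coordinates.
#' @param b_factor_range Range (min, max) of per-data-set isotropic B
#'   factors in A^2.
#' @param coordinate_shift Named pair `c(translation = , rotation = )`:
#'   magnitude of each cluster's rigid-body shift (angstrom) and rotation
#'   (degrees).
#' @param missing_fraction Probability that any one reflection or atom is
#'   unrecorded in a given data set.
#' @param indexing_flip_fraction Probability that a data set is indexed in
#'   the alternative orientation.
#' @param flip_op The indexing flip, as an index-triplet string.
#' @param d_min Resolution limit of the generated reflections (angstrom).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_clusters = NULL, sizes = NULL, n_reflections = 500,
                         n_atoms = 120,
                         base_cell = c(45, 45, 60, 90, 90, 90),
                         cell_jitter = 0.05,
                         amplitude_perturbation = 0.10, noise_sd = 0.05,
                         b_factor_range = c(0, 30),
                         coordinate_shift = c(translation = 0.6, rotation = 1.5),
                         missing_fraction = 0.10,
                         indexing_flip_fraction = 0, flip_op = "k,h,-l",
                         d_min = 3.5, seed = 1L) {
  n_clusters <- n_clusters %||% (if (is.null(sizes)) 3L else length(sizes))
  sizes <- sizes %||% rep(20L, n_clusters)
  if (length(sizes) != n_clusters || any(sizes < 1))
    abort("sizes must give a positive count per cluster",
          class = "xtalclust_config_error")
  if (missing_fraction < 0 || missing_fraction >= 1 ||
      indexing_flip_fraction < 0 || indexing_flip_fraction > 1)
    abort("fractions must lie in [0, 1)", class = "xtalclust_config_error")
  if (noise_sd < 0 || amplitude_perturbation < 0)
    abort("noise_sd and amplitude_perturbation must be >= 0",
          class = "xtalclust_config_error")
  check_unit_cell(base_cell)
  structure(list(n_clusters = as.integer(n_clusters),
                 sizes = as.integer(sizes),
                 n_reflections = as.integer(n_reflections),
                 n_atoms = as.integer(n_atoms),
                 base_cell = as.numeric(base_cell),
                 cell_jitter = cell_jitter,
                 amplitude_perturbation = amplitude_perturbation,
                 noise_sd = noise_sd,
                 b_factor_range = as.numeric(b_factor_range),
                 coordinate_shift = coordinate_shift,
                 missing_fraction = missing_fraction,
                 indexing_flip_fraction = indexing_flip_fraction,
                 flip_op = flip_op,
                 d_min = d_min,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Rodrigues rotation matrix: angle in degrees about unit axis u.
rotation_about <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic multi-data set with planted clusters
#'
#' Base amplitudes are drawn once (log-normal: positive and right-skewed,
#' like crystallographic amplitudes). Each cluster perturbs them
#' multiplicatively along a cluster-specific random direction; each data set
#' then adds observation noise, is damped by its own isotropic B factor
#' `exp(-B s^2 / 4)`, loses a random fraction of reflections, and may be
#' indexed in a flipped orientation. Coordinate models start from a common
#' random fold, take a per-cluster rigid-body shift and rotation, and add
#' per-atom noise and dropout. All randomness derives from `spec$seed`, so
#' regeneration is bitwise reproducible.
#'
#' @param spec A [fixture_spec()].
#' @return A [multidataset()] with an extra `planted_cluster` integer column
#'   (the ground-truth labels).
#' @export
generate_multidataset <- function(spec) {
  if (!inherits(spec, "fixture_spec"))
    abort("spec must be a fixture_spec", class = "xtalclust_config_error")
  withr::with_seed(spec$seed, generate_multidataset_impl(spec))
}

generate_multidataset_impl <- function(spec) {
  cell0 <- spec$base_cell
  # unique-hemisphere index grid within the resolution limit
  hmax <- ceiling(cell0[1:3] / spec$d_min)
  grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                      l = 0:hmax[3])
  hemi <- grid$l > 0 | (grid$l == 0 & grid$k > 0) |
    (grid$l == 0 & grid$k == 0 & grid$h > 0)
  grid <- grid[hemi, ]
  d <- d_spacing(grid$h, grid$k, grid$l, cell0)
  grid <- grid[d >= spec$d_min, ]
  if (nrow(grid) < spec$n_reflections)
    abort(sprintf("only %d reflections available within d_min = %.2f; lower n_reflections",
                  nrow(grid), spec$d_min),
          class = "xtalclust_config_error")
  pick <- sort(sample.int(nrow(grid), spec$n_reflections))
  hkl <- grid[pick, ]

  n_refl <- spec$n_reflections
  F_base <- rlnorm(n_refl, meanlog = log(40), sdlog = 0.7)
  dirs <- matrix(rnorm(n_refl * spec$n_clusters), n_refl, spec$n_clusters)
  flip <- as_symop(spec$flip_op)

  # common fold: a persistent random walk with 3.8 A steps
  steps <- matrix(rnorm(spec$n_atoms * 3), spec$n_atoms, 3)
  for (j in 2:spec$n_atoms)
    steps[j, ] <- 0.7 * steps[j - 1, ] + 0.3 * steps[j, ]
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  fold <- apply(steps, 2, cumsum)
  centroid <- colMeans(fold)
  atom_keys <- sprintf("A/%d", seq_len(spec$n_atoms))

  transforms <- lapply(seq_len(spec$n_clusters), function(c) {
    list(R = rotation_about(random_unit(),
                            spec$coordinate_shift[["rotation"]]),
         t = random_unit() * spec$coordinate_shift[["translation"]])
  })

  labels <- rep(seq_len(spec$n_clusters), times = spec$sizes)
  n_total <- sum(spec$sizes)
  ids <- sprintf("ds%03d", seq_len(n_total))
  tetragonal <- cell0[1] == cell0[2]

  refl <- vector("list", n_total)
  models <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cl <- labels[i]
    # per-data-set unit cell
    if (tetragonal) {
      dab <- rnorm(1, 0, spec$cell_jitter)
      dcell <- c(dab, dab, rnorm(1, 0, spec$cell_jitter))
    } else {
      dcell <- rnorm(3, 0, spec$cell_jitter)
    }
    cell_i <- cell0 + c(dcell, 0, 0, 0)
    # amplitudes: concerted perturbation + observation noise + B damping
    f <- F_base * pmax(1 + spec$amplitude_perturbation * dirs[, cl] +
                         rnorm(n_refl, 0, spec$noise_sd), 0.01)
    B <- runif(1, spec$b_factor_range[1], spec$b_factor_range[2])
    s <- recip_radius(hkl$h, hkl$k, hkl$l, cell_i)
    f <- f * exp(-B * s^2 / 4)
    keep <- runif(n_refl) >= spec$missing_fraction
    rec <- tibble(h = hkl$h[keep], k = hkl$k[keep], l = hkl$l[keep],
                  F = f[keep])
    flipped <- runif(1) < spec$indexing_flip_fraction
    if (flipped) {
      new_hkl <- as.matrix(rec[, c("h", "k", "l")]) %*% t(flip$R)
      rec$h <- as.integer(round(new_hkl[, 1]))
      rec$k <- as.integer(round(new_hkl[, 2]))
      rec$l <- as.integer(round(new_hkl[, 3]))
    }
    refl[[i]] <- reflection_set(rec, ids[i], unit_cell = cell_i)
    # coordinates: per-cluster rigid transform + per-atom noise + dropout
    tr <- transforms[[cl]]
    xyz <- t(tr$R %*% (t(fold) - centroid) + centroid + tr$t) +
      matrix(rnorm(spec$n_atoms * 3, 0, spec$noise_sd), spec$n_atoms, 3)
    akeep <- runif(spec$n_atoms) >= spec$missing_fraction
    models[[i]] <- coordinate_model(
      tibble(atom_key = atom_keys[akeep],
             x = xyz[akeep, 1], y = xyz[akeep, 2], z = xyz[akeep, 3]),
      ids[i], unit_cell = cell_i)
  }
  out <- multidataset(refl, models)
  out$planted_cluster <- labels
  out
}

#' Write a synthetic multi-data set to disk
#'
#' Writes one TSV reflection list (dialect of [write_reflections()]) and one
#' minimal PDB model per data set, a `manifest.tsv` (dataset_id, reflection
#' and model paths) consumable by [run_pipeline()], and — when planted
#' labels are present — a `labels.tsv` sidecar with the ground truth.
#'
#' @param mds A [multidataset()], e.g. from [generate_multidataset()].
#' @param out_dir Output directory, created if absent.
#' @param models Also write PDB models (default `TRUE` when present).
#' @return Invisibly, the manifest tibble.
#' @export
write_fixture <- function(mds, out_dir, models = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (nrow(mds) == 0) {
    warn("empty multi-data set; nothing written")
    return(invisible(tibble(dataset_id = character(),
                            reflections = character(), model = character())))
  }
  have_models <- models && all(!vapply(mds$model, is.null, logical(1)))
  manifest <- tibble(
    dataset_id = mds$dataset_id,
    reflections = file.path(out_dir, paste0(mds$dataset_id, ".tsv")),
    model = if (have_models)
      file.path(out_dir, paste0(mds$dataset_id, ".pdb")) else NA_character_)
  for (i in seq_len(nrow(mds))) {
    write_reflections(mds$reflections[[i]], manifest$reflections[i])
    if (have_models) write_model_pdb(mds$model[[i]], manifest$model[i])
  }
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  if ("planted_cluster" %in% names(mds))
    readr::write_tsv(tibble(dataset_id = mds$dataset_id,
                            planted_cluster = mds$planted_cluster),
                     file.path(out_dir, "labels.tsv"))
  invisible(manifest)
}
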