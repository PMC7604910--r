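# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately take the naive route (explicit loops, textbook
# formulas) so they stay independent of the package's vectorized paths.

# Textbook Pearson as an explicit sum of products.
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  num / sqrt(sxx * syy)
}

# Direct triclinic 1/d^2 formula (volume expansion), independent of the
# metric-tensor route used by the package.
naive_d_spacing <- function(h, k, l, cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  V <- a * b * cc * sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                           2 * cos(al) * cos(be) * cos(ga))
  S11 <- (b * cc * sin(al))^2
  S22 <- (a * cc * sin(be))^2
  S33 <- (a * b * sin(ga))^2
  S12 <- a * b * cc^2 * (cos(al) * cos(be) - cos(ga))
  S23 <- a^2 * b * cc * (cos(be) * cos(ga) - cos(al))
  S13 <- a * b^2 * cc * (cos(ga) * cos(al) - cos(be))
  inv_d2 <- (S11 * h^2 + S22 * k^2 + S33 * l^2 +
               2 * S12 * h * k + 2 * S23 * k * l + 2 * S13 * h * l) / V^2
  1 / sqrt(inv_d2)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

cubic_cell <- c(100, 100, 100, 90, 90, 90)

# Quick reflection set from vectors.
quick_refl <- function(h, k, l, F, id = "d1", cell = cubic_cell) {
  reflection_set(data.frame(h = h, k = k, l = l, F = F), id, unit_cell = cell)
}

quick_model <- function(keys, xyz, id = "m1", cell = NULL) {
  coordinate_model(data.frame(atom_key = keys, x = xyz[, 1], y = xyz[, 2],
                              z = xyz[, 3]), id, unit_cell = cell)
}

# Small standard fixture used by several files.
small_fixture <- function(seed = 2, sizes = c(6L, 6L, 6L), ...) {
  generate_multidataset(fixture_spec(n_clusters = length(sizes),
                                     sizes = sizes, n_reflections = 200,
                                     n_atoms = 40, seed = seed, ...))
}

# Two-level planted hierarchy: 2 super-groups x 2 subgroups, built from
# scratch (no B factors, no dropout) so the nesting is exact: a strong
# super-group amplitude direction plus a weaker subgroup direction.
hierarchical_fixture <- function(n_per_leaf = 6, n_refl = 300, seed = 42) {
  withr::with_seed(seed, {
    F_base <- rlnorm(n_refl, log(40), 0.7)
    super_dir <- matrix(rnorm(n_refl * 2), n_refl, 2)
    sub_dir <- matrix(rnorm(n_refl * 4), n_refl, 4)
    hkl <- expand.grid(h = 1:20, k = 1:20, l = 1:5)[seq_len(n_refl), ]
    refl <- list(); labels <- integer(0)
    i <- 0
    for (g in 1:2) for (s in 1:2) {
      leaf <- (g - 1) * 2 + s
      for (r in seq_len(n_per_leaf)) {
        i <- i + 1
        f <- F_base * pmax(1 + 0.25 * super_dir[, g] + 0.10 * sub_dir[, leaf] +
                             rnorm(n_refl, 0, 0.03), 0.01)
        refl[[i]] <- reflection_set(
          data.frame(h = hkl$h, k = hkl$k, l = hkl$l, F = f),
          sprintf("hd%02d", i), unit_cell = c(60, 60, 60, 90, 90, 90))
        labels <- c(labels, leaf)
      }
    }
    list(mds = multidataset(refl), labels = labels)
  })
}
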