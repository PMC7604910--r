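# Difference series, bounded Pearson, correlation matrix, SVD embedding.

test_that("difference series span exactly the commonly recorded subset", {
  avg_cell <- c(60, 60, 60, 90, 90, 90)
  s1 <- quick_refl(1:4, rep(0, 4), rep(0, 4), c(10, 20, 30, 40), cell = avg_cell)
  s2 <- quick_refl(2:5, rep(0, 5 - 2 + 1), rep(0, 4), c(22, 28, 44, 50),
                   id = "d2", cell = avg_cell)
  avg <- average_amplitudes(list(s1, s2))
  ds <- diff_series_reciprocal(s1, s2, avg)
  expect_identical(ds$h, 2:4)  # intersection only
  expect_equal(ds$v_m, s1$F[2:4] - avg$F_avg[match(2:4, avg$h)])

  # identical sets give identical series; the average itself gives zeros
  ds_same <- diff_series_reciprocal(s1, s1, avg)
  expect_identical(ds_same$v_m, ds_same$v_n)
  rs_avg <- reflection_set(data.frame(h = avg$h, k = avg$k, l = avg$l,
                                      F = avg$F_avg), "avg", avg_cell)
  ds_avg <- diff_series_reciprocal(rs_avg, s2, avg)
  expect_equal(ds_avg$v_m, rep(0, nrow(ds_avg)))

  # dropout fixture: lengths equal the brute-force intersection count
  mds <- small_fixture(seed = 37, missing_fraction = 0.3)
  avg2 <- average_amplitudes(mds)
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    a <- mds$reflections[[pair[1]]]; b <- mds$reflections[[pair[2]]]
    n_common <- length(intersect(paste(a$h, a$k, a$l), paste(b$h, b$k, b$l)))
    expect_equal(nrow(diff_series_reciprocal(a, b, avg2)), n_common)
  }
})

test_that("real-space series interleave x, y, z per common atom", {
  avg <- average_coordinates(list(
    quick_model("A/1", matrix(c(0, 0, 0), 1)),
    quick_model("A/1", matrix(c(0, 0, 0), 1), id = "m0")))
  m1 <- quick_model("A/1", matrix(c(1, 2, 3), 1), id = "a")
  m2 <- quick_model("A/1", matrix(c(2, 4, 6), 1), id = "b")
  ds <- diff_series_realspace(m1, m2, avg)
  expect_equal(ds$v_m, c(1, 2, 3))
  expect_equal(ds$v_n, c(2, 4, 6))
  expect_identical(ds$comp, c("x", "y", "z"))

  mds <- small_fixture(seed = 41, missing_fraction = 0.25)
  avg2 <- average_coordinates(mds)
  a <- mds$model[[2]]; b <- mds$model[[7]]
  n_common <- length(intersect(a$atom_key, b$atom_key))
  expect_equal(nrow(diff_series_realspace(a, b, avg2)), 3L * n_common)
})

test_that("pearson_bounded is textbook Pearson clamped to [0, 1]", {
  v <- c(1.2, -0.4, 3.1, 0.7)
  expect_equal(pearson_bounded(v, v), 1.0)
  # perfect anticorrelation clamps to zero
  expect_equal(pearson_bounded(v, -(v - mean(v)) + mean(v)), 0)
  # worked example: r = 6.5 / sqrt(43.75)
  expect_equal(pearson_bounded(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               6.5 / sqrt(43.75), tolerance = 1e-12)
  expect_equal(naive_pearson(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               6.5 / sqrt(43.75), tolerance = 1e-12)

  # random pairs agree with the sum-of-products oracle
  withr::with_seed(43, {
    for (i in 1:200) {
      n <- sample(3:50, 1)
      x <- rnorm(n); y <- rnorm(n) + 0.3 * x
      expect_equal(pearson_bounded(x, y), max(0, naive_pearson(x, y)),
                   tolerance = 1e-12)
    }
  })

  expect_error(pearson_bounded(1:3, 1:4), "lengths differ",
               class = "xtalclust_contract_error")
  expect_warning(r <- pearson_bounded(1, 1), "too short")
  expect_equal(r, 0)
  expect_warning(r2 <- pearson_bounded(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_equal(r2, 0)
})

test_that("build_matrix equals the per-pair brute-force route", {
  mds <- small_fixture(seed = 47, sizes = c(3L, 3L), missing_fraction = 0.2)
  avg <- average_amplitudes(mds)
  M <- build_matrix(mds, average = avg)
  # dual route: explicit per-pair difference series + pearson_bounded
  for (m in 1:5) for (n in (m + 1):6) {
    ds <- diff_series_reciprocal(mds$reflections[[m]], mds$reflections[[n]],
                                 avg)
    expect_equal(M[m, n], pearson_bounded(ds$v_m, ds$v_n), tolerance = 1e-12)
  }
  expect_identical(unname(diag(M)), rep(0, 6))
  expect_identical(unclass(M), t(unclass(M)))
  expect_true(all(M >= 0 & M <= 1))

  # two identical data sets correlate perfectly against a shared average
  s <- mds$reflections[[1]]
  other <- mds$reflections[[4]]
  twin <- multidataset(list(s, reflection_set(
    as.data.frame(s[, c("h", "k", "l", "F")]), "twin",
    attr(s, "unit_cell")), other))
  M2 <- build_matrix(twin)
  expect_equal(M2[1, 2], 1, tolerance = 1e-12)
  # ... whereas against their own two-set average the difference series
  # have zero variance and the coefficient falls back to 0
  pair_only <- mds_subset2 <- multidataset(list(s, reflection_set(
    as.data.frame(s[, c("h", "k", "l", "F")]), "twin",
    attr(s, "unit_cell"))))
  expect_warning(M3 <- build_matrix(pair_only), "zero-variance")
  expect_equal(M3[1, 2], 0)

  one <- multidataset(list(s))
  expect_error(build_matrix(one), "N >= 2",
               class = "xtalclust_config_error")
})

test_that("matrix entries are invariant to rescaling and translation", {
  mds <- apply_resolution_cutoff(small_fixture(seed = 53, sizes = c(4L, 4L)))
  run <- function(m) {
    sc <- scale_multidataset(m)
    build_matrix(sc$data, average = sc$average)
  }
  M1 <- run(mds)
  # multiply one data set's amplitudes by a positive constant
  mds2 <- mds
  s <- mds2$reflections[[3]]
  mds2$reflections[[3]] <- reflection_set(
    data.frame(h = s$h, k = s$k, l = s$l, F = s$F * 11.7), "ds003",
    attr(s, "unit_cell"))
  M2 <- run(mds2)
  expect_equal(unclass(M1), unclass(M2), tolerance = 1e-9)

  # global translation of all models leaves the real-space matrix unchanged
  Mr1 <- build_matrix(mds, mode = "realspace")
  mds3 <- mds
  mds3$model <- lapply(mds3$model, function(m) {
    coordinate_model(data.frame(atom_key = m$atom_key, x = m$x + 5,
                                y = m$y - 3, z = m$z + 12),
                     attr(m, "dataset_id"), attr(m, "unit_cell"))
  })
  Mr2 <- build_matrix(mds3, mode = "realspace")
  expect_equal(unclass(Mr1), unclass(Mr2), tolerance = 1e-9)
})

test_that("SVD reconstructs the matrix with canonical signs", {
  M <- xtalclust:::new_correlation_matrix(matrix(c(0, 1, 1, 0), 2),
                                          c("a", "b"))
  sv <- svd_decompose(M)
  expect_equal(sv$W, c(1, 1), tolerance = 1e-12)
  expect_equal(sv$U %*% diag(sv$W) %*% t(sv$V), unclass(M),
               tolerance = 1e-12, ignore_attr = TRUE)

  Z <- xtalclust:::new_correlation_matrix(matrix(0, 3, 3), c("a", "b", "c"))
  expect_equal(svd_decompose(Z)$W, rep(0, 3))

  withr::with_seed(59, {
    A <- matrix(runif(400), 20)
    A <- (A + t(A)) / 2; diag(A) <- 0
    cm <- xtalclust:::new_correlation_matrix(A, sprintf("d%02d", 1:20))
    sv2 <- svd_decompose(cm)
    expect_lt(norm(sv2$U %*% diag(sv2$W) %*% t(sv2$V) - A, "F"), 1e-10)
    expect_lt(max(abs(crossprod(sv2$U) - diag(20))), 1e-10)
    expect_true(all(diff(sv2$W) <= 1e-12))
    # canonical sign: the largest-magnitude entry of each column is positive
    for (j in 1:20) expect_gte(sv2$U[which.max(abs(sv2$U[, j])), j], 0)
    # bitwise determinism
    sv3 <- svd_decompose(cm)
    expect_identical(sv2$U, sv3$U)
  })
})

test_that("axis projection selects U columns and is label-equivariant", {
  mds <- small_fixture(seed = 61)
  fit_cm <- build_matrix(scale_multidataset(apply_resolution_cutoff(mds))$data)
  sv <- svd_decompose(fit_cm)
  proj <- project_axes(sv)
  expect_identical(attr(proj, "axes"), 1:3)
  expect_equal(proj$s1, sv$U[, 1])
  pw <- project_axes(sv, axes = c(2, 3, 4), weight = TRUE)
  expect_equal(pw$s1, sv$U[, 2] * sv$W[2])
  expect_error(project_axes(sv, axes = c(1, 1, 2)), "distinct",
               class = "xtalclust_config_error")

  # swapping two data sets swaps the corresponding embedding rows
  perm <- seq_len(nrow(mds)); perm[c(1, 5)] <- c(5, 1)
  mds_p <- xtalclust:::new_multidataset(mds[perm, ])
  cm_p <- build_matrix(scale_multidataset(apply_resolution_cutoff(mds_p))$data)
  proj_p <- project_axes(svd_decompose(cm_p))
  expect_equal(proj_p[match(proj$dataset_id, proj_p$dataset_id), ],
               proj, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the top SVD axis separates a planted two-population fixture", {
  mds <- small_fixture(seed = 67, sizes = c(8L, 8L))
  sc <- scale_multidataset(apply_resolution_cutoff(mds))
  sv <- svd_decompose(build_matrix(sc$data, average = sc$average))
  u1 <- abs(sv$U[, 1])
  member <- u1 > 0.5 * max(u1)
  planted <- mds$planted_cluster == 1
  expect_true(all(member == planted) || all(member == !planted))
})

test_that("reordering by cluster permutes without changing values", {
  mds <- small_fixture(seed = 71)
  fit <- suppressWarnings(cluster_datasets(mds, k = 3, seed = 3))
  ro <- reorder_matrix(fit$matrix, fit$tree)
  expect_setequal(as.vector(ro), as.vector(unclass(fit$matrix)))
  expect_identical(sort(rownames(ro)), sort(rownames(fit$matrix)))
  # members of each terminal cluster are contiguous
  blocks <- attr(ro, "blocks")
  expect_equal(sum(blocks), nrow(ro))
  assignment <- tidy(fit$tree)
  at <- assignment$cluster_path[match(rownames(ro), assignment$dataset_id)]
  expect_identical(at, rep(names(blocks), blocks))
  # planted blocks correlate more within than between
  lab <- mds$planted_cluster[match(rownames(ro), mds$dataset_id)]
  same <- outer(lab, lab, `==`) & upper.tri(ro)
  diff <- outer(lab, lab, `!=`) & upper.tri(ro)
  expect_gt(mean(ro[same]), mean(ro[diff]))

  wrong <- xtalclust:::new_cluster_tree(xtalclust:::new_tree_node(
    "root", c("nope"), children = list(xtalclust:::new_tree_node("1", "nope"))))
  expect_error(reorder_matrix(fit$matrix, wrong), "cover",
               class = "xtalclust_consistency_error")
})
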