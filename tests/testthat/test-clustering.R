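# Cluster assignment, subclustering, outliers, symmetry collapse, indexing.

test_that("k-means assignment is deterministic and recovers planted blobs", {
  blob <- function(center, n, sd = 0.02, seed) withr::with_seed(seed,
    matrix(rnorm(n * 3, rep(center, each = n), sd), n, 3))
  X <- rbind(blob(c(1, 0, 0), 10, seed = 1), blob(c(0, 1, 0), 8, seed = 2),
             blob(c(0, 0, 1), 6, seed = 3))
  proj <- structure(tibble::tibble(dataset_id = sprintf("p%02d", 1:24),
                                   s1 = X[, 1], s2 = X[, 2], s3 = X[, 3]),
                    axes = 1:3, class = c("axis_projection",
                                          class(tibble::tibble())))
  planted <- rep(1:3, c(10, 8, 6))
  a1 <- assign_clusters(proj, k = 3, seed = 5)
  expect_equal(ari(a1$cluster, planted), 1.0)
  # deterministic relabelling: cluster 1 is the largest
  expect_equal(as.vector(table(a1$cluster)), c(10, 8, 6))
  a2 <- assign_clusters(proj, k = 3, seed = 5)
  expect_identical(a1, a2)

  expect_equal(unique(assign_clusters(proj, k = 1)$cluster), 1L)
  expect_error(assign_clusters(proj, k = 30), "exceeds",
               class = "xtalclust_config_error")

  # file mode reproduces a manual selection
  tab <- tibble::tibble(dataset_id = proj$dataset_id,
                        label = c("x", "y", "z")[planted])
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  af <- assign_clusters(proj, method = "file", path = path)
  expect_equal(ari(af$cluster, planted), 1.0)
  readr::write_tsv(tab[-1, ], path)
  expect_error(assign_clusters(proj, method = "file", path = path),
               "lacks", class = "xtalclust_consistency_error")
})

test_that("recursive subclustering recovers a planted two-level hierarchy", {
  hf <- hierarchical_fixture()
  fit <- cluster_datasets(hf$mds, k = 2, seed = 9)
  super <- tidy(fit$tree)
  planted_super <- ifelse(hf$labels <= 2, 1, 2)
  expect_equal(ari(super$cluster_path[match(hf$mds$dataset_id,
                                            super$dataset_id)],
                   planted_super), 1.0)
  fit <- subcluster(fit, "1", k = 2, average_policy = "recalculate", seed = 9)
  fit <- subcluster(fit, "2", k = 2, average_policy = "recalculate", seed = 9)
  leaves <- tidy(fit$tree)
  expect_equal(length(unique(leaves$cluster_path)), 4L)
  expect_equal(ari(leaves$cluster_path[match(hf$mds$dataset_id,
                                             leaves$dataset_id)],
                   hf$labels), 1.0)
  # terminal clusters partition the ids
  expect_setequal(leaves$dataset_id, hf$mds$dataset_id)
  expect_equal(anyDuplicated(leaves$dataset_id), 0L)
})

test_that("subclustering guards small nodes and inherited averages", {
  mds <- small_fixture(seed = 73, sizes = c(10L, 3L))
  fit <- suppressWarnings(cluster_datasets(mds, k = 2, seed = 2))
  small_node <- fit$assignment$cluster[match(fit$tree$children[[2]]$members[1],
                                             fit$assignment$dataset_id)]
  expect_warning(fit2 <- subcluster(fit, as.character(small_node), k = 2),
                 "marking complete")
  nd <- xtalclust:::tree_find(fit2$tree, as.character(small_node))
  expect_true(nd$complete)
  expect_length(nd$children, 0)
  expect_error(subcluster(fit2, as.character(small_node), k = 2),
               "complete", class = "xtalclust_config_error")

  # subclustering the full root membership with recalculated averages
  # reproduces the parent matrix
  fitr <- suppressWarnings(cluster_datasets(mds, k = 1, seed = 2))
  fitr2 <- suppressWarnings(subcluster(fitr, "1", k = 2,
                                       average_policy = "recalculate"))
  nd1 <- xtalclust:::tree_find(fitr2$tree, "1")
  expect_length(nd1$children, 2)
  sub_cm <- build_matrix(xtalclust:::mds_subset(fitr$data, nd1$members),
                         average = fitr$average$reciprocal)
  expect_equal(unclass(sub_cm), unclass(fitr$matrix))
})

test_that("outlier models are detected by robust C-alpha deviation", {
  mds <- small_fixture(seed = 79, sizes = 20L, missing_fraction = 0,
                       coordinate_shift = c(translation = 0, rotation = 0))
  # identical-up-to-noise models: nothing removed
  res <- remove_outliers(mds)
  expect_length(res$removed, 0)

  # rigidly shift one model by 10 A
  shifted <- mds
  m <- shifted$model[[7]]
  shifted$model[[7]] <- coordinate_model(
    data.frame(atom_key = m$atom_key, x = m$x + 10, y = m$y, z = m$z),
    attr(m, "dataset_id"), attr(m, "unit_cell"))
  res2 <- remove_outliers(shifted)
  expect_identical(res2$removed, shifted$dataset_id[7])
  expect_equal(nrow(res2$kept), 19L)

  res3 <- remove_outliers(shifted, threshold_mads = Inf)
  expect_length(res3$removed, 0)

  expect_error(remove_outliers(mds$model[1:2]), "at least 3",
               class = "xtalclust_config_error")
})

test_that("symmetry operators parse from triplet notation", {
  op <- parse_symop("-x,y+1/2,-z")
  expect_equal(op$R, matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3))
  expect_equal(op$t, c(0, 0.5, 0))
  flip <- parse_symop("k,h,-l")
  expect_equal(flip$R, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3))
  expect_equal(flip$t, c(0, 0, 0))
  expect_error(parse_symop("x,y"), "triplet",
               class = "xtalclust_config_error")
  expect_error(parse_symop("x,y,q"), "cannot parse",
               class = "xtalclust_config_error")
})

test_that("symmetry collapse restores a common frame and is idempotent", {
  cell <- c(45, 45, 60, 90, 90, 90)
  mds <- small_fixture(seed = 83, sizes = 16L, missing_fraction = 0,
                       amplitude_perturbation = 0,
                       coordinate_shift = c(translation = 0, rotation = 0))
  avg0 <- average_coordinates(mds)
  planted_noise <- mean(vapply(mds$model, xtalclust:::model_deviation,
                               numeric(1), average = avg0))
  twofold <- "-x,-y,z"
  half <- 1:8
  mds$model[half] <- lapply(mds$model[half], xtalclust:::apply_symop,
                            op = parse_symop(twofold), cell = cell)
  mixed_dev <- mean(vapply(mds$model, xtalclust:::model_deviation,
                           numeric(1),
                           average = average_coordinates(mds)))
  expect_gt(mixed_dev, planted_noise * 5)  # frames truly diverge

  res <- collapse_symmetry(mds, list("x,y,z", twofold), unit_cell = cell)
  expect_lt(mean(res$report$deviation), planted_noise + 1e-6)
  # the two pre-collapse frames get opposite consistent treatments
  expect_length(unique(res$report$chosen_op[half]), 1L)
  expect_length(unique(res$report$chosen_op[-half]), 1L)
  expect_false(res$report$chosen_op[1] == res$report$chosen_op[9])

  # a second collapse is a no-op
  res2 <- collapse_symmetry(res$data, list("x,y,z", twofold),
                            unit_cell = cell)
  expect_setequal(res2$report$chosen_op, "x,y,z")
  expect_equal(res2$data$model[[1]]$x, res$data$model[[1]]$x,
               tolerance = 1e-12)

  # collapse never increases any model's deviation to the running average
  expect_true(all(res$report$deviation <=
                    vapply(mds$model, xtalclust:::model_deviation, numeric(1),
                           average = average_coordinates(mds)) + 1e-9))

  expect_error(collapse_symmetry(mds, list(twofold), unit_cell = cell),
               "identity", class = "xtalclust_config_error")
})

test_that("indexing ambiguity is resolved to one orientation class", {
  mds <- generate_multidataset(fixture_spec(
    n_clusters = 1, sizes = 40L, amplitude_perturbation = 0,
    n_reflections = 400, n_atoms = 30, seed = 89))
  flip <- parse_symop("k,h,-l")
  flipped_idx <- 1:15
  remap <- function(rs) {
    hkl <- as.matrix(tibble::as_tibble(rs)[, c("h", "k", "l")]) %*% t(flip$R)
    reflection_set(data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                              F = rs$F),
                   attr(rs, "dataset_id"), attr(rs, "unit_cell"))
  }
  mds$reflections[flipped_idx] <- lapply(mds$reflections[flipped_idx], remap)

  # ops leaving a set with no common reflections are skipped, with the
  # degenerate-guard warning
  res <- NULL
  warnings <- capture_warnings(
    res <- resolve_indexing(mds, list("h,k,l", "k,h,-l")))
  expect_true(any(grepl("shares [01] < 3", warnings)))
  expect_true(res$converged)
  expect_lte(res$iterations, 10L)
  # single orientation class: the flipped sets get exactly one treatment,
  # the rest the other
  chosen <- res$report$chosen_op
  expect_length(unique(chosen[flipped_idx]), 1L)
  expect_length(unique(chosen[-flipped_idx]), 1L)
  expect_false(chosen[1] == chosen[16])
  # post-resolution, every pair correlates strongly in plain amplitudes
  avg <- average_amplitudes(res$data)
  cors <- vapply(res$data$reflections, function(rs) {
    j <- dplyr::inner_join(tibble::as_tibble(rs), tibble::as_tibble(avg),
                           by = c("h", "k", "l"))
    cor(j$F, j$F_avg)
  }, numeric(1))
  expect_true(all(cors > 0.9))

  # consistently indexed input: everything stays put
  consistent <- generate_multidataset(fixture_spec(
    n_clusters = 1, sizes = 8L, amplitude_perturbation = 0,
    n_reflections = 300, n_atoms = 30, seed = 97))
  res2 <- suppressWarnings(resolve_indexing(consistent, list("h,k,l", "k,h,-l")))
  expect_setequal(res2$report$chosen_op, "h,k,l")

  expect_error(resolve_indexing(mds, list("h,k,l", "h,k,0")),
               "det", class = "xtalclust_config_error")
  expect_error(resolve_indexing(mds, list("k,h,-l")), "identity",
               class = "xtalclust_config_error")
})
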