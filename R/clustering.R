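# Cluster assignment on the SVD embedding, outlier-model removal, collapse
# of symmetry-related frames, and indexing-ambiguity resolution.

#' Assign flat clusters on an embedding
#'
#' Either k-means on the 3-D SVD embedding (seeded, `nstart = 25`, so runs
#' are reproducible) or an explicit assignment file reproducing a manual
#' selection. Labels are relabelled deterministically: clusters ordered by
#' descending size, ties broken by the lexicographically smallest member id.
#'
#' @param proj An `axis_projection` from [project_axes()].
#' @param method `"kmeans"` or `"file"`.
#' @param k Number of clusters (k-means).
#' @param seed Integer seed for the k-means starts.
#' @param path For `method = "file"`, a TSV with columns `dataset_id`,
#'   `label` covering every embedded data set.
#' @return Tibble with columns `dataset_id` and `cluster` (integer, 1-based).
#' @export
assign_clusters <- function(proj, method = c("kmeans", "file"), k = NULL,
                            seed = 1L, path = NULL) {
  method <- match.arg(method)
  n <- nrow(proj)
  if (method == "kmeans") {
    if (is.null(k) || k < 1)
      abort("k >= 1 required for k-means assignment",
            class = "xtalclust_config_error")
    if (k > n)
      abort(sprintf("k = %d exceeds the number of data sets (%d)", k, n),
            class = "xtalclust_config_error")
    X <- as.matrix(proj[, c("s1", "s2", "s3")])
    raw <- if (k == 1) rep(1L, n) else
      withr::with_seed(as.integer(seed),
                       kmeans(X, centers = k, nstart = 25, iter.max = 100)$cluster)
  } else {
    if (is.null(path))
      abort("assignment file path required", class = "xtalclust_config_error")
    tab <- readr::read_tsv(path, col_types = readr::cols(
      dataset_id = readr::col_character(), label = readr::col_character()))
    missing <- setdiff(proj$dataset_id, tab$dataset_id)
    if (length(missing))
      abort(sprintf("assignment file lacks %d dataset id(s), e.g. '%s'",
                    length(missing), missing[1]),
            class = "xtalclust_consistency_error")
    raw <- as.integer(factor(tab$label[match(proj$dataset_id, tab$dataset_id)]))
  }
  tibble(dataset_id = proj$dataset_id,
         cluster = relabel_deterministic(proj$dataset_id, raw))
}

# Relabel integer cluster labels: 1 = largest cluster; ties by smallest
# member id. Stable across permutations of the raw labels.
relabel_deterministic <- function(ids, raw) {
  raw <- as.integer(factor(raw))
  sizes <- tabulate(raw)
  first_member <- vapply(seq_along(sizes),
                         function(g) min(ids[raw == g]), character(1))
  rank <- order(-sizes, first_member)
  new_label <- integer(length(sizes))
  new_label[rank] <- seq_along(sizes)
  new_label[raw]
}

#' Remove outlier coordinate models
#'
#' Scores each model by the mean Euclidean deviation of its C-alpha atoms
#' from the average positions, and removes models whose score exceeds
#' `median + threshold_mads * MAD` over all models. The MAD is floored at
#' 0.1 angstrom so that an essentially identical multi-data set removes
#' nothing. Recompute the coordinate average afterwards so it is unbiased by
#' the outliers.
#'
#' @param x A [multidataset()] with models, or a list of
#'   [coordinate_model()]s.
#' @param average Optional [average_coordinates()]; computed when `NULL`.
#' @param threshold_mads Threshold in MADs above the median (default 5; use
#'   `Inf` to disable).
#' @param mad_floor Absolute floor on the MAD in angstroms (default 0.1).
#' @return List with `kept` (same type as `x`), `removed` (dataset ids) and
#'   `scores` (tibble: `dataset_id`, `score`, `removed`).
#' @export
remove_outliers <- function(x, average = NULL, threshold_mads = 5,
                            mad_floor = 0.1) {
  is_mds <- inherits(x, "multidataset")
  models <- if (is_mds) x$model else x
  if (length(models) < 3)
    abort("at least 3 models required for outlier detection",
          class = "xtalclust_config_error")
  average <- average %||% average_coordinates(if (is_mds) x else models)
  ids <- vapply(models, attr, character(1), "dataset_id")
  scores <- vapply(models, model_deviation, numeric(1), average = average)
  cut <- median(scores) + threshold_mads * max(mad(scores), mad_floor)
  out <- scores > cut
  report <- tibble(dataset_id = ids, score = scores, removed = out)
  kept <- if (is_mds) mds_subset(x, ids[!out]) else models[!out]
  list(kept = kept, removed = ids[out], scores = report)
}

# Mean Euclidean C-alpha deviation of one model from the average positions,
# over the atoms present in both.
model_deviation <- function(model, average) {
  idx <- match(model$atom_key, average$atom_key)
  ok <- !is.na(idx)
  if (!any(ok)) return(Inf)
  mean(sqrt((model$x[ok] - average$x[idx[ok]])^2 +
            (model$y[ok] - average$y[idx[ok]])^2 +
            (model$z[ok] - average$z[idx[ok]])^2))
}

#' Parse a symmetry operator triplet
#'
#' Parses crystallographic triplet notation such as `"-x,y+1/2,-z"` into a
#' rotation matrix and translation vector in the fractional frame. The
#' letters `h,k,l` are accepted as synonyms for `x,y,z`, so reciprocal-space
#' index remappings like `"k,h,-l"` use the same notation.
#'
#' @param triplet Operator string: three comma-separated components, each a
#'   signed combination of `x`, `y`, `z` (or `h`, `k`, `l`) and numeric
#'   fractions.
#' @return A `symop`: list with `R` (3 x 3) and `t` (length 3), plus the
#'   source string as attribute `"label"`.
#' @examples
#' parse_symop("-x,-y,z")
#' parse_symop("k,h,-l")
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub("\\s", "", tolower(triplet)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    abort(sprintf("'%s' is not an x,y,z triplet", triplet),
          class = "xtalclust_config_error")
  axes <- c(x = 1L, y = 2L, z = 3L, h = 1L, k = 2L, l = 3L)
  as_frac <- function(s) {
    if (grepl("/", s, fixed = TRUE)) {
      num <- strsplit(s, "/", fixed = TRUE)[[1]]
      as.numeric(num[1]) / as.numeric(num[2])
    } else as.numeric(s)
  }
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    # split into signed terms
    terms <- regmatches(parts[i],
                        gregexpr("[+-]?[^+-]+", parts[i]))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      letter <- sub("^[0-9/.]*\\*?", "", body)
      if (nzchar(letter) && letter %in% names(axes)) {
        coef <- sub("\\*?[xyzhkl]$", "", body)
        coef <- if (coef == "") 1 else as_frac(coef)
        R[i, axes[[letter]]] <- R[i, axes[[letter]]] + sign * coef
      } else if (!nzchar(letter)) {
        t[i] <- t[i] + sign * as_frac(body)
      } else {
        abort(sprintf("cannot parse operator term '%s' in '%s'",
                      term, triplet),
              class = "xtalclust_config_error")
      }
    }
  }
  if (anyNA(R) || anyNA(t))
    abort(sprintf("cannot parse operator '%s'", triplet),
          class = "xtalclust_config_error")
  structure(list(R = R, t = t), label = triplet, class = "symop")
}

as_symop <- function(op) {
  if (inherits(op, "symop")) return(op)
  if (is.character(op)) return(parse_symop(op))
  if (is.list(op) && !is.null(op$R))
    return(structure(list(R = op$R, t = op$t %||% numeric(3)),
                     label = op$label %||% "matrix", class = "symop"))
  if (is.matrix(op))
    return(structure(list(R = op, t = numeric(3)),
                     label = "matrix", class = "symop"))
  abort("cannot interpret symmetry operator", class = "xtalclust_config_error")
}

is_identity_op <- function(op) {
  isTRUE(all.equal(op$R, diag(3))) && isTRUE(all.equal(op$t, numeric(3)))
}

# Apply a symop (fractional convention) to a model's orthogonal coordinates.
apply_symop <- function(model, op, cell) {
  A <- orth_matrix(cell)
  X <- t(as.matrix(model[, c("x", "y", "z")]))
  Fr <- solve(A, X)
  Xp <- A %*% (op$R %*% Fr + op$t)
  out <- as_tibble(model)
  out$x <- Xp[1, ]; out$y <- Xp[2, ]; out$z <- Xp[3, ]
  model_like(out, model)
}

#' Collapse symmetry-related coordinate frames
#'
#' Where data sets of one multi-data set have been modelled in different
#' symmetry-equivalent frames, comparing C-alpha positions directly is
#' meaningless. For each model this applies every candidate operator (in
#' fractional coordinates) and keeps the one minimizing the mean C-alpha
#' deviation to the average positions, bringing all models to a common
#' frame; ties go to the earlier operator in the list, which must include
#' the identity. A single refresh pass recomputes the average from the
#' collapsed models and re-collapses once, so the reference is not biased by
#' the initial mixture of frames.
#'
#' @param x A [multidataset()] with models, or a list of
#'   [coordinate_model()]s.
#' @param operators List of operators: xyz triplet strings (see
#'   [parse_symop()]), `symop` objects, or rotation matrices.
#' @param average Optional initial [average_coordinates()].
#' @param unit_cell Unit cell for the fractional/orthogonal conversion;
#'   defaults to the cell attached to the first model.
#' @return List with `data` (collapsed, same type as `x`), `report` (tibble:
#'   `dataset_id`, `chosen_op`, `deviation`), and `average` (refreshed).
#' @export
collapse_symmetry <- function(x, operators, average = NULL, unit_cell = NULL) {
  if (length(operators) == 0)
    abort("at least one symmetry operator required (include the identity)",
          class = "xtalclust_config_error")
  ops <- lapply(operators, as_symop)
  if (!any(vapply(ops, is_identity_op, logical(1))))
    abort("operator list must include the identity",
          class = "xtalclust_config_error")
  is_mds <- inherits(x, "multidataset")
  models <- if (is_mds) x$model else x
  unit_cell <- unit_cell %||% attr(models[[1]], "unit_cell")
  if (is.null(unit_cell))
    abort("a unit cell is required for symmetry collapse",
          class = "xtalclust_config_error")
  average <- average %||% average_coordinates(models)

  pass <- function(models, average) {
    choice <- integer(length(models))
    for (i in seq_along(models)) {
      devs <- vapply(ops, function(op)
        model_deviation(apply_symop(models[[i]], op, unit_cell), average),
        numeric(1))
      choice[i] <- which.min(devs)  # which.min takes the first on ties
      models[[i]] <- apply_symop(models[[i]], ops[[choice[i]]], unit_cell)
    }
    list(models = models, choice = choice)
  }

  p1 <- pass(models, average)
  average <- average_coordinates(p1$models)
  p2 <- pass(p1$models, average)
  average <- average_coordinates(p2$models)

  labels <- vapply(ops, function(o) attr(o, "label") %||% "op", character(1))
  # net operator applied over both passes: (R2, t2) o (R1, t1)
  net_label <- vapply(seq_along(models), function(i) {
    o1 <- ops[[p1$choice[i]]]; o2 <- ops[[p2$choice[i]]]
    net_R <- o2$R %*% o1$R
    net_t <- as.vector(o2$R %*% o1$t) + o2$t
    hit <- which(vapply(ops, function(o)
      isTRUE(all.equal(o$R, net_R)) && isTRUE(all.equal(o$t, net_t)),
      logical(1)))
    if (length(hit)) labels[hit[1]] else
      sprintf("%s * %s", labels[p2$choice[i]], labels[p1$choice[i]])
  }, character(1))
  report <- tibble(
    dataset_id = vapply(models, attr, character(1), "dataset_id"),
    chosen_op = net_label,
    deviation = vapply(p2$models, model_deviation, numeric(1),
                       average = average))
  if (is_mds) {
    x$model <- p2$models
    list(data = x, report = report, average = average)
  } else {
    list(data = p2$models, report = report, average = average)
  }
}

#' Resolve an indexing ambiguity across a multi-data set
#'
#' In lattices with an indexing ambiguity, geometrically equivalent but
#' symmetry-inequivalent index assignments make amplitude lists from
#' different crystals mutually incomparable. For each data set, every
#' candidate index remapping is applied and the plain (unclamped) Pearson
#' correlation of its amplitudes against the current reference is evaluated
#' over the common indices; the remapping with the highest correlation is
#' adopted. The first pass uses a single data set (the one with the most
#' reflections) as the reference — an average over a mixture of orientations
#' supports every orientation equally and cannot break the ambiguity —
#' and subsequent passes recompute the average from the adopted orientations
#' until no choice changes (at most `max_iter` rounds).
#'
#' @param mds A [multidataset()] (amplitudes within the resolution cutoff;
#'   scaling is not required).
#' @param twin_ops List of candidate remappings: index triplet strings (e.g.
#'   `"k,h,-l"`) or integer 3 x 3 matrices. Must include the identity.
#' @param max_iter Iteration cap (default 10).
#' @param min_common Minimum common reflections for a remapping to be
#'   evaluated (default 3); remappings below it are skipped with a warning.
#' @return List with `data` (reindexed multidataset), `report` (tibble:
#'   `dataset_id`, `chosen_op`, `cor_before`, `cor_after`), `iterations`,
#'   and `converged`.
#' @export
resolve_indexing <- function(mds, twin_ops, max_iter = 10L, min_common = 3L) {
  ops <- lapply(twin_ops, as_symop)
  for (op in ops) {
    if (!all(op$R == round(op$R)) || abs(det(op$R)) != 1 ||
        any(op$t != 0))
      abort("index remappings must be integer matrices with |det| = 1 and no translation",
            class = "xtalclust_config_error")
  }
  if (!any(vapply(ops, is_identity_op, logical(1))))
    abort("twin_ops must include the identity", class = "xtalclust_config_error")
  labels <- vapply(ops, function(o) attr(o, "label") %||% "op", character(1))

  remap <- function(rs, op) {
    hkl <- as.matrix(as_tibble(rs)[, c("h", "k", "l")]) %*% t(op$R)
    refl_like(tibble(h = as.integer(round(hkl[, 1])),
                     k = as.integer(round(hkl[, 2])),
                     l = as.integer(round(hkl[, 3])), F = rs$F), rs)
  }
  op_cor <- function(rs, op, avg) {
    j <- dplyr::inner_join(as_tibble(remap(rs, op)),
                           as_tibble(avg)[, c("h", "k", "l", "F_avg")],
                           by = c("h", "k", "l"))
    if (nrow(j) < min_common) {
      warn(sprintf("data set '%s': remapping '%s' shares %d < %d reflections with the average; skipped",
                   attr(rs, "dataset_id"), attr(op, "label"), nrow(j), min_common))
      return(-Inf)
    }
    if (stats::sd(j$F) == 0 || stats::sd(j$F_avg) == 0) return(-Inf)
    stats::cor(j$F, j$F_avg)
  }

  originals <- mds$reflections
  n <- length(originals)
  id_op <- ops[[which(vapply(ops, is_identity_op, logical(1)))[1]]]
  cor_before <- vapply(originals, function(rs)
    op_cor(rs, id_op, average_amplitudes(originals)), numeric(1))
  # anchor: the most complete single data set; an average over mixed
  # orientations is self-confirming and cannot break the ambiguity
  anchor <- originals[[which.max(vapply(originals, nrow, integer(1)))]]
  avg <- structure(tibble(h = anchor$h, k = anchor$k, l = anchor$l,
                          F_avg = anchor$F, n_obs = 1L),
                   class = c("avg_refl", class(tibble())))
  choice <- rep(NA_integer_, n)
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    new_choice <- vapply(seq_len(n), function(i) {
      cors <- vapply(ops, op_cor, numeric(1), rs = originals[[i]], avg = avg)
      which.max(cors)
    }, integer(1))
    current <- lapply(seq_len(n), function(i) remap(originals[[i]],
                                                    ops[[new_choice[i]]]))
    avg <- average_amplitudes(current)
    if (identical(new_choice, choice)) { converged <- TRUE; break }
    choice <- new_choice
    if (iterations >= max_iter) break
  }
  cor_after <- vapply(seq_len(n), function(i)
    op_cor(originals[[i]], ops[[choice[i]]], avg), numeric(1))
  mds$reflections <- lapply(seq_len(n), function(i)
    remap(originals[[i]], ops[[choice[i]]]))
  list(data = mds,
       report = tibble(dataset_id = mds$dataset_id,
                       chosen_op = labels[choice],
                       cor_before = cor_before,
                       cor_after = cor_after),
       iterations = iterations,
       converged = converged)
}
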