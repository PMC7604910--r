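# Core containers. Reflection sets and coordinate models are tibbles with a
# small set of attributes (dataset_id, unit_cell, ...); a multidataset is a
# nested tibble with one row per data set and list-columns of the two.

#' Construct a reflection set
#'
#' A reflection set is a tibble with integer Miller-index columns `h`, `k`,
#' `l` and an amplitude column `F`, carrying the data-set identifier and unit
#' cell as attributes. Miller-index triples must be unique and amplitudes
#' finite and non-negative.
#'
#' @param records Data frame with columns `h`, `k`, `l` (integer) and `F`
#'   (numeric amplitude, arbitrary positive units).
#' @param dataset_id Identifier string for the data set.
#' @param unit_cell Six numbers: a, b, c (angstrom), alpha, beta, gamma
#'   (degrees). May be `NULL` when no resolution-dependent operation is
#'   needed.
#' @param space_group Optional Hermann-Mauguin symbol (informational).
#' @return A `refl_tbl` tibble.
#' @export
reflection_set <- function(records, dataset_id, unit_cell = NULL,
                           space_group = NA_character_) {
  rec <- as_tibble(records)[, c("h", "k", "l", "F")]
  rec$h <- as.integer(rec$h); rec$k <- as.integer(rec$k)
  rec$l <- as.integer(rec$l); rec$F <- as.numeric(rec$F)
  if (anyNA(rec$h) || anyNA(rec$k) || anyNA(rec$l))
    abort("Miller indices must be integers", class = "xtalclust_parse_error")
  key <- paste(rec$h, rec$k, rec$l)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicated Miller index (%s) in data set '%s'",
                  gsub(" ", ",", dup), dataset_id),
          class = "xtalclust_invariant_error")
  }
  if (!all(is.finite(rec$F)) || any(rec$F < 0))
    abort(sprintf("amplitudes must be finite and >= 0 in data set '%s'",
                  dataset_id),
          class = "xtalclust_invariant_error")
  if (!is.null(unit_cell)) unit_cell <- check_unit_cell(unit_cell)
  structure(rec,
            dataset_id = as.character(dataset_id),
            unit_cell = unit_cell,
            space_group = space_group,
            class = c("refl_tbl", class(rec)))
}

# Rebuild a refl_tbl from a plain data frame, inheriting attributes.
refl_like <- function(records, template) {
  reflection_set(records,
                 dataset_id = attr(template, "dataset_id"),
                 unit_cell = attr(template, "unit_cell"),
                 space_group = attr(template, "space_group"))
}

#' @export
print.refl_tbl <- function(x, ...) {
  cell <- attr(x, "unit_cell")
  cat(sprintf("<reflection set '%s': %d reflections%s>\n",
              attr(x, "dataset_id"), nrow(x),
              if (is.null(cell)) "" else
                sprintf(", cell %.2f %.2f %.2f / %.1f %.1f %.1f",
                        cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])))
  NextMethod()
}

#' Construct a coordinate model
#'
#' An ordered table of C-alpha positions, one row per residue: `atom_key`
#' (chain/residue-number/insertion-code), `x`, `y`, `z` in angstroms
#' (orthogonal frame). Keys must be unique and coordinates finite.
#'
#' @param atoms Data frame with columns `atom_key`, `x`, `y`, `z`.
#' @param dataset_id Identifier string for the data set.
#' @param unit_cell Optional six-number unit cell (needed for symmetry
#'   collapse).
#' @return A `model_tbl` tibble.
#' @export
coordinate_model <- function(atoms, dataset_id, unit_cell = NULL) {
  at <- as_tibble(atoms)[, c("atom_key", "x", "y", "z")]
  at$atom_key <- as.character(at$atom_key)
  if (anyDuplicated(at$atom_key))
    abort(sprintf("duplicate atom_key '%s' in model '%s'",
                  at$atom_key[duplicated(at$atom_key)][1], dataset_id),
          class = "xtalclust_invariant_error")
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
    abort(sprintf("non-finite coordinates in model '%s'", dataset_id),
          class = "xtalclust_invariant_error")
  if (!is.null(unit_cell)) unit_cell <- check_unit_cell(unit_cell)
  structure(at,
            dataset_id = as.character(dataset_id),
            unit_cell = unit_cell,
            class = c("model_tbl", class(at)))
}

model_like <- function(atoms, template) {
  coordinate_model(atoms,
                   dataset_id = attr(template, "dataset_id"),
                   unit_cell = attr(template, "unit_cell"))
}

#' @export
print.model_tbl <- function(x, ...) {
  cat(sprintf("<coordinate model '%s': %d C-alpha atoms>\n",
              attr(x, "dataset_id"), nrow(x)))
  NextMethod()
}

#' Assemble a multi-data set
#'
#' Pairs reflection sets with coordinate models sharing a `dataset_id` into a
#' nested tibble: one row per data set, list-columns `reflections` and
#' `model`. All clustering operations require at least two entries.
#'
#' @param reflections List of [reflection_set()] objects (names ignored; ids
#'   are taken from the objects).
#' @param models List of [coordinate_model()] objects, or `NULL` when only
#'   reciprocal-space work is intended.
#' @return A `multidataset` tibble with columns `dataset_id`, `reflections`,
#'   `model`.
#' @export
multidataset <- function(reflections, models = NULL) {
  ids <- vapply(reflections, attr, character(1), "dataset_id")
  if (anyDuplicated(ids))
    abort(sprintf("duplicate dataset_id '%s'", ids[duplicated(ids)][1]),
          class = "xtalclust_invariant_error")
  out <- tibble(dataset_id = ids, reflections = unname(reflections))
  if (!is.null(models)) {
    mids <- vapply(models, attr, character(1), "dataset_id")
    if (!setequal(mids, ids))
      abort("model dataset_ids do not match reflection dataset_ids",
            class = "xtalclust_invariant_error")
    out$model <- unname(models)[match(ids, mids)]
  } else {
    out$model <- rep(list(NULL), length(ids))
  }
  new_multidataset(out)
}

new_multidataset <- function(tbl) {
  structure(as_tibble(tbl), class = c("multidataset", class(as_tibble(tbl))))
}

#' @export
print.multidataset <- function(x, ...) {
  has_models <- any(!vapply(x$model, is.null, logical(1)))
  cat(sprintf("<multidataset: %d data sets%s>\n", nrow(x),
              if (has_models) " with coordinate models" else ""))
  NextMethod()
}

n_datasets <- function(mds) nrow(mds)

# Retrieve one data set's reflections/model by id.
mds_reflections <- function(mds, id) mds$reflections[[match(id, mds$dataset_id)]]
mds_model <- function(mds, id) mds$model[[match(id, mds$dataset_id)]]

# Subset a multidataset by dataset_id, preserving class.
mds_subset <- function(mds, ids) {
  stopifnot(all(ids %in% mds$dataset_id))
  new_multidataset(mds[match(ids, mds$dataset_id), ])
}

check_min_n <- function(mds, n = 2L) {
  if (n_datasets(mds) < n)
    abort(sprintf("N >= %d data sets required (got %d)", n, n_datasets(mds)),
          class = "xtalclust_config_error")
  invisible(mds)
}
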