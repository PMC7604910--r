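# File I/O: the plain TSV reflection dialect, MTZ (via a gemmi bridge), PDB
# coordinate models, and partition output.
#
# TSV dialect: tab-separated, header row "h k l F", with an optional comment
# line "# cell a b c alpha beta gamma" carrying the unit cell. Deliberately
# minimal so that fixtures and exports interoperate without binary formats.

#' Read a reflection list
#'
#' Reads one data set's Miller-indexed amplitudes from either the plain TSV
#' dialect (header `h k l F`, optional `# cell ...` comment line) or a binary
#' MTZ file. MTZ reading converts through the `gemmi` Python module, which
#' must be importable by the `python` on `PATH`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtz"`.
#' @param dataset_id Identifier; defaults to the file name without extension.
#' @param column For MTZ input, the amplitude column label to use; by default
#'   the first column of MTZ type `F` is taken.
#' @param unit_cell Unit cell to attach when the file carries none.
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, format = c("auto", "tsv", "mtz"),
                             dataset_id = NULL, column = NULL,
                             unit_cell = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), class = "xtalclust_io_error")
  if (format == "auto")
    format <- if (grepl("\\.mtz$", path, ignore.case = TRUE)) "mtz" else "tsv"
  dataset_id <- dataset_id %||% sub("\\.[^.]+$", "", basename(path))
  switch(format,
         tsv = read_reflections_tsv(path, dataset_id, unit_cell),
         mtz = read_reflections_mtz(path, dataset_id, column))
}

read_reflections_tsv <- function(path, dataset_id, unit_cell = NULL) {
  lines <- readLines(path)
  cell_line <- grep("^#\\s*cell\\b", lines, value = TRUE)
  if (length(cell_line) >= 1 && is.null(unit_cell)) {
    unit_cell <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", cell_line[1])),
                                     "\\s+")[[1]])
  }
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body_idx) < 1)
    abort(sprintf("%s: no header row", path), class = "xtalclust_format_error")
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("h", "k", "l", "F")))
    abort(sprintf("%s: expected header 'h\\tk\\tl\\tF', found '%s'",
                  path, lines[body_idx[1]]),
          class = "xtalclust_format_error")
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0) {
    rec <- tibble(h = integer(), k = integer(), l = integer(), F = numeric())
    return(reflection_set(rec, dataset_id, unit_cell))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad_len <- which(lengths(fields) != 4)
  if (length(bad_len))
    abort(sprintf("%s line %d: expected 4 tab-separated fields",
                  path, data_idx[bad_len[1]]),
          class = "xtalclust_parse_error")
  m <- matrix(trimws(unlist(fields)), ncol = 4, byrow = TRUE)
  hkl <- suppressWarnings(apply(m[, 1:3, drop = FALSE], 2, as.numeric))
  hkl <- matrix(hkl, ncol = 3)
  bad <- which(!is.finite(hkl) | hkl != round(hkl), arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort(sprintf("%s line %d: non-integer Miller index '%s'",
                  path, data_idx[bad[1, 1]], m[bad[1, 1], bad[1, 2]]),
          class = "xtalclust_parse_error")
  rec <- tibble(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                l = as.integer(hkl[, 3]),
                F = suppressWarnings(as.numeric(m[, 4])))
  if (anyNA(rec$F))
    abort(sprintf("%s line %d: unreadable amplitude",
                  path, data_idx[which(is.na(rec$F))[1]]),
          class = "xtalclust_parse_error")
  reflection_set(rec, dataset_id, unit_cell)
}

# MTZ -> TSV through python/gemmi, then parse the TSV dialect.
read_reflections_mtz <- function(path, dataset_id, column = NULL) {
  py <- Sys.which("python")
  if (!nzchar(py))
    abort("MTZ reading requires a 'python' with the gemmi module on PATH",
          class = "xtalclust_config_error")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  script <- paste(
    "import sys, gemmi",
    "mtz = gemmi.read_mtz_file(sys.argv[1])",
    "label = sys.argv[3] if len(sys.argv) > 3 else ''",
    "fcols = [c for c in mtz.columns if c.type == 'F']",
    "if label:",
    "    cols = [c for c in mtz.columns if c.label == label]",
    "    if not cols:",
    "        sys.stderr.write('NOCOL:' + ' '.join(c.label for c in mtz.columns))",
    "        sys.exit(3)",
    "    col = cols[0]",
    "else:",
    "    if not fcols:",
    "        sys.stderr.write('NOAMP:' + ' '.join(c.label for c in mtz.columns))",
    "        sys.exit(3)",
    "    col = fcols[0]",
    "cell = mtz.cell",
    "out = open(sys.argv[2], 'w')",
    "out.write('# cell %.6f %.6f %.6f %.6f %.6f %.6f\\n' % (cell.a, cell.b, cell.c, cell.alpha, cell.beta, cell.gamma))",
    "out.write('h\\tk\\tl\\tF\\n')",
    "import math",
    "for hkl, val in zip(mtz.array[:, 0:3], mtz.column_with_label(col.label).array):",
    "    if not math.isnan(val):",
    "        out.write('%d\\t%d\\t%d\\t%.9g\\n' % (int(hkl[0]), int(hkl[1]), int(hkl[2]), val))",
    "out.close()",
    sep = "\n")
  res <- suppressWarnings(
    system2(py, c("-c", shQuote(script), shQuote(path), shQuote(tmp),
                  if (!is.null(column)) shQuote(column)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0) {
    msg <- paste(res, collapse = " ")
    if (grepl("NOCOL:|NOAMP:", msg))
      abort(sprintf("%s: no usable amplitude column; available columns: %s",
                    path, sub(".*(NOCOL:|NOAMP:)", "", msg)),
            class = "xtalclust_format_error")
    abort(sprintf("gemmi failed to read %s: %s", path, msg),
          class = "xtalclust_io_error")
  }
  read_reflections_tsv(tmp, dataset_id)
}

#' Write a reflection set in the TSV dialect
#'
#' @param rs A [reflection_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(rs, path) {
  lines <- character(0)
  cell <- attr(rs, "unit_cell")
  if (!is.null(cell))
    lines <- sprintf("# cell %.6f %.6f %.6f %.6f %.6f %.6f",
                     cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  lines <- c(lines, "h\tk\tl\tF",
             sprintf("%d\t%d\t%d\t%.9g", rs$h, rs$k, rs$l, rs$F))
  writeLines(lines, path)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Retains only C-alpha atoms of ATOM records. Where a residue carries
#' alternate locations, the first C-alpha conformer encountered in file order
#' is kept; later conformers of the same residue are dropped regardless of
#' their altloc label. The atom key is `chain/resno` with any insertion code
#' appended.
#'
#' @param path Path to a PDB file.
#' @param dataset_id Identifier; defaults to the file name without extension.
#' @return A [coordinate_model()].
#' @export
read_model <- function(path, dataset_id = NULL) {
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), class = "xtalclust_io_error")
  dataset_id <- dataset_id %||% sub("\\.[^.]+$", "", basename(path))
  # rm.alt = FALSE: keep every alternate-location record so the
  # first-conformer-in-file-order rule applies, whatever the altloc labels
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0)
    abort(sprintf("%s: no C-alpha atoms found", path),
          class = "xtalclust_empty_model_error")
  ins <- ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert)
  key <- paste0(ca$chain, "/", ca$resno, ins)
  first <- !duplicated(key)  # first conformer in file order
  ca <- ca[first, , drop = FALSE]
  cell <- pdb_unit_cell(path)
  coordinate_model(tibble(atom_key = key[first],
                          x = ca$x, y = ca$y, z = ca$z),
                   dataset_id, unit_cell = cell)
}

pdb_unit_cell <- function(path) {
  cry <- grep("^CRYST1", readLines(path, n = 200), value = TRUE)
  if (length(cry) == 0) return(NULL)
  v <- suppressWarnings(as.numeric(c(
    substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33),
    substr(cry[1], 34, 40), substr(cry[1], 41, 47), substr(cry[1], 48, 54))))
  if (anyNA(v)) NULL else v
}

#' Write a C-alpha model as a minimal PDB file
#'
#' Writes one ATOM record per C-alpha (residue numbers and chains recovered
#' from the atom keys) plus a CRYST1 record when a unit cell is attached.
#'
#' @param cm A [coordinate_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(cm, path) {
  lines <- character(0)
  cell <- attr(cm, "unit_cell")
  if (!is.null(cell))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  chain <- sub("/.*", "", cm$atom_key)
  resno <- as.integer(sub("[A-Za-z]*$", "", sub(".*/", "", cm$atom_key)))
  lines <- c(lines,
             sprintf("ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00 20.00           C",
                     seq_len(nrow(cm)), substr(chain, 1, 1), resno,
                     cm$x, cm$y, cm$z),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a cluster partition to disk
#'
#' Emits one plain-text file of dataset ids per terminal cluster
#' (`cluster_<path>.txt`, one id per line, lexicographically sorted), an
#' assignment table `assignment.tsv` (`dataset_id`, `cluster_path`), and a
#' machine-readable `tree.json`. Output is deterministic: re-running on the
#' same tree yields byte-identical files.
#'
#' @param tree A `cluster_tree` (see [cluster_datasets()]).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the assignment tibble.
#' @export
write_partition <- function(tree, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  leaves <- tree_leaves(tree)
  all_ids <- unlist(lapply(leaves, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(all_ids))
    abort(sprintf("dataset '%s' appears in more than one terminal cluster",
                  all_ids[duplicated(all_ids)][1]),
          class = "xtalclust_consistency_error")
  rows <- list()
  for (leaf in leaves) {
    ids <- sort(leaf$members)
    if (length(ids) == 0) {
      warn(sprintf("terminal cluster '%s' is empty; file omitted", leaf$id))
      next
    }
    safe <- gsub("[^A-Za-z0-9_.-]", "_", leaf$id)
    writeLines(ids, file.path(out_dir, paste0("cluster_", safe, ".txt")))
    rows[[length(rows) + 1]] <- tibble(dataset_id = ids, cluster_path = leaf$id)
  }
  assignment <- dplyr::arrange(dplyr::bind_rows(rows), .data$dataset_id)
  readr::write_tsv(assignment, file.path(out_dir, "assignment.tsv"))
  jsonlite::write_json(tree_to_list(tree), file.path(out_dir, "tree.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(assignment)
}
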