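# Unit-cell geometry: metric tensors, d-spacings, orthogonalization.

check_unit_cell <- function(cell) {
  if (is.null(cell) || length(cell) != 6 || !all(is.finite(cell)))
    abort("unit cell must be six finite numbers (a, b, c, alpha, beta, gamma)",
          class = "xtalclust_config_error")
  if (any(cell[1:3] <= 0))
    abort("unit-cell lengths must be positive", class = "xtalclust_config_error")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    abort("unit-cell angles must lie in (0, 180) degrees",
          class = "xtalclust_config_error")
  as.numeric(cell)
}

# Direct-space metric tensor G; h' G* h = 1/d^2 with G* = solve(G).
cell_metric <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  ca <- cos(cell[4] * pi / 180)
  cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  matrix(c(a * a,     a * b * cg, a * c * cb,
           a * b * cg, b * b,     b * c * ca,
           a * c * cb, b * c * ca, c * c), 3, 3)
}

#' Resolution (d-spacing) of reflections
#'
#' Computes the d-spacing in angstroms for Miller indices `(h, k, l)` in a
#' given unit cell via the reciprocal metric tensor, valid for any crystal
#' system including triclinic.
#'
#' @param h,k,l Integer vectors of Miller indices (recycled to a common
#'   length).
#' @param cell Numeric vector of six: a, b, c in angstroms and alpha, beta,
#'   gamma in degrees.
#' @return Numeric vector of d-spacings in angstroms (`Inf` for (0,0,0)).
#' @examples
#' d_spacing(10, 0, 0, c(100, 100, 100, 90, 90, 90))  # 10 A
#' @export
d_spacing <- function(h, k, l, cell) {
  cell <- check_unit_cell(cell)
  H <- cbind(h, k, l)
  Gstar <- solve(cell_metric(cell))
  q <- rowSums((H %*% Gstar) * H)  # 1/d^2
  ifelse(q > 0, 1 / sqrt(q), Inf)
}

# |s| = 1/d in 1/angstrom
recip_radius <- function(h, k, l, cell) {
  1 / d_spacing(h, k, l, cell)
}

# Standard PDB orthogonalization matrix: x = A %*% fractional.
orth_matrix <- function(cell) {
  cell <- check_unit_cell(cell)
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  ca <- cos(cell[4] * pi / 180)
  cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180); sg <- sin(cell[6] * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(a, b * cg, c * cb,
           0, b * sg, c * (ca - cb * cg) / sg,
           0, 0,      c * v / sg), 3, 3, byrow = TRUE)
}
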