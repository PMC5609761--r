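## Internal geometry and validation helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180

#' Elementary rotation matrices (right-handed, degrees)
#'
#' `rot_x()` and `rot_y()` return 3x3 right-handed rotation matrices about
#' the +X and +Y laboratory axes; `rot_z()` about +Z. Angles are in degrees.
#'
#' @param theta rotation angle in degrees.
#' @return a 3x3 orthogonal matrix with determinant +1.
#' @export
rot_x <- function(theta) {
  t <- deg2rad(theta)
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(theta) {
  t <- deg2rad(theta)
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, s,
           0, 1, 0,
           -s, 0, c), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(theta) {
  t <- deg2rad(theta)
  c <- cos(t); s <- sin(t)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Minimum-image displacement components
#'
#' Wraps per-axis displacement(s) into the nearest periodic image of an
#' orthorhombic box. `box = NULL` disables periodicity.
#'
#' @param d numeric vector/matrix of displacements along one axis (Angstrom).
#' @param l box length along that axis, or `NULL`.
#' @keywords internal
min_image1 <- function(d, l) {
  if (is.null(l) || !is.finite(l) || l <= 0) return(d)
  d - l * round(d / l)
}

## All-pairs squared distances between coordinate matrices (n x 3, m x 3)
## under the minimum-image convention; returns an n x m matrix.
pair_dist2 <- function(xa, xb, box = NULL) {
  dx <- outer(xa[, 1], xb[, 1], "-")
  dy <- outer(xa[, 2], xb[, 2], "-")
  dz <- outer(xa[, 3], xb[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image1(dx, box[1])
    dy <- min_image1(dy, box[2])
    dz <- min_image1(dz, box[3])
  }
  dx * dx + dy * dy + dz * dz
}

## Minimum distance between two coordinate sets.
min_pair_dist <- function(xa, xb, box = NULL) {
  sqrt(min(pair_dist2(xa, xb, box)))
}

#' Extract or replace atom coordinates as a matrix
#'
#' Atom tables carry coordinates in columns `x`, `y`, `z`; these helpers
#' convert to and from an n x 3 matrix.
#'
#' @param atoms an atom table (`data.frame`).
#' @return `atom_coords()`: an n x 3 numeric matrix.
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' @rdname atom_coords
#' @param value an n x 3 numeric matrix of replacement coordinates.
#' @export
set_atom_coords <- function(atoms, value) {
  stopifnot(nrow(value) == nrow(atoms), ncol(value) == 3)
  atoms$x <- value[, 1]
  atoms$y <- value[, 2]
  atoms$z <- value[, 3]
  atoms
}

## Shared validation for atom tables.
validate_atoms <- function(atoms, what = "atom table") {
  req <- c("id", "residue_index", "residue_name", "atom_name",
           "charge", "lj_sigma", "lj_epsilon", "is_backbone",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop(what, " is missing columns: ", paste(missing_cols, collapse = ", "))
  xyz <- atom_coords(atoms)
  if (!all(is.finite(xyz)))
    stop(what, " contains non-finite coordinates")
  if (any(!is.finite(atoms$charge)))
    stop(what, " has unassigned (non-finite) charges")
  if (any(atoms$lj_sigma < 0) || any(atoms$lj_epsilon < 0))
    stop(what, " has negative Lennard-Jones parameters")
  invisible(atoms)
}

#' Construct an atom table
#'
#' Creates the flat per-atom `data.frame` used throughout the package:
#' one row per atom with identity, residue assignment, partial charge (e),
#' Lennard-Jones `sigma` (Angstrom) and `epsilon` (kcal/mol), a backbone
#' flag and Cartesian coordinates in Angstrom.
#'
#' @param id integer atom ids (unique within a system).
#' @param residue_index integer residue numbers (1-based, as in PDB files).
#' @param residue_name three-letter residue codes.
#' @param atom_name atom names (e.g. "CA", "P").
#' @param charge partial charges in elementary-charge units.
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters (Angstrom, kcal/mol).
#' @param is_backbone logical backbone flag (N/CA/C/O for proteins).
#' @param x,y,z coordinates in Angstrom.
#' @return a validated atom `data.frame`.
#' @export
atom_table <- function(id, residue_index, residue_name, atom_name,
                       charge = 0, lj_sigma = 0, lj_epsilon = 0,
                       is_backbone = FALSE, x, y, z) {
  atoms <- data.frame(
    id = as.integer(id),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    atom_name = as.character(atom_name),
    charge = as.numeric(charge),
    lj_sigma = as.numeric(lj_sigma),
    lj_epsilon = as.numeric(lj_epsilon),
    is_backbone = as.logical(is_backbone),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  validate_atoms(atoms)
}
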