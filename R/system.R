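## Combined system container and trajectory class. A system concatenates
## protein, membrane and ion atoms into one globally indexed atom table so
## that trajectory frames are plain (n_atoms x 3) coordinate matrices.

## Default Lennard-Jones parameters for Ca2+ beads (Angstrom, kcal/mol).
CA_LJ_SIGMA <- 2.4
CA_LJ_EPSILON <- 0.1

ion_atom_table <- function(ions, id_start = 1L) {
  n <- nrow(ions$calcium)
  if (n == 0) {
    return(atom_table(id = integer(), residue_index = integer(),
                      residue_name = character(), atom_name = character(),
                      charge = numeric(), lj_sigma = numeric(),
                      lj_epsilon = numeric(), is_backbone = logical(),
                      x = numeric(), y = numeric(), z = numeric()))
  }
  atom_table(id = seq.int(id_start, length.out = n),
             residue_index = seq_len(n),
             residue_name = "CAL", atom_name = "CA",
             charge = 2, lj_sigma = CA_LJ_SIGMA, lj_epsilon = CA_LJ_EPSILON,
             is_backbone = FALSE,
             x = ions$calcium$x, y = ions$calcium$y, z = ions$calcium$z)
}

#' Assemble a protein/membrane/ion system
#'
#' Concatenates the component atom tables into one globally indexed table
#' (column `component` in `"protein"`, `"membrane"`, `"ion"`). Atom ids are
#' reassigned to consecutive global ids; trajectory frames address rows of
#' this combined table.
#'
#' @param protein a [protein_model()] or `NULL`.
#' @param membrane a [membrane_model()] or `NULL`.
#' @param ions an [ion_set()] or `NULL`.
#' @param box orthorhombic box lengths `c(Lx, Ly, Lz)` in Angstrom, or
#'   `NULL` for no periodicity.
#' @return an object of class `md_system`.
#' @export
md_system <- function(protein = NULL, membrane = NULL, ions = NULL,
                      box = NULL) {
  blank <- c(lipid_id = NA_integer_, lipid_type = NA_character_,
             leaflet = NA_character_, role = NA_character_,
             carbon_index = NA_integer_, h_parent = NA_integer_)
  pieces <- list()
  index <- list()
  offset <- 0L
  add <- function(atoms, component) {
    atoms$component <- component
    for (nm in names(blank)) {
      if (is.null(atoms[[nm]])) atoms[[nm]] <- blank[[nm]]
    }
    atoms
  }
  if (!is.null(protein) && nrow(protein$atoms)) {
    a <- add(protein$atoms, "protein")
    a$id <- seq.int(offset + 1L, length.out = nrow(a))
    protein$atoms$id <- a$id
    index$protein <- seq.int(offset + 1L, length.out = nrow(a))
    offset <- offset + nrow(a)
    pieces <- c(pieces, list(a))
  }
  if (!is.null(membrane) && nrow(membrane$atoms)) {
    ## h_parent indexes rows of the membrane atom table; shift to global rows
    a <- add(membrane$atoms, "membrane")
    a$h_parent <- ifelse(is.na(a$h_parent), NA_integer_,
                         a$h_parent + offset)
    a$id <- seq.int(offset + 1L, length.out = nrow(a))
    membrane$atoms$id <- a$id
    index$membrane <- seq.int(offset + 1L, length.out = nrow(a))
    offset <- offset + nrow(a)
    pieces <- c(pieces, list(a))
  }
  if (!is.null(ions) && nrow(ions$calcium)) {
    a <- add(ion_atom_table(ions, id_start = offset + 1L), "ion")
    index$ion <- seq.int(offset + 1L, length.out = nrow(a))
    offset <- offset + nrow(a)
    pieces <- c(pieces, list(a))
  }
  atoms <- if (length(pieces)) do.call(rbind, pieces) else NULL
  if (is.null(atoms)) stop("empty system")
  rownames(atoms) <- NULL
  structure(list(protein = protein, membrane = membrane, ions = ions,
                 atoms = atoms, index = index, box = box),
            class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  cat("md_system:", nrow(x$atoms), "atoms (",
    paste(vapply(names(x$index), function(k)
      paste0(k, ": ", length(x$index[[k]])), character(1)), collapse = ", "),
    ")\n")
  if (!is.null(x$box))
    cat("box:", paste(signif(x$box, 6), collapse = " x "), "Angstrom\n")
  invisible(x)
}

#' Replace all coordinates of a system
#'
#' Writes an `(n_atoms x 3)` coordinate matrix (one trajectory frame) back
#' into the combined atom table and the per-component models.
#'
#' @param system an [md_system()].
#' @param coords numeric matrix with one row per system atom.
#' @return the updated `md_system`.
#' @export
set_system_coords <- function(system, coords) {
  stopifnot(nrow(coords) == nrow(system$atoms), ncol(coords) == 3)
  system$atoms <- set_atom_coords(system$atoms, coords)
  if (!is.null(system$index$protein))
    system$protein$atoms <- set_atom_coords(
      system$protein$atoms, coords[system$index$protein, , drop = FALSE])
  if (!is.null(system$index$membrane))
    system$membrane$atoms <- set_atom_coords(
      system$membrane$atoms, coords[system$index$membrane, , drop = FALSE])
  if (!is.null(system$index$ion)) {
    ion_xyz <- coords[system$index$ion, , drop = FALSE]
    system$ions$calcium$x <- ion_xyz[, 1]
    system$ions$calcium$y <- ion_xyz[, 2]
    system$ions$calcium$z <- ion_xyz[, 3]
  }
  system
}

#' Select atoms of a system
#'
#' Returns global row indices into the combined atom table matching all
#' supplied filters (each filter is optional).
#'
#' @param system an [md_system()].
#' @param component `"protein"`, `"membrane"` or `"ion"`.
#' @param residue_index integer residue numbers (protein numbering).
#' @param residue_name residue codes, e.g. `"LYS"`.
#' @param atom_name atom names, e.g. `"CA"`.
#' @param lipid_type lipid types, e.g. `"POPS"`.
#' @param lipid_id lipid ids.
#' @param role membrane atom roles (`"P"`, `"C"`, `"H"`, `"head"`).
#' @param backbone if `TRUE`, keep backbone atoms only.
#' @return integer vector of row indices.
#' @export
select_atoms <- function(system, component = NULL, residue_index = NULL,
                         residue_name = NULL, atom_name = NULL,
                         lipid_type = NULL, lipid_id = NULL, role = NULL,
                         backbone = FALSE) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(component)) keep <- keep & a$component %in% component
  if (!is.null(residue_index)) keep <- keep & a$residue_index %in% residue_index
  if (!is.null(residue_name)) keep <- keep & a$residue_name %in% residue_name
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  if (!is.null(lipid_type))
    keep <- keep & !is.na(a$lipid_type) & a$lipid_type %in% lipid_type
  if (!is.null(lipid_id))
    keep <- keep & !is.na(a$lipid_id) & a$lipid_id %in% lipid_id
  if (!is.null(role)) keep <- keep & !is.na(a$role) & a$role %in% role
  if (backbone) keep <- keep & a$is_backbone
  which(keep)
}

#' Construct a trajectory
#'
#' An ordered list of frames: coordinates for all system atoms, a shared
#' orthorhombic box and strictly increasing time stamps in nanoseconds.
#'
#' @param frames list of `(n_atoms x 3)` coordinate matrices.
#' @param times numeric frame times in ns, strictly increasing.
#' @param box orthorhombic box `c(Lx, Ly, Lz)` in Angstrom, or `NULL`.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, times, box = NULL) {
  if (length(frames) != length(times))
    stop("frames and times must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) && (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3)))
    stop("all frames must share one (n_atoms x 3) coordinate shape")
  structure(list(frames = frames, times = as.numeric(times), box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", length(x$frames), "frames,",
      if (length(x$frames)) nrow(x$frames[[1]]) else 0, "atoms, t = [",
      if (length(x$times)) paste(range(x$times), collapse = ", ") else "",
      "] ns\n")
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

## Indices of frames inside a trailing (or leading) window of given length.
window_frames <- function(times, window_ns, from_end = TRUE) {
  if (!length(times)) stop("empty time axis")
  if (from_end) which(times > times[length(times)] - window_ns)
  else which(times <= times[1] + window_ns)
}
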