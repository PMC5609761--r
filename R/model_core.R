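## Domain types and system-building arithmetic: lipid composition counts,
## charge accounting and neutralization/salt bookkeeping.

## Headgroup charges (elementary-charge units) by lipid type. PS carries -1,
## PI(4,5)P2 -4; PC, PE and cholesterol are neutral.
LIPID_CHARGES <- c(POPC = 0, DOPC = 0, POPS = -1, PIP2 = -4, CHOL = 0,
                   POPE = 0)

#' Known lipid types
#'
#' Lipid types understood by the builders, with their headgroup charges in
#' elementary-charge units.
#'
#' @return named numeric vector of headgroup charges.
#' @export
lipid_charges <- function() LIPID_CHARGES

#' Construct a protein model
#'
#' A protein model is an atom table plus repeat annotations: contiguous,
#' non-overlapping residue ranges labelling the four core repeats of an
#' annexin-type protein (or any other domain decomposition).
#'
#' @param atoms an atom table (see [atom_table()]).
#' @param repeats `data.frame` with columns `label`, `first_residue`,
#'   `last_residue`; ranges must be ascending and non-overlapping.
#' @return an object of class `protein_model`.
#' @export
protein_model <- function(atoms, repeats = NULL) {
  validate_atoms(atoms, "protein atom table")
  if (is.null(repeats)) {
    repeats <- data.frame(label = character(), first_residue = integer(),
                          last_residue = integer(), stringsAsFactors = FALSE)
  }
  if (nrow(repeats)) {
    stopifnot(all(c("label", "first_residue", "last_residue") %in%
                    names(repeats)))
    if (any(repeats$first_residue > repeats$last_residue))
      stop("repeat ranges must have first_residue <= last_residue")
    if (nrow(repeats) > 1) {
      o <- order(repeats$first_residue)
      repeats <- repeats[o, , drop = FALSE]
      if (any(repeats$first_residue[-1] <= repeats$last_residue[-nrow(repeats)]))
        stop("repeat ranges overlap")
    }
  }
  structure(list(atoms = atoms, repeats = repeats), class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat("protein_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$residue_index)), "residues,",
      nrow(x$repeats), "annotated repeats\n")
  invisible(x)
}

#' Construct a membrane model
#'
#' A membrane model holds a flat atom table for all lipid atoms plus a
#' per-lipid summary table. Atom rows carry, in addition to the standard
#' atom-table columns, `lipid_id`, `lipid_type`, `leaflet` and a `role`
#' column: `"P"` (phosphorus-equivalent headgroup bead), `"C"` (chain
#' carbon), `"H"` (chain hydrogen, with `h_parent` giving the row index of
#' its parent carbon) or `"head"` (headgroup bead of P-less lipids such as
#' cholesterol). The bilayer normal is fixed to the laboratory Z axis.
#'
#' @param atoms lipid atom table with the extra columns described above.
#' @param lipids `data.frame` with one row per lipid: `lipid_id`,
#'   `lipid_type`, `leaflet` (`"upper"`/`"lower"`), `headgroup_charge`.
#' @return an object of class `membrane_model`.
#' @export
membrane_model <- function(atoms, lipids) {
  validate_atoms(atoms, "membrane atom table")
  extra <- c("lipid_id", "lipid_type", "leaflet", "role", "carbon_index",
             "h_parent")
  missing_cols <- setdiff(extra, names(atoms))
  if (length(missing_cols))
    stop("membrane atom table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  stopifnot(all(c("lipid_id", "lipid_type", "leaflet", "headgroup_charge")
                %in% names(lipids)))
  bad <- !lipids$headgroup_charge %in% c(0, -1, -4)
  if (any(bad))
    stop("headgroup charges must be one of 0, -1, -4; offending lipid(s): ",
         paste(lipids$lipid_id[bad], collapse = ", "))
  structure(list(atoms = atoms, lipids = lipids, normal_axis = "z"),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  tab <- table(x$lipids$lipid_type, x$lipids$leaflet)
  cat("membrane_model:", nrow(x$lipids), "lipids,", nrow(x$atoms), "atoms\n")
  print(tab)
  invisible(x)
}

#' Construct an ion set
#'
#' Divalent Ca2+ positions plus monovalent salt bookkeeping. Sodium and
#' chloride are tracked as counts only (the analyses never need their
#' coordinates).
#'
#' @param calcium `data.frame` with columns `x`, `y`, `z` (Angstrom); each
#'   ion carries charge +2e.
#' @param sodium_count,chloride_count non-negative integers.
#' @return an object of class `ion_set`.
#' @export
ion_set <- function(calcium = NULL, sodium_count = 0L, chloride_count = 0L) {
  if (is.null(calcium))
    calcium <- data.frame(x = numeric(), y = numeric(), z = numeric())
  stopifnot(all(c("x", "y", "z") %in% names(calcium)))
  if (sodium_count < 0 || chloride_count < 0)
    stop("ion counts must be non-negative")
  structure(list(calcium = calcium[, c("x", "y", "z"), drop = FALSE],
                 sodium_count = as.integer(sodium_count),
                 chloride_count = as.integer(chloride_count)),
            class = "ion_set")
}

#' @export
print.ion_set <- function(x, ...) {
  cat("ion_set:", nrow(x$calcium), "Ca2+,", x$sodium_count, "Na+,",
      x$chloride_count, "Cl-\n")
  invisible(x)
}

#' Construct a composition specification
#'
#' Target lipid composition of a bilayer: mole fractions per lipid type,
#' total lipid count (split evenly over two leaflets), number of Ca2+ ions
#' and bulk salt concentration.
#'
#' @param ratios named numeric vector of mole fractions (must sum to 1).
#' @param total_lipids total lipid count over both leaflets (even).
#' @param n_ca number of Ca2+ ions.
#' @param salt_mM bulk NaCl concentration in mM.
#' @return an object of class `composition_spec`.
#' @export
composition_spec <- function(ratios, total_lipids, n_ca = 0L, salt_mM = 0) {
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("ratios must be a named vector of lipid-type fractions")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("lipid fractions must sum to 1 (got ", format(sum(ratios)), ")")
  if (total_lipids < 0) stop("total_lipids must be >= 0")
  if (total_lipids %% 2 != 0)
    stop("total_lipids must be even (two leaflets)")
  structure(list(ratios = ratios, total_lipids = as.integer(total_lipids),
                 n_ca = as.integer(n_ca), salt_mM = salt_mM),
            class = "composition_spec")
}

#' Integer lipid counts from mole fractions
#'
#' Converts mole fractions into integer per-type lipid counts that sum
#' exactly to `total_lipids`, using largest-remainder rounding. The
#' per-leaflet split of each type is `count / 2`, with odd counts giving
#' the extra lipid to the upper leaflet.
#'
#' @param ratios named numeric vector of mole fractions summing to 1, or a
#'   [composition_spec()].
#' @param total_lipids total lipid count (ignored when `ratios` is a
#'   `composition_spec`).
#' @return named integer vector of per-type counts.
#' @examples
#' composition_counts(c(POPC = .38, DOPC = .19, POPS = .24, CHOL = .19), 400)
#' @export
composition_counts <- function(ratios, total_lipids) {
  if (inherits(ratios, "composition_spec")) {
    total_lipids <- ratios$total_lipids
    ratios <- ratios$ratios
  }
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("lipid fractions must sum to 1 (got ", format(sum(ratios)), ")")
  if (total_lipids < 0) stop("total_lipids must be >= 0")
  exact <- ratios * total_lipids
  counts <- floor(exact + 1e-12)   # guard against 0.38*400 = 151.99999...
  rem <- exact - counts
  shortfall <- as.integer(round(total_lipids - sum(counts)))
  if (shortfall > 0) {
    ## largest remainder first; ties broken by position in `ratios`
    take <- order(-rem, seq_along(rem))[seq_len(shortfall)]
    counts[take] <- counts[take] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

## Per-leaflet split of integer counts: odd counts give the extra lipid to
## the upper (protein-facing) leaflet.
leaflet_split <- function(counts) {
  upper <- as.integer(ceiling(counts / 2))
  lower <- as.integer(counts) - upper
  list(upper = stats::setNames(upper, names(counts)),
       lower = stats::setNames(lower, names(counts)))
}

#' Total system charge
#'
#' Sums protein partial charges, lipid headgroup charges, +2e per Ca2+ and
#' the monovalent salt counts. Any component may be `NULL`.
#'
#' @param protein a [protein_model()] or `NULL`.
#' @param membrane a [membrane_model()] or `NULL`.
#' @param ions an [ion_set()] or `NULL`.
#' @return net charge in elementary-charge units.
#' @export
net_charge <- function(protein = NULL, membrane = NULL, ions = NULL) {
  q <- 0
  if (!is.null(protein)) {
    if (any(!is.finite(protein$atoms$charge)))
      stop("protein has unassigned charges")
    q <- q + sum(protein$atoms$charge)
  }
  if (!is.null(membrane)) {
    if (any(!is.finite(membrane$lipids$headgroup_charge)))
      stop("membrane has unassigned headgroup charges")
    q <- q + sum(membrane$lipids$headgroup_charge)
  }
  if (!is.null(ions)) {
    q <- q + 2 * nrow(ions$calcium) + ions$sodium_count - ions$chloride_count
  }
  q
}

#' Neutralizing and bulk salt ion counts
#'
#' Computes the sodium and chloride counts that (i) bring the system to
#' exactly zero net charge and (ii) provide `salt_mM` of bulk NaCl pairs in
#' the given free water volume: `min(n_Na, n_Cl) = round(c * N_A * V)` and
#' `n_Na - n_Cl = -net_charge`.
#'
#' @param net_charge system net charge before salt, in e units (must be an
#'   integer to 1e-6).
#' @param salt_mM target salt concentration in mM.
#' @param water_volume free water volume in cubic Angstrom.
#' @return list with integer elements `n_na` and `n_cl`.
#' @export
neutralize_and_salt <- function(net_charge, salt_mM = 0, water_volume = 0) {
  if (salt_mM < 0) stop("salt_mM must be >= 0")
  if (salt_mM > 0 && water_volume <= 0)
    stop("water_volume must be > 0 when salt is requested")
  if (abs(net_charge - round(net_charge)) > 1e-6)
    stop("net charge must be integral to neutralize with monovalent ions")
  q <- as.integer(round(net_charge))
  ## mM * 1e-3 mol/L * N_A / L * (1e-27 L/A^3) * V[A^3]
  n_pairs <- as.integer(round(salt_mM * 1e-3 * 6.02214076e23 * 1e-27 *
                                water_volume))
  n_na <- n_pairs + max(0L, -q)
  n_cl <- n_pairs + max(0L, q)
  if (n_na < 0 || n_cl < 0) stop("over-charged system: negative ion count")
  list(n_na = n_na, n_cl = n_cl)
}
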