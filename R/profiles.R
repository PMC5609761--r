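## Per-residue contact and energy profiles, reference Ca2+-site
## comparison, and the Z-constrained rotational RMSD between orientations.

#' Per-residue minimal-distance profile
#'
#' For every protein residue, the minimum over that residue's atoms and
#' the target atoms of the (minimum-image) distance, and its inverse.
#' Plotted as 1/d_min, large values flag residues in closest contact with
#' the membrane or the Ca2+ ions.
#'
#' @param protein a [protein_model()].
#' @param target atom table of the partner group (non-empty).
#' @param box orthorhombic box or `NULL`.
#' @return `data.frame` with `residue_index`, `residue_name`, `d_min`
#'   (Angstrom) and `inv_d` (1/Angstrom).
#' @export
min_distance_profile <- function(protein, target, box = NULL) {
  if (is.null(target) || nrow(target) == 0)
    stop("target atom set is empty")
  tx <- atom_coords(target)
  res <- unique(protein$atoms$residue_index)
  rows <- lapply(res, function(ri) {
    sub <- protein$atoms[protein$atoms$residue_index == ri, , drop = FALSE]
    d <- min_pair_dist(atom_coords(sub), tx, box)
    data.frame(residue_index = ri, residue_name = sub$residue_name[1],
               d_min = d, inv_d = 1 / d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$residue_index), , drop = FALSE]
}

#' Per-residue interaction-energy profile
#'
#' [group_energy()] between each protein residue and a partner atom set;
#' combine with [min_distance_profile()] to mirror joint distance/energy
#' residue profiles. The partner can be any atom subset, e.g. one lipid
#' type (select with [select_atoms()]) or the Ca2+ ions.
#'
#' @inheritParams min_distance_profile
#' @param partner atom table of the partner group.
#' @param params an [energy_params()].
#' @return `data.frame` with `residue_index`, `residue_name`, `energy`
#'   (kcal/mol).
#' @export
residue_energy_profile <- function(protein, partner,
                                   params = energy_params(), box = NULL) {
  if (is.null(partner) || nrow(partner) == 0)
    stop("partner atom set is empty")
  res <- unique(protein$atoms$residue_index)
  rows <- lapply(res, function(ri) {
    sub <- protein$atoms[protein$atoms$residue_index == ri, , drop = FALSE]
    data.frame(residue_index = ri, residue_name = sub$residue_name[1],
               energy = group_energy(sub, partner, params, box),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$residue_index), , drop = FALSE]
}

#' Time-averaged residue profiles over a trajectory window
#'
#' Averages the per-residue inverse minimal distance (the plotted
#' quantity; not d_min itself) and, optionally, the per-residue energy
#' over the frames of a trailing window.
#'
#' @param traj an [md_trajectory()].
#' @param system an [md_system()].
#' @param target_sel integer atom indices of the partner group.
#' @param window_ns trailing window length in ns (default: all frames).
#' @param energy also compute the energy profile.
#' @param params an [energy_params()].
#' @return `data.frame` with `residue_index`, `residue_name`, `inv_d`
#'   (window mean), `d_min` (1/mean inv_d) and optionally `energy`.
#' @export
residue_profile_traj <- function(traj, system, target_sel, window_ns = Inf,
                                 energy = FALSE, params = energy_params()) {
  if (!length(target_sel)) stop("target atom set is empty")
  idx <- window_frames(traj$times, window_ns)
  acc_inv <- NULL; acc_e <- NULL
  for (i in idx) {
    s <- set_system_coords(system, traj$frames[[i]])
    tgt <- s$atoms[target_sel, , drop = FALSE]
    prof <- min_distance_profile(s$protein, tgt, traj$box)
    acc_inv <- if (is.null(acc_inv)) prof$inv_d else acc_inv + prof$inv_d
    if (energy) {
      ep <- residue_energy_profile(s$protein, tgt, params, traj$box)
      acc_e <- if (is.null(acc_e)) ep$energy else acc_e + ep$energy
    }
  }
  s <- set_system_coords(system, traj$frames[[idx[1]]])
  out <- min_distance_profile(s$protein, s$atoms[target_sel, , drop = FALSE],
                              traj$box)
  out$inv_d <- acc_inv / length(idx)
  out$d_min <- 1 / out$inv_d
  if (energy) out$energy <- acc_e / length(idx)
  out
}

#' Identify contact residues from a distance profile
#'
#' Residues whose (time-averaged) minimal distance is at most `d_contact`
#' are reported as contact/binding-site residues.
#'
#' @param profile output of [min_distance_profile()] or
#'   [residue_profile_traj()].
#' @param d_contact contact threshold in Angstrom (default 3).
#' @return a `reference_site_list`: character vector of identifiers like
#'   `"GLU53"`, with the profile subset in attribute `"profile"`.
#' @export
identify_contact_residues <- function(profile, d_contact = 3) {
  hit <- profile$d_min <= d_contact
  sites <- toupper(paste0(profile$residue_name[hit],
                          profile$residue_index[hit]))
  structure(sites, profile = profile[hit, , drop = FALSE],
            class = "reference_site_list")
}

#' Reference residue-site list
#'
#' Plain list of residue identifiers (`"GLU53"` style) used for
#' crystal-structure Ca2+-site comparison; readable from JSON via
#' [read_site_list()].
#'
#' @param residues character identifiers (unique after normalization).
#' @param source free-text label for provenance.
#' @return an object of class `reference_site_list`.
#' @export
site_list <- function(residues, source = "") {
  residues <- toupper(trimws(as.character(residues)))
  if (anyDuplicated(residues)) stop("duplicate residue identifiers")
  structure(residues, source = source, class = "reference_site_list")
}

#' Compare observed and reference binding-site lists
#'
#' Exact set operations on residue identifiers, e.g. simulation-derived
#' Ca2+ contact residues versus crystallographic coordination sites.
#'
#' @param observed,reference `reference_site_list`s or character vectors.
#' @return list with `intersection`, `observed_only`, `reference_only`.
#' @export
crystal_site_overlap <- function(observed, reference) {
  o <- toupper(as.character(observed))
  r <- toupper(as.character(reference))
  list(intersection = sort(intersect(o, r)),
       observed_only = sort(setdiff(o, r)),
       reference_only = sort(setdiff(r, o)))
}

#' Backbone RMSD under optimal rotation about Z
#'
#' Translates the mobile structure's backbone centroid onto the
#' reference's, then rotates about the Z axis only by the closed-form
#' optimal angle before computing the backbone RMSD. Restricting the
#' superposition to Z-rotations preserves the membrane-relative
#' orientation, which a full 3D (Kabsch) fit would destroy.
#'
#' The optimal angle maximizes the in-plane overlap
#' `cos(t) * sum(x_r x_m + y_r y_m) + sin(t) * sum(y_r x_m - x_r y_m)`
#' on centered coordinates, i.e. `theta_star = atan2(B, A)`; the
#' degenerate case `A = B = 0` returns 0 degrees.
#'
#' @param mobile,reference [protein_model()]s with identical backbone atom
#'   counts and ordering.
#' @param selection `"backbone"` (N, CA, C, O) or `"all"`.
#' @return list with `theta_star` (degrees, in (-180, 180]) and `rmsd`
#'   (Angstrom).
#' @export
rotational_rmsd <- function(mobile, reference, selection = "backbone") {
  pick <- function(p) {
    a <- p$atoms
    if (selection == "backbone") {
      keep <- a$is_backbone | a$atom_name %in% c("N", "CA", "C", "O")
      a <- a[keep, , drop = FALSE]
    }
    atom_coords(a)
  }
  xm <- pick(mobile)
  xr <- pick(reference)
  if (nrow(xm) != nrow(xr))
    stop("selection atom counts differ (", nrow(xm), " vs ", nrow(xr), ")")
  if (nrow(xm) == 0) stop("empty selection")
  xm <- sweep(xm, 2, colMeans(xm))
  xr <- sweep(xr, 2, colMeans(xr))
  a <- sum(xr[, 1] * xm[, 1] + xr[, 2] * xm[, 2])
  b <- sum(xr[, 2] * xm[, 1] - xr[, 1] * xm[, 2])
  theta <- if (a == 0 && b == 0) 0 else atan2(b, a)
  rot <- rot_z(theta * 180 / pi)
  xm_rot <- xm %*% t(rot)
  list(theta_star = theta * 180 / pi,
       rmsd = sqrt(mean(rowSums((xm_rot - xr)^2))))
}

#' Rotational RMSD of trajectory frames against a fixed reference
#'
#' Per-frame [rotational_rmsd()] of the protein against a reference
#' structure, averaged per frame then over a window (e.g. first or last
#' 20 ns) by [window_average()].
#'
#' @param traj an [md_trajectory()].
#' @param system an [md_system()] containing the protein.
#' @param reference a [protein_model()].
#' @param selection `"backbone"` or `"all"`.
#' @return `data.frame` with `time_ns`, `theta_star`, `rmsd`.
#' @export
rotational_rmsd_series <- function(traj, system, reference,
                                   selection = "backbone") {
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    s <- set_system_coords(system, traj$frames[[i]])
    r <- rotational_rmsd(s$protein, reference, selection)
    data.frame(time_ns = traj$times[i], theta_star = r$theta_star,
               rmsd = r$rmsd)
  })
  do.call(rbind, rows)
}
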