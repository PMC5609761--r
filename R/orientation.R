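## Systematic protein orientation generation above a bilayer:
## principal-axis pre-alignment, X/Y rotation grids, minimal-distance Z
## placement and interfacial Ca2+ seeding.

#' Align the protein principal axes with the laboratory frame
#'
#' Rotates the protein about its centroid so that the first and second
#' principal axes of the positional covariance lie along X and Y (largest
#' variance on X, smallest on Z). The axis-sign ambiguity is fixed by
#' requiring a non-negative coordinate of the first atom along the first
#' and second principal axes; the third axis is their cross product, which
#' makes the rotation proper (determinant +1).
#'
#' @param protein a [protein_model()] with at least 3 non-collinear atoms.
#' @param tol relative eigenvalue-gap tolerance below which the cloud is
#'   treated as degenerate (isotropic or collinear).
#' @return the rotated `protein_model`.
#' @export
principal_axis_align <- function(protein, tol = 1e-8) {
  xyz <- atom_coords(protein$atoms)
  if (nrow(xyz) < 3) stop("need at least 3 atoms for principal-axis alignment")
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  cv <- crossprod(xc) / nrow(xc)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values                       # descending
  if (ev[1] <= 0 || (ev[1] - ev[2]) / ev[1] < tol ||
      (ev[2] - ev[3]) / ev[1] < tol)
    stop("degenerate atom cloud: principal axes are not uniquely defined")
  a1 <- eg$vectors[, 1]
  a2 <- eg$vectors[, 2]
  if (sum(xc[1, ] * a1) < 0) a1 <- -a1
  if (sum(xc[1, ] * a2) < 0) a2 <- -a2
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  v <- cbind(a1, a2, a3)
  new_xyz <- sweep(xc %*% v, 2, ctr, "+")
  protein$atoms <- set_atom_coords(protein$atoms, new_xyz)
  protein
}

#' Rotate a protein about its center of mass
#'
#' Applies `R = Ry(theta_y) %*% Rx(theta_x)` (rotation about X first, then
#' about Y; right-handed, degrees) to all atom coordinates relative to the
#' centroid. The centroid is unchanged.
#'
#' @param protein a [protein_model()].
#' @param theta_x,theta_y rotation angles in degrees.
#' @return the rotated `protein_model`.
#' @export
rotate_about_com <- function(protein, theta_x, theta_y) {
  xyz <- atom_coords(protein$atoms)
  com <- colMeans(xyz)
  r <- rot_y(theta_y) %*% rot_x(theta_x)
  new_xyz <- sweep(sweep(xyz, 2, com) %*% t(r), 2, com, "+")
  protein$atoms <- set_atom_coords(protein$atoms, new_xyz)
  protein
}

#' Generate an orientation grid
#'
#' Cartesian product of X- and Y-rotation angles, row-major (X outer, Y
#' inner), labelled `O1`, `O2`, .... The default grid — X in
#' \{0, 60, 120, 180, 240, 300\} degrees crossed with Y in \{-60, 0, 60\}
#' degrees — yields the standard 18 orientations, with `O5 = (60, 0)` and
#' `O14 = (240, 0)`.
#'
#' @param theta_x_list,theta_y_list angle lists in degrees.
#' @return `data.frame` with columns `label`, `theta_x`, `theta_y`.
#' @export
generate_orientation_grid <- function(theta_x_list = seq(0, 300, by = 60),
                                      theta_y_list = c(-60, 0, 60)) {
  if (!length(theta_x_list) || !length(theta_y_list))
    stop("angle lists must be non-empty")
  grid <- expand.grid(theta_y = theta_y_list, theta_x = theta_x_list,
                      KEEP.OUT.ATTRS = FALSE)   # Y varies fastest
  grid <- grid[, c("theta_x", "theta_y")]
  key <- paste(grid$theta_x %% 360, grid$theta_y %% 360)
  if (anyDuplicated(key))
    stop("duplicate (theta_x, theta_y) pairs in the grid (modulo 360)")
  data.frame(label = paste0("O", seq_len(nrow(grid))),
             theta_x = grid$theta_x, theta_y = grid$theta_y,
             stringsAsFactors = FALSE)
}

## Minimal protein-membrane distance as a function of a protein Z shift.
## Placement happens at build time before periodic wrapping matters, so
## plain (non-periodic) distances are used.
min_dist_at_shift <- function(a2, dz0, shift) {
  sqrt(min(a2 + (dz0 + shift)^2))
}

#' Translate the protein along Z to a target minimal distance
#'
#' Shifts the protein along Z only (X, Y unchanged) until the minimum over
#' all protein-atom x membrane-atom distances equals `d_target`. Of the two
#' Z shifts that realize the target distance, the upper one is taken, so
#' the protein ends above the membrane.
#'
#' @param protein a [protein_model()].
#' @param membrane a [membrane_model()].
#' @param d_target target minimal atom-pair distance in Angstrom (default
#'   6, the standard orientation-build separation; PI(4,5)P2-containing
#'   builds use 2).
#' @return the translated `protein_model`.
#' @export
place_at_min_distance <- function(protein, membrane, d_target = 6) {
  if (d_target <= 0) stop("d_target must be > 0")
  pa <- atom_coords(protein$atoms)
  ma <- atom_coords(membrane$atoms)
  ## per-pair in-plane distance^2 and z offset; distance(shift)^2 =
  ## a2 + (dz0 + shift)^2 for each pair
  dx <- outer(pa[, 1], ma[, 1], "-")
  dy <- outer(pa[, 2], ma[, 2], "-")
  a2 <- dx * dx + dy * dy
  dz0 <- outer(pa[, 3], ma[, 3], "-")
  ## closest lateral approach over all pairs bounds what any Z shift can do
  if (sqrt(min(a2)) > d_target)
    stop("no Z translation reaches d_target = ", d_target,
         " Angstrom: protein is laterally outside the membrane footprint")
  f <- function(s) min_dist_at_shift(a2, dz0, s) - d_target
  ## bracket the upper root: high shift -> protein far above (f > 0);
  ## at the argmin of the minimal distance f < 0 (checked above)
  smin <- -dz0[which.min(a2 + dz0 * dz0)]   # near the global minimum
  lo <- smin
  hi <- max(abs(dz0)) + d_target + 10
  if (f(lo) > 0) {
    ## refine: scan for a point below the target
    grid <- seq(min(-dz0), max(-dz0), length.out = 200)
    vals <- vapply(grid, f, numeric(1))
    if (all(vals > 0))
      stop("no Z translation reaches d_target = ", d_target, " Angstrom")
    lo <- grid[which.min(vals)]
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  xyz <- pa
  xyz[, 3] <- xyz[, 3] + root
  protein$atoms <- set_atom_coords(protein$atoms, xyz)
  protein
}

#' Seed Ca2+ ions in the protein-membrane interfacial slab
#'
#' Samples `n_ions` positions uniformly (seeded RNG) in the slab bounded
#' below by the highest upper-leaflet P atom and above by the lowest
#' protein atom, laterally within the protein's XY bounding box. A minimum
#' pairwise separation of `min_sep` is enforced by rejection.
#'
#' @param protein a [protein_model()] already placed above the membrane.
#' @param membrane a [membrane_model()].
#' @param n_ions number of Ca2+ ions (default 12, the standard build).
#' @param seed integer RNG seed; fixed seed gives identical positions.
#' @param min_sep minimum pairwise ion separation in Angstrom.
#' @param max_attempts rejection budget before a packing error is raised.
#' @return an [ion_set()] with `n_ions` calcium positions.
#' @export
seed_ions <- function(protein, membrane, n_ions = 12, seed = 1,
                      min_sep = 2.5, max_attempts = 10000 * max(n_ions, 1)) {
  if (n_ions < 0) stop("n_ions must be >= 0")
  if (n_ions == 0) return(ion_set())
  pa <- atom_coords(protein$atoms)
  is_p <- membrane$atoms$role == "P"
  if (!any(is_p)) stop("membrane has no P atoms to define the slab")
  up <- membrane$atoms$leaflet == "upper" & is_p
  z_lo <- max(membrane$atoms$z[up])
  z_hi <- min(pa[, 3])
  if (z_hi <= z_lo)
    stop("no interfacial slab: protein overlaps the upper leaflet")
  xr <- range(pa[, 1]); yr <- range(pa[, 2])
  set.seed(seed)
  pos <- matrix(NA_real_, n_ions, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n_ions) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not pack ", n_ions, " ions at ", min_sep,
           " Angstrom separation in the interfacial slab")
    cand <- c(stats::runif(1, xr[1], xr[2]),
              stats::runif(1, yr[1], yr[2]),
              stats::runif(1, z_lo, z_hi))
    if (placed > 0) {
      d2 <- rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2,
                          cand)^2)
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
  }
  ion_set(calcium = data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3]))
}
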