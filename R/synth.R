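## Synthetic protein/bilayer/ion systems and pseudo-trajectories with
## controllable, known statistical structure. The generator has no
## physics: its contract is that every imposed feature (curvature field,
## chain ordering, couplings) is known exactly, so the analysis modules
## can be validated by parameter recovery.

## Fixed bead parameters of the synthetic models (Angstrom, kcal/mol).
SYN_LJ <- list(P = c(sigma = 3.7, eps = 0.2),
               C = c(sigma = 3.5, eps = 0.1),
               H = c(sigma = 2.0, eps = 0.03),
               head = c(sigma = 3.5, eps = 0.1),
               protein = c(sigma = 3.5, eps = 0.1))
## Second C-H bond azimuth offset (tetrahedral methylene), degrees.
CH_AZIMUTH_OFFSET <- 109.4712

RESIDUE_CHARGES <- c(LYS = 1, ARG = 1, GLU = -1, ASP = -1)

#' Configuration of the synthetic-system generator
#'
#' Bundles the bilayer composition and all statistical knobs of the
#' pseudo-trajectory: positional jitter, the ion-tied curvature field, the
#' proximity-tied chain ordering and the RNG seed.
#'
#' @param composition a [composition_spec()]; the default is the standard
#'   400-lipid POPC/DOPC/POPS/CHOL 0.38:0.19:0.24:0.19 mixture with 12
#'   Ca2+ and 150 mM salt.
#' @param box orthorhombic box `c(Lx, Ly, Lz)` in Angstrom; `NULL` sizes
#'   the box from the lipid lattice with `Lz = 150`.
#' @param area_per_lipid lateral area per lipid in Angstrom^2.
#' @param leaflet_z half the P-P bilayer thickness in Angstrom (P planes
#'   at +/- `leaflet_z`).
#' @param n_frames,dt_ns number of pseudo-trajectory frames and spacing.
#' @param jitter_sigma Gaussian positional jitter SD per atom per frame
#'   (Angstrom).
#' @param curvature_amplitude,curvature_length amplitude `A` (Angstrom)
#'   and lateral decay length `lambda` (Angstrom) of the ion-tied Gaussian
#'   z-displacement field.
#' @param curvature_coupling `"ion_field"` (P atoms displaced by
#'   `-A * sum_ions exp(-d_xy^2 / (2 lambda^2))`, upper leaflet full,
#'   lower leaflet half amplitude) or `"none"`.
#' @param order_coupling `"protein_proximity"` (chain tilt SD shrinks near
#'   the protein footprint and grows with the ion field, giving more order
#'   near the protein and less near ions) or `"none"`.
#' @param tilt_sigma0 baseline chain-segment tilt SD in degrees.
#' @param order_length lateral decay length of the order coupling
#'   (Angstrom).
#' @param chain_beads chain carbons per lipid.
#' @param chain_spacing carbon-carbon spacing along the chain (Angstrom).
#' @param ch_length C-H bond length (Angstrom).
#' @param seed integer RNG seed; every random draw derives from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(composition = composition_spec(
                           c(POPC = 0.38, DOPC = 0.19, POPS = 0.24,
                             CHOL = 0.19), 400, n_ca = 12, salt_mM = 150),
                         box = NULL, area_per_lipid = 65, leaflet_z = 18,
                         n_frames = 50, dt_ns = 1, jitter_sigma = 0.3,
                         curvature_amplitude = 2, curvature_length = 10,
                         curvature_coupling = c("ion_field", "none"),
                         order_coupling = c("protein_proximity", "none"),
                         tilt_sigma0 = 25, order_length = 15,
                         chain_beads = 8, chain_spacing = 1.5,
                         ch_length = 1.09, seed = 1) {
  curvature_coupling <- match.arg(curvature_coupling)
  order_coupling <- match.arg(order_coupling)
  stopifnot(area_per_lipid > 0, leaflet_z > 0, n_frames >= 1, dt_ns > 0,
            jitter_sigma >= 0, curvature_length > 0, tilt_sigma0 >= 0,
            order_length > 0, chain_beads >= 1, chain_spacing > 0,
            ch_length > 0)
  if (!is.null(box)) stopifnot(length(box) == 3, all(box > 0))
  structure(list(composition = composition, box = box,
                 area_per_lipid = area_per_lipid, leaflet_z = leaflet_z,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 jitter_sigma = jitter_sigma,
                 curvature_amplitude = curvature_amplitude,
                 curvature_length = curvature_length,
                 curvature_coupling = curvature_coupling,
                 order_coupling = order_coupling,
                 tilt_sigma0 = tilt_sigma0, order_length = order_length,
                 chain_beads = as.integer(chain_beads),
                 chain_spacing = chain_spacing, ch_length = ch_length,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## Chain-segment direction and C-H basis, analytic in (alpha, phi):
## upper-leaflet segments point down (dz = -cos(alpha)). e1 and e2 span
## the plane perpendicular to the segment; H.z = sin(psi) sin(alpha), so
## the order parameter depends only on alpha and psi, never on phi.
chain_axes <- function(alpha, phi, down) {
  sa <- sin(alpha); ca <- cos(alpha)
  dz_sign <- ifelse(down, -1, 1)
  list(d = cbind(sa * cos(phi), sa * sin(phi), dz_sign * ca),
       e1 = cbind(-sin(phi), cos(phi), 0),
       e2 = cbind(-dz_sign * ca * cos(phi), -dz_sign * ca * sin(phi), sa))
}

## Build chain C and H coordinates for all chain lipids at once.
## p_xyz: per-lipid P positions (n x 3); alpha: n x k tilt matrix
## (radians); geom: per-lipid-per-carbon fixed phases (phi, psi).
build_chains <- function(p_xyz, leaflet, alpha, geom, config) {
  k <- config$chain_beads
  n <- nrow(p_xyz)
  down <- leaflet == "upper"
  cc <- matrix(NA_real_, n * k, 3)
  h1 <- matrix(NA_real_, n * k, 3)
  h2 <- matrix(NA_real_, n * k, 3)
  pos <- p_xyz
  for (j in seq_len(k)) {
    ax <- chain_axes(alpha[, j], geom$phi[, j], down)
    pos <- pos + config$chain_spacing * ax$d
    idx <- (seq_len(n) - 1) * k + j
    cc[idx, ] <- pos
    psi <- geom$psi[, j]
    psi2 <- psi + deg2rad(CH_AZIMUTH_OFFSET)
    h1[idx, ] <- pos + config$ch_length *
      (cos(psi) * ax$e1 + sin(psi) * ax$e2)
    h2[idx, ] <- pos + config$ch_length *
      (cos(psi2) * ax$e1 + sin(psi2) * ax$e2)
  }
  list(c = cc, h1 = h1, h2 = h2)
}

#' Build a synthetic bilayer
#'
#' Places lipids on a square lattice per leaflet at the configured area
#' per lipid (box centered on the origin, P planes at +/- `leaflet_z`),
#' assigns types by [composition_counts()] shuffled with the seeded RNG,
#' and gives every non-cholesterol lipid a P bead plus `chain_beads`
#' chain carbons, each carrying two attached hydrogens whose directions
#' realize a chain-segment tilt drawn from `N(0, tilt_sigma0)`.
#' Cholesterol gets a single neutral headgroup bead and is thereby
#' excluded from curvature and S_CD analyses.
#'
#' @param config a [synth_config()].
#' @return a [membrane_model()]; the per-carbon azimuthal phases drawn at
#'   build time are kept in `$chain_phase` so pseudo-trajectory frames and
#'   the generator oracle share them.
#' @export
synth_bilayer <- function(config = synth_config()) {
  counts <- composition_counts(config$composition)
  split <- leaflet_split(counts)
  spacing <- sqrt(config$area_per_lipid)
  n_side <- ceiling(sqrt(max(sum(split$upper), sum(split$lower))))
  need <- n_side * spacing
  box <- config$box %||% c(need, need, 150)
  if (box[1] < need - 1e-9 || box[2] < need - 1e-9)
    stop("box too small for the lipid lattice: need ", signif(need, 4),
         " Angstrom laterally")
  set.seed(config$seed)
  lat <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  lat_x <- (lat$ix - (n_side + 1) / 2) * spacing
  lat_y <- (lat$iy - (n_side + 1) / 2) * spacing

  lipid_rows <- list(); atom_rows <- list(); phase_rows <- list()
  lipid_id <- 0L
  for (lf in c("upper", "lower")) {
    cnt <- split[[lf]]
    n_lf <- sum(cnt)
    if (n_lf == 0) next
    types <- sample(rep(names(cnt), cnt))        # shuffled lattice fill
    ## spread the lipids evenly over the available lattice sites
    site <- round(seq(1, n_side^2, length.out = n_lf))
    zP <- if (lf == "upper") config$leaflet_z else -config$leaflet_z
    for (i in seq_len(n_lf)) {
      lipid_id <- lipid_id + 1L
      ty <- types[i]
      s <- site[i]
      lipid_rows[[lipid_id]] <- data.frame(
        lipid_id = lipid_id, lipid_type = ty, leaflet = lf,
        headgroup_charge = unname(LIPID_CHARGES[ty]),
        x = lat_x[s], y = lat_y[s], stringsAsFactors = FALSE)
    }
  }
  lipids <- do.call(rbind, lipid_rows)

  ## Atom tables, lipid by lipid: P (or CHOL head bead), then per carbon
  ## C, H1, H2. Chain conformation of the built (frame-0) membrane uses
  ## the baseline tilt SD.
  k <- config$chain_beads
  is_chol <- lipids$lipid_type == "CHOL"
  chain <- lipids[!is_chol, , drop = FALSE]
  nc <- nrow(chain)
  geom <- list(phi = matrix(stats::runif(nc * k, 0, 2 * pi), nc, k),
               psi = matrix(stats::runif(nc * k, 0, 2 * pi), nc, k))
  alpha <- matrix(stats::rnorm(nc * k, 0, deg2rad(config$tilt_sigma0)),
                  nc, k)
  p_xyz <- cbind(chain$x, chain$y,
                 ifelse(chain$leaflet == "upper", config$leaflet_z,
                        -config$leaflet_z))
  ch <- build_chains(p_xyz, chain$leaflet, alpha, geom, config)

  mk_atom <- function(lipid_id, lipid_type, leaflet, resno, name, role,
                      carbon_index, h_parent, charge, lj, xyz) {
    data.frame(id = 0L, residue_index = resno, residue_name = lipid_type,
               atom_name = name, charge = charge,
               lj_sigma = unname(lj["sigma"]), lj_epsilon = unname(lj["eps"]),
               is_backbone = FALSE, x = xyz[1], y = xyz[2], z = xyz[3],
               lipid_id = lipid_id, lipid_type = lipid_type,
               leaflet = leaflet, role = role, carbon_index = carbon_index,
               h_parent = h_parent, stringsAsFactors = FALSE)
  }

  rows <- vector("list", nrow(lipids))
  row_counter <- 0L
  chain_pos <- 0L
  for (li in seq_len(nrow(lipids))) {
    L <- lipids[li, ]
    if (L$lipid_type == "CHOL") {
      rows[[li]] <- mk_atom(L$lipid_id, L$lipid_type, L$leaflet, L$lipid_id,
                            "C1", "head", NA_integer_, NA_integer_, 0,
                            SYN_LJ$head,
                            c(L$x, L$y,
                              if (L$leaflet == "upper") config$leaflet_z - 1
                              else -config$leaflet_z + 1))
      row_counter <- row_counter + 1L
      next
    }
    chain_pos <- chain_pos + 1L
    p_row <- mk_atom(L$lipid_id, L$lipid_type, L$leaflet, L$lipid_id, "P",
                     "P", NA_integer_, NA_integer_, L$headgroup_charge,
                     SYN_LJ$P, c(L$x, L$y,
                                 if (L$leaflet == "upper") config$leaflet_z
                                 else -config$leaflet_z))
    sub <- vector("list", 1 + 3 * k)
    sub[[1]] <- p_row
    base_row <- row_counter + 1L   # membrane-table row of this lipid's P
    for (j in seq_len(k)) {
      idx <- (chain_pos - 1) * k + j
      c_local_row <- base_row + 1L + 3L * (j - 1L)
      sub[[3 * j - 1]] <- mk_atom(L$lipid_id, L$lipid_type, L$leaflet,
                                  L$lipid_id, paste0("C", j), "C", j,
                                  NA_integer_, 0, SYN_LJ$C, ch$c[idx, ])
      sub[[3 * j]] <- mk_atom(L$lipid_id, L$lipid_type, L$leaflet,
                              L$lipid_id, paste0("H", j, "A"), "H", j,
                              c_local_row, 0, SYN_LJ$H, ch$h1[idx, ])
      sub[[3 * j + 1]] <- mk_atom(L$lipid_id, L$lipid_type, L$leaflet,
                                  L$lipid_id, paste0("H", j, "B"), "H", j,
                                  c_local_row, 0, SYN_LJ$H, ch$h2[idx, ])
    }
    rows[[li]] <- do.call(rbind, sub)
    row_counter <- row_counter + 1L + 3L * k
  }
  atoms <- do.call(rbind, rows)
  atoms$id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  m <- membrane_model(atoms, lipids[, c("lipid_id", "lipid_type", "leaflet",
                                        "headgroup_charge")])
  m$lipid_sites <- lipids[, c("lipid_id", "x", "y")]
  m$chain_phase <- list(lipid_id = chain$lipid_id, phi = geom$phi,
                        psi = geom$psi)
  m$build_box <- box
  m
}

#' Build a synthetic disc-like protein
#'
#' Residue beads on the lower half of a flattened ellipsoid (convex face
#' down, toward the membrane), each residue carrying an N/CA/C/O
#' pseudo-backbone with the residue charge on CA. The charged residues
#' named in `charge_plan` occupy the lowest (membrane-facing) sites, in
#' plan order; remaining residues are neutral alanines. Residues are
#' numbered 1..n from the bottom of the convex face upward, and four
#' repeat annotations split the sequence into near-equal contiguous
#' ranges. The construction is deterministic.
#'
#' @param n_residues number of residues (>= 4).
#' @param radius nominal protein radius in Angstrom.
#' @param charge_plan named integer vector: how many residues of each
#'   charged type (LYS/ARG +1e, GLU/ASP -1e) to place on the convex face.
#' @return a [protein_model()].
#' @export
synth_protein <- function(n_residues = 60, radius = 15,
                          charge_plan = c(LYS = 6, GLU = 4, ASP = 4)) {
  if (n_residues < 4) stop("need at least 4 residues")
  if (sum(charge_plan) > n_residues)
    stop("charge_plan places more residues than n_residues")
  i <- seq_len(n_residues)
  cos_theta <- -(i - 0.5) / n_residues          # lower half: z < 0
  sin_theta <- sqrt(1 - cos_theta^2)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * i
  ## flattened, slightly elongated ellipsoid: distinct principal axes
  x <- 1.25 * radius * sin_theta * cos(phi)
  y <- 1.00 * radius * sin_theta * sin(phi)
  z <- 0.45 * radius * cos_theta
  o <- order(z)                                  # bottom (convex face) first
  x <- x[o]; y <- y[o]; z <- z[o]
  resnames <- rep("ALA", n_residues)
  pos <- 1L
  for (nm in names(charge_plan)) {
    cnt <- charge_plan[[nm]]
    if (cnt > 0) {
      resnames[pos:(pos + cnt - 1)] <- nm
      pos <- pos + cnt
    }
  }
  charges <- ifelse(resnames %in% names(RESIDUE_CHARGES),
                    RESIDUE_CHARGES[resnames], 0)
  off <- list(N = c(-0.75, 0, 0), CA = c(0, 0, 0), C = c(0.75, 0, 0),
              O = c(1.25, 0.6, 0))
  rows <- lapply(seq_len(n_residues), function(r) {
    do.call(rbind, lapply(names(off), function(an) {
      data.frame(id = 0L, residue_index = r, residue_name = resnames[r],
                 atom_name = an,
                 charge = if (an == "CA") unname(charges[r]) else 0,
                 lj_sigma = unname(SYN_LJ$protein["sigma"]),
                 lj_epsilon = unname(SYN_LJ$protein["eps"]),
                 is_backbone = TRUE,
                 x = x[r] + off[[an]][1], y = y[r] + off[[an]][2],
                 z = z[r] + off[[an]][3], stringsAsFactors = FALSE)
    }))
  })
  atoms <- do.call(rbind, rows)
  atoms$id <- seq_len(nrow(atoms))
  bounds <- unique(round(seq(0, n_residues, length.out = 5)))
  repeats <- data.frame(label = paste0("repeat", 1:4),
                        first_residue = utils::head(bounds, 4) + 1L,
                        last_residue = bounds[-1],
                        stringsAsFactors = FALSE)
  protein_model(atoms, repeats)
}

#' Assemble a full synthetic system
#'
#' Builds the bilayer and protein, applies an X/Y orientation rotation,
#' drops the protein to the target minimal distance, seeds the Ca2+ ions
#' and adds neutralizing/bulk salt counts.
#'
#' @param config a [synth_config()].
#' @param protein a [protein_model()]; default [synth_protein()].
#' @param orientation `c(theta_x, theta_y)` in degrees.
#' @param d_target placement distance in Angstrom (6 for the standard
#'   build, 2 for PI(4,5)P2-containing builds).
#' @param ion_placement `"interface"` (seeded in the protein-membrane
#'   slab, the standard build) or `"scatter"` (uniform over the box above
#'   the upper leaflet, decoupling the ion field from the protein
#'   footprint).
#' @return an [md_system()].
#' @export
synth_system <- function(config = synth_config(), protein = NULL,
                         orientation = c(60, 0), d_target = 6,
                         ion_placement = c("interface", "scatter")) {
  ion_placement <- match.arg(ion_placement)
  membrane <- synth_bilayer(config)
  box <- membrane$build_box
  if (is.null(protein)) protein <- synth_protein()
  protein <- rotate_about_com(protein, orientation[1], orientation[2])
  ## start well above the membrane, then drop to the target distance
  xyz <- atom_coords(protein$atoms)
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + config$leaflet_z + 30
  protein$atoms <- set_atom_coords(protein$atoms, xyz)
  protein <- place_at_min_distance(protein, membrane, d_target)
  n_ca <- config$composition$n_ca
  if (ion_placement == "interface") {
    ions <- seed_ions(protein, membrane, n_ca, seed = config$seed + 1L)
  } else {
    set.seed(config$seed + 1L)
    ions <- ion_set(calcium = data.frame(
      x = stats::runif(n_ca, -box[1] / 2, box[1] / 2),
      y = stats::runif(n_ca, -box[2] / 2, box[2] / 2),
      z = stats::runif(n_ca, config$leaflet_z + 2, config$leaflet_z + 6)))
  }
  q <- net_charge(protein, membrane, ions)
  ## free water volume: box minus a membrane+interface exclusion slab
  slab <- 2 * config$leaflet_z + 20
  v_free <- box[1] * box[2] * max(box[3] - slab, 0)
  salt <- neutralize_and_salt(q, config$composition$salt_mM, v_free)
  ions$sodium_count <- salt$n_na
  ions$chloride_count <- salt$n_cl
  md_system(protein, membrane, ions, box = box)
}

## Per-lipid generator fields shared by the pseudo-trajectory and the
## oracle: ion Gaussian field F, imposed z displacement, order-coupled
## tilt SDs (radians) for chain lipids.
synth_fields <- function(system, config) {
  lip <- system$membrane$lipids
  sites <- system$membrane$lipid_sites
  sx <- sites$x[match(lip$lipid_id, sites$lipid_id)]
  sy <- sites$y[match(lip$lipid_id, sites$lipid_id)]
  f <- rep(0, nrow(lip))
  if (!is.null(system$ions) && nrow(system$ions$calcium)) {
    ix <- system$ions$calcium$x; iy <- system$ions$calcium$y
    lam2 <- 2 * config$curvature_length^2
    for (j in seq_along(ix)) {
      f <- f + exp(-((sx - ix[j])^2 + (sy - iy[j])^2) / lam2)
    }
  }
  dz <- rep(0, nrow(lip))
  if (config$curvature_coupling == "ion_field") {
    amp <- ifelse(lip$leaflet == "upper", config$curvature_amplitude,
                  config$curvature_amplitude / 2)
    dz <- -amp * f
  }
  sigma <- rep(deg2rad(config$tilt_sigma0), nrow(lip))
  if (config$order_coupling == "protein_proximity" &&
      !is.null(system$protein)) {
    pxy <- colMeans(atom_coords(system$protein$atoms))[1:2]
    d2 <- (sx - pxy[1])^2 + (sy - pxy[2])^2
    fac <- 1 - 0.5 * exp(-d2 / (2 * config$order_length^2))
    if (max(f) > 0) fac <- fac + 0.5 * f / max(f)
    sigma <- sigma * pmin(pmax(fac, 0.05), 2)
  }
  list(x = sx, y = sy, field = f, dz_imposed = dz, tilt_sigma = sigma)
}

#' Generate a pseudo-trajectory
#'
#' Produces `n_frames` frames from a built system: (i) i.i.d. Gaussian
#' positional jitter on protein, ion, P and headgroup beads; (ii) the
#' ion-tied curvature field displaces each lipid along Z (upper leaflet at
#' full, lower at half amplitude); (iii) lipid chains are rebuilt every
#' frame with per-carbon segment tilts drawn from the (possibly
#' proximity-coupled) per-lipid tilt SD, the build-time azimuthal phases
#' being reused so that a zero-noise configuration reproduces the built
#' system exactly in every frame.
#'
#' @param system an [md_system()] built by [synth_system()].
#' @param config the same [synth_config()] used to build it.
#' @return an [md_trajectory()].
#' @export
synth_trajectory <- function(system, config) {
  fields <- synth_fields(system, config)
  lip <- system$membrane$lipids
  matoms <- system$membrane$atoms
  mrows <- system$index$membrane
  base <- atom_coords(system$atoms)
  k <- config$chain_beads
  phase <- system$membrane$chain_phase
  chain_ids <- phase$lipid_id
  nc <- length(chain_ids)
  ## membrane-local rows of each chain lipid's P / C / H atoms, in build
  ## order (P, then C,H1,H2 per carbon)
  p_local <- match(chain_ids, matoms$lipid_id[matoms$role == "P"])
  p_rows <- which(matoms$role == "P")[p_local]
  lipid_of <- match(matoms$lipid_id, lip$lipid_id)
  dz_atom <- fields$dz_imposed[lipid_of]          # every membrane atom
  sig_chain <- fields$tilt_sigma[match(chain_ids, lip$lipid_id)]
  chain_leaflet <- lip$leaflet[match(chain_ids, lip$lipid_id)]
  c_rows <- matrix(0L, nc, k)
  h1_rows <- matrix(0L, nc, k)
  h2_rows <- matrix(0L, nc, k)
  for (j in seq_len(k)) {
    c_rows[, j] <- p_rows + 1L + 3L * (j - 1L)
    h1_rows[, j] <- c_rows[, j] + 1L
    h2_rows[, j] <- c_rows[, j] + 2L
  }
  set.seed(config$seed + 2L)
  frames <- vector("list", config$n_frames)
  jit <- config$jitter_sigma
  for (fr in seq_len(config$n_frames)) {
    xyz <- base
    ## jitter protein and ions
    for (comp in c("protein", "ion")) {
      idx <- system$index[[comp]]
      if (!is.null(idx) && jit > 0)
        xyz[idx, ] <- xyz[idx, ] +
          matrix(stats::rnorm(3 * length(idx), 0, jit), ncol = 3)
    }
    ## membrane: field displacement on all atoms of each lipid, jitter on
    ## P/head beads, chains rebuilt below
    xyz[mrows, 3] <- xyz[mrows, 3] + dz_atom
    ph <- mrows[matoms$role %in% c("P", "head")]
    if (jit > 0)
      xyz[ph, ] <- xyz[ph, ] +
        matrix(stats::rnorm(3 * length(ph), 0, jit), ncol = 3)
    alpha <- matrix(stats::rnorm(nc * k, 0, rep(sig_chain, k)), nc, k)
    p_xyz <- xyz[mrows[p_rows], , drop = FALSE]
    ch <- build_chains(p_xyz, chain_leaflet, alpha, phase, config)
    for (j in seq_len(k)) {
      idx <- (seq_len(nc) - 1) * k + j
      xyz[mrows[c_rows[, j]], ] <- ch$c[idx, , drop = FALSE]
      xyz[mrows[h1_rows[, j]], ] <- ch$h1[idx, , drop = FALSE]
      xyz[mrows[h2_rows[, j]], ] <- ch$h2[idx, , drop = FALSE]
    }
    frames[[fr]] <- xyz
  }
  md_trajectory(frames, times = config$dt_ns * seq_len(config$n_frames),
                box = system$box)
}

#' Generator-side ground truth
#'
#' Computes, directly from the generator internals and independently of
#' the analysis modules: the imposed per-lipid curvature displacement
#' (leaflet-centered), the correlations between that field and a simple
#' generator-side interaction proxy (headgroup point charge at the P site
#' against the partner point charges, Coulomb within the generator's
#' 12-Angstrom locality scale), and the expected per-lipid |S_CD| from
#' the closed form `E[S_CD | psi] = (3 sin^2(psi) E[sin^2 alpha] - 1)/2`
#' with `E[sin^2 alpha] = (1 - exp(-2 sigma^2))/2` for segment tilts
#' `alpha ~ N(0, sigma)`, averaged over the lipid's fixed C-H phases.
#'
#' @param system an [md_system()] built by [synth_system()].
#' @param config the matching [synth_config()].
#' @return list with `curvature` (per P-lipid imposed, centered dz),
#'   `correlations` (per leaflet: `r_ion`, `r_protein`), `scd` (per chain
#'   lipid expected |S_CD| and tilt SD in degrees).
#' @export
oracle_statistics <- function(system, config) {
  fields <- synth_fields(system, config)
  lip <- system$membrane$lipids
  has_p <- lip$lipid_type != "CHOL"
  k_coul <- 332.0636
  locality <- 12   # generator locality scale for the proxy, Angstrom
  ## Interaction proxy on base positions: headgroup point charge at the P
  ## site against the partner point charges, truncated Coulomb, no LJ
  px <- fields$x; py <- fields$y
  pz <- ifelse(lip$leaflet == "upper", config$leaflet_z,
               -config$leaflet_z) + fields$dz_imposed
  proxy <- function(part_xyz, part_q) {
    out <- rep(0, nrow(lip))
    for (j in seq_len(nrow(part_xyz))) {
      d <- sqrt((px - part_xyz[j, 1])^2 + (py - part_xyz[j, 2])^2 +
                  (pz - part_xyz[j, 3])^2)
      out <- out + ifelse(d <= locality, part_q[j] / d, 0)
    }
    k_coul * lip$headgroup_charge * out
  }
  e_ion <- rep(0, nrow(lip)); e_prot <- rep(0, nrow(lip))
  if (!is.null(system$ions) && nrow(system$ions$calcium))
    e_ion <- proxy(as.matrix(system$ions$calcium),
                   rep(2, nrow(system$ions$calcium)))
  if (!is.null(system$protein)) {
    pq <- system$protein$atoms$charge
    keep <- pq != 0
    if (any(keep))
      e_prot <- proxy(atom_coords(system$protein$atoms)[keep, , drop = FALSE],
                      pq[keep])
  }
  curv <- lapply(c("upper", "lower"), function(lf) {
    sel <- has_p & lip$leaflet == lf
    data.frame(lipid_id = lip$lipid_id[sel], leaflet = lf,
               dz_imposed = fields$dz_imposed[sel] -
                 mean(fields$dz_imposed[sel]),
               field = fields$field[sel], stringsAsFactors = FALSE)
  })
  curv <- do.call(rbind, curv)
  cors <- do.call(rbind, lapply(c("upper", "lower"), function(lf) {
    sel <- has_p & lip$leaflet == lf
    dz <- fields$dz_imposed[sel] - mean(fields$dz_imposed[sel])
    data.frame(leaflet = lf,
               r_ion = safe_pearson(dz, e_ion[sel])$r,
               r_protein = safe_pearson(dz, e_prot[sel])$r,
               stringsAsFactors = FALSE)
  }))
  ## expected |S_CD| per chain lipid, averaged over its fixed psi phases
  phase <- system$membrane$chain_phase
  sig <- fields$tilt_sigma[match(phase$lipid_id, lip$lipid_id)]
  e_sin2 <- (1 - exp(-2 * sig^2)) / 2
  psi2 <- phase$psi + deg2rad(CH_AZIMUTH_OFFSET)
  mean_sin2psi <- (rowMeans(sin(phase$psi)^2) + rowMeans(sin(psi2)^2)) / 2
  scd_exp <- (3 * mean_sin2psi * e_sin2 - 1) / 2
  scd <- data.frame(lipid_id = phase$lipid_id,
                    tilt_sigma_deg = sig * 180 / pi,
                    scd_expected = scd_exp,
                    abs_scd_expected = abs(scd_exp),
                    stringsAsFactors = FALSE)
  list(curvature = curv, correlations = cors, scd = scd)
}
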