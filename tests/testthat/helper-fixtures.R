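# Shared fixtures and independent oracles. Everything is generated in
# code; the heavyweight parameter-recovery run is built once per session
# and cached.

# Minimal standard mixture scaled down for fast module tests.
tiny_config <- function(n_lipids = 80, n_frames = 3, seed = 7, ...) {
  synth_config(
    composition = composition_spec(
      c(POPC = 0.38, DOPC = 0.19, POPS = 0.24, CHOL = 0.19),
      n_lipids, n_ca = 6, salt_mM = 150),
    n_frames = n_frames, seed = seed, ...)
}

# Bare atom table with sensible defaults for hand-built test systems.
mk_atoms <- function(x, y, z, charge = 0, sigma = 0, eps = 0,
                     residue_index = seq_along(x), residue_name = "ALA",
                     atom_name = "CA", id = seq_along(x)) {
  atom_table(id = id, residue_index = residue_index,
             residue_name = residue_name, atom_name = atom_name,
             charge = charge, lj_sigma = sigma, lj_epsilon = eps,
             is_backbone = atom_name %in% c("N", "CA", "C", "O"),
             x = x, y = y, z = z)
}

# Hand-built membrane with explicit P/C/H rows; ch is a list of
# per-lipid lists of C-H entries: list(c_xyz, h_xyz). Each lipid gets a
# P bead at p_xyz[i,].
mk_membrane <- function(p_xyz, lipid_type = "POPC", leaflet = "upper",
                        ch = NULL) {
  n <- nrow(p_xyz)
  lipid_type <- rep(lipid_type, length.out = n)
  leaflet <- rep(leaflet, length.out = n)
  rows <- list()
  lip <- list()
  rid <- 0L
  for (i in seq_len(n)) {
    rid <- rid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      id = 0L, residue_index = i, residue_name = lipid_type[i],
      atom_name = "P", charge = unname(lipid_charges()[lipid_type[i]]),
      lj_sigma = 3.7, lj_epsilon = 0.2, is_backbone = FALSE,
      x = p_xyz[i, 1], y = p_xyz[i, 2], z = p_xyz[i, 3],
      lipid_id = i, lipid_type = lipid_type[i], leaflet = leaflet[i],
      role = "P", carbon_index = NA_integer_, h_parent = NA_integer_,
      stringsAsFactors = FALSE)
    if (!is.null(ch) && length(ch) >= i && !is.null(ch[[i]])) {
      for (k in seq_along(ch[[i]])) {
        e <- ch[[i]][[k]]
        c_row <- sum(vapply(rows, nrow, integer(1))) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id = 0L, residue_index = i, residue_name = lipid_type[i],
          atom_name = paste0("C", k), charge = 0, lj_sigma = 3.5,
          lj_epsilon = 0.1, is_backbone = FALSE,
          x = e$c[1], y = e$c[2], z = e$c[3],
          lipid_id = i, lipid_type = lipid_type[i], leaflet = leaflet[i],
          role = "C", carbon_index = k, h_parent = NA_integer_,
          stringsAsFactors = FALSE)
        for (hx in e$h) {
          rows[[length(rows) + 1L]] <- data.frame(
            id = 0L, residue_index = i, residue_name = lipid_type[i],
            atom_name = paste0("H", k), charge = 0, lj_sigma = 2.0,
            lj_epsilon = 0.03, is_backbone = FALSE,
            x = hx[1], y = hx[2], z = hx[3],
            lipid_id = i, lipid_type = lipid_type[i], leaflet = leaflet[i],
            role = "H", carbon_index = k, h_parent = c_row,
            stringsAsFactors = FALSE)
        }
      }
    }
    lip[[i]] <- data.frame(lipid_id = i, lipid_type = lipid_type[i],
                           leaflet = leaflet[i],
                           headgroup_charge =
                             unname(lipid_charges()[lipid_type[i]]),
                           stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$id <- seq_len(nrow(atoms))
  membrane_model(atoms, do.call(rbind, lip))
}

# Independent all-pairs nonbonded oracle: per-atom loop with plain
# arithmetic, coded separately from the package's matrix implementation.
naive_group_energy <- function(a, b, cutoff = 12, k = 332.0636,
                               dielectric = 1, box = NULL) {
  total <- 0
  for (i in seq_len(nrow(a))) {
    dx <- a$x[i] - b$x; dy <- a$y[i] - b$y; dz <- a$z[i] - b$z
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    r <- sqrt(dx^2 + dy^2 + dz^2)
    coul <- k * a$charge[i] * b$charge / (dielectric * r)
    sig <- (a$lj_sigma[i] + b$lj_sigma) / 2
    eps <- sqrt(a$lj_epsilon[i] * b$lj_epsilon)
    sr6 <- (sig / r)^6
    lj <- 4 * eps * (sr6^2 - sr6)
    e <- coul + lj
    e[r > cutoff] <- 0
    total <- total + sum(e)
  }
  total
}

# Parameter-recovery study: 200 lipids/leaflet, 50 frames, charged face
# down, ions scattered so the ion field is decoupled from the protein
# footprint. Built once and cached for the session.
recovery_env <- new.env(parent = emptyenv())
recovery_fixture <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(recovery_env[[key]])) {
    cfg <- synth_config(n_frames = 50, seed = seed)
    sys <- synth_system(cfg, orientation = c(0, 0),
                        ion_placement = "scatter")
    traj <- synth_trajectory(sys, cfg)
    recovery_env[[key]] <- list(
      cfg = cfg, sys = sys, traj = traj,
      oracle = oracle_statistics(sys, cfg),
      cortab = curvature_correlation_table(traj, sys),
      scd = scd_vs_energy(traj, sys))
  }
  recovery_env[[key]]
}
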