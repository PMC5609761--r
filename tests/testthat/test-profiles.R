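test_that("min_distance_profile reports per-residue minima and inverses", {
  prot <- protein_model(mk_atoms(c(0, 0, 0), c(0, 4, 9), c(0, 0, 0),
                                 residue_index = 1:3))
  target <- mk_atoms(0, 0, 4, id = 50)
  prof <- min_distance_profile(prot, target)
  ## one-atom residue 4 Angstrom from the nearest target atom
  expect_equal(prof$d_min[1], 4)
  expect_equal(prof$inv_d[1], 0.25)
  expect_equal(prof$inv_d, 1 / prof$d_min, tolerance = 1e-12)
  ## two equidistant target atoms: minimum well-defined
  t2 <- mk_atoms(c(3, -3), c(0, 0), c(0, 0), id = 51:52)
  expect_equal(min_distance_profile(prot, t2)$d_min[1], 3)
  expect_error(min_distance_profile(prot, t2[0, ]), "empty")
})

test_that("the closest residue ranks top by inverse distance", {
  set.seed(41)
  n <- 12
  xyz <- cbind(stats::runif(n, 10, 30), stats::runif(n, 10, 30),
               stats::runif(n, 10, 30))
  xyz[7, ] <- c(0, 0, 2.5)      # residue 7 placed 2.5 Angstrom from ion
  prot <- protein_model(mk_atoms(xyz[, 1], xyz[, 2], xyz[, 3],
                                 residue_index = 1:n))
  ion <- mk_atoms(0, 0, 0, charge = 2, id = 99)
  prof <- min_distance_profile(prot, ion)
  expect_equal(prof$residue_index[which.max(prof$inv_d)], 7)
  ## brute force over residues
  brute <- vapply(1:n, function(i) sqrt(sum(xyz[i, ]^2)), numeric(1))
  expect_equal(prof$d_min, brute, tolerance = 1e-12)
  ## invariant under a rigid transformation of the whole system
  rot <- rot_z(33) %*% rot_x(17)
  prot2 <- prot
  prot2$atoms <- set_atom_coords(prot$atoms,
                                 atom_coords(prot$atoms) %*% t(rot) + 5)
  ion2 <- ion
  v <- c(ion$x, ion$y, ion$z) %*% t(rot) + 5
  ion2$x <- v[1]; ion2$y <- v[2]; ion2$z <- v[3]
  expect_equal(min_distance_profile(prot2, ion2)$inv_d, prof$inv_d,
               tolerance = 1e-9)
})

test_that("residue energy profiles are additive and charge-sensitive", {
  p <- energy_params()
  ## synthetic Lys bead near a POPS headgroup vs a neutral PC one
  lys <- protein_model(mk_atoms(0, 0, 5, charge = 1, residue_name = "LYS",
                                id = 501))
  pops <- mk_membrane(matrix(c(0, 0, 0), 1), lipid_type = "POPS")
  pc <- mk_membrane(matrix(c(0, 0, 0), 1), lipid_type = "POPC")
  e_pops <- residue_energy_profile(lys, pops$atoms, p)$energy
  e_pc <- residue_energy_profile(lys, pc$atoms, p)$energy
  expect_lt(e_pops, -30)
  expect_lt(abs(e_pc), 1)          # LJ only
  ## neutral residue beyond the cutoff
  far <- protein_model(mk_atoms(0, 0, 100, id = 502))
  expect_identical(residue_energy_profile(far, pops$atoms, p)$energy, 0)
  ## sum over residues equals the whole-protein group energy
  cfg <- tiny_config()
  sys <- synth_system(cfg, orientation = c(0, 0))
  prof <- residue_energy_profile(sys$protein, sys$membrane$atoms, p,
                                 sys$box)
  expect_equal(sum(prof$energy),
               group_energy(sys$protein$atoms, sys$membrane$atoms, p,
                            sys$box), tolerance = 1e-9)
})

test_that("contact residues come from the distance threshold, nested", {
  prof <- data.frame(residue_index = c(53, 82, 162),
                     residue_name = c("GLU", "GLU", "ASP"),
                     d_min = c(2.9, 3.5, 8), inv_d = 1 / c(2.9, 3.5, 8))
  expect_identical(as.character(identify_contact_residues(prof, 3.0)),
                   "GLU53")
  expect_length(identify_contact_residues(prof, 1.0), 0)
  ## nested thresholds give nested site sets
  s1 <- identify_contact_residues(prof, 3.0)
  s2 <- identify_contact_residues(prof, 4.0)
  expect_true(all(as.character(s1) %in% as.character(s2)))
})

test_that("crystal_site_overlap performs exact set comparison", {
  o5 <- site_list(c("GLU53", "GLU82", "ASP154", "GLU156", "ASP162",
                    "ASP166", "ASP285", "ASP326"), source = "simulation")
  expt <- site_list(c("GLU53", "GLU96", "GLU125", "ASP162", "GLU253",
                      "GLU247", "ASP322"), source = "crystal")
  ov <- crystal_site_overlap(o5, expt)
  expect_setequal(ov$intersection, c("ASP162", "GLU53"))
  expect_setequal(ov$observed_only,
                  c("ASP154", "ASP166", "ASP285", "ASP326", "GLU156",
                    "GLU82"))
  expect_setequal(ov$reference_only,
                  c("ASP322", "GLU125", "GLU247", "GLU253", "GLU96"))
  same <- crystal_site_overlap(o5, o5)
  expect_setequal(same$intersection, as.character(o5))
  expect_length(same$observed_only, 0)
  disj <- crystal_site_overlap(site_list("LYS1"), site_list("ASP2"))
  expect_length(disj$intersection, 0)
})

test_that("rotational_rmsd recovers pure Z rotations exactly", {
  set.seed(42)
  ref <- synth_protein(24, radius = 10)
  r0 <- rotational_rmsd(ref, ref)
  expect_equal(r0$theta_star, 0, tolerance = 1e-9)
  expect_equal(r0$rmsd, 0, tolerance = 1e-9)
  ## mobile = reference rotated 37 degrees about Z plus a translation
  mob <- ref
  mob$atoms <- set_atom_coords(ref$atoms,
                               atom_coords(ref$atoms) %*% t(rot_z(37)) +
                                 rep(c(3, -7, 11), each = nrow(ref$atoms)))
  r <- rotational_rmsd(mob, ref)
  expect_equal((r$theta_star + 360) %% 360, 360 - 37, tolerance = 1e-6)
  expect_equal(r$rmsd, 0, tolerance = 1e-9)
  ## atom-count mismatch
  short <- ref
  short$atoms <- short$atoms[1:8, ]
  expect_error(rotational_rmsd(short, ref), "differ")
})

test_that("rotational_rmsd is invariant and never worse than no rotation", {
  set.seed(43)
  for (i in 1:10) {
    n <- 15
    ref <- protein_model(mk_atoms(stats::rnorm(n, 0, 5),
                                  stats::rnorm(n, 0, 5),
                                  stats::rnorm(n, 0, 5),
                                  residue_index = 1:n))
    mob <- protein_model(mk_atoms(stats::rnorm(n, 0, 5),
                                  stats::rnorm(n, 0, 5),
                                  stats::rnorm(n, 0, 5),
                                  residue_index = 1:n))
    r <- rotational_rmsd(mob, ref)
    ## plain RMSD after COM superposition alone
    xm <- sweep(atom_coords(mob$atoms), 2, colMeans(atom_coords(mob$atoms)))
    xr <- sweep(atom_coords(ref$atoms), 2, colMeans(atom_coords(ref$atoms)))
    plain <- sqrt(mean(rowSums((xm - xr)^2)))
    expect_lte(r$rmsd, plain + 1e-12)
    ## invariance to any prior Z-rotation and translation of mobile
    mob2 <- mob
    mob2$atoms <- set_atom_coords(mob$atoms,
                                  atom_coords(mob$atoms) %*%
                                    t(rot_z(stats::runif(1, 0, 360))) +
                                    stats::rnorm(1, 0, 20))
    expect_equal(rotational_rmsd(mob2, ref)$rmsd, r$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("residue_profile_traj averages inverse distances over the window", {
  cfg <- tiny_config(n_frames = 4, jitter_sigma = 0, tilt_sigma0 = 0,
                     curvature_amplitude = 0)
  sys <- synth_system(cfg)
  traj <- synth_trajectory(sys, cfg)
  sel <- select_atoms(sys, component = "membrane")
  prof <- residue_profile_traj(traj, sys, sel, energy = TRUE)
  ## static frames: equals the single-frame profile
  one <- min_distance_profile(sys$protein, sys$membrane$atoms, sys$box)
  expect_equal(prof$inv_d, one$inv_d, tolerance = 1e-9)
  e1 <- residue_energy_profile(sys$protein, sys$membrane$atoms,
                               energy_params(), sys$box)
  expect_equal(prof$energy, e1$energy, tolerance = 1e-9)
})
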