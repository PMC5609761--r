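test_that("synth_bilayer realizes the requested composition on a lattice", {
  cfg <- synth_config(n_frames = 1)
  mem <- synth_bilayer(cfg)
  tab <- table(mem$lipids$lipid_type)
  expect_equal(as.integer(tab[c("POPC", "DOPC", "POPS", "CHOL")]),
               c(152L, 76L, 96L, 76L))
  expect_equal(sum(mem$lipids$leaflet == "upper"), 200)
  ## headgroup charges by type
  expect_true(all(mem$lipids$headgroup_charge[
    mem$lipids$lipid_type == "POPS"] == -1))
  expect_true(all(mem$lipids$headgroup_charge[
    mem$lipids$lipid_type %in% c("POPC", "DOPC", "CHOL")] == 0))
  ## cholesterol has neither P nor chain atoms
  chol_atoms <- mem$atoms[mem$atoms$lipid_type == "CHOL", ]
  expect_true(all(chol_atoms$role == "head"))
  ## determinism
  mem2 <- synth_bilayer(cfg)
  expect_identical(mem$atoms, mem2$atoms)
  ## box too small for the lattice
  expect_error(synth_bilayer(synth_config(box = c(30, 30, 150))),
               "too small")
})

test_that("the all-trans limit gives |S_CD| exactly one half", {
  cfg <- tiny_config(tilt_sigma0 = 0)
  mem <- synth_bilayer(cfg)
  s <- scd_per_lipid(mem)
  expect_equal(s$abs_scd[is.finite(s$abs_scd)],
               rep(0.5, sum(is.finite(s$abs_scd))), tolerance = 1e-12)
})

test_that("synth_protein places plan residues on the convex face", {
  prot <- synth_protein(60, radius = 15,
                        charge_plan = c(LYS = 6, GLU = 4, ASP = 4))
  expect_equal(nrow(prot$atoms), 240)
  expect_equal(net_charge(prot), 6 - 4 - 4)
  ## all-zero plan: neutral
  expect_equal(net_charge(synth_protein(30, charge_plan = c(LYS = 0))), 0)
  ## the 6 lysines are the 6 residues closest to the membrane after an
  ## upright placement (distance sort oracle on CA z)
  cfg <- tiny_config()
  mem <- synth_bilayer(cfg)
  up <- prot
  xyz <- atom_coords(up$atoms)
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + cfg$leaflet_z + 30
  up$atoms <- set_atom_coords(up$atoms, xyz)
  up <- place_at_min_distance(up, mem, 6)
  ca <- up$atoms[up$atoms$atom_name == "CA", ]
  lowest6 <- ca$residue_name[order(ca$z)][1:6]
  expect_equal(lowest6, rep("LYS", 6))
  ## four contiguous repeat annotations covering the sequence
  expect_equal(nrow(prot$repeats), 4)
  expect_equal(prot$repeats$first_residue[1], 1L)
  expect_equal(prot$repeats$last_residue[4], 60L)
  expect_true(all(prot$repeats$first_residue[-1] ==
                    utils::head(prot$repeats$last_residue, 3) + 1L))
  ## rigid body under rotation
  d0 <- stats::dist(atom_coords(prot$atoms))
  rot <- rotate_about_com(prot, 123, -45)
  expect_equal(as.numeric(stats::dist(atom_coords(rot$atoms))),
               as.numeric(d0), tolerance = 1e-9)
})

test_that("synth_system assembles a neutral, correctly placed system", {
  cfg <- tiny_config()
  sys <- synth_system(cfg)
  ## placement at 6 Angstrom
  md <- sqrt(min(anxmem:::pair_dist2(
    atom_coords(sys$protein$atoms), atom_coords(sys$membrane$atoms))))
  expect_equal(md, 6, tolerance = 1e-6)
  ## after salt the total charge is exactly zero
  expect_equal(net_charge(sys$protein, sys$membrane, sys$ions), 0)
  expect_equal(nrow(sys$ions$calcium), 6)
  ## standard build seeds 12 ions
  sys12 <- synth_system(synth_config(n_frames = 1, seed = 2))
  expect_equal(nrow(sys12$ions$calcium), 12)
})

test_that("synth_trajectory is deterministic and noise-free when frozen", {
  cfg <- tiny_config(n_frames = 3, jitter_sigma = 0, tilt_sigma0 = 0,
                     curvature_amplitude = 0)
  sys <- synth_system(cfg)
  traj <- synth_trajectory(sys, cfg)
  base <- atom_coords(sys$atoms)
  ## A = 0, jitter = 0, tilt SD = 0: every frame equals the built system
  for (f in traj$frames) expect_equal(f, base, tolerance = 1e-12)
  ## fixed seed: reproducible frames
  cfg2 <- tiny_config(n_frames = 3)
  sys2 <- synth_system(cfg2)
  t1 <- synth_trajectory(sys2, cfg2)
  t2 <- synth_trajectory(sys2, cfg2)
  for (i in 1:3) expect_identical(t1$frames[[i]], t2$frames[[i]])
  ## strictly increasing times
  expect_true(all(diff(t1$times) > 0))
})

test_that("a single ion cluster bends the leaflet by the closed-form field", {
  ## jitter-free: measured dz equals -A * field, leaflet-centered
  cfg <- tiny_config(n_lipids = 100, n_frames = 1, jitter_sigma = 0,
                     tilt_sigma0 = 0, curvature_amplitude = 2,
                     curvature_length = 10)
  sys <- synth_system(cfg)
  ## replace the seeded ions by one ion over the lattice center
  sys$ions$calcium <- data.frame(x = 0, y = 0, z = cfg$leaflet_z + 4)
  sys <- md_system(sys$protein, sys$membrane, sys$ions, sys$box)
  traj <- synth_trajectory(sys, cfg)
  s1 <- set_system_coords(sys, traj$frames[[1]])
  map <- z_shift_map(s1$membrane, "upper")
  sites <- sys$membrane$lipid_sites
  m <- match(map$lipid_id, sites$lipid_id)
  field <- exp(-(sites$x[m]^2 + sites$y[m]^2) / (2 * 10^2))
  expected <- -2 * field - mean(-2 * field)
  expect_equal(map$dz, expected, tolerance = 1e-9)
  ## lower leaflet at half amplitude
  maplo <- z_shift_map(s1$membrane, "lower")
  mlo <- match(maplo$lipid_id, sites$lipid_id)
  fieldlo <- exp(-(sites$x[mlo]^2 + sites$y[mlo]^2) / (2 * 10^2))
  expect_equal(maplo$dz, -1 * fieldlo - mean(-1 * fieldlo),
               tolerance = 1e-9)
})

test_that("z_shift_map recovers the imposed field within the jitter bound", {
  cfg <- tiny_config(n_lipids = 100, n_frames = 25, jitter_sigma = 0.4,
                     seed = 9)
  sys <- synth_system(cfg, orientation = c(0, 0), ion_placement = "scatter")
  traj <- synth_trajectory(sys, cfg)
  or <- oracle_statistics(sys, cfg)
  imp <- or$curvature[or$curvature$leaflet == "upper", ]
  acc <- NULL
  for (i in seq_len(n_frames(traj))) {
    s <- set_system_coords(sys, traj$frames[[i]])
    map <- z_shift_map(s$membrane, "upper")
    v <- map$dz[match(imp$lipid_id, map$lipid_id)]
    acc <- if (is.null(acc)) v else acc + v
  }
  recovered <- acc / n_frames(traj)
  rms <- sqrt(mean((recovered - imp$dz_imposed)^2))
  expect_lte(rms, 2 * cfg$jitter_sigma / sqrt(cfg$n_frames))
})

test_that("oracle_statistics reports the generator-side ground truth", {
  ## uncoupled curvature: imposed field is zero, correlations undefined
  cfg0 <- tiny_config(curvature_coupling = "none")
  sys0 <- synth_system(cfg0)
  or0 <- oracle_statistics(sys0, cfg0)
  expect_true(all(or0$curvature$dz_imposed == 0))
  expect_true(all(is.na(or0$correlations$r_ion)))
  ## coupled: the imposed upper-leaflet correlation with the ion proxy is
  ## positive (both dz and the charged-lipid energies drop near ions)
  cfg1 <- tiny_config(n_lipids = 200, seed = 3)
  sys1 <- synth_system(cfg1, orientation = c(0, 0),
                       ion_placement = "scatter")
  or1 <- oracle_statistics(sys1, cfg1)
  expect_gt(or1$correlations$r_ion[or1$correlations$leaflet == "upper"], 0)
  ## zero tilt SD everywhere: expected |S_CD| is exactly one half
  cfg2 <- tiny_config(tilt_sigma0 = 0, order_coupling = "none")
  sys2 <- synth_system(cfg2)
  or2 <- oracle_statistics(sys2, cfg2)
  expect_equal(or2$scd$abs_scd_expected,
               rep(0.5, nrow(or2$scd)), tolerance = 1e-12)
})
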