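test_that("pair_energy matches the analytic Coulomb and LJ forms", {
  p <- energy_params()
  a <- list(x = 0, y = 0, z = 0, charge = 1, lj_sigma = 0, lj_epsilon = 0)
  b <- list(x = 10, y = 0, z = 0, charge = 1, lj_sigma = 0, lj_epsilon = 0)
  expect_equal(pair_energy(a, b, p), 332.0636 / 10, tolerance = 1e-12)
  ## beyond the 12 Angstrom cutoff
  b13 <- b; b13$x <- 13
  expect_identical(pair_energy(a, b13, p), 0)
  ## LJ minimum: charges zero, r = 2^(1/6) sigma_ab -> -eps_ab
  a2 <- list(x = 0, y = 0, z = 0, charge = 0, lj_sigma = 3.2,
             lj_epsilon = 0.4)
  b2 <- list(x = 2^(1 / 6) * 3.2, y = 0, z = 0, charge = 0, lj_sigma = 3.2,
             lj_epsilon = 0.4)
  expect_equal(pair_energy(a2, b2, p), -0.4, tolerance = 1e-12)
  ## dielectric scales the Coulomb term
  expect_equal(pair_energy(a, b, energy_params(dielectric = 2)),
               332.0636 / 20, tolerance = 1e-12)
  ## coincident atoms raise a singularity error
  expect_error(pair_energy(a, a, p), "singular")
})

test_that("pair distances honour the minimum-image convention", {
  p <- energy_params()
  a <- list(x = 1, y = 0, z = 0, charge = 1, lj_sigma = 0, lj_epsilon = 0)
  b <- list(x = 99, y = 0, z = 0, charge = 1, lj_sigma = 0, lj_epsilon = 0)
  ## wrapped distance is 2 Angstrom in a 100 Angstrom box
  expect_equal(pair_energy(a, b, p, box = c(100, 100, 100)),
               332.0636 / 2, tolerance = 1e-12)
  expect_identical(pair_energy(a, b, p), 0)   # unwrapped: beyond cutoff
})

test_that("group_energy equals hand sums and rejects overlap", {
  p <- energy_params()
  plus <- mk_atoms(c(0, 0), c(0, 10), c(10, 0), charge = 1, id = 1:2)
  minus <- mk_atoms(0, 0, 0, charge = -1, id = 3)
  ## two +1e each at 10 Angstrom from one -1e -> -2 * 33.20636
  expect_equal(group_energy(plus, minus, p), -66.41272, tolerance = 1e-9)
  ## single-atom groups reduce to pair_energy
  expect_equal(group_energy(plus[1, ], minus, p),
               pair_energy(plus[1, ], minus[1, ], p), tolerance = 1e-12)
  far <- mk_atoms(100, 100, 100, charge = 5, id = 4)
  expect_identical(group_energy(plus, far, p), 0)
  expect_error(group_energy(plus, plus, p), "overlap")
})

test_that("group_energy is symmetric, additive and matches the naive oracle", {
  set.seed(31)
  p <- energy_params()
  box <- c(40, 40, 60)
  rand_atoms <- function(n, id0) {
    mk_atoms(stats::runif(n, 0, 40), stats::runif(n, 0, 40),
             stats::runif(n, 0, 60),
             charge = sample(c(-1, 0, 1, 2), n, replace = TRUE),
             sigma = stats::runif(n, 2, 4), eps = stats::runif(n, 0, .3),
             id = id0 + seq_len(n))
  }
  for (rep in 1:5) {
    a <- rand_atoms(40, 0)
    b <- rand_atoms(60, 100)
    cc <- rand_atoms(30, 1000)
    eab <- group_energy(a, b, p, box)
    expect_equal(eab, group_energy(b, a, p, box), tolerance = 1e-12)
    expect_equal(group_energy(a, rbind(b, cc), p, box),
                 eab + group_energy(a, cc, p, box), tolerance = 1e-10)
    expect_equal(eab, naive_group_energy(a, b, box = box),
                 tolerance = 1e-10)
  }
})

test_that("classify_bound_ions applies the dual energy/distance criterion", {
  p <- energy_params()
  ## protein: one -1e bead; membrane: one POPS P bead (-1e)
  prot <- protein_model(mk_atoms(0, 0, 30, charge = -1))
  mem <- mk_membrane(matrix(c(0, 0, 18), 1), lipid_type = "POPS")
  near <- ion_set(calcium = data.frame(x = 0, y = 0, z = 24))
  cls <- classify_bound_ions(near, prot, mem, bound_ion_criteria(), p)
  expect_true(cls$bound)
  expect_lt(cls$e_protein, -1)
  expect_lt(cls$d_protein, 10)
  ## too far from the protein (d >= 10) even though attractive
  far <- ion_set(calcium = data.frame(x = 0, y = 0, z = 6))
  clsf <- classify_bound_ions(far, prot, mem, bound_ion_criteria(), p)
  expect_gt(clsf$d_protein, 10)
  expect_false(clsf$bound)
  ## interaction weaker than 1 kcal/mol excludes the ion: push the
  ## threshold instead of the geometry
  weak <- classify_bound_ions(near, prot, mem,
                              bound_ion_criteria(e_threshold = -1e5), p)
  expect_false(weak$bound)
})

test_that("classify_bound_ions is monotone in both thresholds", {
  set.seed(32)
  cfg <- tiny_config()
  sys <- synth_system(cfg)
  base <- classify_bound_ions(sys$ions, sys$protein, sys$membrane,
                              bound_ion_criteria(), energy_params(),
                              sys$box)
  for (crit in list(bound_ion_criteria(e_threshold = -2),
                    bound_ion_criteria(d_threshold = 5),
                    bound_ion_criteria(e_threshold = -3, d_threshold = 4))) {
    tight <- classify_bound_ions(sys$ions, sys$protein, sys$membrane, crit,
                                 energy_params(), sys$box)
    expect_true(all(!tight$bound | base$bound))   # tight subset of base
  }
})

test_that("binding_enthalpy sums partner terms and excludes membrane-Ca", {
  cfg <- tiny_config()
  sys <- synth_system(cfg)
  p <- energy_params()
  h <- binding_enthalpy(sys$protein, sys$membrane, sys$ions,
                        bound_ion_criteria(), p, sys$box)
  expect_equal(h$total, h$e_protein_membrane + h$e_protein_ca,
               tolerance = 1e-12)
  ## independent recomputation from raw coordinates via the naive oracle
  cls <- classify_bound_ions(sys$ions, sys$protein, sys$membrane,
                             bound_ion_criteria(), p, sys$box)
  iat <- mk_atoms(sys$ions$calcium$x, sys$ions$calcium$y,
                  sys$ions$calcium$z, charge = 2, sigma = 2.4, eps = 0.1,
                  id = 90000 + seq_len(nrow(sys$ions$calcium)))
  expect_equal(h$e_protein_membrane,
               naive_group_energy(sys$protein$atoms, sys$membrane$atoms,
                                  box = sys$box), tolerance = 1e-9)
  expect_equal(h$e_protein_ca,
               naive_group_energy(sys$protein$atoms,
                                  iat[cls$bound, , drop = FALSE],
                                  box = sys$box), tolerance = 1e-9)
  expect_equal(h$n_bound_ca, sum(cls$bound))
  ## with no ions the total is the protein-membrane term alone
  h0 <- binding_enthalpy(sys$protein, sys$membrane, ion_set(),
                         bound_ion_criteria(), p, sys$box)
  expect_equal(h0$total, h0$e_protein_membrane)
  expect_equal(h0$n_bound_ca, 0L)
})

test_that("per_component_energy divides totals by interacting species", {
  cfg <- tiny_config()
  sys <- synth_system(cfg, orientation = c(0, 0))
  p <- energy_params()
  pc <- per_component_energy(sys$protein, sys$membrane, sys$ions, p,
                             sys$box)
  expect_setequal(pc$component, c("POPS", "PIP2", "Ca"))
  for (i in seq_len(nrow(pc))) {
    if (pc$n_interacting[i] > 0) {
      expect_equal(pc$per_species[i], pc$total[i] / pc$n_interacting[i],
                   tolerance = 1e-12)
      expect_false(pc$no_interactors[i])
    } else {
      expect_identical(pc$per_species[i], 0)
      expect_true(pc$no_interactors[i])
    }
  }
  ## PIP2 absent from this mixture: flagged, zero
  expect_true(pc$no_interactors[pc$component == "PIP2"])
  ## totals match group_energy restricted to the interacting subset
  pops <- sys$membrane$lipids$lipid_id[
    sys$membrane$lipids$lipid_type == "POPS"]
  e <- vapply(pops, function(id) group_energy(
    sys$membrane$atoms[sys$membrane$atoms$lipid_id == id, ],
    sys$protein$atoms, p, sys$box), numeric(1))
  expect_equal(pc$total[pc$component == "POPS"], sum(e[abs(e) >= 1]),
               tolerance = 1e-9)
})

test_that("energy_time_series tracks group interactions over frames", {
  cfg <- tiny_config(n_frames = 4, jitter_sigma = 0, tilt_sigma0 = 0,
                     curvature_amplitude = 0)
  sys <- synth_system(cfg)
  traj <- synth_trajectory(sys, cfg)
  sel_a <- select_atoms(sys, component = "protein")
  sel_b <- select_atoms(sys, component = "membrane", lipid_type = "POPS")
  ts <- energy_time_series(traj, sys, sel_a, sel_b)
  expect_equal(nrow(ts), 4)
  ## static frames give a constant series
  expect_equal(diff(range(ts$energy)), 0, tolerance = 1e-9)
  expect_error(energy_time_series(traj, sys, integer(0), sel_b), "empty")
  expect_error(energy_time_series(traj, sys, sel_a, sel_a), "overlap")

  ## constructed approach of opposite charges: energy is monotone
  ## non-increasing once inside the cutoff
  plus <- protein_model(mk_atoms(0, 0, 0, charge = 1, id = 1))
  minus <- protein_model(mk_atoms(0, 0, 30, charge = -1, id = 2))
  frames <- lapply(seq(30, 2, by = -2), function(z)
    rbind(c(0, 0, 0), c(0, 0, z)))
  sys2 <- md_system(protein = protein_model(rbind(plus$atoms,
                                                  minus$atoms)))
  traj2 <- md_trajectory(frames, times = seq_along(frames))
  ts2 <- energy_time_series(traj2, sys2, 1L, 2L)
  expect_true(all(diff(ts2$energy) <= 1e-12))
  ## zero while beyond the cutoff
  expect_identical(ts2$energy[1], 0)
})

test_that("window_average computes trailing means and SDs", {
  s <- data.frame(time_ns = 0:10, v = rep(4.5, 11))
  w <- window_average(s, 5)
  expect_equal(w$mean, 4.5)
  expect_equal(w$sd, 0)
  ## linear ramp 0..10 over 11 frames, full window -> mean 5
  r <- data.frame(time_ns = 0:10, v = 0:10)
  expect_equal(window_average(r, Inf)$mean, 5)
  ## trailing window semantics: strictly after t_end - window
  expect_equal(window_average(r, 3)$mean, mean(8:10))
  expect_equal(window_average(r, 3)$n_frames, 3L)
  ## leading window
  expect_equal(window_average(r, 3, from_end = FALSE)$mean, mean(0:3))
  expect_error(window_average(data.frame(time_ns = numeric(), v = numeric()),
                              5), "empty")
})
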