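## Simplified nonbonded interaction model: cutoff Coulomb plus
## Lennard-Jones with Lorentz-Berthelot combining over minimum-image
## distances. This is the analysis-side energy model; it makes no claim to
## reproduce force-field magnitudes, only the decomposition and threshold
## logic built on top of it.

#' Nonbonded energy model parameters
#'
#' @param cutoff pair cutoff distance in Angstrom (default 12, i.e.
#'   1.2 nm).
#' @param coulomb_k Coulomb constant in kcal Angstrom / (mol e^2).
#' @param dielectric relative dielectric constant (>= 1).
#' @return an object of class `energy_params`.
#' @export
energy_params <- function(cutoff = 12, coulomb_k = 332.0636,
                          dielectric = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (dielectric < 1) stop("dielectric must be >= 1")
  structure(list(cutoff = cutoff, coulomb_k = coulomb_k,
                 dielectric = dielectric, lj_combining = "lorentz-berthelot"),
            class = "energy_params")
}

#' Bound-ion classification criteria
#'
#' An ion counts as bound when its interaction with the protein AND with
#' the membrane is attractive with magnitude at least `|e_threshold|`
#' kcal/mol (i.e. `E <= e_threshold`), and its minimal distance to each
#' partner is below `d_threshold` Angstrom.
#'
#' @param e_threshold energy threshold in kcal/mol (default -1).
#' @param d_threshold distance threshold in Angstrom (default 10).
#' @return an object of class `bound_ion_criteria`.
#' @export
bound_ion_criteria <- function(e_threshold = -1, d_threshold = 10) {
  if (d_threshold <= 0) stop("d_threshold must be > 0")
  structure(list(e_threshold = e_threshold, d_threshold = d_threshold),
            class = "bound_ion_criteria")
}

## Vectorized cross-group energy. xa/xb: coordinate matrices; q/s/e:
## charge, LJ sigma, LJ epsilon vectors. Returns the total, or per-row-of-a
## sums when per_row = TRUE.
cross_energy <- function(xa, qa, sa, ea, xb, qb, sb, eb, params,
                         box = NULL, per_row = FALSE) {
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0 || nb == 0)
    return(if (per_row) numeric(na) else 0)
  r2 <- pair_dist2(xa, xb, box)
  if (any(r2 < 1e-12))
    stop("singular atom pair at distance < 1e-6 Angstrom")
  within <- r2 <= params$cutoff^2
  r <- sqrt(r2)
  e <- matrix(0, na, nb)
  qq <- outer(qa, qb)
  if (any(qq != 0)) {
    e <- e + (params$coulomb_k / params$dielectric) * qq / r
  }
  epair <- outer(sqrt(ea), sqrt(eb))
  if (any(epair != 0)) {
    sig <- outer(sa, sb, "+") / 2
    sr6 <- (sig / r)^6
    e <- e + 4 * epair * (sr6 * sr6 - sr6)
  }
  e[!within] <- 0
  if (per_row) rowSums(e) else sum(e)
}

atoms_energy_args <- function(atoms) {
  list(x = atom_coords(atoms), q = atoms$charge, s = atoms$lj_sigma,
       e = atoms$lj_epsilon)
}

#' Nonbonded energy of a single atom pair
#'
#' Minimum-image distance `r`; zero beyond the cutoff, otherwise
#' `k q_a q_b / (eps r) + 4 e_ab ((s_ab/r)^12 - (s_ab/r)^6)` with
#' Lorentz-Berthelot combining (`s_ab` arithmetic mean, `e_ab` geometric
#' mean).
#'
#' @param a,b single-row atom tables (or lists with `x`, `y`, `z`,
#'   `charge`, `lj_sigma`, `lj_epsilon`).
#' @param params an [energy_params()].
#' @param box orthorhombic box `c(Lx, Ly, Lz)` or `NULL`.
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(a, b, params = energy_params(), box = NULL) {
  cross_energy(matrix(c(a$x, a$y, a$z), 1, 3), a$charge, a$lj_sigma,
               a$lj_epsilon,
               matrix(c(b$x, b$y, b$z), 1, 3), b$charge, b$lj_sigma,
               b$lj_epsilon, params, box)
}

#' Total nonbonded energy between two atom groups
#'
#' Sum of [pair_energy()] over the cross product of two disjoint groups
#' (disjointness is checked on atom ids when both tables carry them).
#'
#' @param group_a,group_b atom tables.
#' @param params an [energy_params()].
#' @param box orthorhombic box or `NULL`.
#' @return energy in kcal/mol.
#' @export
group_energy <- function(group_a, group_b, params = energy_params(),
                         box = NULL) {
  if (!is.null(group_a$id) && !is.null(group_b$id) &&
      length(intersect(group_a$id, group_b$id)))
    stop("groups overlap: shared atom ids ",
         paste(utils::head(intersect(group_a$id, group_b$id), 5),
               collapse = ", "))
  a <- atoms_energy_args(group_a)
  b <- atoms_energy_args(group_b)
  cross_energy(a$x, a$q, a$s, a$e, b$x, b$q, b$s, b$e, params, box)
}

#' Classify Ca2+ ions as bound or unbound
#'
#' Applies the dual bound-ion criterion to every ion: attractive
#' interaction of magnitude at least `|e_threshold|` with both the protein
#' and the membrane, and minimal distance below `d_threshold` to both.
#'
#' @param ions an [ion_set()] or an ion atom table.
#' @param protein a [protein_model()].
#' @param membrane a [membrane_model()].
#' @param criteria a [bound_ion_criteria()].
#' @param params an [energy_params()].
#' @param box orthorhombic box or `NULL`.
#' @return `data.frame` with one row per ion: `e_protein`, `e_membrane`,
#'   `d_protein`, `d_membrane` and logical `bound`.
#' @export
classify_bound_ions <- function(ions, protein, membrane,
                                criteria = bound_ion_criteria(),
                                params = energy_params(), box = NULL) {
  iat <- if (inherits(ions, "ion_set")) ion_atom_table(ions, 10000000L)
         else ions
  n <- nrow(iat)
  out <- data.frame(e_protein = numeric(n), e_membrane = numeric(n),
                    d_protein = numeric(n), d_membrane = numeric(n),
                    bound = logical(n))
  if (n == 0) return(out)
  pa <- atoms_energy_args(protein$atoms)
  ma <- atoms_energy_args(membrane$atoms)
  ia <- atoms_energy_args(iat)
  for (i in seq_len(n)) {
    xi <- ia$x[i, , drop = FALSE]
    out$e_protein[i] <- cross_energy(xi, ia$q[i], ia$s[i], ia$e[i],
                                     pa$x, pa$q, pa$s, pa$e, params, box)
    out$e_membrane[i] <- cross_energy(xi, ia$q[i], ia$s[i], ia$e[i],
                                      ma$x, ma$q, ma$s, ma$e, params, box)
    out$d_protein[i] <- min_pair_dist(xi, pa$x, box)
    out$d_membrane[i] <- min_pair_dist(xi, ma$x, box)
  }
  out$bound <- out$e_protein <= criteria$e_threshold &
    out$e_membrane <= criteria$e_threshold &
    out$d_protein < criteria$d_threshold &
    out$d_membrane < criteria$d_threshold
  out
}

#' Binding-enthalpy decomposition for one frame
#'
#' Total binding enthalpy = protein-membrane energy plus protein-Ca2+
#' energy over *bound* ions only. The membrane-Ca2+ energy never enters
#' the total.
#'
#' @inheritParams classify_bound_ions
#' @return list with `e_protein_membrane`, `e_protein_ca`, `total` (all
#'   kcal/mol) and `n_bound_ca`.
#' @export
binding_enthalpy <- function(protein, membrane, ions,
                             criteria = bound_ion_criteria(),
                             params = energy_params(), box = NULL) {
  e_pm <- group_energy(protein$atoms, membrane$atoms, params, box)
  cls <- classify_bound_ions(ions, protein, membrane, criteria, params, box)
  e_pc <- 0
  if (any(cls$bound)) {
    iat <- ion_atom_table(ions, 10000000L)
    e_pc <- group_energy(protein$atoms, iat[cls$bound, , drop = FALSE],
                         params, box)
  }
  list(e_protein_membrane = e_pm, e_protein_ca = e_pc,
       total = e_pm + e_pc, n_bound_ca = sum(cls$bound))
}

#' Binding enthalpy along a trajectory
#'
#' Per-frame [binding_enthalpy()] decomposition; bound ions are classified
#' per frame and the (possibly fractional) `n_bound_ca` reported by
#' [window_average()] is a time average of the per-frame counts.
#'
#' @param traj an [md_trajectory()].
#' @param system an [md_system()] with protein, membrane and ions.
#' @inheritParams classify_bound_ions
#' @return `data.frame` with `time_ns`, `e_protein_membrane`,
#'   `e_protein_ca`, `total`, `n_bound_ca`.
#' @export
binding_enthalpy_series <- function(traj, system,
                                    criteria = bound_ion_criteria(),
                                    params = energy_params()) {
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    s <- set_system_coords(system, traj$frames[[i]])
    h <- binding_enthalpy(s$protein, s$membrane, s$ions, criteria, params,
                          traj$box)
    data.frame(time_ns = traj$times[i],
               e_protein_membrane = h$e_protein_membrane,
               e_protein_ca = h$e_protein_ca, total = h$total,
               n_bound_ca = h$n_bound_ca)
  })
  do.call(rbind, rows)
}

#' Per-component interaction energies with the protein
#'
#' For the charged membrane components (POPS, PI(4,5)P2) and the Ca2+
#' ions: total protein interaction energy, the number of "interacting"
#' species (|E| at or above `e_interact` kcal/mol) and the energy per
#' interacting species (total / n; reported as 0 with `no_interactors =
#' TRUE` when n = 0).
#'
#' @param protein,membrane,ions system components.
#' @param params an [energy_params()].
#' @param box orthorhombic box or `NULL`.
#' @param e_interact magnitude threshold in kcal/mol defining an
#'   interacting species.
#' @param components which components to report.
#' @return `data.frame` with `component`, `total`, `n_interacting`,
#'   `per_species`, `no_interactors`.
#' @export
per_component_energy <- function(protein, membrane, ions,
                                 params = energy_params(), box = NULL,
                                 e_interact = 1,
                                 components = c("POPS", "PIP2", "Ca")) {
  res <- lapply(components, function(comp) {
    if (comp == "Ca") {
      iat <- ion_atom_table(ions, 10000000L)
      e <- vapply(seq_len(nrow(iat)), function(i)
        group_energy(iat[i, , drop = FALSE], protein$atoms, params, box),
        numeric(1))
    } else {
      ids <- membrane$lipids$lipid_id[membrane$lipids$lipid_type == comp]
      e <- vapply(ids, function(id) {
        sub <- membrane$atoms[membrane$atoms$lipid_id == id, , drop = FALSE]
        group_energy(sub, protein$atoms, params, box)
      }, numeric(1))
    }
    n_int <- sum(abs(e) >= e_interact)
    tot <- if (length(e)) sum(e[abs(e) >= e_interact]) else 0
    data.frame(component = comp, total = tot, n_interacting = n_int,
               per_species = if (n_int > 0) tot / n_int else 0,
               no_interactors = n_int == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Interaction-energy time series between two atom selections
#'
#' Evaluates [group_energy()] between two selections (global atom indices,
#' see [select_atoms()]) in every trajectory frame.
#'
#' @param traj an [md_trajectory()].
#' @param system an [md_system()].
#' @param sel_a,sel_b integer atom-index vectors (non-empty, disjoint).
#' @param params an [energy_params()].
#' @return `data.frame` with `time_ns` and `energy` (kcal/mol).
#' @export
energy_time_series <- function(traj, system, sel_a, sel_b,
                               params = energy_params()) {
  if (!length(sel_a) || !length(sel_b))
    stop("empty atom selection")
  if (length(intersect(sel_a, sel_b)))
    stop("selections overlap")
  meta_a <- system$atoms[sel_a, , drop = FALSE]
  meta_b <- system$atoms[sel_b, , drop = FALSE]
  energy <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- traj$frames[[i]]
    cross_energy(xyz[sel_a, , drop = FALSE], meta_a$charge,
                 meta_a$lj_sigma, meta_a$lj_epsilon,
                 xyz[sel_b, , drop = FALSE], meta_b$charge,
                 meta_b$lj_sigma, meta_b$lj_epsilon, params, traj$box)
  }, numeric(1))
  data.frame(time_ns = traj$times, energy = energy)
}

#' Windowed mean and standard deviation of a time series
#'
#' Averages a per-frame series over a trailing (default) or leading time
#' window, e.g. the last 50 ns of a production run.
#'
#' @param series `data.frame` whose first column is `time_ns`; all other
#'   numeric columns are averaged.
#' @param window_ns window length in ns (must not exceed the series span
#'   by more than one frame spacing).
#' @param from_end if `TRUE`, take the trailing window (`time > t_end -
#'   window`); otherwise the leading one.
#' @return `data.frame` with one row per averaged column: `quantity`,
#'   `mean`, `sd`, `n_frames`.
#' @export
window_average <- function(series, window_ns, from_end = TRUE) {
  stopifnot("time_ns" %in% names(series))
  idx <- window_frames(series$time_ns, window_ns, from_end)
  if (!length(idx)) stop("empty averaging window")
  cols <- setdiff(names(series), "time_ns")
  do.call(rbind, lapply(cols, function(cn) {
    v <- series[[cn]][idx]
    data.frame(quantity = cn, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_frames = length(idx), stringsAsFactors = FALSE)
  }))
}
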