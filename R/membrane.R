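## Leaflet-resolved curvature (P-atom z-shift) maps, per-lipid interaction
## energy maps, curvature-energy Pearson correlations, and deuterium order
## parameter (S_CD) analysis.

#' Assign lipids to leaflets
#'
#' A lipid belongs to the upper leaflet when its P atom lies above the
#' membrane midplane (the mean z of all P atoms); the upper leaflet is the
#' protein-facing one by build convention. Lipids without a P atom
#' (cholesterol) get `NA`.
#'
#' @param membrane a [membrane_model()].
#' @return character vector (`"upper"`/`"lower"`/`NA`) along
#'   `membrane$lipids`.
#' @export
assign_leaflets <- function(membrane) {
  p <- membrane$atoms[membrane$atoms$role == "P", , drop = FALSE]
  if (!nrow(p)) stop("membrane has no P atoms")
  mid <- mean(p$z)
  if (diff(range(p$z)) < 10) {
    ## no bilayer-scale separation in z: monolayer input
    warning("P atoms span < 10 Angstrom in z: single-leaflet mode, ",
            "all lipids assigned to the upper leaflet")
    lab <- rep("upper", nrow(p))
  } else {
    lab <- ifelse(p$z > mid, "upper", "lower")
  }
  out <- rep(NA_character_, nrow(membrane$lipids))
  out[match(p$lipid_id, membrane$lipids$lipid_id)] <- lab
  out
}

#' Per-lipid z-shift (curvature) map for one leaflet
#'
#' For every P-bearing lipid of a leaflet: the P atom's z coordinate minus
#' the leaflet mean z. By construction the map has exactly zero mean over
#' the leaflet; negative values mark local depressions.
#'
#' @param membrane a [membrane_model()].
#' @param leaflet `"upper"` or `"lower"`.
#' @return `data.frame` with `lipid_id`, `lipid_type`, `leaflet`, `x`,
#'   `y`, `dz` (all lengths in Angstrom).
#' @export
z_shift_map <- function(membrane, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  p <- membrane$atoms[membrane$atoms$role == "P" &
                        membrane$atoms$leaflet == leaflet, , drop = FALSE]
  if (!nrow(p)) stop("leaflet '", leaflet, "' has no P atoms")
  data.frame(lipid_id = p$lipid_id, lipid_type = p$lipid_type,
             leaflet = leaflet, x = p$x, y = p$y, dz = p$z - mean(p$z),
             stringsAsFactors = FALSE)
}

#' Per-lipid interaction energy map
#'
#' [group_energy()] between each lipid (all its atoms) and a partner atom
#' set (the protein or the Ca2+ ions). Summing the map reproduces the
#' whole-membrane group energy.
#'
#' @param membrane a [membrane_model()].
#' @param partner atom table of the partner group.
#' @param params an [energy_params()].
#' @param box orthorhombic box or `NULL`.
#' @param leaflet optionally restrict to one leaflet.
#' @return `data.frame` with `lipid_id`, `lipid_type`, `leaflet`,
#'   `energy` (kcal/mol).
#' @export
lipid_energy_map <- function(membrane, partner, params = energy_params(),
                             box = NULL, leaflet = NULL) {
  if (is.null(partner) || nrow(partner) == 0)
    stop("partner atom set is empty")
  lip <- membrane$lipids
  if (!is.null(leaflet)) lip <- lip[lip$leaflet %in% leaflet, , drop = FALSE]
  ma <- membrane$atoms[membrane$atoms$lipid_id %in% lip$lipid_id, ,
                       drop = FALSE]
  b <- atoms_energy_args(partner)
  a <- atoms_energy_args(ma)
  per_atom <- cross_energy(a$x, a$q, a$s, a$e, b$x, b$q, b$s, b$e, params,
                           box, per_row = TRUE)
  e <- tapply(per_atom, factor(ma$lipid_id, levels = lip$lipid_id), sum)
  data.frame(lipid_id = lip$lipid_id, lipid_type = lip$lipid_type,
             leaflet = lip$leaflet, energy = as.numeric(e),
             stringsAsFactors = FALSE)
}

## Pearson correlation with explicit degenerate handling. Returns a list
## (r, n, reason) where r is NA for undefined correlations.
safe_pearson <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n)
    return(list(r = NA_real_, n = length(x), reason = "too few points"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x), reason = "zero variance"))
  list(r = stats::cor(x, y), n = length(x), reason = NA_character_)
}

#' Curvature-energy correlation for one curvature/energy map
#'
#' Pearson correlation over the lipids of a leaflet between the z-shift
#' and a per-lipid interaction energy. Undefined correlations (zero
#' variance, too few lipids) are reported as `NA` with a reason, mirroring
#' "N/A" table entries.
#'
#' @param map output of [z_shift_map()].
#' @param energy_map output of [lipid_energy_map()] (same lipids).
#' @return list with `r`, `n`, `reason`.
#' @export
curvature_energy_correlation <- function(map, energy_map) {
  e <- energy_map$energy[match(map$lipid_id, energy_map$lipid_id)]
  safe_pearson(map$dz, e)
}

#' Curvature-energy correlations along a trajectory
#'
#' For each leaflet and each partner (protein, Ca2+): per-frame Pearson
#' correlation between the per-lipid z-shift and the per-lipid interaction
#' energy, averaged over the frames of a trailing window. Frames with
#' undefined correlation are dropped from the average; if all frames are
#' undefined the entry is `NA` with a reason.
#'
#' @param traj an [md_trajectory()].
#' @param system an [md_system()] with membrane and at least one partner.
#' @param params an [energy_params()].
#' @param window_ns trailing window length in ns (default all frames).
#' @return `data.frame` with `leaflet`, `partner`, `r` (window-mean),
#'   `r_sd`, `n_frames`, `reason`.
#' @export
curvature_correlation_table <- function(traj, system,
                                        params = energy_params(),
                                        window_ns = Inf) {
  idx <- window_frames(traj$times, window_ns)
  partners <- list()
  if (!is.null(system$index$protein)) partners$protein <- system$index$protein
  if (!is.null(system$index$ion)) partners$ca <- system$index$ion
  if (!length(partners)) stop("system has neither protein nor ions")
  out <- list()
  for (lf in c("upper", "lower")) {
    rs <- lapply(partners, function(p) numeric(0))
    for (i in idx) {
      s <- set_system_coords(system, traj$frames[[i]])
      map <- z_shift_map(s$membrane, lf)
      for (pn in names(partners)) {
        emap <- lipid_energy_map(s$membrane,
                                 s$atoms[partners[[pn]], , drop = FALSE],
                                 params, traj$box, leaflet = lf)
        cc <- curvature_energy_correlation(map, emap)
        if (is.finite(cc$r)) rs[[pn]] <- c(rs[[pn]], cc$r)
      }
    }
    for (pn in names(partners)) {
      v <- rs[[pn]]
      out[[length(out) + 1L]] <- data.frame(
        leaflet = lf, partner = pn,
        r = if (length(v)) mean(v) else NA_real_,
        r_sd = if (length(v) > 1) stats::sd(v) else 0,
        n_frames = length(v),
        reason = if (length(v)) NA_character_ else
          "correlation undefined in every frame",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Deuterium order parameter per lipid
#'
#' `S_CD = mean over chain C-H bonds of (3 cos^2(theta) - 1)/2`, with
#' `theta` the angle between the C-H vector and the bilayer normal (Z).
#' A perfectly ordered all-trans chain along Z (C-H perpendicular to Z)
#' gives -0.5; the magnitude `|S_CD|` is the conventionally reported
#' value. Lipids without chain atoms (cholesterol) return `NA`.
#'
#' @param membrane a [membrane_model()].
#' @return `data.frame` with `lipid_id`, `lipid_type`, `leaflet`, `scd`
#'   (signed) and `abs_scd`.
#' @export
scd_per_lipid <- function(membrane) {
  a <- membrane$atoms
  h <- which(a$role == "H")
  lip <- membrane$lipids
  scd <- rep(NA_real_, nrow(lip))
  if (length(h)) {
    cpar <- a$h_parent[h]
    vx <- a$x[h] - a$x[cpar]
    vy <- a$y[h] - a$y[cpar]
    vz <- a$z[h] - a$z[cpar]
    cz2 <- vz^2 / (vx^2 + vy^2 + vz^2)
    s <- (3 * cz2 - 1) / 2
    m <- tapply(s, factor(a$lipid_id[h], levels = lip$lipid_id), mean)
    scd <- as.numeric(m)
  }
  out <- data.frame(lipid_id = lip$lipid_id, lipid_type = lip$lipid_type,
                    leaflet = lip$leaflet, scd = scd, abs_scd = abs(scd),
                    stringsAsFactors = FALSE)
  bad <- is.finite(out$scd) & (out$scd < -0.5 - 1e-9 | out$scd > 1 + 1e-9)
  if (any(bad))
    warning("S_CD outside the physical range for lipid(s): ",
            paste(out$lipid_id[bad], collapse = ", "))
  out
}

#' Order parameter versus interaction energy over a window
#'
#' Per lipid: window-averaged |S_CD|, protein interaction energy and Ca2+
#' interaction energy, plus a dual-interactor flag for lipids interacting
#' significantly (magnitude at least `dual_threshold` kcal/mol) with both
#' partners.
#'
#' @param traj an [md_trajectory()].
#' @param system an [md_system()] with membrane, protein and ions.
#' @param params an [energy_params()].
#' @param window_ns trailing window length in ns (default all frames).
#' @param dual_threshold magnitude threshold (kcal/mol) for the dual flag.
#' @return `data.frame` with `lipid_id`, `lipid_type`, `leaflet`, `scd`
#'   (signed window mean), `abs_scd`, `e_protein`, `e_ca`,
#'   `dual_interactor`.
#' @export
scd_vs_energy <- function(traj, system, params = energy_params(),
                          window_ns = Inf, dual_threshold = 1) {
  idx <- window_frames(traj$times, window_ns)
  lip <- system$membrane$lipids
  acc_s <- rep(0, nrow(lip)); acc_ep <- rep(0, nrow(lip))
  acc_ec <- rep(0, nrow(lip)); n_s <- rep(0, nrow(lip))
  for (i in idx) {
    s <- set_system_coords(system, traj$frames[[i]])
    sc <- scd_per_lipid(s$membrane)
    fin <- is.finite(sc$scd)
    acc_s[fin] <- acc_s[fin] + sc$scd[fin]
    n_s[fin] <- n_s[fin] + 1
    if (!is.null(system$index$protein)) {
      ep <- lipid_energy_map(s$membrane,
                             s$atoms[system$index$protein, , drop = FALSE],
                             params, traj$box)
      acc_ep <- acc_ep + ep$energy[match(lip$lipid_id, ep$lipid_id)]
    }
    if (!is.null(system$index$ion)) {
      ec <- lipid_energy_map(s$membrane,
                             s$atoms[system$index$ion, , drop = FALSE],
                             params, traj$box)
      acc_ec <- acc_ec + ec$energy[match(lip$lipid_id, ec$lipid_id)]
    }
  }
  nf <- length(idx)
  scd <- ifelse(n_s > 0, acc_s / pmax(n_s, 1), NA_real_)
  e_p <- acc_ep / nf
  e_c <- acc_ec / nf
  data.frame(lipid_id = lip$lipid_id, lipid_type = lip$lipid_type,
             leaflet = lip$leaflet, scd = scd, abs_scd = abs(scd),
             e_protein = e_p, e_ca = e_c,
             dual_interactor = abs(e_p) >= dual_threshold &
               abs(e_c) >= dual_threshold,
             stringsAsFactors = FALSE)
}
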