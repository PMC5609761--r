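## Structure and results I/O. PDB files are read through bio3d; GRO files
## (which no installed package reads) use a fixed-column parser here.
## Coordinates are Angstrom internally; GRO nanometers are converted on
## read and write. Structure formats carry no charges or LJ parameters,
## so those come from a user-supplied parameter table keyed by
## (residue name, atom name) with wildcard fallback.

#' Default lipid residue-name alias table
#'
#' Maps structure-file residue names to the lipid types understood by the
#' builders. Extend or override via the `aliases` argument of
#' [as_membrane()].
#'
#' @return named character vector (residue name -> lipid type).
#' @export
default_lipid_aliases <- function() {
  c(POPC = "POPC", DOPC = "DOPC", POPS = "POPS", CHOL = "CHOL",
    CHL1 = "CHOL", PIP2 = "PIP2", SAPI = "PIP2", POPE = "POPE")
}

#' Read atoms from a PDB or GRO file
#'
#' Returns a plain atom table (charges and LJ parameters zero; assign
#' them with [apply_parameters()]). The format is inferred from the file
#' extension unless given.
#'
#' @param path input file.
#' @param format `"pdb"`, `"gro"` or `"auto"`.
#' @return an atom table (see [atom_table()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (format == "pdb") read_pdb_atoms(path) else read_gro_atoms(path)
}

read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  atom_table(id = seq_len(nrow(a)), residue_index = a$resno,
             residue_name = a$resid, atom_name = a$elety,
             is_backbone = a$elety %in% c("N", "CA", "C", "O"),
             x = a$x, y = a$y, z = a$z)
}

read_gro_atoms <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("truncated GRO file (", length(lines), " lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count on line 2 of ", path)
  if (length(lines) < n + 3)
    stop("truncated GRO file: header declares ", n, " atoms but only ",
         length(lines) - 3, " atom lines present")
  al <- lines[3:(n + 2)]
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("malformed GRO ", what, " on line ", ln[which(is.na(v))[1]],
           " of ", path)
    v
  }
  ln <- seq_along(al) + 2L
  atom_table(
    id = seq_len(n),
    residue_index = as.integer(num(substr(al, 1, 5), "residue number", ln)),
    residue_name = trimws(substr(al, 6, 10)),
    atom_name = trimws(substr(al, 11, 15)),
    is_backbone = trimws(substr(al, 11, 15)) %in% c("N", "CA", "C", "O"),
    x = 10 * num(substr(al, 21, 28), "x coordinate", ln),
    y = 10 * num(substr(al, 29, 36), "y coordinate", ln),
    z = 10 * num(substr(al, 37, 44), "z coordinate", ln))
}

#' Read the box vector of a GRO file
#'
#' @param path input GRO file.
#' @return `c(Lx, Ly, Lz)` in Angstrom.
#' @export
read_gro_box <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  v <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  10 * v[1:3]
}

#' Assign charges and Lennard-Jones parameters from a table
#'
#' The parameter table is a list of records with fields `residue`,
#' `atom`, `charge`, `lj_sigma`, `lj_epsilon`; `residue` or `atom` may be
#' `"*"`. The most specific match wins (exact/exact, then exact residue,
#' then exact atom, then global wildcard). Atoms with no match at all
#' raise an error naming the offender.
#'
#' @param atoms an atom table.
#' @param params parameter records, or a path to a YAML/JSON file with a
#'   top-level `parameters` list.
#' @return the atom table with charges and LJ parameters filled in.
#' @export
apply_parameters <- function(atoms, params) {
  if (is.character(params)) params <- read_param_table(params)
  key <- function(r, a) paste(r, a, sep = ":")
  tab <- list()
  for (p in params) {
    tab[[key(p$residue %||% "*", p$atom %||% "*")]] <-
      c(charge = p$charge %||% 0, lj_sigma = p$lj_sigma %||% 0,
        lj_epsilon = p$lj_epsilon %||% 0)
  }
  lookup <- function(res, at) {
    for (k in c(key(res, at), key(res, "*"), key("*", at), key("*", "*"))) {
      if (!is.null(tab[[k]])) return(tab[[k]])
    }
    NULL
  }
  for (i in seq_len(nrow(atoms))) {
    v <- lookup(atoms$residue_name[i], atoms$atom_name[i])
    if (is.null(v))
      stop("no parameters for residue '", atoms$residue_name[i],
           "', atom '", atoms$atom_name[i], "'")
    atoms$charge[i] <- v[["charge"]]
    atoms$lj_sigma[i] <- v[["lj_sigma"]]
    atoms$lj_epsilon[i] <- v[["lj_epsilon"]]
  }
  atoms
}

#' @rdname apply_parameters
#' @param path YAML or JSON file with a top-level `parameters` list.
#' @export
read_param_table <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path) else yaml::read_yaml(path)
  cfg$parameters %||% cfg
}

#' Interpret an atom table as a protein model
#'
#' @param atoms an atom table (e.g. from [read_structure()]).
#' @param repeats optional repeat annotation `data.frame`.
#' @return a [protein_model()].
#' @export
as_protein <- function(atoms, repeats = NULL) {
  protein_model(atoms, repeats)
}

#' Interpret an atom table as a membrane model
#'
#' Groups atoms into lipids by residue index, types them through the
#' alias table, assigns headgroup charges by type and infers atom roles:
#' `"P"` for the phosphorus-equivalent atom, `"C"`/`"H"` for numbered
#' chain carbons and hydrogens (each hydrogen attached to the nearest
#' preceding carbon), `"head"` otherwise. Leaflets are assigned from the
#' P-atom z relative to the midplane.
#'
#' @param atoms an atom table.
#' @param aliases residue-name alias table, see [default_lipid_aliases()].
#' @return a [membrane_model()].
#' @export
as_membrane <- function(atoms, aliases = default_lipid_aliases()) {
  unknown <- setdiff(unique(atoms$residue_name), names(aliases))
  if (length(unknown))
    stop("unknown lipid residue name(s) with no alias: ",
         paste(unknown, collapse = ", "))
  atoms$lipid_type <- unname(aliases[atoms$residue_name])
  atoms$lipid_id <- match(atoms$residue_index, unique(atoms$residue_index))
  atoms$role <- ifelse(atoms$atom_name == "P", "P",
                ifelse(grepl("^C[0-9]+$", atoms$atom_name), "C",
                ifelse(grepl("^H[0-9]+", atoms$atom_name), "H", "head")))
  ## lipids with no P atom (cholesterol-like) carry headgroup beads only
  has_p <- atoms$lipid_id %in% atoms$lipid_id[atoms$role == "P"]
  atoms$role[!has_p] <- "head"
  atoms$carbon_index <- ifelse(atoms$role %in% c("C", "H"),
    suppressWarnings(as.integer(sub("^[CH]([0-9]+).*$", "\\1",
                                    atoms$atom_name))), NA_integer_)
  atoms$h_parent <- NA_integer_
  for (lid in unique(atoms$lipid_id)) {
    rows <- which(atoms$lipid_id == lid)
    for (r in rows[atoms$role[rows] == "H"]) {
      cand <- rows[atoms$role[rows] == "C" &
                     atoms$carbon_index[rows] == atoms$carbon_index[r]]
      if (length(cand)) atoms$h_parent[r] <- cand[1]
    }
  }
  first <- !duplicated(atoms$lipid_id)
  lipids <- data.frame(lipid_id = atoms$lipid_id[first],
                       lipid_type = atoms$lipid_type[first],
                       leaflet = NA_character_,
                       headgroup_charge =
                         unname(LIPID_CHARGES[atoms$lipid_type[first]]),
                       stringsAsFactors = FALSE)
  ## leaflet from P z (or the first atom for P-less lipids)
  pz <- atoms$z[atoms$role == "P"]
  mid <- if (length(pz)) mean(pz) else mean(atoms$z)
  zref <- vapply(lipids$lipid_id, function(lid) {
    rows <- which(atoms$lipid_id == lid)
    p <- rows[atoms$role[rows] == "P"]
    if (length(p)) atoms$z[p[1]] else atoms$z[rows[1]]
  }, numeric(1))
  lipids$leaflet <- ifelse(zref > mid, "upper", "lower")
  atoms$leaflet <- lipids$leaflet[match(atoms$lipid_id, lipids$lipid_id)]
  ## assign per-type headgroup charge to the P bead so energies see it
  pr <- which(atoms$role == "P")
  atoms$charge[pr] <-
    lipids$headgroup_charge[match(atoms$lipid_id[pr], lipids$lipid_id)]
  membrane_model(atoms, lipids)
}

## Fixed-column ATOM record; 4-character residue names occupy columns
## 18-21 (the common MD extension), coordinates sit at the standard 31-54.
pdb_atom_line <- function(i, name, resname, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
          i %% 100000, substr(name, 1, 4), substr(resname, 1, 4),
          resno %% 10000, x, y, z)
}

#' Write a system or atom table to a PDB file
#'
#' @param x an atom table, [protein_model()], [membrane_model()] or
#'   [md_system()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pdb <- function(x, path) {
  atoms <- if (is.data.frame(x)) x
  else if (inherits(x, "md_system")) x$atoms
  else x$atoms
  lines <- pdb_atom_line(seq_len(nrow(atoms)), atoms$atom_name,
                         atoms$residue_name, atoms$residue_index,
                         atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an [md_trajectory()].
#' @param system the matching [md_system()] (atom metadata).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, system, path) {
  atoms <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_line(seq_len(nrow(atoms)), atoms$atom_name,
                             atoms$residue_name, atoms$residue_index,
                             xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' Frame times are not stored in PDB files and are supplied via `dt_ns`.
#'
#' @param path multi-model PDB file.
#' @param dt_ns frame spacing in ns.
#' @param box orthorhombic box or `NULL`.
#' @return an [md_trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt_ns = 1, box = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  md_trajectory(frames, times = dt_ns * seq_along(frames), box = box)
}

#' Write a system or atom table to a GRO file
#'
#' @param x an atom table, model or [md_system()].
#' @param path output file.
#' @param box orthorhombic box in Angstrom (taken from the system when
#'   available).
#' @param title header line.
#' @return the path, invisibly.
#' @export
write_gro <- function(x, path, box = NULL, title = "anxmem system") {
  atoms <- if (is.data.frame(x)) x
  else if (inherits(x, "md_system")) x$atoms
  else x$atoms
  if (is.null(box) && inherits(x, "md_system")) box <- x$box
  if (is.null(box)) box <- c(0, 0, 0)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   atoms$residue_index %% 100000,
                   substr(atoms$residue_name, 1, 5),
                   substr(atoms$atom_name, 1, 5),
                   seq_len(nrow(atoms)) %% 100000,
                   atoms$x / 10, atoms$y / 10, atoms$z / 10)
  writeLines(c(title, sprintf("%5d", nrow(atoms)), lines,
               sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                       box[3] / 10)), path)
  invisible(path)
}

#' Read a reference residue-site list from JSON
#'
#' Expected shape: `{"residues": ["GLU53", "ASP162", ...], "source": "..."}`.
#'
#' @param path JSON file.
#' @return a [site_list()].
#' @export
read_site_list <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$residues)) stop("site-list JSON lacks a 'residues' field")
  site_list(j$residues, source = j$source %||% path)
}

## Small deterministic content hash (FNV-1a over the serialized object),
## for run-provenance logging without external digest dependencies.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write analysis tables and summaries to an output directory
#'
#' Tables become CSV files (deterministic column order as supplied);
#' summaries become a single JSON file with `NA` rendered as `null`. A
#' `run_info.json` with the seed and a config hash makes runs
#' identifiable.
#'
#' @param tables named list of `data.frame`s.
#' @param out_dir output directory (created if needed).
#' @param summaries named list of summary objects for JSON.
#' @param seed,config optional provenance to record.
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(tables = list(), out_dir, summaries = list(),
                          seed = NULL, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(summaries)) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summaries, p, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  info <- list(seed = seed,
               config_hash = if (!is.null(config)) config_hash(config))
  p <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(info, p, auto_unbox = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
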