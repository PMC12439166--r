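# File formats: inhibition-table CSV, multi-model PDB and multi-frame XYZ
# trajectories (PDB reading and element masses via bio3d), flat key=value
# config files, and reproducibility manifests. Canonical units: molar for
# concentrations, nm for trajectory coordinates in memory, Angstrom in
# structure files (PDB convention).

.unit_factor <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, "μM" = 1e-6,
                  nM = 1e-9)

#' Read an inhibition screening table from CSV
#'
#' Required columns: `compound_id`, `enzyme_id`, `concentration`,
#' `replicate`, `percent_inhibition`. An optional `concentration_unit` column
#' (`M`, `mM`, `uM`/`µM`, `nM`) converts concentrations to molar;
#' otherwise concentrations must already be molar. Duplicate
#' (compound, enzyme, concentration, replicate) keys and non-numeric or
#' non-positive concentrations are rejected.
#'
#' @param path CSV file path (comma-separated, header mandatory).
#' @return a data.frame of class `fa_inhibition_table`.
#' @export
read_inhibition_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "enzyme_id", "concentration", "replicate",
                "percent_inhibition")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    fa_stop("fa_schema_error", "missing column(s): %s", paste(missing, collapse = ", "))
  conc <- suppressWarnings(as.numeric(tbl$concentration))
  if (anyNA(conc))
    fa_stop("fa_parse_error", "non-numeric concentration at row %d",
            which(is.na(conc))[1])
  if ("concentration_unit" %in% names(tbl)) {
    f <- .unit_factor[tbl$concentration_unit]
    if (anyNA(f))
      fa_stop("fa_parse_error", "unknown concentration unit at row %d",
              which(is.na(f))[1])
    conc <- conc * as.numeric(f)
    tbl$concentration_unit <- NULL
  }
  tbl$concentration <- conc
  if (any(conc <= 0))
    fa_stop("fa_validation_error", "concentrations must be > 0 (row %d)",
            which(conc <= 0)[1])
  key <- paste(tbl$compound_id, tbl$enzyme_id, tbl$concentration, tbl$replicate)
  if (anyDuplicated(key))
    fa_stop("fa_integrity_error", "duplicate (compound, enzyme, concentration, replicate) key at row %d",
            which(duplicated(key))[1])
  tbl <- tbl[required]
  class(tbl) <- c("fa_inhibition_table", "data.frame")
  tbl
}

#' @rdname read_inhibition_table
#' @param tbl table to write.
#' @param path output path.
#' @export
write_inhibition_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl)[, c("compound_id", "enzyme_id",
                                          "concentration", "replicate",
                                          "percent_inhibition")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- structure / trajectory files -----------------------------------------

.pdb_atom_line <- function(serial, name, resname, resno, xyz, element) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, substr(name, 1, 4), substr(resname, 1, 3),
          resno %% 10000L, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

.group_resname <- c(flavonoid_core = "FLV", glycoside = "GLC", protein = "PRO",
                    other = "UNK")
.resname_group <- stats::setNames(names(.group_resname), .group_resname)

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Coordinates are written in Angstrom (trajectories, stored in nm, are
#' converted); each frame becomes one MODEL. Molecule ids map to residue
#' numbers and groups to residue names (`FLV`, `GLC`, `PRO`, `UNK`), so the
#' paired reader can restore tags.
#'
#' @param x an [structure3d()] or [trajectory()].
#' @param path output path.
#' @export
write_structure_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "fa_structure")) {
    frames <- list(x$coords)
    tags <- x$atoms
  } else if (inherits(x, "fa_trajectory")) {
    frames <- lapply(seq_len(dim(x$coords)[1]), function(f) {
      m <- x$coords[f, , , drop = FALSE] * 10   # nm -> Angstrom
      dim(m) <- dim(x$coords)[2:3]
      m
    })
    tags <- x$tags
  } else fa_stop("fa_validation_error", "x must be a structure or trajectory")
  mol_no <- as.integer(factor(tags$molecule_id, levels = unique(tags$molecule_id)))
  resn <- .group_resname[tags$group]
  resn[is.na(resn)] <- "UNK"
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frames[[f]]
    for (a in seq_len(nrow(xyz)))
      writeLines(.pdb_atom_line(a, sprintf("C%d", ((a - 1L) %% 99L) + 1L),
                                resn[a], mol_no[a], xyz[a, ], "C"), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Load a trajectory from a multi-model PDB or multi-frame XYZ file
#'
#' PDB files are parsed with [bio3d::read.pdb] (`multi = TRUE`); coordinates
#' are converted from Angstrom to nm. Masses come from the element column via
#' [bio3d::atom2mass] unless `masses` is supplied. Molecule ids are taken
#' from residue numbers and groups from residue names (see
#' [write_structure_pdb()]); a `tags` data.frame overrides both. XYZ files
#' need a sidecar tags CSV (columns `molecule_id`, `group`, optionally
#' `mass`) or explicit `masses`.
#'
#' @param path trajectory file (`.pdb` or `.xyz`).
#' @param tags optional data.frame (`molecule_id`, `group`, optional `mass`)
#'   or path to a CSV with those columns.
#' @param masses optional per-atom masses (amu), overriding element lookup.
#' @param dt frame spacing in ns used when the file carries no times
#'   (default 1 ns).
#' @return an [trajectory()].
#' @export
load_trajectory <- function(path, tags = NULL, masses = NULL, dt = 1) {
  ext <- tolower(tools::file_ext(path))
  if (is.character(tags)) tags <- utils::read.csv(tags, stringsAsFactors = FALSE)
  if (ext == "pdb") .load_pdb_trajectory(path, tags, masses, dt)
  else if (ext == "xyz") .load_xyz_trajectory(path, tags, masses, dt)
  else fa_stop("fa_validation_error", "unsupported trajectory format '.%s'", ext)
}

.load_pdb_trajectory <- function(path, tags, masses, dt) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                      # frames x 3N, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  if (is.null(masses)) {
    elem <- new.env()
    utils::data("elements", package = "bio3d", envir = elem)
    masses <- elem$elements$mass[match(trimws(pdb$atom$elesy), elem$elements$symb)]
    if (anyNA(masses) || any(masses <= 0))
      fa_stop("fa_validation_error",
              "unknown element(s) in %s; supply masses explicitly", path)
  }
  if (is.null(tags)) {
    grp <- .resname_group[pdb$atom$resid]
    grp[is.na(grp)] <- "other"
    tags <- data.frame(molecule_id = sprintf("M%03d", pdb$atom$resno),
                       group = unname(grp))
  }
  trajectory(coords, masses, times = (seq_len(n_frames) - 1L) * dt,
             tags = tags[, c("molecule_id", "group")])
}

#' Write a trajectory as multi-frame XYZ plus a tags sidecar
#'
#' Coordinates in Angstrom; the comment line of each frame records the time.
#' A sidecar CSV `<path>.tags.csv` stores `molecule_id`, `group`, `mass`.
#'
#' @param traj an [trajectory()].
#' @param path output `.xyz` path.
#' @return invisibly, c(path, sidecar path).
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_atoms <- dim(traj$coords)[2]
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("t= %.8f ns", traj$times[f]), con)
    xyz <- traj$coords[f, , , drop = FALSE] * 10
    dim(xyz) <- c(n_atoms, 3L)
    writeLines(sprintf("C %12.6f %12.6f %12.6f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  sidecar <- paste0(path, ".tags.csv")
  utils::write.csv(data.frame(molecule_id = traj$tags$molecule_id,
                              group = traj$tags$group, mass = traj$masses),
                   sidecar, row.names = FALSE, quote = FALSE)
  invisible(c(path, sidecar))
}

.load_xyz_trajectory <- function(path, tags, masses, dt) {
  if (is.null(tags)) {
    sidecar <- paste0(path, ".tags.csv")
    if (file.exists(sidecar)) tags <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  }
  lines <- readLines(path)
  i <- 1L; frames <- list(); times <- numeric(0); n_atoms <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) fa_stop("fa_parse_error", "bad atom count at line %d", i)
    if (is.null(n_atoms)) n_atoms <- n
    else if (n != n_atoms)
      fa_stop("fa_validation_error",
              "frame %d has %d atoms, expected %d", length(frames) + 1L, n, n_atoms)
    tm <- regmatches(lines[i + 1L], regexec("t= *([-0-9.eE+]+)", lines[i + 1L]))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else
      (length(frames)) * dt)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3) / 10   # A -> nm
    i <- i + 2L + n
  }
  coords <- array(NA_real_, c(length(frames), n_atoms, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  if (is.null(masses)) masses <- tags$mass %||% rep(12, n_atoms)
  if (is.null(tags)) tags <- data.frame(molecule_id = "M001", group = "other")[rep(1, n_atoms), ]
  trajectory(coords, masses, times, tags[, c("molecule_id", "group")])
}

# ---- config + manifest -----------------------------------------------------

#' Read a flat key=value config file with sections
#'
#' Sections are `[name]` headers; entries are `key = value` lines; `#` starts
#' a comment. Values that parse as numbers become numeric; `true`/`false`
#' become logical; comma-separated values become vectors.
#'
#' @param path config file path.
#' @return named list of sections, each a named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  out <- list(); section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) fa_stop("fa_parse_error", "key=value before any [section]")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      parsed <- if (!anyNA(num)) num
        else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
        else parts
      out[[section]][[key]] <- parsed
    } else fa_stop("fa_parse_error", "unparseable config line: '%s'", ln)
  }
  out
}

#' Build a generator/run spec from a config section
#'
#' Section names map to constructors: `panel` -> [default_panel_spec()],
#' `collapse` -> [collapse_traj_spec()], `fiber` -> [fiber_spec()] (branch
#' points encoded as `branch_points = unit:length` pairs, e.g. `3:2, 5:1`),
#' `double_well` -> [double_well_spec()], `revo` -> [revo_params()].
#'
#' @param config a file path or the result of [read_config()].
#' @param section section name.
#' @return the corresponding spec object.
#' @export
spec_from_config <- function(config, section) {
  if (is.character(config)) config <- read_config(config)
  args <- config[[section]]
  if (is.null(args)) fa_stop("fa_validation_error", "config has no [%s] section", section)
  ctor <- switch(section,
                 panel = default_panel_spec, collapse = collapse_traj_spec,
                 fiber = fiber_spec, double_well = double_well_spec,
                 revo = revo_params,
                 fa_stop("fa_validation_error", "unknown spec section '%s'", section))
  if (section == "fiber" && !is.null(args$branch_points)) {
    bp <- strsplit(as.character(args$branch_points), ":", fixed = TRUE)
    args$branch_points <- lapply(bp, function(p) as.integer(p))
  }
  do.call(ctor, args)
}

#' Write a run manifest
#'
#' Records tool version, a digest of the configuration, digests of input
#' files, the seed and a timestamp, as JSON — enough to re-run an analysis
#' bit-identically.
#'
#' @param path output JSON path.
#' @param config configuration object (any serialisable R value) or NULL.
#' @param inputs character vector of input file paths to digest.
#' @param seed the run seed.
#' @return invisibly, the manifest list.
#' @export
run_manifest <- function(path, config = NULL, inputs = character(0), seed = NULL) {
  cfg_hash <- if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(config, tmp, version = 2)
    unname(tools::md5sum(tmp))
  } else NA_character_
  man <- list(tool = "flavassembly",
              version = as.character(utils::packageVersion("flavassembly")),
              created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
              seed = seed, config_md5 = cfg_hash,
              inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(man)
}
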