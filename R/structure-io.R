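#' Read a PDB structure
#'
#' Parses a (single-model) PDB file into a [new_structure_model()] container.
#' Residues are grouped by (chain, residue number, insertion code); waters
#' (residue names HOH/TIP3/WAT/SOL) are retained as ordinary residues.  Only
#' alternate-location indicator 'A' or blank is kept, so each atom appears as
#' a single conformer.  An orthorhombic box is taken from the CRYST1 record
#' when present.
#'
#' @param path Path to a PDB file (v3 ATOM/HETATM records).
#' @return A `structure_model`.
#' @seealso [read_trajectory()] for multi-model files.
#' @export
read_structure <- function(path) {
  pdb <- read_pdb_checked(path, multi = FALSE)
  pdb_to_model(pdb$bio3d, pdb$box)
}

#' Read a multi-model PDB trajectory
#'
#' Reads an ordered stack of conformations from a multi-model PDB file.  When
#' `topology_path` is given, atom metadata is taken from it and
#' `trajectory_path` supplies only coordinates; otherwise the trajectory file
#' provides both.  Frames are returned in file order; frame indices are
#' 0-based.
#'
#' @param topology_path Path to a PDB file defining the topology, or `NULL`.
#' @param trajectory_path Path to a multi-model PDB file.  If missing,
#'   `topology_path` is used for both.
#' @param frame_interval Time per frame in ns (default 1).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(topology_path, trajectory_path = NULL,
                            frame_interval = 1) {
  trajectory_path <- trajectory_path %||% topology_path
  parsed <- read_pdb_checked(trajectory_path, multi = TRUE)
  pdb <- parsed$bio3d
  topo <- if (!is.null(topology_path) && !identical(topology_path, trajectory_path)) {
    read_structure(topology_path)
  } else {
    pdb_to_model(pdb, parsed$box)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  keep <- pdb_keep(pdb)
  if (length(keep) < nrow(pdb$atom)) xyz <- xyz[, xyz_cols(keep), drop = FALSE]
  if (ncol(xyz) != 3L * n_atoms(topo)) {
    abort(sprintf(
      "trajectory frames have %d atoms but topology has %d",
      ncol(xyz) / 3, n_atoms(topo)
    ))
  }
  new_trajectory(topo, unclass(xyz), frame_interval = frame_interval)
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' @param x A `structure_model` or `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "trajectory")) {
    atoms <- x$topology$atoms
    xyz <- x$xyz
    box <- x$box
  } else {
    stopifnot(inherits(x, "structure_model"))
    atoms <- x$atoms
    xyz <- matrix(as.vector(t(cbind(atoms$x, atoms$y, atoms$z))), nrow = 1)
    box <- x$box
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(is_water(atoms), "HETATM", "ATOM"),
    resno = atoms$resno, resid = atoms$resid, eleno = atoms$eleno,
    elety = atoms$elety, chain = atoms$chain,
    elesy = atoms$element
  )
  if (!is.null(box)) {
    lines <- readLines(path)
    cryst <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
      box[1], box[2], box[3]
    )
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}

# -- internals ---------------------------------------------------------------

# Pre-scan a PDB file: validate ATOM/HETATM records (raising errors that name
# the offending line), check per-MODEL atom counts, and pull the CRYST1 box.
# Then delegate actual parsing to bio3d::read.pdb.
read_pdb_checked <- function(path, multi = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0) {
    abort(sprintf("no ATOM/HETATM records in %s", path))
  }
  for (i in atom_lines) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (nchar(ln) < 54 || any(is.na(coords))) {
      abort(sprintf("malformed ATOM/HETATM record at line %d of %s", i, path))
    }
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    ends <- c(model_starts[-1] - 1L, length(lines))
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(atom_lines >= model_starts[k] & atom_lines <= ends[k])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      abort(sprintf(
        "atom count mismatch at frame %d: %d atoms, expected %d",
        bad - 1L, counts[bad], counts[1]
      ))
    }
  }
  box <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr) > 0) {
    b <- suppressWarnings(as.numeric(c(
      substr(lines[cr[1]], 7, 15), substr(lines[cr[1]], 16, 24),
      substr(lines[cr[1]], 25, 33)
    )))
    if (all(is.finite(b)) && all(b > 1)) box <- b
  }
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  list(bio3d = pdb, box = box)
}

pdb_keep <- function(pdb) {
  which(is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A"))
}

pdb_to_model <- function(pdb, box = NULL) {
  a <- pdb$atom[pdb_keep(pdb), , drop = FALSE]
  atoms <- tibble(
    eleno = as.integer(a$eleno),
    elety = a$elety,
    resid = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z
  )
  new_structure_model(atoms, box = box)
}
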