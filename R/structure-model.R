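#' Structure and trajectory containers
#'
#' A `structure_model` holds one conformation of a molecular system as a
#' tibble of atoms (one row per atom, coordinates in Angstrom) plus an
#' optional orthorhombic box.  A `trajectory` holds an ordered stack of
#' conformations sharing one topology: the per-frame coordinates live in an
#' `n_frames x 3N` matrix (the column layout of bio3d, x1 y1 z1 x2 ...), and
#' `frame_interval` gives the time per frame in nanoseconds.  Frame indices
#' are 0-based everywhere in the user interface, so a 100-frame trajectory
#' spans frames 0..99.
#'
#' @param atoms A data frame with columns `eleno`, `elety` (atom name),
#'   `resid` (3-letter residue name), `chain`, `resno`, `element`, `x`, `y`,
#'   `z`.  Extra columns are kept.
#' @param box Optional numeric length-3 vector of box edge lengths (Angstrom).
#' @return `new_structure_model()` returns a `structure_model`;
#'   `new_trajectory()` returns a `trajectory`.
#' @examples
#' atoms <- tibble::tibble(
#'   eleno = 1:2, elety = c("N", "CA"), resid = "ALA", chain = "A",
#'   resno = 1L, element = c("N", "C"), x = c(0, 1.46), y = 0, z = 0
#' )
#' m <- new_structure_model(atoms)
#' n_atoms(m)
#' @export
new_structure_model <- function(atoms, box = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (is.null(atoms[["eleno"]])) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms[["element"]])) atoms$element <- substr(trimws(atoms$elety), 1, 1)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      abort("box must be three positive edge lengths in Angstrom")
    }
  }
  structure(list(atoms = atoms, box = box), class = "structure_model")
}

#' @rdname new_structure_model
#' @param topology A `structure_model` giving atom metadata (its own
#'   coordinates are replaced by frame 0 of `xyz`).
#' @param xyz Numeric matrix, `n_frames` rows by `3 * n_atoms` columns.
#' @param frame_interval Time per frame in ns (default 1, i.e. 1 frame/ns).
#' @export
new_trajectory <- function(topology, xyz, frame_interval = 1) {
  stopifnot(inherits(topology, "structure_model"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology)) {
    abort(sprintf(
      "xyz has %d columns but topology has %d atoms (need %d columns)",
      ncol(xyz), n_atoms(topology), 3L * n_atoms(topology)
    ))
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 || frame_interval <= 0) {
    abort("frame_interval must be a single positive number (ns per frame)")
  }
  topology$atoms$x <- xyz[1, seq(1, ncol(xyz), 3)]
  topology$atoms$y <- xyz[1, seq(2, ncol(xyz), 3)]
  topology$atoms$z <- xyz[1, seq(3, ncol(xyz), 3)]
  structure(
    list(topology = topology, xyz = xyz, frame_interval = frame_interval,
         box = topology$box),
    class = "trajectory"
  )
}

#' @rdname new_structure_model
#' @param x A `structure_model` or `trajectory`.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' @rdname new_structure_model
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  nrow(x$xyz)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d atoms, %d residues, chains: %s%s\n",
    n_atoms(x), nrow(dplyr::distinct(x$atoms, .data$chain, .data$resno)),
    paste(unique(x$atoms$chain), collapse = " "),
    if (is.null(x$box)) "" else sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3])
  ))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames x %d atoms, %.3g ns/frame\n",
    n_frames(x), n_atoms(x), x$frame_interval
  ))
  invisible(x)
}

#' Select atom indices
#'
#' Returns the row indices (1-based, into the topology atom table) of atoms
#' matching the given residue/atom filters.  All filters are optional and
#' combined with AND.
#'
#' @param x A `structure_model` or `trajectory`.
#' @param chain,resno,elety,resid Optional vectors to match against.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, elety = NULL, resid = NULL) {
  atoms <- if (inherits(x, "trajectory")) x$topology$atoms else x$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(elety)) keep <- keep & atoms$elety %in% elety
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  which(keep)
}

#' Coordinates of one frame
#'
#' @param traj A `trajectory`.
#' @param frame 0-based frame index.
#' @param atoms Optional integer atom indices to subset.
#' @return `n x 3` numeric matrix of coordinates (Angstrom).
#' @export
frame_coords <- function(traj, frame, atoms = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 0 || frame >= n_frames(traj)) {
    abort(sprintf("frame %d out of range [0, %d]", frame, n_frames(traj) - 1L))
  }
  v <- traj$xyz[frame + 1L, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(atoms)) m <- m[atoms, , drop = FALSE]
  m
}

#' @rdname frame_coords
#' @param model A `structure_model`.
#' @export
model_coords <- function(model, atoms = NULL) {
  stopifnot(inherits(model, "structure_model"))
  m <- cbind(model$atoms$x, model$atoms$y, model$atoms$z)
  if (!is.null(atoms)) m <- m[atoms, , drop = FALSE]
  m
}

#' Extract one frame of a trajectory as a structure model
#'
#' @inheritParams frame_coords
#' @return A `structure_model` carrying the frame's coordinates.
#' @export
get_frame <- function(traj, frame) {
  co <- frame_coords(traj, frame)
  top <- traj$topology
  top$atoms$x <- co[, 1]
  top$atoms$y <- co[, 2]
  top$atoms$z <- co[, 3]
  top
}

# xyz column indices for a set of atom indices
xyz_cols <- function(atoms) {
  as.vector(rbind(3L * atoms - 2L, 3L * atoms - 1L, 3L * atoms))
}

# Water residue names and the corresponding oxygen atom names
WATER_RESIDS <- c("HOH", "TIP3", "WAT", "SOL")
WATER_O_NAMES <- c("O", "OH2", "OW")

is_water <- function(atoms) atoms$resid %in% WATER_RESIDS
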