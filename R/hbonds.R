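#' Detect hydrogen bonds in one frame
#'
#' Geometric hydrogen-bond criterion: a donor heavy atom D carrying an
#' explicit hydrogen H forms a bond to an acceptor heavy atom A when the
#' D-A distance is at most `d_cut` and the donor-centred angle between the
#' D->H and D->A vectors is at most `angle_cut`.  In `"n_o"` mode (the
#' published criterion) donors are restricted to nitrogen and acceptors to
#' oxygen; `"generic"` mode allows N and O on both sides.  Pairs within the
#' same residue are not reported.  Hydrogens are identified by element and
#' covalent proximity (within 1.25 A of the donor heavy atom).
#'
#' @param x A `structure_model`, or a `trajectory` together with `frame`.
#' @param frame 0-based frame index (trajectories only).
#' @param d_cut Donor-acceptor heavy-atom distance cutoff, A (default 3.5).
#' @param angle_cut Donor-centred angle cutoff, degrees (default 20).
#' @param mode `"n_o"` (N donors, O acceptors; default) or `"generic"`
#'   (N and O on both sides).
#' @param donors,acceptors Optional integer atom indices restricting the
#'   search.
#' @param require_hydrogens When `TRUE`, a donor atom without an attached
#'   hydrogen is an error naming the atom.  Defaults to `TRUE` in `"n_o"`
#'   mode (every amide/amine nitrogen must carry its explicit hydrogen) and
#'   `FALSE` in `"generic"` mode (carbonyl oxygens legitimately carry none).
#' @return Tibble of events: donor/acceptor chain, resno, resid, atom names,
#'   hydrogen name, `dist` (A) and `angle` (degrees).
#' @export
detect_hbonds <- function(x, frame = NULL, d_cut = 3.5, angle_cut = 20,
                          mode = c("n_o", "generic"),
                          donors = NULL, acceptors = NULL,
                          require_hydrogens = NULL) {
  mode <- match.arg(mode)
  require_hydrogens <- require_hydrogens %||% (mode == "n_o")
  if (inherits(x, "trajectory")) {
    if (is.null(frame)) abort("supply a frame index for trajectories")
    atoms <- x$topology$atoms
    co <- frame_coords(x, frame)
  } else {
    stopifnot(inherits(x, "structure_model"))
    atoms <- x$atoms
    co <- model_coords(x)
  }
  donor_elements <- if (mode == "n_o") "N" else c("N", "O")
  acceptor_elements <- if (mode == "n_o") "O" else c("N", "O")
  don <- donors %||% which(atoms$element %in% donor_elements)
  acc <- acceptors %||% which(atoms$element %in% acceptor_elements)
  don <- don[atoms$element[don] %in% donor_elements]
  acc <- acc[atoms$element[acc] %in% acceptor_elements]
  hyd <- which(atoms$element == "H")
  if (length(don) == 0 || length(acc) == 0) {
    return(empty_hbond_table())
  }
  events <- list()
  for (d in don) {
    # hydrogens covalently attached to this donor
    hs <- if (length(hyd) == 0) {
      integer(0)
    } else {
      hyd[sqrt(colSums((t(co[hyd, , drop = FALSE]) - co[d, ])^2)) <= 1.25]
    }
    if (length(hs) == 0) {
      if (require_hydrogens) {
        abort(sprintf(
          "donor atom %s of %s %s %d has no attached hydrogen",
          atoms$elety[d], atoms$resid[d], atoms$chain[d], atoms$resno[d]
        ))
      }
      next
    }
    da <- sqrt(colSums((t(co[acc, , drop = FALSE]) - co[d, ])^2))
    close <- acc[da <= d_cut & da > 1e-6]
    close_d <- da[da <= d_cut & da > 1e-6]
    if (length(close) == 0) next
    for (j in seq_along(close)) {
      a <- close[j]
      if (atoms$chain[a] == atoms$chain[d] && atoms$resno[a] == atoms$resno[d]) next
      va <- co[a, ] - co[d, ]
      best <- NULL
      for (h in hs) {
        vh <- co[h, ] - co[d, ]
        ang <- angle_deg(vh, va)
        if (ang <= angle_cut && (is.null(best) || ang < best$angle)) {
          best <- list(h = h, angle = ang)
        }
      }
      if (!is.null(best)) {
        events[[length(events) + 1L]] <- tibble(
          donor_chain = atoms$chain[d], donor_resno = atoms$resno[d],
          donor_resid = atoms$resid[d], donor_atom = atoms$elety[d],
          hydrogen = atoms$elety[best$h],
          acceptor_chain = atoms$chain[a], acceptor_resno = atoms$resno[a],
          acceptor_resid = atoms$resid[a], acceptor_atom = atoms$elety[a],
          dist = close_d[j], angle = best$angle
        )
      }
    }
  }
  if (length(events) == 0) return(empty_hbond_table())
  dplyr::bind_rows(events)
}

empty_hbond_table <- function() {
  tibble(
    donor_chain = character(0), donor_resno = integer(0),
    donor_resid = character(0), donor_atom = character(0),
    hydrogen = character(0),
    acceptor_chain = character(0), acceptor_resno = integer(0),
    acceptor_resid = character(0), acceptor_atom = character(0),
    dist = numeric(0), angle = numeric(0)
  )
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Hydrogen-bond occupancy of a residue pair over a trajectory
#'
#' Fraction of frames in which the pair forms at least one qualifying
#' hydrogen bond (in either direction).  Donor atoms without an explicit
#' hydrogen simply cannot donate here (they are skipped, not an error), so
#' side chains with partially modelled hydrogens scan cleanly.
#'
#' @param traj A `trajectory`.
#' @param pair Character vector of two residue references `"chain/resno"`.
#' @inheritParams detect_hbonds
#' @return One-row tibble: `a`, `b`, `occupancy`, `n_frames`, plus the
#'   per-frame logical as the `present` list-column.
#' @export
hbond_occupancy <- function(traj, pair, d_cut = 3.5, angle_cut = 20,
                            mode = c("n_o", "generic")) {
  mode <- match.arg(mode)
  stopifnot(length(pair) == 2)
  atoms <- traj$topology$atoms
  r1 <- parse_residue_ref(pair[1])
  r2 <- parse_residue_ref(pair[2])
  i1 <- which(atoms$chain == r1$chain & atoms$resno == r1$resno)
  i2 <- which(atoms$chain == r2$chain & atoms$resno == r2$resno)
  if (length(i1) == 0 || length(i2) == 0) {
    abort("both pair residues must exist in the trajectory")
  }
  sub <- c(i1, i2)
  present <- vapply(seq_len(n_frames(traj)) - 1L, function(f) {
    ev <- detect_hbonds(traj, frame = f, d_cut = d_cut,
                        angle_cut = angle_cut, mode = mode,
                        donors = sub, acceptors = sub,
                        require_hydrogens = FALSE)
    if (nrow(ev) == 0) return(FALSE)
    cross <- (ev$donor_resno == r1$resno & ev$acceptor_resno == r2$resno) |
      (ev$donor_resno == r2$resno & ev$acceptor_resno == r1$resno)
    any(cross)
  }, logical(1))
  out <- tibble(a = pair[1], b = pair[2], occupancy = mean(present),
                n_frames = n_frames(traj))
  out$present <- list(present)
  out
}
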