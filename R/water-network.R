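#' Water-mediated bridge between two residues
#'
#' A frame is bridged when at least one water oxygen lies within `d_cut` of
#' a polar heavy atom (nitrogen or oxygen, side chain or backbone) of BOTH
#' partner residues.  This is the distance-only bridging criterion used for
#' water-network analysis; it is deliberately distinct from the angular
#' hydrogen-bond criterion of [detect_hbonds()].  Occupancy is the bridged
#' fraction of frames, and a bridge is flagged significant when occupancy
#' reaches `significance` (default 0.10).
#'
#' @param traj A `trajectory` containing explicit waters (residue names
#'   HOH/TIP3/WAT/SOL; oxygen named O/OH2/OW).
#' @param pair Character vector of two residue references `"chain/resno"`.
#' @param d_cut Heavy-atom to water-oxygen cutoff, A (default 3.5).
#' @param significance Occupancy threshold for the `significant` flag
#'   (default 0.10).
#' @return A `bridge_series` list: `pair`, per-frame tibble (`frame`,
#'   `bridged`, `n_bridging_waters`, `bridging_waters` list-column of water
#'   residue numbers), `occupancy`, `significant`, `status`.
#' @export
water_bridges <- function(traj, pair, d_cut = 3.5, significance = 0.10) {
  stopifnot(length(pair) == 2)
  atoms <- traj$topology$atoms
  r1 <- parse_residue_ref(pair[1])
  r2 <- parse_residue_ref(pair[2])
  p1 <- polar_heavy_atoms(atoms, r1)
  p2 <- polar_heavy_atoms(atoms, r2)
  if (length(p1) == 0 || length(p2) == 0) {
    abort("both partners need at least one polar heavy atom (N or O)")
  }
  wat_o <- which(is_water(atoms) & atoms$elety %in% WATER_O_NAMES)
  nf <- n_frames(traj)
  frames <- seq_len(nf) - 1L
  if (length(wat_o) == 0) {
    per_frame <- tibble(frame = frames, bridged = FALSE,
                        n_bridging_waters = 0L,
                        bridging_waters = rep(list(integer(0)), nf))
    return(structure(
      list(pair = pair, per_frame = per_frame, occupancy = 0,
           significant = FALSE, significance = significance,
           status = "no waters"),
      class = "bridge_series"
    ))
  }
  near1 <- matrix(FALSE, nf, length(wat_o))
  near2 <- matrix(FALSE, nf, length(wat_o))
  for (k in seq_along(wat_o)) {
    near1[, k] <- atom_set_min_dist(traj$xyz, wat_o[k], p1) <= d_cut
    near2[, k] <- atom_set_min_dist(traj$xyz, wat_o[k], p2) <= d_cut
  }
  both <- near1 & near2
  bridged <- rowSums(both) > 0
  per_frame <- tibble(
    frame = frames,
    bridged = bridged,
    n_bridging_waters = rowSums(both),
    bridging_waters = lapply(seq_len(nf), function(f) {
      atoms$resno[wat_o[both[f, ]]]
    })
  )
  occ <- mean(bridged)
  structure(
    list(pair = pair, per_frame = per_frame, occupancy = occ,
         significant = occ >= significance, significance = significance,
         status = "ok"),
    class = "bridge_series"
  )
}

#' @export
print.bridge_series <- function(x, ...) {
  cat(sprintf(
    "<bridge_series> %s - %s: occupancy %.3f (%s at %.0f%%)%s\n",
    x$pair[1], x$pair[2], x$occupancy,
    if (x$significant) "significant" else "not significant",
    100 * x$significance,
    if (x$status != "ok") paste0(" [", x$status, "]") else ""
  ))
  invisible(x)
}

polar_heavy_atoms <- function(atoms, ref) {
  which(atoms$chain == ref$chain & atoms$resno == ref$resno &
          atoms$element %in% c("N", "O"))
}

#' Classify a residue pair's interaction mode per frame
#'
#' Each frame is classified as `direct` when any inter-partner heavy-atom
#' distance is at most `d_cut`, otherwise `water_mediated` when the pair is
#' water-bridged (see [water_bridges()]), otherwise `none`.  The three modes
#' are mutually exclusive and exhaustive, so the reported fractions sum
#' to 1.
#'
#' @inheritParams water_bridges
#' @return An `interaction_modes` list: `pair`, per-frame tibble (`frame`,
#'   `mode`), and `fractions` (named numeric: direct, water_mediated, none).
#' @export
classify_interaction <- function(traj, pair, d_cut = 3.5) {
  atoms <- traj$topology$atoms
  r1 <- parse_residue_ref(pair[1])
  r2 <- parse_residue_ref(pair[2])
  h1 <- which(atoms$chain == r1$chain & atoms$resno == r1$resno &
                atoms$element != "H")
  h2 <- which(atoms$chain == r2$chain & atoms$resno == r2$resno &
                atoms$element != "H")
  if (length(h1) == 0 || length(h2) == 0) {
    abort("both pair residues must exist with heavy atoms")
  }
  nf <- n_frames(traj)
  dmin <- rep(Inf, nf)
  for (i in h1) dmin <- pmin(dmin, atom_set_min_dist(traj$xyz, i, h2))
  direct <- dmin <= d_cut
  bridged <- water_bridges(traj, pair, d_cut = d_cut)$per_frame$bridged
  mode <- ifelse(direct, "direct", ifelse(bridged, "water_mediated", "none"))
  fractions <- c(
    direct = mean(mode == "direct"),
    water_mediated = mean(mode == "water_mediated"),
    none = mean(mode == "none")
  )
  structure(
    list(pair = pair,
         per_frame = tibble(frame = seq_len(nf) - 1L, mode = mode),
         fractions = fractions),
    class = "interaction_modes"
  )
}

#' @export
print.interaction_modes <- function(x, ...) {
  cat(sprintf(
    "<interaction_modes> %s - %s: direct %.1f%%, water-mediated %.1f%%, none %.1f%%\n",
    x$pair[1], x$pair[2], 100 * x$fractions["direct"],
    100 * x$fractions["water_mediated"], 100 * x$fractions["none"]
  ))
  invisible(x)
}

#' Centred moving average with shrinking edges
#'
#' Smooths a per-frame series with a centred moving average of `window`
#' frames; near the edges the window shrinks symmetrically so the output has
#' the same length as the input and no frame is extrapolated.
#'
#' @param series Numeric (or logical, coerced to 0/1) vector.
#' @param window Window size in frames (default 50).
#' @return Numeric vector, same length as `series`.
#' @export
smooth_series <- function(series, window = 50) {
  x <- as.numeric(series)
  n <- length(x)
  if (window < 1) abort("window must be >= 1")
  if (window > n) abort(sprintf("window (%d) exceeds series length (%d)", window, n))
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- cumsum(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    out[i] <- (cs[hi] - if (lo > 1) cs[lo - 1L] else 0) / (hi - lo + 1L)
  }
  out
}
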