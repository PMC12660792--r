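#' Salt bridges over a trajectory, with lifetimes
#'
#' A salt bridge between a basic and an acidic side chain is scored present
#' in a frame when the minimum distance between the basic side-chain
#' nitrogens (ARG NE/NH1/NH2, LYS NZ) and the acidic side-chain oxygens
#' (ASP OD1/OD2, GLU OE1/OE2) is at most `d_cut`.  Histidine is excluded
#' from the basic side by default because its protonation state is not
#' encoded in a PDB file; set `include_his = TRUE` to count HIS ND1/NE2.
#' Durations are the maximal runs of consecutive present frames.
#'
#' @param traj A `trajectory`.
#' @param d_cut N-O distance cutoff in Angstrom (default 3.5).
#' @param include_his Count histidine as basic (default `FALSE`).
#' @param pairs Optional tibble (`basic`, `acidic` as `"chain/resno"`) to
#'   restrict scoring; by default every basic-acidic residue pair with at
#'   least one present frame is reported.
#' @return A `saltbridge_series` tibble: one row per pair with
#'   `basic_chain`, `basic_resno`, `basic_resid`, `acidic_chain`,
#'   `acidic_resno`, `acidic_resid`, `occupancy`, `n_events`,
#'   `mean_duration`, `max_duration`, and list-columns `present`
#'   (per-frame logical) and `durations` (run lengths in frames).
#' @export
salt_bridges <- function(traj, d_cut = 3.5, include_his = FALSE, pairs = NULL) {
  atoms <- traj$topology$atoms
  basic_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  if (include_his) basic_atoms$HIS <- c("ND1", "NE2")
  acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  basic_idx <- which(
    mapply(function(r, a) !is.null(basic_atoms[[r]]) && a %in% basic_atoms[[r]],
           atoms$resid, atoms$elety)
  )
  acidic_idx <- which(
    mapply(function(r, a) !is.null(acidic_atoms[[r]]) && a %in% acidic_atoms[[r]],
           atoms$resid, atoms$elety)
  )
  basic_res <- dplyr::distinct(atoms[basic_idx, c("chain", "resno", "resid")])
  acidic_res <- dplyr::distinct(atoms[acidic_idx, c("chain", "resno", "resid")])
  if (!is.null(pairs)) {
    keep_b <- vapply(pairs$basic, function(p) {
      r <- parse_residue_ref(p); paste(r$chain, r$resno)
    }, character(1))
    keep_a <- vapply(pairs$acidic, function(p) {
      r <- parse_residue_ref(p); paste(r$chain, r$resno)
    }, character(1))
  }
  rows <- list()
  for (bi in seq_len(nrow(basic_res))) {
    for (ai in seq_len(nrow(acidic_res))) {
      if (!is.null(pairs)) {
        tag_b <- paste(basic_res$chain[bi], basic_res$resno[bi])
        tag_a <- paste(acidic_res$chain[ai], acidic_res$resno[ai])
        if (!any(keep_b == tag_b & keep_a == tag_a)) next
      }
      bset <- basic_idx[atoms$chain[basic_idx] == basic_res$chain[bi] &
                          atoms$resno[basic_idx] == basic_res$resno[bi]]
      aset <- acidic_idx[atoms$chain[acidic_idx] == acidic_res$chain[ai] &
                           atoms$resno[acidic_idx] == acidic_res$resno[ai]]
      dmin <- rep(Inf, n_frames(traj))
      for (i in bset) for (j in aset) {
        dmin <- pmin(dmin, atom_pair_dist(traj$xyz, i, j))
      }
      present <- dmin <= d_cut
      if (!any(present) && is.null(pairs)) next
      durations <- run_durations(present)
      rows[[length(rows) + 1L]] <- tibble(
        basic_chain = basic_res$chain[bi], basic_resno = basic_res$resno[bi],
        basic_resid = basic_res$resid[bi],
        acidic_chain = acidic_res$chain[ai], acidic_resno = acidic_res$resno[ai],
        acidic_resid = acidic_res$resid[ai],
        occupancy = mean(present),
        n_events = length(durations),
        mean_duration = if (length(durations)) mean(durations) else 0,
        max_duration = if (length(durations)) max(durations) else 0,
        present = list(present),
        durations = list(durations)
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble()
  class(out) <- c("saltbridge_series", class(out))
  out
}

#' Run lengths of TRUE stretches in a boolean series
#'
#' @param present Logical vector.
#' @return Integer vector of maximal consecutive-`TRUE` run lengths, in
#'   order of occurrence (empty when nothing is present).
#' @export
run_durations <- function(present) {
  r <- rle(as.logical(present))
  r$lengths[r$values]
}
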