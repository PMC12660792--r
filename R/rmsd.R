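#' Backbone RMSD against a reference frame
#'
#' Per-frame root-mean-square deviation of backbone atoms (N, CA, C, O) of a
#' selection against a reference frame.  By default each frame is first
#' superposed onto the reference by the optimal least-squares rotation
#' (Kabsch), so the RMSD reflects internal deformation rather than rigid
#' drift; `fit = FALSE` gives the raw positional RMSD.
#'
#' @param traj A `trajectory`.
#' @param selection Integer atom indices to restrict to (before the backbone
#'   filter), or `NULL` for all atoms.
#' @param reference_frame 0-based frame used as reference (default 0).
#' @param fit Superpose before measuring (default `TRUE`).
#' @param backbone_only Keep only N/CA/C/O atoms of the selection (default
#'   `TRUE`).
#' @return Tibble with `frame` (0-based), `time` (ns), `rmsd` (A).
#' @export
backbone_rmsd <- function(traj, selection = NULL, reference_frame = 0,
                          fit = TRUE, backbone_only = TRUE) {
  atoms <- traj$topology$atoms
  sel <- selection %||% seq_len(nrow(atoms))
  if (backbone_only) {
    sel <- sel[atoms$elety[sel] %in% c("N", "CA", "C", "O")]
  }
  if (length(sel) < 3) abort("selection has fewer than 3 atoms")
  cols <- xyz_cols(sel)
  ref <- traj$xyz[reference_frame + 1L, cols]
  vals <- bio3d::rmsd(ref, traj$xyz[, cols, drop = FALSE], fit = fit)
  tibble(
    frame = seq_len(n_frames(traj)) - 1L,
    time = (seq_len(n_frames(traj)) - 1L) * traj$frame_interval,
    rmsd = as.numeric(vals)
  )
}
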