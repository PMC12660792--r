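#' Radial distribution function
#'
#' Frame-averaged radial distribution function g(r) between a reference and
#' a target atom set under the minimum-image convention for an orthorhombic
#' periodic box:
#' `g(r_k) = <count in shell [r_k - dr/2, r_k + dr/2)> / (n_ref * 4 pi r_k^2 dr * rho)`,
#' with the target bulk density `rho = n_target / V` taken from the
#' per-frame box volume (or from `bulk_density` when no box is present).
#' Self-pairs (identical atom indices) are excluded.  For hydration
#' analysis the reference set is typically a residue's polar heavy atoms
#' and the target set the water oxygens; a structured first hydration shell
#' shows as a sharp peak near 2.8 A.
#'
#' @param traj A `trajectory`.
#' @param ref_atoms,target_atoms Integer atom indices.
#' @param r_max Maximum radius, A (default 8).
#' @param dr Bin width, A (default 0.05).
#' @param bulk_density Target number density in 1/A^3, required when the
#'   trajectory has no box.
#' @return An `rdf_curve` tibble: `r` (bin centres, A), `g`, `count`; with
#'   attributes `n_ref`, `n_target`, `bulk_density`.
#' @export
rdf <- function(traj, ref_atoms, target_atoms, r_max = 8, dr = 0.05,
                bulk_density = NULL) {
  if (length(ref_atoms) == 0) abort("ref_atoms must be non-empty")
  box <- traj$box
  if (is.null(box) && is.null(bulk_density)) {
    abort("trajectory has no box; supply bulk_density explicitly")
  }
  n_bins <- as.integer(ceiling(r_max / dr))
  edges <- seq(0, n_bins * dr, by = dr)
  centres <- edges[-1] - dr / 2
  counts <- numeric(n_bins)
  if (length(target_atoms) == 0) {
    out <- tibble(r = centres, g = 0, count = 0)
    attr(out, "n_ref") <- length(ref_atoms)
    attr(out, "n_target") <- 0L
    attr(out, "bulk_density") <- bulk_density %||% 0
    class(out) <- c("rdf_curve", class(out))
    return(out)
  }
  nf <- n_frames(traj)
  for (f in seq_len(nf) - 1L) {
    co <- frame_coords(traj, f)
    counts <- counts + shell_counts(
      co[ref_atoms, , drop = FALSE], co[target_atoms, , drop = FALSE],
      ref_atoms, target_atoms, box, r_max, dr, n_bins
    )
  }
  counts <- counts / nf
  rho <- bulk_density %||% (length(target_atoms) / prod(box))
  shell_vol <- 4 * pi * centres^2 * dr
  g <- counts / (length(ref_atoms) * shell_vol * rho)
  out <- tibble(r = centres, g = g, count = counts)
  attr(out, "n_ref") <- length(ref_atoms)
  attr(out, "n_target") <- length(target_atoms)
  attr(out, "bulk_density") <- rho
  class(out) <- c("rdf_curve", class(out))
  out
}

# Histogram of minimum-image pair distances, chunked over reference atoms to
# bound memory.  Self-pairs (same topology index) are skipped.
shell_counts <- function(ref_co, tgt_co, ref_idx, tgt_idx, box, r_max, dr, n_bins) {
  counts <- numeric(n_bins)
  chunk <- max(1L, floor(2e6 / nrow(tgt_co)))
  n_ref <- nrow(ref_co)
  for (start in seq(1L, n_ref, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_ref)
    dx <- outer(ref_co[rows, 1], tgt_co[, 1], "-")
    dy <- outer(ref_co[rows, 2], tgt_co[, 2], "-")
    dz <- outer(ref_co[rows, 3], tgt_co[, 3], "-")
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    d <- sqrt(dx^2 + dy^2 + dz^2)
    same <- outer(ref_idx[rows], tgt_idx, "==")
    d[same] <- Inf
    d <- d[d < r_max]
    if (length(d) > 0) {
      bins <- pmin(n_bins, floor(d / dr) + 1L)
      tab <- tabulate(bins, nbins = n_bins)
      counts <- counts + tab
    }
  }
  counts
}
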