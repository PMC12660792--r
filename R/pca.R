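#' Sub-domain principal component analysis of a trajectory
#'
#' Characterises the essential dynamics of a residue range (by default the
#' receptor N-terminal residues 1-17) by PCA of its atomic coordinates:
#' frames are optionally superposed on a core Calpha selection to remove
#' rigid-body tumbling, the selected atoms' coordinates are flattened to a
#' frames x 3N matrix and column-centred, and the covariance matrix is
#' eigendecomposed.  Explained-variance ratios are the eigenvalues divided
#' by their sum; projections are the centred coordinates on the leading
#' components.  Component signs are fixed so each component's
#' largest-magnitude loading is positive, making results reproducible up to
#' machine precision.
#'
#' @param traj A `trajectory` with at least 2 frames.
#' @param residue_range `c(first, last)` residue numbers (default
#'   `c(1, 17)`).
#' @param chain Chain id of the sub-domain (default `"A"`).
#' @param atom_mode `"backbone"` (N/CA/C/O; default) or `"heavy"` (all
#'   non-hydrogen atoms).
#' @param superpose Superpose frames before PCA (default `TRUE`).
#' @param core Integer atom indices for the superposition core; default all
#'   Calpha atoms outside the residue range.
#' @param frames Optional 0-based frame window `c(first, last)` restricting
#'   the analysis (e.g. the equilibrated portion of a run).
#' @param n_components Number of projection columns to return (default 2).
#' @return A `pca_result`: list with `eigenvalues`, `variance_ratio`,
#'   `components` (3N x k matrix), `projection` (tibble: `frame`, `PC1`,
#'   `PC2`, ...), `atom_indices`, `center`.
#' @export
subdomain_pca <- function(traj, residue_range = c(1, 17), chain = "A",
                          atom_mode = c("backbone", "heavy"),
                          superpose = TRUE, core = NULL, frames = NULL,
                          n_components = 2) {
  atom_mode <- match.arg(atom_mode)
  atoms <- traj$topology$atoms
  xyz <- traj$xyz
  frame_ids <- seq_len(n_frames(traj)) - 1L
  if (!is.null(frames)) {
    keep <- frame_ids >= frames[1] & frame_ids <= frames[2]
    xyz <- xyz[keep, , drop = FALSE]
    frame_ids <- frame_ids[keep]
  }
  if (nrow(xyz) < 2) abort("PCA needs at least 2 frames")
  in_range <- atoms$chain == chain & atoms$resno >= residue_range[1] &
    atoms$resno <= residue_range[2]
  sel <- if (atom_mode == "backbone") {
    which(in_range & atoms$elety %in% c("N", "CA", "C", "O"))
  } else {
    which(in_range & atoms$element != "H")
  }
  if (length(sel) == 0) {
    abort(sprintf("no atoms for residues %d-%d on chain %s",
                  residue_range[1], residue_range[2], chain))
  }
  if (superpose) {
    core <- core %||% which(atoms$elety == "CA" & !in_range)
    if (length(core) >= 3) {
      xyz <- bio3d::fit.xyz(
        xyz[1, ], xyz,
        fixed.inds = xyz_cols(core), mobile.inds = xyz_cols(core)
      )
      xyz <- matrix(as.numeric(xyz), nrow = length(frame_ids))
    }
  }
  mat <- xyz[, xyz_cols(sel), drop = FALSE]
  ctr <- colMeans(mat)
  matc <- sweep(mat, 2, ctr)
  covm <- cov(matc)
  e <- eigen(covm, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  ratio <- ev / sum(ev)
  comps <- e$vectors
  for (k in seq_len(ncol(comps))) {
    j <- which.max(abs(comps[, k]))
    if (comps[j, k] < 0) comps[, k] <- -comps[, k]
  }
  k <- min(n_components, ncol(comps))
  proj <- matc %*% comps[, seq_len(k), drop = FALSE]
  proj_tbl <- as_tibble(as.data.frame(proj))
  names(proj_tbl) <- paste0("PC", seq_len(k))
  proj_tbl <- dplyr::bind_cols(tibble(frame = frame_ids), proj_tbl)
  structure(
    list(eigenvalues = ev, variance_ratio = ratio, components = comps,
         projection = proj_tbl, atom_indices = sel, center = ctr),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d frames x %d coordinates; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$projection), length(x$center),
    100 * x$variance_ratio[1], 100 * x$variance_ratio[2]
  ))
  invisible(x)
}

#' Kernel density estimate of a PC1-PC2 projection
#'
#' Gaussian KDE with Scott's-rule bandwidths over a regular grid spanning
#' the projection plus a margin of three bandwidths, so the grid captures
#' essentially all of the probability mass (the numerical integral over the
#' grid is close to 1).  High-density regions of this map are the
#' preferentially populated conformational sub-states.
#'
#' @param projection The projection tibble of a [subdomain_pca()] result (or
#'   the result itself); needs columns `PC1` and `PC2`.
#' @param grid_n Grid points per axis (default 100).
#' @param margin Margin around the data range, in bandwidths (default 3).
#' @return A `kde_surface`: list with `x`, `y` (grid axes), `z` (density
#'   matrix), `bandwidth`, and `grid_integral`.
#' @export
kde_density <- function(projection, grid_n = 100, margin = 3) {
  if (inherits(projection, "pca_result")) projection <- projection$projection
  p1 <- projection$PC1
  p2 <- projection$PC2
  n <- length(p1)
  if (n < 2) abort("KDE needs at least 2 points")
  s1 <- sd(p1)
  s2 <- sd(p2)
  if (s1 < 1e-12 || s2 < 1e-12) {
    abort("projection is degenerate (zero variance); jitter the points or check the input")
  }
  # Scott's rule for 2-D data: bandwidth sigma_i * n^(-1/6).
  # MASS::kde2d uses h/4 as the kernel standard deviation.
  bw <- c(s1, s2) * n^(-1 / 6)
  lims <- c(min(p1) - margin * bw[1], max(p1) + margin * bw[1],
            min(p2) - margin * bw[2], max(p2) + margin * bw[2])
  k <- MASS::kde2d(p1, p2, h = 4 * bw, n = grid_n, lims = lims)
  dx <- diff(k$x[1:2])
  dy <- diff(k$y[1:2])
  integral <- sum(k$z) * dx * dy
  structure(
    list(x = k$x, y = k$y, z = k$z, bandwidth = bw,
         grid_integral = integral),
    class = "kde_surface"
  )
}

#' @export
print.kde_surface <- function(x, ...) {
  cat(sprintf(
    "<kde_surface> %d x %d grid; integral %.3f; peak density %.3g\n",
    length(x$x), length(x$y), x$grid_integral, max(x$z)
  ))
  invisible(x)
}

#' Local maxima of a KDE surface
#'
#' Interior grid points whose density exceeds all 8 neighbours and a
#' fraction of the global peak; used to count conformational sub-states.
#'
#' @param surface A `kde_surface`.
#' @param min_fraction Minimum density relative to the global peak
#'   (default 0.05).
#' @return Tibble `x`, `y`, `density`, ordered by decreasing density.
#' @export
kde_modes <- function(surface, min_fraction = 0.05) {
  z <- surface$z
  nx <- nrow(z)
  ny <- ncol(z)
  peaks <- list()
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      v <- z[i, j]
      if (v < min_fraction * max(z)) next
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb) && sum(nb == v) == 1) {
        peaks[[length(peaks) + 1L]] <- tibble(
          x = surface$x[i], y = surface$y[j], density = v
        )
      }
    }
  }
  if (length(peaks) == 0) return(tibble(x = numeric(0), y = numeric(0), density = numeric(0)))
  dplyr::arrange(dplyr::bind_rows(peaks), dplyr::desc(.data$density))
}
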