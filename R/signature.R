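#' Segment definitions for the activation-signature panel
#'
#' Residue spans used by [signature_panel()]: the TM1-TM4 core (the
#' superposition reference, which moves least on activation), the TM6 span,
#' the intracellular-loop spans, and the micro-switch motif residues to
#' track individually (by BW code; defaults: the 3.50 ionic-lock arginine,
#' the 6.48 toggle tryptophan, and the 7.49/7.53 residues of the
#' DPxxY motif).  The defaults are the helix spans of the synthetic bundle
#' generator in GnRH1 receptor author numbering; supply your own spans for
#' other models.
#'
#' @param chain Receptor chain id.
#' @param core List of `c(first, last)` residue spans for the superposition
#'   core.
#' @param tm6 TM6 residue span.
#' @param icl Named list of loop spans.
#' @param motif Character vector of BW codes.
#' @param membrane_normal Unit vector normal to the membrane plane
#'   (default z).
#' @return A list of class `panel_segments`.
#' @export
panel_segments <- function(chain = "A",
                           core = list(c(32, 63), c(75, 102), c(113, 145),
                                       c(150, 178)),
                           tm6 = c(255, 290),
                           icl = list(ICL2 = c(143, 152), ICL3 = c(238, 257)),
                           motif = c("3.50", "6.48", "7.49", "7.53"),
                           membrane_normal = c(0, 0, 1)) {
  structure(
    list(chain = chain, core = core, tm6 = tm6, icl = icl, motif = motif,
         membrane_normal = normalize(membrane_normal)),
    class = "panel_segments"
  )
}

#' Activation-signature panel between two conformations
#'
#' Quantifies the hallmark geometric changes of class A GPCR activation
#' between an inactive and an active conformation sharing one topology.
#' After least-squares superposition of the active model onto the inactive
#' one over the TM1-TM4 core Calpha atoms, the panel reports: the total
#' rigid-body rotation angle of the TM6 segment (`tm6_rotation`, from the
#' optimal Kabsch rotation between the centred TM6 Calpha sets), the tilt
#' between the TM6 principal axes (`tm6_axis_tilt`), the displacement of the
#' cytoplasmic third of TM6 decomposed perpendicular (`tm6_lateral`) and
#' parallel (`tm6_vertical`) to the membrane normal, per-residue Calpha
#' displacements of the configured motif residues, and the Calpha-centroid
#' displacement of each intracellular loop.
#'
#' @param inactive,active `structure_model`s with identical atom ordering.
#' @param bwmap BW map for resolving motif codes.
#' @param segments A [panel_segments()] definition.
#' @return A `signature_panel` list: `tm6_rotation`, `tm6_axis_tilt`
#'   (degrees), `tm6_lateral`, `tm6_vertical` (A), `residue_displacements`
#'   and `icl_displacements` (tibbles).
#' @export
signature_panel <- function(inactive, active, bwmap = gnrh1r_bw_map(),
                            segments = panel_segments()) {
  stopifnot(inherits(inactive, "structure_model"),
            inherits(active, "structure_model"))
  if (n_atoms(inactive) != n_atoms(active)) {
    abort("inactive and active models must share one topology")
  }
  atoms <- inactive$atoms
  span_ca <- function(span) {
    which(atoms$chain == segments$chain & atoms$elety == "CA" &
            atoms$resno >= span[1] & atoms$resno <= span[2])
  }
  core_idx <- unlist(lapply(segments$core, span_ca))
  if (length(core_idx) < 3) abort("superposition core has fewer than 3 CA atoms")
  fixed <- as.vector(t(model_coords(inactive)))
  mobile <- as.vector(t(model_coords(active)))
  fitted <- bio3d::fit.xyz(
    fixed, mobile,
    fixed.inds = xyz_cols(core_idx), mobile.inds = xyz_cols(core_idx)
  )
  co_in <- matrix(fixed, ncol = 3, byrow = TRUE)
  co_ac <- matrix(as.numeric(fitted), ncol = 3, byrow = TRUE)

  tm6_idx <- span_ca(segments$tm6)
  if (length(tm6_idx) < 4) abort("TM6 segment has fewer than 4 CA atoms; axis undefined")
  a_in <- co_in[tm6_idx, , drop = FALSE]
  a_ac <- co_ac[tm6_idx, , drop = FALSE]

  rot <- kabsch_rotation(a_in, a_ac)
  tm6_rotation <- rotation_angle_deg(rot)
  tm6_axis_tilt <- axis_angle_deg(principal_axis(a_in), principal_axis(a_ac))

  nrm <- segments$membrane_normal
  proj <- as.vector(a_in %*% nrm)
  third <- tm6_idx[proj <= stats::quantile(proj, 1 / 3)]
  if (length(third) < 1) third <- tm6_idx[which.min(proj)]
  disp <- colMeans(co_ac[third, , drop = FALSE]) -
    colMeans(co_in[third, , drop = FALSE])
  tm6_vertical <- abs(sum(disp * nrm))
  tm6_lateral <- sqrt(max(0, sum(disp^2) - sum(disp * nrm)^2))

  res_disp <- dplyr::bind_rows(lapply(segments$motif, function(code) {
    ref <- resolve_bw(bwmap, code)
    i <- which(atoms$chain == ref$chain & atoms$resno == ref$resno &
                 atoms$elety == "CA")
    if (length(i) != 1) {
      return(tibble(bw = code, resno = ref$resno, displacement = NA_real_))
    }
    tibble(bw = code, resno = ref$resno,
           displacement = sqrt(sum((co_ac[i, ] - co_in[i, ])^2)))
  }))

  icl_disp <- dplyr::bind_rows(lapply(names(segments$icl), function(nm) {
    idx <- span_ca(segments$icl[[nm]])
    if (length(idx) == 0) {
      return(tibble(loop = nm, displacement = NA_real_))
    }
    d <- colMeans(co_ac[idx, , drop = FALSE]) - colMeans(co_in[idx, , drop = FALSE])
    tibble(loop = nm, displacement = sqrt(sum(d^2)))
  }))

  structure(
    list(tm6_rotation = tm6_rotation, tm6_axis_tilt = tm6_axis_tilt,
         tm6_lateral = tm6_lateral, tm6_vertical = tm6_vertical,
         residue_displacements = res_disp, icl_displacements = icl_disp,
         segments = segments),
    class = "signature_panel"
  )
}

#' @export
print.signature_panel <- function(x, ...) {
  cat(sprintf(
    "<signature_panel> TM6 rotation %.1f deg (axis tilt %.1f deg), lateral %.2f A, vertical %.2f A\n",
    x$tm6_rotation, x$tm6_axis_tilt, x$tm6_lateral, x$tm6_vertical
  ))
  invisible(x)
}

# Optimal rotation matrix mapping centred `a` onto centred `b` (Kabsch)
kabsch_rotation <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(t(ac) %*% bc)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

rotation_angle_deg <- function(rot) {
  tr <- sum(diag(rot))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# Principal axis of a point set: leading eigenvector of the coordinate
# covariance (the helix axis for an elongated segment)
principal_axis <- function(co) {
  e <- eigen(cov(co), symmetric = TRUE)
  normalize(e$vectors[, 1])
}

axis_angle_deg <- function(u, v) {
  # axes are directionless: take the acute angle
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}
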