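#' Tidiers for gnrhkit result objects
#'
#' Broom-style methods turning result objects into tibbles: `tidy()` returns
#' the per-frame (or per-pair) observations, `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name gnrhkit-tidiers
NULL

#' @rdname gnrhkit-tidiers
#' @export
tidy.activation_report <- function(x, ...) {
  tibble(
    frame = seq_along(x$trace) - 1L,
    distance = x$trace,
    rolling_mean = x$rolling_mean
  )
}

#' @rdname gnrhkit-tidiers
#' @export
glance.activation_report <- function(x, ...) {
  tibble(
    activated = x$activated,
    activation_frame = x$activation_frame,
    delta = x$delta,
    baseline = x$baseline,
    threshold_delta = x$threshold_delta,
    window = x$window,
    n_frames = length(x$trace)
  )
}

#' @rdname gnrhkit-tidiers
#' @export
tidy.bridge_series <- function(x, ...) {
  dplyr::mutate(x$per_frame, a = x$pair[1], b = x$pair[2])
}

#' @rdname gnrhkit-tidiers
#' @export
glance.bridge_series <- function(x, ...) {
  tibble(
    a = x$pair[1], b = x$pair[2],
    occupancy = x$occupancy, significant = x$significant,
    significance = x$significance, status = x$status,
    n_frames = nrow(x$per_frame)
  )
}

#' @rdname gnrhkit-tidiers
#' @export
tidy.interaction_modes <- function(x, ...) {
  dplyr::mutate(x$per_frame, a = x$pair[1], b = x$pair[2])
}

#' @rdname gnrhkit-tidiers
#' @export
glance.interaction_modes <- function(x, ...) {
  tibble(
    a = x$pair[1], b = x$pair[2],
    direct = x$fractions[["direct"]],
    water_mediated = x$fractions[["water_mediated"]],
    none = x$fractions[["none"]]
  )
}

#' @rdname gnrhkit-tidiers
#' @export
tidy.pca_result <- function(x, ...) {
  x$projection
}

#' @rdname gnrhkit-tidiers
#' @export
glance.pca_result <- function(x, ...) {
  tibble(
    pc1_ratio = x$variance_ratio[1],
    pc2_ratio = if (length(x$variance_ratio) > 1) x$variance_ratio[2] else NA_real_,
    n_frames = nrow(x$projection),
    n_coordinates = length(x$center)
  )
}

#' @rdname gnrhkit-tidiers
#' @export
tidy.triage_result <- function(x, ...) {
  x$audit
}

#' @rdname gnrhkit-tidiers
#' @export
glance.triage_result <- function(x, ...) {
  tibble(
    n_decoys = nrow(x$decoys),
    n_eliminated = nrow(x$audit),
    n_candidates = nrow(x$candidates),
    top_candidate = if (nrow(x$candidates) > 0) x$candidates$decoy_id[1] else NA_character_,
    status = x$status
  )
}

#' @rdname gnrhkit-tidiers
#' @export
tidy.signature_panel <- function(x, ...) {
  dplyr::bind_rows(
    tibble(quantity = "tm6_rotation", unit = "deg", value = x$tm6_rotation),
    tibble(quantity = "tm6_axis_tilt", unit = "deg", value = x$tm6_axis_tilt),
    tibble(quantity = "tm6_lateral", unit = "A", value = x$tm6_lateral),
    tibble(quantity = "tm6_vertical", unit = "A", value = x$tm6_vertical),
    tibble(quantity = paste0("displacement_", x$residue_displacements$bw),
           unit = "A", value = x$residue_displacements$displacement),
    tibble(quantity = paste0("displacement_", x$icl_displacements$loop),
           unit = "A", value = x$icl_displacements$displacement)
  )
}
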