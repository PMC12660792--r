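#' TM3-TM6 activation distance trace
#'
#' The canonical class A GPCR activation metric: the per-frame Euclidean
#' distance between the Calpha atoms of the BW 3.50 and 6.33 residues (for
#' the GnRH1 receptor, R139 and T265).  In the inactive receptor this
#' distance sits near 8 A; activation opens the cytoplasmic G-protein cavity
#' and raises it by roughly 4 A.
#'
#' @param traj A `trajectory`.
#' @param bwmap A BW map (default [gnrh1r_bw_map()]).
#' @param codes The two BW codes measured (default `c("3.50", "6.33")`).
#' @return Tibble with `frame` (0-based), `time` (ns) and `distance` (A).
#' @export
tm3_tm6_trace <- function(traj, bwmap = gnrh1r_bw_map(),
                          codes = c("3.50", "6.33")) {
  atoms <- traj$topology$atoms
  idx <- vapply(codes, function(code) {
    ref <- resolve_bw(bwmap, code)
    i <- which(atoms$chain == ref$chain & atoms$resno == ref$resno &
                 atoms$elety == "CA")
    if (length(i) != 1) {
      abort(sprintf("BW %s (%s %d) has no unique CA atom in the trajectory",
                    code, ref$chain, ref$resno))
    }
    i
  }, integer(1))
  d <- atom_pair_dist(traj$xyz, idx[1], idx[2])
  tibble(
    frame = seq_len(n_frames(traj)) - 1L,
    time = (seq_len(n_frames(traj)) - 1L) * traj$frame_interval,
    distance = d
  )
}

#' @rdname tm3_tm6_trace
#' @param model A `structure_model` (single conformation).
#' @export
tm3_tm6_distance <- function(model, bwmap = gnrh1r_bw_map(),
                             codes = c("3.50", "6.33")) {
  xyz <- matrix(as.vector(t(model_coords(model))), nrow = 1)
  traj <- new_trajectory(model, xyz)
  tm3_tm6_trace(traj, bwmap, codes)$distance
}

#' Detect sustained receptor activation in a distance trace
#'
#' Smooths the TM3-TM6 trace with a trailing rolling mean (shrinking at the
#' start so every frame has a value) and flags activation when the rolling
#' mean reaches `baseline + threshold_delta` and stays there to the end of
#' the trajectory.  The activation frame is the first frame of that
#' sustained window, and `delta` is the mean distance over the window minus
#' the baseline.
#'
#' @param trace Numeric distance vector, or the tibble from
#'   [tm3_tm6_trace()].
#' @param baseline Inactive-state reference distance (A).  Default: mean of
#'   the first `baseline_frames` frames.
#' @param threshold_delta Required sustained increase (A; default 3, a
#'   conservative gate under an activation-scale shift of about 4).
#' @param window Rolling-mean window in frames (default 10).
#' @param baseline_frames Frames used for the default baseline (default
#'   `min(100, length(trace) %/% 4)`).
#' @return An `activation_report`: list with `trace`, `rolling_mean`,
#'   `baseline`, `activated`, `activation_frame` (0-based or `NA`), `delta`,
#'   `threshold_delta`, `window`.
#' @export
detect_activation <- function(trace, baseline = NULL, threshold_delta = 3,
                              window = 10, baseline_frames = NULL) {
  if (is.data.frame(trace)) trace <- trace$distance
  n <- length(trace)
  if (window < 1) abort("window must be >= 1")
  if (window > n) abort(sprintf("window (%d) exceeds trace length (%d)", window, n))
  if (is.null(baseline)) {
    baseline_frames <- baseline_frames %||% max(1L, min(100L, n %/% 4L))
    baseline <- mean(trace[seq_len(baseline_frames)])
  }
  cs <- cumsum(trace)
  roll <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    roll[i] <- (cs[i] - if (lo > 1) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  above <- roll >= baseline + threshold_delta
  # first frame from which `above` holds through to the end
  sustained_from <- if (!above[n]) {
    NA_integer_
  } else {
    last_false <- max(c(0L, which(!above)))
    last_false + 1L
  }
  activated <- !is.na(sustained_from)
  activation_frame <- if (activated) sustained_from - 1L else NA_integer_
  delta <- if (activated) {
    mean(trace[sustained_from:n]) - baseline
  } else {
    NA_real_
  }
  structure(
    list(trace = trace, rolling_mean = roll, baseline = baseline,
         activated = activated, activation_frame = activation_frame,
         delta = delta, threshold_delta = threshold_delta, window = window),
    class = "activation_report"
  )
}

#' @export
print.activation_report <- function(x, ...) {
  if (x$activated) {
    cat(sprintf(
      "<activation_report> activated at frame %d; delta = %.2f A over baseline %.2f A\n",
      x$activation_frame, x$delta, x$baseline
    ))
  } else {
    cat(sprintf("<activation_report> not activated (baseline %.2f A)\n",
                x$baseline))
  }
  invisible(x)
}
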