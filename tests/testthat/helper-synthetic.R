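# Shared fixture builders and independent oracles, all constructed in code.

# Trajectory from a list of n x 3 coordinate matrices sharing one atom table
make_traj <- function(atoms, frames, box = NULL, frame_interval = 1) {
  xyz <- do.call(rbind, lapply(frames, function(co) as.vector(t(co))))
  new_trajectory(new_structure_model(atoms, box = box), xyz,
                 frame_interval = frame_interval)
}

# Minimal atom table; coordinates filled per frame by make_traj
atom_table <- function(elety, resid, chain, resno, element = NULL) {
  tibble::tibble(
    eleno = seq_along(elety), elety = elety, resid = resid, chain = chain,
    resno = as.integer(resno),
    element = element %||% substr(elety, 1, 1),
    x = 0, y = 0, z = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney test on
# tie-free samples: the permutation distribution of U1 over all
# C(n1+n2, n1) group assignments of the pooled values.
mwu_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u1_of <- function(first_idx) {
    xs <- pooled[first_idx]
    ys <- pooled[-first_idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u1_obs <- u1_of(seq_len(n1))
  all_u1 <- apply(utils::combn(n1 + n2, n1), 2, u1_of)
  p <- 2 * min(mean(all_u1 <= u1_obs), mean(all_u1 >= u1_obs))
  list(U = min(u1_obs, n1 * n2 - u1_obs), U1 = u1_obs, p = min(1, p))
}

# Brute-force two-sided KS distance of a sample against a fitted normal
ks_D_brute <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  f <- stats::pnorm(xs, mean(x), stats::sd(x))
  max(pmax(abs(seq_len(n) / n - f), abs((seq_len(n) - 1) / n - f)))
}

# Brute-force hydrogen-bond scan: plain triple loop over donors, attached
# hydrogens and acceptors, applying the distance + donor-centred-angle rule.
hbond_brute_force <- function(model, d_cut = 3.5, angle_cut = 20,
                              mode = "n_o") {
  atoms <- model$atoms
  co <- model_coords(model)
  don_el <- if (mode == "n_o") "N" else c("N", "O")
  acc_el <- if (mode == "n_o") "O" else c("N", "O")
  don <- which(atoms$element %in% don_el)
  acc <- which(atoms$element %in% acc_el)
  hyd <- which(atoms$element == "H")
  out <- list()
  for (d in don) {
    for (a in acc) {
      if (a == d) next
      if (atoms$chain[a] == atoms$chain[d] && atoms$resno[a] == atoms$resno[d]) next
      da <- sqrt(sum((co[a, ] - co[d, ])^2))
      if (da > d_cut || da < 1e-6) next
      best <- Inf
      for (h in hyd) {
        if (sqrt(sum((co[h, ] - co[d, ])^2)) > 1.25) next
        vh <- co[h, ] - co[d, ]
        va <- co[a, ] - co[d, ]
        ang <- acos(min(1, max(-1, sum(vh * va) /
                                 sqrt(sum(vh^2) * sum(va^2))))) * 180 / pi
        if (ang < best) best <- ang
      }
      if (best <= angle_cut) {
        out[[length(out) + 1L]] <- data.frame(donor = d, acceptor = a,
                                              dist = da, angle = best)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      dist = numeric(0), angle = numeric(0)))
  }
  do.call(rbind, out)
}

# Brute-force water-bridge detection: plain triple loop over frames, waters
# and partner polar atoms.
water_bridge_brute_force <- function(traj, pair, d_cut = 3.5) {
  atoms <- traj$topology$atoms
  parse1 <- function(p) {
    parts <- strsplit(p, "/")[[1]]
    list(chain = parts[1], resno = as.integer(parts[2]))
  }
  r1 <- parse1(pair[1]); r2 <- parse1(pair[2])
  p1 <- which(atoms$chain == r1$chain & atoms$resno == r1$resno &
                atoms$element %in% c("N", "O"))
  p2 <- which(atoms$chain == r2$chain & atoms$resno == r2$resno &
                atoms$element %in% c("N", "O"))
  wat <- which(atoms$resid %in% c("HOH", "TIP3", "WAT", "SOL") &
                 atoms$elety %in% c("O", "OH2", "OW"))
  bridged <- logical(n_frames(traj))
  for (f in seq_len(n_frames(traj)) - 1L) {
    co <- frame_coords(traj, f)
    hit <- FALSE
    for (w in wat) {
      near1 <- FALSE
      for (i in p1) {
        if (sqrt(sum((co[w, ] - co[i, ])^2)) <= d_cut) { near1 <- TRUE; break }
      }
      if (!near1) next
      for (i in p2) {
        if (sqrt(sum((co[w, ] - co[i, ])^2)) <= d_cut) { hit <- TRUE; break }
      }
      if (hit) break
    }
    bridged[f + 1L] <- hit
  }
  bridged
}

# Random mixed-residue frame with explicit amide hydrogens for every
# nitrogen, used for brute-force hydrogen-bond equivalence checks.
random_polar_frame <- function(n_res = 30, seed = 1, box = 15) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_res)) {
    base <- runif(3, 0, box)
    n_pos <- base
    h_pos <- base + c(0.6, 0.55, 0.55) * runif(3, 0.8, 1.2) / sqrt(3)
    o_pos <- base + runif(3, -3, 3)
    rows[[i]] <- tibble::tibble(
      elety = c("N", "H", "O"), resid = "ALA", chain = "A",
      resno = i, element = c("N", "H", "O"),
      x = c(n_pos[1], h_pos[1], o_pos[1]),
      y = c(n_pos[2], h_pos[2], o_pos[2]),
      z = c(n_pos[3], h_pos[3], o_pos[3])
    )
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure_model(atoms)
}

# Planted two-mode trajectory: static base geometry plus motion along two
# orthonormal 3N-directions with exact sample variances var1 and var2.
make_mode_trajectory <- function(n_frames = 60, n_atoms = 20,
                                 var1 = 4, var2 = 1, seed = 2) {
  set.seed(seed)
  base <- matrix(rnorm(3 * n_atoms, sd = 5), ncol = 3)
  v1 <- rnorm(3 * n_atoms); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(3 * n_atoms); v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  s1 <- rnorm(n_frames); s1 <- s1 - mean(s1)
  s2 <- stats::resid(stats::lm(rnorm(n_frames) ~ s1))
  s2 <- s2 - mean(s2)
  s1 <- s1 / stats::sd(s1) * sqrt(var1)
  s2 <- s2 / stats::sd(s2) * sqrt(var2)
  xyz <- matrix(rep(as.vector(t(base)), each = n_frames), nrow = n_frames) +
    s1 %*% t(v1) + s2 %*% t(v2)
  atoms <- atom_table(rep("CA", n_atoms), "ALA", "A", seq_len(n_atoms))
  atoms$x <- base[, 1]; atoms$y <- base[, 2]; atoms$z <- base[, 3]
  new_trajectory(new_structure_model(atoms), xyz)
}
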