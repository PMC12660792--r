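test_that("TM3-TM6 trace measures plain Calpha distances", {
  atoms <- atom_table(c("CA", "CA"), c("ARG", "THR"), "A", c(139, 265))
  frames <- list(
    rbind(c(0, 0, 0), c(10, 0, 0)),
    rbind(c(0, 0, 0), c(0, 12, 0))
  )
  traj <- make_traj(atoms, frames)
  tr <- tm3_tm6_trace(traj)
  expect_equal(tr$distance, c(10, 12))
  expect_equal(tr$frame, c(0, 1))
  # unresolved BW code errors
  expect_error(tm3_tm6_trace(traj, codes = c("3.50", "9.99")), "9.99")
  # missing CA errors
  atoms2 <- atom_table("CB", "ARG", "A", 139)
  expect_error(tm3_tm6_trace(make_traj(atoms2, list(rbind(c(0, 0, 0))))),
               "no unique CA")
})

test_that("activation detection finds a planted sustained step", {
  set.seed(3)
  trace <- c(rnorm(500, 8, 0.05), rnorm(500, 12, 0.05))
  rep_ <- detect_activation(trace, baseline = 8, threshold_delta = 3, window = 10)
  expect_true(rep_$activated)
  expect_gte(rep_$activation_frame, 500)
  expect_lte(rep_$activation_frame, 510)
  expect_equal(rep_$delta, 4, tolerance = 0.1)

  # constant trace at baseline: not activated
  flat <- detect_activation(rep(8, 100), baseline = 8, threshold_delta = 3,
                            window = 10)
  expect_false(flat$activated)
  expect_true(is.na(flat$activation_frame))

  # zero threshold: any trace at/above baseline activates at frame 0
  zero <- detect_activation(rep(8, 50), baseline = 8, threshold_delta = 0,
                            window = 5)
  expect_true(zero$activated)
  expect_equal(zero$activation_frame, 0)

  expect_error(detect_activation(rep(8, 5), baseline = 8, window = 10), "window")
})

test_that("activation detection is invariant under a constant shift", {
  set.seed(9)
  trace <- c(rnorm(80, 8, 0.1), rnorm(120, 12.2, 0.1))
  a <- detect_activation(trace, baseline = 8)
  b <- detect_activation(trace + 5, baseline = 13)
  expect_equal(a$activated, b$activated)
  expect_equal(a$activation_frame, b$activation_frame)
  expect_equal(a$delta, b$delta, tolerance = 1e-9)
})

test_that("activation on the planted bundle recovers the swing", {
  out <- gen_bundle_trajectory(bundle_plant_spec(n_frames = 200, swing_frame = 100,
                                                 swing_delta = 4, seed = 12))
  tr <- tm3_tm6_trace(out$trajectory)
  rep_ <- detect_activation(tr, baseline_frames = 50)
  expect_true(rep_$activated)
  expect_gte(rep_$activation_frame, 100)
  expect_lte(rep_$activation_frame, 110)
  expect_equal(rep_$delta, 4, tolerance = 0.2)
})

test_that("hydrogen-bond criterion honours both boundaries", {
  mk_hb <- function(no_dist, angle_deg) {
    # donor N at origin, H along x; acceptor O at no_dist with the given
    # donor-centred angle off the N-H axis
    th <- angle_deg * pi / 180
    atoms <- dplyr::bind_rows(
      atom_table(c("N", "H"), "ALA", "A", c(1, 1)),
      atom_table("O", "ALA", "A", 2)
    )
    atoms$eleno <- 1:3
    atoms$x <- c(0, 1, no_dist * cos(th))
    atoms$y <- c(0, 0, no_dist * sin(th))
    atoms$z <- 0
    new_structure_model(atoms)
  }
  expect_equal(nrow(detect_hbonds(mk_hb(3.4, 0))), 1)   # collinear, in range
  expect_equal(nrow(detect_hbonds(mk_hb(3.6, 0))), 0)   # distance boundary
  expect_equal(nrow(detect_hbonds(mk_hb(3.0, 25))), 0)  # angle boundary
  expect_equal(nrow(detect_hbonds(mk_hb(3.0, 19))), 1)
  ev <- detect_hbonds(mk_hb(3.2, 10))
  expect_equal(ev$dist, 3.2, tolerance = 1e-9)
  expect_equal(ev$angle, 10, tolerance = 1e-9)

  # donor without an attached hydrogen is an error naming the atom
  bare <- mk_hb(3.0, 0)
  bare$atoms <- bare$atoms[bare$atoms$elety != "H", ]
  expect_error(detect_hbonds(bare), "no attached hydrogen")
  expect_error(detect_hbonds(bare), "N")
})

test_that("hydrogen-bond detection equals a brute-force pair scan", {
  for (seed in 1:3) {
    m <- random_polar_frame(n_res = 40, seed = seed)
    fast <- detect_hbonds(m)
    brute <- hbond_brute_force(m)
    expect_equal(nrow(fast), nrow(brute), info = paste("seed", seed))
    if (nrow(fast) > 0) {
      key_fast <- sort(paste(fast$donor_resno, fast$acceptor_resno, fast$acceptor_atom))
      key_brute <- sort(paste(m$atoms$resno[brute$donor],
                              m$atoms$resno[brute$acceptor],
                              m$atoms$elety[brute$acceptor]))
      expect_equal(key_fast, key_brute)
      expect_equal(sort(fast$dist), sort(brute$dist), tolerance = 1e-12)
    }
  }
})

test_that("hydrogen-bond occupancy recovers a planted Bernoulli pattern", {
  set.seed(31)
  pattern <- runif(300) < 0.6
  out <- gen_bundle_trajectory(bundle_plant_spec(
    n_frames = 300, swing_frame = 150, saltbridge_pattern = pattern, seed = 3
  ))
  occ <- hbond_occupancy(out$trajectory, c("A/75", "A/138"))
  expect_equal(occ$occupancy, mean(pattern), tolerance = 1e-9)
  expect_identical(occ$present[[1]], pattern)
})

test_that("salt bridges recover planted patterns and run-length durations", {
  expect_equal(run_durations(c(TRUE, TRUE, FALSE, TRUE)), c(2L, 1L))
  expect_equal(run_durations(rep(FALSE, 5)), integer(0))
  expect_equal(sum(run_durations(c(TRUE, FALSE, TRUE, TRUE, TRUE))), 4L)
  # run-length durations reconstruct the boolean series
  set.seed(17)
  series <- runif(200) < 0.4
  durs <- run_durations(series)
  expect_equal(sum(durs), sum(series))
  expect_equal(length(durs), sum(diff(c(FALSE, series)) == 1))

  pattern <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 3), rep(FALSE, 12))
  out <- gen_bundle_trajectory(bundle_plant_spec(
    n_frames = 30, swing_frame = 15, saltbridge_pattern = pattern, seed = 23
  ))
  sb <- salt_bridges(out$trajectory)
  planted <- sb[sb$basic_resno == 75 & sb$acidic_resno == 138, ]
  expect_equal(nrow(planted), 1)
  expect_identical(planted$present[[1]], pattern)
  expect_equal(planted$durations[[1]], c(10L, 3L))
  expect_equal(planted$occupancy, mean(pattern))
})

test_that("backbone RMSD is zero on self, superposition-invariant, and matches closed form", {
  out <- gen_bundle_trajectory(bundle_plant_spec(n_frames = 2, swing_frame = 1,
                                                 jitter_sd = 0, seed = 2))
  traj <- out$trajectory
  r <- backbone_rmsd(traj, reference_frame = 0)
  expect_equal(r$rmsd[1], 0, tolerance = 1e-6)

  # rigidly transformed copy superposes back to ~0
  co <- frame_coords(traj, 0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co2 <- sweep(co %*% t(R), 2, c(5, -3, 2), "+")
  traj2 <- make_traj(traj$topology$atoms, list(co, co2))
  r2 <- backbone_rmsd(traj2, reference_frame = 0)
  expect_lt(r2$rmsd[2], 1e-6)

  # closed form: 1 of 100 atoms displaced by 1 A, no fitting -> RMSD 0.1
  atoms <- atom_table(rep("CA", 100), "ALA", "A", 1:100)
  base <- matrix(seq_len(300), ncol = 3)
  moved <- base
  moved[1, 1] <- moved[1, 1] + 1
  traj3 <- make_traj(atoms, list(base, moved))
  r3 <- backbone_rmsd(traj3, reference_frame = 0, fit = FALSE,
                      backbone_only = FALSE)
  expect_equal(r3$rmsd[2], 0.1, tolerance = 1e-9)

  expect_error(backbone_rmsd(traj, selection = 1:2), "fewer than 3")
})

test_that("signature panel reports zeros on identical frames and a constructed rotation", {
  ref <- gnrh1r_synthetic_reference()
  same <- signature_panel(ref, ref)
  expect_equal(same$tm6_rotation, 0, tolerance = 1e-4)
  expect_equal(same$tm6_lateral, 0, tolerance = 1e-9)
  expect_equal(same$tm6_vertical, 0, tolerance = 1e-9)
  expect_true(all(same$residue_displacements$displacement < 1e-9))
  expect_true(all(same$icl_displacements$displacement < 1e-9, na.rm = TRUE))

  # TM6 rotated 15 degrees about its own (z-aligned) axis
  act <- ref
  tm6 <- which(act$atoms$resno >= 255 & act$atoms$resno <= 290)
  ca <- cbind(act$atoms$x[tm6], act$atoms$y[tm6], act$atoms$z[tm6])
  ctr <- colMeans(ca)
  th <- 15 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sweep(sweep(ca, 2, ctr) %*% t(R), 2, ctr, "+")
  act$atoms$x[tm6] <- rot[, 1]
  act$atoms$y[tm6] <- rot[, 2]
  act$atoms$z[tm6] <- rot[, 3]
  sp <- signature_panel(ref, act)
  expect_equal(sp$tm6_rotation, 15, tolerance = 0.5)
  expect_lt(sp$tm6_axis_tilt, 1)
  expect_gte(sp$tm6_rotation, 0)
  expect_lte(sp$tm6_rotation, 180)
})

test_that("signature panel recovers the planted outward swing displacement", {
  out <- gen_bundle_trajectory(bundle_plant_spec(n_frames = 4, swing_frame = 2,
                                                 swing_delta = 4, jitter_sd = 0,
                                                 seed = 5))
  inact <- get_frame(out$trajectory, 0)
  act <- get_frame(out$trajectory, 3)
  sp <- signature_panel(inact, act)
  u <- unname(out$ground_truth$swing_direction * 4)
  expect_equal(sp$tm6_lateral, sqrt(u[1]^2 + u[2]^2), tolerance = 0.1)
  expect_equal(sp$tm6_vertical, abs(u[3]), tolerance = 0.1)
  disp350 <- sp$residue_displacements$displacement[sp$residue_displacements$bw == "3.50"]
  disp648 <- sp$residue_displacements$displacement[sp$residue_displacements$bw == "6.48"]
  expect_lt(disp350, 0.1)       # TM3 does not move
  expect_equal(disp648, 4, tolerance = 0.1)  # TM6 residues move by the swing

  # segments shorter than 4 residues leave the axis undefined
  segs <- panel_segments(tm6 = c(255, 257))
  expect_error(signature_panel(inact, act, segments = segs), "fewer than 4")
})
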