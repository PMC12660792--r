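# Small hand-built system: two polar residues and two waters whose positions
# are scripted per frame.
two_residue_system <- function(frames_spec, box = c(50, 50, 50)) {
  atoms <- dplyr::bind_rows(
    atom_table(c("N", "OD1"), "ASN", "A", c(87, 87)),
    atom_table(c("N", "OE1"), "GLU", "A", c(90, 90)),
    atom_table("O", "HOH", "W", 1001),
    atom_table("O", "HOH", "W", 1002)
  )
  atoms$eleno <- seq_len(nrow(atoms))
  make_traj(atoms, frames_spec, box = box)
}

base_positions <- function(sep = 6, water1 = NULL, water2 = c(40, 40, 40)) {
  rbind(
    c(-1, 2, 0), c(0, 0, 0),          # ASN 87 N, OD1
    c(sep + 1, 2, 0), c(sep, 0, 0),   # GLU 90 N, OE1
    water1 %||% c(sep / 2, 0, 0),     # water between the OD1/OE1 tips
    water2
  )
}

test_that("water bridges follow the distance-only criterion with its boundary", {
  # permanent bridge: water at 3.0 A from each tip
  traj <- two_residue_system(list(base_positions(sep = 6)))
  br <- water_bridges(traj, c("A/87", "A/90"))
  expect_equal(br$occupancy, 1)
  expect_true(br$significant)
  expect_equal(br$per_frame$n_bridging_waters, 1L)
  expect_equal(br$per_frame$bridging_waters[[1]], 1001L)

  # water at 3.6 A from one partner: no bridge
  pos <- base_positions(sep = 7.2)
  expect_false(water_bridges(two_residue_system(list(pos)),
                             c("A/87", "A/90"))$per_frame$bridged)

  # no waters at all: explicit status, occupancy 0
  atoms <- dplyr::bind_rows(
    atom_table(c("N", "OD1"), "ASN", "A", c(87, 87)),
    atom_table(c("N", "OE1"), "GLU", "A", c(90, 90))
  )
  atoms$eleno <- seq_len(nrow(atoms))
  dry <- make_traj(atoms, list(base_positions(sep = 6)[1:4, , drop = FALSE]))
  br_dry <- water_bridges(dry, c("A/87", "A/90"))
  expect_equal(br_dry$status, "no waters")
  expect_equal(br_dry$occupancy, 0)
  expect_false(br_dry$significant)
})

test_that("bridge occupancy is invariant under frame permutation and flags significance", {
  near <- base_positions(sep = 6)
  far <- base_positions(sep = 6, water1 = c(3, 0, 30))
  frames <- list(near, far, near, far, far, far, far, far, far, far)
  traj <- two_residue_system(frames)
  br <- water_bridges(traj, c("A/87", "A/90"))
  expect_equal(br$occupancy, 0.2)
  expect_true(br$significant)   # 0.2 >= 0.10
  set.seed(1)
  perm <- sample(length(frames))
  br_p <- water_bridges(two_residue_system(frames[perm]), c("A/87", "A/90"))
  expect_equal(br_p$occupancy, br$occupancy)
  # below the 10% threshold the flag drops
  br_low <- water_bridges(two_residue_system(c(frames[1], frames[rep(2, 19)])),
                          c("A/87", "A/90"))
  expect_equal(br_low$occupancy, 0.05)
  expect_false(br_low$significant)
})

test_that("planted Bernoulli bridge occupancy is recovered from the trajectory", {
  out <- gen_bundle_trajectory(bundle_plant_spec(
    n_frames = 1000, swing_frame = 500,
    bridge_pairs = list(list(a = "A/87", b = "A/90", occupancy = 0.6)),
    seed = 2
  ))
  br <- water_bridges(out$trajectory, c("A/87", "A/90"))
  expect_gte(br$occupancy, 0.55)
  expect_lte(br$occupancy, 0.65)
  expect_true(br$significant)
  expect_equal(br$occupancy, out$ground_truth$bridges[[1]]$planted_occupancy)
  truth_frames <- out$ground_truth$bridges[[1]]$frames
  expect_identical(which(br$per_frame$bridged) - 1L, truth_frames)
})

test_that("water-bridge detection equals a brute-force triple loop on a 50-water system", {
  set.seed(44)
  n_wat <- 50
  wat_rows <- atom_table(rep("O", n_wat), "HOH", "W", 1000 + seq_len(n_wat))
  atoms <- dplyr::bind_rows(
    atom_table(c("N", "OD1"), "ASN", "A", c(87, 87)),
    atom_table(c("N", "OE1"), "GLU", "A", c(90, 90)),
    wat_rows
  )
  atoms$eleno <- seq_len(nrow(atoms))
  frames <- lapply(1:8, function(f) {
    rbind(base_positions(sep = 6)[1:4, , drop = FALSE],
          matrix(runif(3 * n_wat, -2, 8), ncol = 3))
  })
  traj <- make_traj(atoms, frames, box = c(60, 60, 60))
  br <- water_bridges(traj, c("A/87", "A/90"))
  brute <- water_bridge_brute_force(traj, c("A/87", "A/90"))
  expect_identical(br$per_frame$bridged, brute)
  expect_equal(br$occupancy, mean(brute))
})

test_that("interaction modes are exclusive, exhaustive, and match a planted pattern", {
  # frame A: direct contact (tips 3 A apart); frame B: bridged at 6 A;
  # frame C: isolated, water parked away
  direct <- base_positions(sep = 3, water1 = c(1.5, 0, 30))
  bridged <- base_positions(sep = 6)
  none <- base_positions(sep = 6, water1 = c(3, 0, 30))
  traj <- two_residue_system(list(direct, bridged, direct, none))
  cls <- classify_interaction(traj, c("A/87", "A/90"))
  expect_equal(cls$per_frame$mode, c("direct", "water_mediated", "direct", "none"))
  expect_equal(unname(cls$fractions),  c(0.5, 0.25, 0.25))
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-12)

  # permanent contact
  always <- classify_interaction(two_residue_system(list(direct, direct)),
                                 c("A/87", "A/90"))
  expect_equal(unname(always$fractions[["direct"]]), 1)

  # isolated partners with no waters: none fraction 1
  atoms <- dplyr::bind_rows(
    atom_table(c("N", "OD1"), "ASN", "A", c(87, 87)),
    atom_table(c("N", "OE1"), "GLU", "A", c(90, 90))
  )
  atoms$eleno <- seq_len(nrow(atoms))
  iso <- make_traj(atoms, list(base_positions(sep = 20)[1:4, , drop = FALSE]))
  expect_equal(unname(classify_interaction(iso, c("A/87", "A/90"))$fractions[["none"]]), 1)
})

test_that("the centred shrinking-window smoother behaves as specified", {
  expect_equal(smooth_series(rep(3.5, 40), 7), rep(3.5, 40))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smooth_series(imp, 5)
  expect_equal(sm[9:13], rep(0.2, 5))   # interior plateau of 1/5
  expect_equal(sm[c(8, 14)], c(0, 0))
  expect_identical(smooth_series(imp, 1), imp)
  expect_equal(length(smooth_series(rnorm(100), 50)), 100)
  expect_error(smooth_series(rnorm(10), 11), "exceeds")
  expect_error(smooth_series(rnorm(10), 0), ">= 1")
})

test_that("RDF reproduces constructed geometries", {
  # all targets exactly at 2.8 A on a sphere around one reference atom
  set.seed(6)
  n_t <- 500
  dirs <- matrix(rnorm(3 * n_t), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  centre <- c(20, 20, 20)
  co <- rbind(centre, sweep(2.8 * dirs, 2, centre, "+"))
  atoms <- atom_table(rep("O", n_t + 1), "HOH", "W", seq_len(n_t + 1))
  traj <- make_traj(atoms, list(co), box = c(40, 40, 40))
  curve <- rdf(traj, 1, 2:(n_t + 1), r_max = 8, dr = 0.05)
  occupied <- which(curve$count > 0)
  # all mass in the bin(s) at 2.8 A (floating point may straddle the edge)
  expect_lte(length(occupied), 2)
  expect_true(all(abs(curve$r[occupied] - 2.8) < 0.05))
  expect_equal(sum(curve$count), n_t)

  # empty target set: g identically zero
  empty <- rdf(traj, 1, integer(0), r_max = 8, dr = 0.05)
  expect_true(all(empty$g == 0))

  # no box and no density: error
  traj_nobox <- make_traj(atoms, list(co))
  expect_error(rdf(traj_nobox, 1, 2:10), "bulk_density")
  expect_no_error(rdf(traj_nobox, 1, 2:10, bulk_density = 0.03))
})

test_that("RDF of a uniform ideal gas converges to one", {
  set.seed(8)
  n <- 4000
  L <- 25
  co <- matrix(runif(3 * n, 0, L), ncol = 3)
  atoms <- atom_table(rep("O", n), "HOH", "W", seq_len(n))
  traj <- make_traj(atoms, list(co), box = c(L, L, L))
  curve <- rdf(traj, seq_len(n), seq_len(n), r_max = 7, dr = 0.1)
  sel <- curve$r >= 2 & curve$r <= 6
  expect_true(all(abs(curve$g[sel] - 1) < 0.1))
  expect_equal(mean(curve$g[sel]), 1, tolerance = 0.02)
  expect_true(all(curve$g >= 0))
})
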