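#' Specification for a planted-truth helical-bundle trajectory
#'
#' Describes a synthetic 7-transmembrane-helix trajectory with features
#' planted at known frames: an outward swing of the cytoplasmic end of TM6
#' (the class A GPCR activation signature), water-mediated hydrogen-bond
#' bridges with a prescribed Bernoulli occupancy, and a salt bridge following
#' a per-frame boolean template.  Geometry is idealised (alpha-helical rise
#' 1.5 A per residue, 100 degrees of twist per residue, helices on a ring);
#' residues carry explicit backbone amide hydrogens, and labelled interaction
#' residues (ARG/GLU/ASN/...) carry named side-chain atoms so hydrogen-bond
#' and salt-bridge operations see conventional PDB atom names.  There is no
#' force field: this emulates the geometry that detection criteria test, not
#' physics.
#'
#' @param n_frames Number of frames (default 1000; at the default 1 ns/frame
#'   this emulates a 1 microsecond observation window).
#' @param swing_frame 0-based frame at which the TM6 swing switches on
#'   (default 500).
#' @param swing_delta Outward displacement in Angstrom applied to TM6 from
#'   `swing_frame` onward, measured as the increase of the 3.50-6.33
#'   Calpha-Calpha distance (default 4, the activation-scale shift).
#' @param bridge_pairs List of planted water bridges; each element is
#'   `list(a = "chain/resno", b = "chain/resno", occupancy = p)`.  The default
#'   plants the high-occupancy 2.50-2.53 (N87-E90) bridge at 0.88.
#' @param saltbridge_pattern Logical vector (length `n_frames`, recycled) of
#'   frames on which the planted R75(2.38)-D138(3.49) ionic lock is formed;
#'   default all `TRUE` (a retained lock).
#' @param jitter_sd Per-atom Gaussian positional noise, Angstrom
#'   (default 0.02).
#' @param frame_interval ns per frame (default 1).
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return A `bundle_plant_spec` list.
#' @export
bundle_plant_spec <- function(n_frames = 1000, swing_frame = 500,
                              swing_delta = 4,
                              bridge_pairs = list(
                                list(a = "A/87", b = "A/90", occupancy = 0.88)
                              ),
                              saltbridge_pattern = TRUE,
                              jitter_sd = 0.02, frame_interval = 1,
                              seed = 1L) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (swing_frame < 0 || swing_frame >= n_frames) {
    abort("swing_frame must satisfy 0 <= swing_frame < n_frames")
  }
  for (bp in bridge_pairs) {
    if (bp$occupancy < 0 || bp$occupancy > 1) {
      abort("bridge occupancies must lie in [0, 1]")
    }
  }
  pattern <- rep_len(as.logical(saltbridge_pattern), n_frames)
  structure(
    list(n_frames = as.integer(n_frames), swing_frame = as.integer(swing_frame),
         swing_delta = swing_delta, bridge_pairs = bridge_pairs,
         saltbridge_pattern = pattern, jitter_sd = jitter_sd,
         frame_interval = frame_interval, seed = as.integer(seed)),
    class = "bundle_plant_spec"
  )
}

# Helix spans of the synthetic receptor, in GnRH1R author numbering so the
# shipped BW map resolves on generated structures.  `dir` gives the direction
# the sequence runs: +1 for intracellular (low z) to extracellular (high z).
BUNDLE_HELICES <- data.frame(
  tm = 1:7,
  first = c(32L, 75L, 113L, 150L, 204L, 255L, 299L),
  last = c(63L, 102L, 145L, 178L, 240L, 290L, 325L),
  dir = c(-1, 1, -1, 1, -1, 1, -1)
)

BUNDLE_RING_RADIUS <- 11
HELIX_RADIUS <- 2.3
HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180

# Side-chain atom names appended radially outward from CB, with the terminal
# polar atom last (the atom bridge/salt-bridge planting repositions).
SIDE_CHAINS <- list(
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  THR = c("CB", "OG1", "CG2"),
  SER = c("CB", "OG"),
  TYR = c("CB", "CG", "OH"),
  HIS = c("CB", "CG", "ND1"),
  GLY = character(0)
)

# Terminal polar heavy atom used when planting a bridge on a residue
polar_tip <- function(resid) {
  switch(resid,
    ARG = "NH1", LYS = "NZ", GLU = "OE1", ASP = "OD1", ASN = "OD1",
    GLN = "OE1", THR = "OG1", SER = "OG", TYR = "OH", HIS = "ND1",
    "O"
  )
}

parse_residue_ref <- function(ref) {
  parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(sprintf("residue ref '%s' is not 'chain/resno'", ref))
  list(chain = parts[1], resno = as.integer(parts[2]))
}

# Base (frame-independent) atom table and coordinates of the idealised bundle
build_bundle_base <- function() {
  map <- gnrh1r_bw_map()
  rows <- list()
  for (h in seq_len(nrow(BUNDLE_HELICES))) {
    tm <- BUNDLE_HELICES[h, ]
    n_res <- tm$last - tm$first + 1L
    phi <- 2 * pi * (tm$tm - 1) / 7
    u <- c(cos(phi), sin(phi), 0)
    v <- c(-sin(phi), cos(phi), 0)
    centre <- BUNDLE_RING_RADIUS * u
    half <- (n_res - 1) * HELIX_RISE / 2
    ca <- matrix(0, n_res, 3)
    for (i in seq_len(n_res)) {
      th <- (i - 1) * HELIX_TWIST
      radial <- cos(th) * u + sin(th) * v
      z <- -tm$dir * half + tm$dir * (i - 1) * HELIX_RISE
      ca[i, ] <- centre + HELIX_RADIUS * radial + c(0, 0, z)
    }
    for (i in seq_len(n_res)) {
      resno <- tm$first + i - 1L
      resid <- map$resid[match(resno, map$resno)]
      if (is.na(resid) || !resid %in% names(SIDE_CHAINS)) {
        resid <- if (is.na(resid)) "ALA" else resid
      }
      prev <- if (i > 1) ca[i - 1, ] else 2 * ca[i, ] - ca[i + 1, ]
      nxt <- if (i < n_res) ca[i + 1, ] else 2 * ca[i, ] - ca[i - 1, ]
      th <- (i - 1) * HELIX_TWIST
      outward <- cos(th) * u + sin(th) * v
      n_pos <- ca[i, ] + 1.46 * normalize(prev - ca[i, ] + 0.4 * outward)
      h_pos <- n_pos + 1.00 * normalize(n_pos - ca[i, ])
      c_pos <- ca[i, ] + 1.52 * normalize(nxt - ca[i, ] - 0.4 * outward)
      o_pos <- c_pos + 1.23 * outward
      names_i <- c("N", "H", "CA", "C", "O")
      coords_i <- rbind(n_pos, h_pos, ca[i, ], c_pos, o_pos)
      side <- SIDE_CHAINS[[resid]] %||% c("CB")
      if (identical(resid, "ALA")) side <- "CB"
      if (length(side) > 0) {
        for (s in seq_along(side)) {
          # walk outward in ~1.4 A steps; branch atoms (NH2, OE2/OD2, CG2)
          # are offset sideways off the previous atom instead
          nm <- side[s]
          if (nm %in% c("NH2", "OE2", "OD2", "CG2", "NE2", "ND2")) {
            base_at <- coords_i[nrow(coords_i), ]
            pos <- base_at + 1.3 * normalize(v + c(0, 0, 0.3))
          } else {
            pos <- ca[i, ] + (1.53 + 1.35 * (s - 1)) * outward
          }
          names_i <- c(names_i, nm)
          coords_i <- rbind(coords_i, pos)
        }
      }
      rows[[length(rows) + 1L]] <- list(
        elety = names_i, resid = resid, chain = "A", resno = resno,
        coords = coords_i
      )
    }
  }
  atoms <- tibble(
    elety = unlist(lapply(rows, `[[`, "elety")),
    resid = rep(vapply(rows, `[[`, character(1), "resid"),
                vapply(rows, function(r) length(r$elety), integer(1))),
    chain = "A",
    resno = rep(vapply(rows, `[[`, integer(1), "resno"),
                vapply(rows, function(r) length(r$elety), integer(1)))
  )
  coords <- do.call(rbind, lapply(rows, `[[`, "coords"))
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$element <- substr(atoms$elety, 1, 1)
  atoms$x <- coords[, 1]
  atoms$y <- coords[, 2]
  atoms$z <- coords[, 3]
  atoms
}

normalize <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) abort("cannot normalise a zero vector")
  x / n
}

#' Generate a planted-truth helical-bundle trajectory
#'
#' Builds the idealised 7-helix bundle described by a [bundle_plant_spec()]
#' and animates it: Gaussian positional jitter on every atom, a rigid outward
#' displacement of TM6 from `swing_frame` onward sized so the 3.50-6.33
#' Calpha-Calpha distance grows by exactly `swing_delta` (before jitter), one
#' explicit three-site water per bridge pair placed midway between the
#' partners' planted polar atoms on a seeded Bernoulli subset of frames (and
#' parked far outside the bundle otherwise), and the planted salt bridge's
#' acidic oxygens placed at 3.2 A from the basic nitrogen on pattern-true
#' frames and 10 A away otherwise.  After generation every planted feature is
#' re-measured with the package's own distance criteria; any violation aborts
#' with a generation error, and the measured per-frame truth is returned.
#'
#' @param spec A [bundle_plant_spec()].
#' @return A list with elements `trajectory` (a [new_trajectory()] object,
#'   box included) and `ground_truth` (swing frame/direction, per-pair
#'   planted bridge frames, salt-bridge pattern, and the self-check summary).
#' @examples
#' out <- gen_bundle_trajectory(bundle_plant_spec(n_frames = 20, swing_frame = 10))
#' out$ground_truth$swing_frame
#' @export
gen_bundle_trajectory <- function(spec = bundle_plant_spec()) {
  stopifnot(inherits(spec, "bundle_plant_spec"))
  set.seed(spec$seed)
  base <- build_bundle_base()
  nf <- spec$n_frames

  # planted salt bridge: ARG 75 (2.38) reaches toward ASP 138 (3.49)
  sb_basic <- list(chain = "A", resno = 75L)
  sb_acidic <- list(chain = "A", resno = 138L)
  base <- plant_arg_reach(base, sb_basic$resno, sb_acidic$resno)

  na <- nrow(base)
  base_xyz <- as.vector(t(cbind(base$x, base$y, base$z)))

  # append one water (O, H1, H2) per bridge pair
  n_bridge <- length(spec$bridge_pairs)
  water_atoms <- NULL
  if (n_bridge > 0) {
    water_atoms <- tibble(
      elety = rep(c("O", "H1", "H2"), n_bridge),
      resid = "HOH", chain = "W",
      resno = rep(1000L + seq_len(n_bridge), each = 3),
      eleno = na + seq_len(3 * n_bridge),
      element = rep(c("O", "H", "H"), n_bridge),
      x = 0, y = 0, z = 40
    )
  }
  atoms <- dplyr::bind_rows(base, water_atoms)
  n_total <- nrow(atoms)

  # frame stack: base + jitter
  xyz <- matrix(rep(c(base_xyz, rep(c(0, 0, 40), 3L * n_bridge)), each = nf),
                nrow = nf)
  xyz <- xyz + matrix(rnorm(nf * 3L * n_total, sd = spec$jitter_sd), nrow = nf)

  # TM6 swing: rigid translation along the 3.50 -> 6.33 direction
  ca350 <- atom_index_one(base, "A", 139L, "CA")
  ca633 <- atom_index_one(base, "A", 265L, "CA")
  u_swing <- normalize(c(base$x[ca633] - base$x[ca350],
                         base$y[ca633] - base$y[ca350],
                         base$z[ca633] - base$z[ca350]))
  tm6_resnos <- seq(BUNDLE_HELICES$first[6], BUNDLE_HELICES$last[6])
  tm6_atoms <- which(base$chain == "A" & base$resno %in% tm6_resnos)
  swing_rows <- (spec$swing_frame + 1L):nf
  if (spec$swing_delta != 0) {
    for (d in 1:3) {
      cols <- 3L * tm6_atoms - 3L + d
      xyz[swing_rows, cols] <- xyz[swing_rows, cols] + spec$swing_delta * u_swing[d]
    }
  }

  # salt bridge: place ASP 138 OD1/OD2 relative to the jittered ARG 75 NE
  ne_i <- atom_index_one(base, "A", sb_basic$resno, "NE")
  ca_acid <- atom_index_one(base, "A", sb_acidic$resno, "CA")
  od1_i <- atom_index_one(base, "A", sb_acidic$resno, "OD1")
  od2_i <- atom_index_one(base, "A", sb_acidic$resno, "OD2")
  he_i <- atom_index_one(base, "A", sb_basic$resno, "HE")
  ne_xyz <- xyz[, c(3L * ne_i - 2L, 3L * ne_i - 1L, 3L * ne_i)]
  dir_mat <- xyz[, c(3L * ca_acid - 2L, 3L * ca_acid - 1L, 3L * ca_acid)] - ne_xyz
  dir_mat <- dir_mat / sqrt(rowSums(dir_mat^2))
  sb_dist <- ifelse(spec$saltbridge_pattern, 3.2, 10.0)
  od1 <- ne_xyz + dir_mat * sb_dist
  perp <- cbind(-dir_mat[, 2], dir_mat[, 1], 0)
  perp <- perp / sqrt(rowSums(perp^2))
  od2 <- od1 + 1.1 * perp
  he <- ne_xyz + 1.0 * dir_mat  # N-H points at the acceptor: donor angle ~ 0
  xyz[, c(3L * od1_i - 2L, 3L * od1_i - 1L, 3L * od1_i)] <- od1
  xyz[, c(3L * od2_i - 2L, 3L * od2_i - 1L, 3L * od2_i)] <- od2
  xyz[, c(3L * he_i - 2L, 3L * he_i - 1L, 3L * he_i)] <- he

  # water bridges
  bridge_truth <- list()
  for (k in seq_along(spec$bridge_pairs)) {
    bp <- spec$bridge_pairs[[k]]
    r1 <- parse_residue_ref(bp$a)
    r2 <- parse_residue_ref(bp$b)
    ca1 <- atom_index_one(base, r1$chain, r1$resno, "CA")
    ca2 <- atom_index_one(base, r2$chain, r2$resno, "CA")
    tip1 <- atom_index_one(base, r1$chain, r1$resno,
                           polar_tip(base$resid[ca1]))
    tip2 <- atom_index_one(base, r2$chain, r2$resno,
                           polar_tip(base$resid[ca2]))
    p_ca1 <- xyz[, c(3L * ca1 - 2L, 3L * ca1 - 1L, 3L * ca1)]
    p_ca2 <- xyz[, c(3L * ca2 - 2L, 3L * ca2 - 1L, 3L * ca2)]
    d_ca <- sqrt(rowSums((p_ca2 - p_ca1)^2))
    offset <- pmin(2.5, d_ca / 2 - 1.0)
    sep <- d_ca - 2 * offset
    if (any(sep > 6.6)) {
      abort(sprintf(
        "generation error: bridge pair %s - %s is too far apart (%.1f A) for a single bridging water",
        bp$a, bp$b, max(d_ca)
      ))
    }
    dir12 <- (p_ca2 - p_ca1) / d_ca
    t1 <- p_ca1 + dir12 * offset
    t2 <- p_ca2 - dir12 * offset
    xyz[, c(3L * tip1 - 2L, 3L * tip1 - 1L, 3L * tip1)] <- t1
    xyz[, c(3L * tip2 - 2L, 3L * tip2 - 1L, 3L * tip2)] <- t2
    bridged <- runif(nf) < bp$occupancy
    wi <- na + 3L * (k - 1L) + 1L  # water O atom index
    mid <- (t1 + t2) / 2
    park <- sweep(mid, 2, c(0, 0, 45), "+")
    o_pos <- ifelse(matrix(bridged, nf, 3), mid, park)
    xyz[, c(3L * wi - 2L, 3L * wi - 1L, 3L * wi)] <- o_pos
    # rigid ideal water: hydrogens 0.9572 A from O, 104.52 deg apart
    hx <- 0.9572 * sin(104.52 * pi / 360)
    hz <- 0.9572 * cos(104.52 * pi / 360)
    xyz[, c(3L * (wi + 1L) - 2L, 3L * (wi + 1L) - 1L, 3L * (wi + 1L))] <-
      sweep(o_pos, 2, c(hx, 0, hz), "+")
    xyz[, c(3L * (wi + 2L) - 2L, 3L * (wi + 2L) - 1L, 3L * (wi + 2L))] <-
      sweep(o_pos, 2, c(-hx, 0, hz), "+")
    bridge_truth[[k]] <- list(
      a = bp$a, b = bp$b, target_occupancy = bp$occupancy,
      frames = which(bridged) - 1L,
      planted_occupancy = mean(bridged),
      water_resno = 1000L + k
    )
  }

  topo <- new_structure_model(atoms, box = c(70, 70, 120))
  traj <- new_trajectory(topo, xyz, frame_interval = spec$frame_interval)

  truth <- list(
    swing_frame = spec$swing_frame,
    swing_delta = spec$swing_delta,
    swing_direction = u_swing,
    bridges = bridge_truth,
    saltbridge_pattern = spec$saltbridge_pattern,
    saltbridge_pair = list(basic = "A/75", acidic = "A/138"),
    spec = spec
  )
  truth$self_check <- bundle_self_check(traj, truth)
  list(trajectory = traj, ground_truth = truth)
}

# Stretch ARG `basic` side chain along the line toward residue `acidic` so the
# guanidinium nitrogens sit within salt-bridge reach of plantable oxygens.
plant_arg_reach <- function(base, basic, acidic) {
  ca_b <- atom_index_one(base, "A", basic, "CA")
  ca_a <- atom_index_one(base, "A", acidic, "CA")
  dir <- normalize(c(base$x[ca_a] - base$x[ca_b],
                     base$y[ca_a] - base$y[ca_b],
                     base$z[ca_a] - base$z[ca_b]))
  dists <- c(CB = 1.53, CG = 2.9, CD = 4.3, NE = 5.7, CZ = 7.0,
             NH1 = 7.9, NH2 = 7.9)
  off <- c(NH1 = 0.9, NH2 = -0.9)
  perp <- normalize(c(-dir[2], dir[1], 0))
  for (nm in names(dists)) {
    i <- atom_index_one(base, "A", basic, nm)
    pos <- c(base$x[ca_b], base$y[ca_b], base$z[ca_b]) + dists[[nm]] * dir
    if (nm %in% names(off)) pos <- pos + off[[nm]] * perp
    base$x[i] <- pos[1]; base$y[i] <- pos[2]; base$z[i] <- pos[3]
  }
  # explicit HE on NE (donor hydrogen); repositioned per-frame later
  he <- base[atom_index_one(base, "A", basic, "NE"), ]
  he$elety <- "HE"; he$element <- "H"
  he$x <- he$x + dir[1]; he$y <- he$y + dir[2]; he$z <- he$z + dir[3]
  base <- dplyr::bind_rows(base, he)
  base$eleno <- seq_len(nrow(base))
  base
}

atom_index_one <- function(atoms, chain, resno, elety) {
  i <- which(atoms$chain == chain & atoms$resno == resno & atoms$elety == elety)
  if (length(i) != 1) {
    abort(sprintf("expected exactly one atom %s/%d/%s, found %d",
                  chain, resno, elety, length(i)))
  }
  i
}

# Per-frame distance between two atoms across the whole trajectory
atom_pair_dist <- function(xyz, i, j) {
  dx <- xyz[, 3L * i - 2L] - xyz[, 3L * j - 2L]
  dy <- xyz[, 3L * i - 1L] - xyz[, 3L * j - 1L]
  dz <- xyz[, 3L * i] - xyz[, 3L * j]
  sqrt(dx^2 + dy^2 + dz^2)
}

# Per-frame minimum distance from one atom to a set of atoms
atom_set_min_dist <- function(xyz, i, set) {
  d <- atom_pair_dist(xyz, i, set[1])
  for (j in set[-1]) d <- pmin(d, atom_pair_dist(xyz, i, j))
  d
}

# Re-measure every planted feature with plain distance checks; abort on
# violation so ground truth is guaranteed detectable.
bundle_self_check <- function(traj, truth) {
  atoms <- traj$topology$atoms
  xyz <- traj$xyz
  nf <- n_frames(traj)
  # bridges: water O within 3.5 A of a polar atom of both partners
  for (b in truth$bridges) {
    wi <- atom_index_one(atoms, "W", b$water_resno, "O")
    r1 <- parse_residue_ref(b$a)
    r2 <- parse_residue_ref(b$b)
    p1 <- which(atoms$chain == r1$chain & atoms$resno == r1$resno &
                  atoms$element %in% c("N", "O"))
    p2 <- which(atoms$chain == r2$chain & atoms$resno == r2$resno &
                  atoms$element %in% c("N", "O"))
    ok <- atom_set_min_dist(xyz, wi, p1) <= 3.5 &
      atom_set_min_dist(xyz, wi, p2) <= 3.5
    planted <- (seq_len(nf) - 1L) %in% b$frames
    if (!identical(as.logical(ok), planted)) {
      abort(sprintf("generation error: planted bridge %s-%s fails its own criterion",
                    b$a, b$b))
    }
  }
  # salt bridge: min basic-N to acidic-O distance
  ne <- which(atoms$chain == "A" & atoms$resno == 75 &
                atoms$elety %in% c("NE", "NH1", "NH2"))
  od <- which(atoms$chain == "A" & atoms$resno == 138 &
                atoms$elety %in% c("OD1", "OD2"))
  dmin <- rep(Inf, nf)
  for (i in ne) for (j in od) dmin <- pmin(dmin, atom_pair_dist(xyz, i, j))
  pat <- truth$saltbridge_pattern
  if (any(dmin[pat] > 3.4) || any(dmin[!pat] < 6)) {
    abort("generation error: planted salt bridge violates its distance template")
  }
  list(bridge_ok = TRUE, saltbridge_ok = TRUE,
       saltbridge_min_dist = range(dmin))
}

#' Synthetic inactive-state receptor reference model
#'
#' An idealised 7-helix bundle in GnRH1 receptor author numbering whose
#' 3.50-6.33 (R139 Calpha - T265 Calpha) distance is constructed to equal the
#' published inactive-state value of 7.9 A.  This is a synthetic stand-in
#' built entirely in code -- it is not the deposited crystal structure -- and
#' is intended as a fixed, self-contained anchor for the TM3-TM6 measurement
#' pipeline (BW-code resolution, Calpha extraction, distance).
#'
#' @param tm3_tm6 Target 3.50-6.33 Calpha distance in Angstrom (default 7.9).
#' @return A `structure_model`.
#' @export
gnrh1r_synthetic_reference <- function(tm3_tm6 = 7.9) {
  base <- build_bundle_base()
  ca350 <- atom_index_one(base, "A", 139L, "CA")
  ca633 <- atom_index_one(base, "A", 265L, "CA")
  d <- c(base$x[ca633] - base$x[ca350], base$y[ca633] - base$y[ca350],
         base$z[ca633] - base$z[ca350])
  d0 <- sqrt(sum(d^2))
  shift <- (tm3_tm6 - d0) * normalize(d)
  tm6 <- which(base$resno >= BUNDLE_HELICES$first[6] &
                 base$resno <= BUNDLE_HELICES$last[6])
  base$x[tm6] <- base$x[tm6] + shift[1]
  base$y[tm6] <- base$y[tm6] + shift[2]
  base$z[tm6] <- base$z[tm6] + shift[3]
  new_structure_model(base)
}
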