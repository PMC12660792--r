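#' Specification for a planted-truth docking decoy set
#'
#' Describes a synthetic decoy population organised in clusters with
#' per-cluster Gaussian score distributions (total score and interface
#' binding energy in REU, buried interface area in Angstrom^2) and planted
#' geometry: each cluster docks a toy 10-residue peptide at a distinct site
#' of a toy receptor, and only the native cluster's site places peptide
#' Cbeta atoms within contact range of important receptor residues.  The
#' defaults emulate a triage-ready set: a dominant native-like cluster that
#' satisfies every published survival criterion in expectation
#' (population above 1000, total score well below -620 REU, binding energy
#' well below -20 REU, important contacts formed) and two competitor
#' clusters that fail the population, score, and contact gates.
#'
#' @param n_clusters Number of clusters.
#' @param populations Integer vector of cluster populations (all >= 1).
#' @param score_means,score_sds Numeric `n_clusters x 3` matrices (columns
#'   `total_score`, `dg_binding`, `dsasa`).
#' @param native_cluster_index Which cluster is the planted near-native one.
#' @param site_jitter_sd Per-decoy positional noise of the docked peptide,
#'   Angstrom (default 0.3).
#' @param seed Integer seed.
#' @return A `decoy_plant_spec` list.
#' @export
decoy_plant_spec <- function(n_clusters = 3,
                             populations = c(1200L, 300L, 40L),
                             score_means = rbind(
                               c(-700, -35, 1400),
                               c(-600, -5, 900),
                               c(-655, -28, 1100)
                             ),
                             score_sds = rbind(
                               c(15, 4, 80),
                               c(15, 4, 80),
                               c(15, 4, 80)
                             ),
                             native_cluster_index = 1L,
                             site_jitter_sd = 0.3,
                             seed = 1L) {
  if (length(populations) != n_clusters) {
    abort("populations must have one entry per cluster")
  }
  if (any(populations < 1)) abort("populations must all be >= 1")
  score_means <- as.matrix(score_means)
  score_sds <- as.matrix(score_sds)
  if (!all(dim(score_means) == c(n_clusters, 3)) ||
      !all(dim(score_sds) == c(n_clusters, 3))) {
    abort("score_means and score_sds must be n_clusters x 3 matrices")
  }
  if (native_cluster_index < 1 || native_cluster_index > n_clusters) {
    abort("native_cluster_index out of range")
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         populations = as.integer(populations),
         score_means = score_means, score_sds = score_sds,
         native_cluster_index = as.integer(native_cluster_index),
         site_jitter_sd = site_jitter_sd, seed = as.integer(seed)),
    class = "decoy_plant_spec"
  )
}

# Toy receptor: the important residues on a ring (Cbeta pointing inward at
# the native site), plus generic residues near the second site so non-native
# decoys can form general-but-not-important contacts.
build_toy_receptor <- function() {
  imp <- gnrh1r_important_residues()
  n <- nrow(imp)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  ca <- cbind(9.5 * cos(ang), 9.5 * sin(ang), rep(0, n))
  cb <- cbind(6.5 * cos(ang), 6.5 * sin(ang), rep(0, n))
  rows_imp <- tibble(
    elety = rep(c("CA", "CB"), n),
    resid = rep(imp$resid, each = 2),
    chain = "A",
    resno = rep(imp$resno, each = 2),
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3]))
  )
  # generic (non-important) residues around the decoy site at (0, 0, -12)
  m <- 6L
  ang2 <- 2 * pi * (seq_len(m) - 1) / m
  ca2 <- cbind(6 * cos(ang2), 6 * sin(ang2), rep(-12, m))
  cb2 <- cbind(3.5 * cos(ang2), 3.5 * sin(ang2), rep(-12, m))
  rows_gen <- tibble(
    elety = rep(c("CA", "CB"), m),
    resid = "ALA", chain = "A",
    resno = rep(400L + seq_len(m), each = 2),
    x = as.vector(rbind(ca2[, 1], cb2[, 1])),
    y = as.vector(rbind(ca2[, 2], cb2[, 2])),
    z = as.vector(rbind(ca2[, 3], cb2[, 3]))
  )
  dplyr::bind_rows(rows_imp, rows_gen)
}

# Toy peptide: the GnRH decapeptide sequence (pyroglutamate modelled as GLU),
# compact ring of Calpha with inward Cbeta (Calpha only for glycine).
build_toy_peptide <- function() {
  seqs <- c("GLU", "HIS", "TRP", "SER", "TYR", "GLY", "LEU", "ARG", "PRO", "GLY")
  n <- length(seqs)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  ca <- cbind(2.5 * cos(ang), 2.5 * sin(ang), 0.4 * sin(2 * ang))
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- tibble(
      elety = "CA", resid = seqs[i], chain = "B", resno = i,
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3]
    )
    if (seqs[i] != "GLY") {
      cb <- ca[i, ] * c(1.5, 1.5, 1) / c(1, 1, 1)
      cb <- ca[i, ] + 1.2 * c(cos(ang[i]), sin(ang[i]), 0)
      rows[[length(rows) + 1L]] <- tibble(
        elety = "CB", resid = seqs[i], chain = "B", resno = i,
        x = cb[1], y = cb[2], z = cb[3]
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Docking sites, one per cluster (recycled if more clusters than sites):
# site 1 = native pocket centre, site 2 = generic-contact shelf, others far.
decoy_sites <- function(n) {
  base <- rbind(
    c(0, 0, 0),
    c(0, 0, -12),
    c(30, 0, 6),
    c(-30, 10, -6),
    c(0, -32, 10)
  )
  base[((seq_len(n) - 1) %% nrow(base)) + 1, , drop = FALSE]
}

#' Generate a planted-truth docking decoy set
#'
#' Draws per-cluster Gaussian scores with the spec's seed, builds one toy
#' two-chain structure per decoy (receptor chain A fixed; peptide chain B
#' docked at the cluster's site plus per-decoy jitter), and returns the
#' records, the in-memory structures, and the planted ground truth.  Decoy
#' order is shuffled (seeded) so downstream order-invariance is meaningful.
#' Only the native cluster's site places peptide Cbeta atoms within 5 A of
#' an important receptor residue; the second site touches only generic
#' residues; further sites are isolated.
#'
#' @param spec A [decoy_plant_spec()].
#' @param dir Optional directory: when given, a score table
#'   (`scores.tsv`), one PDB per decoy, and a ground-truth sidecar
#'   (`ground_truth.tsv`) are written there.
#' @return List with `decoys` (tibble of records), `structures` (named list
#'   of `structure_model`), and `ground_truth` (tibble `decoy_id`,
#'   `cluster`, `is_native`).
#' @export
gen_decoy_set <- function(spec = decoy_plant_spec(), dir = NULL) {
  stopifnot(inherits(spec, "decoy_plant_spec"))
  set.seed(spec$seed)
  receptor <- build_toy_receptor()
  peptide <- build_toy_peptide()
  sites <- decoy_sites(spec$n_clusters)
  n_total <- sum(spec$populations)
  cluster <- rep(seq_len(spec$n_clusters), spec$populations)
  ids <- sprintf("decoy_%05d", seq_len(n_total))
  decoys <- tibble(
    decoy_id = ids,
    total_score = rnorm(n_total, spec$score_means[cluster, 1],
                        spec$score_sds[cluster, 1]),
    dg_binding = rnorm(n_total, spec$score_means[cluster, 2],
                       spec$score_sds[cluster, 2]),
    dsasa = pmax(0, rnorm(n_total, spec$score_means[cluster, 3],
                          spec$score_sds[cluster, 3]))
  )
  structures <- vector("list", n_total)
  names(structures) <- ids
  jit <- matrix(rnorm(3L * n_total, sd = spec$site_jitter_sd), ncol = 3)
  for (i in seq_len(n_total)) {
    pep <- peptide
    shift <- sites[cluster[i], ] + jit[i, ]
    pep$x <- pep$x + shift[1]
    pep$y <- pep$y + shift[2]
    pep$z <- pep$z + shift[3]
    atoms <- dplyr::bind_rows(receptor, pep)
    atoms$eleno <- seq_len(nrow(atoms))
    atoms$element <- substr(atoms$elety, 1, 1)
    structures[[i]] <- new_structure_model(atoms)
  }
  perm <- sample.int(n_total)
  decoys <- decoys[perm, , drop = FALSE]
  structures <- structures[decoys$decoy_id]
  planted_cluster <- cluster[perm]
  truth <- tibble(
    decoy_id = ids[perm],
    cluster = planted_cluster,
    is_native = planted_cluster == spec$native_cluster_index
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(decoys$decoy_id, ".pdb"))
    for (i in seq_along(paths)) write_pdb(structures[[i]], paths[i])
    out <- decoys
    out$structure_path <- paths
    write_scorefile(out, file.path(dir, "scores.tsv"))
    readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"))
    decoys$structure_path <- paths
  }
  list(decoys = decoys, structures = structures, ground_truth = truth,
       spec = spec)
}
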