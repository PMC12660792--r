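#' Configuration for staged decoy triage
#'
#' Thresholds for the staged elimination and candidate-selection protocol
#' applied to docking decoy sets.  Defaults are the published criteria:
#' clusters with population below 50 are dropped first; clusters not
#' exceeding population 1000 are dropped next, along with decoys whose total
#' score exceeds -620 REU or whose interface binding energy exceeds 0 REU;
#' decoys without at least one general Cbeta-Cbeta contact are dropped; and
#' final candidates must show at least one important contact and binding
#' energy below -20 REU, ranked by important-contact count (descending) then
#' binding energy (ascending).
#'
#' @param pop_min_stage1 Minimum cluster population at the first gate
#'   (strict: population `< pop_min_stage1` is eliminated; default 50).
#' @param pop_min_stage2 Population that must be exceeded at the second gate
#'   (strict: population `<= pop_min_stage2` is eliminated; default 1000).
#' @param total_score_max Decoys with total score above this survive
#'   elimination only if `total_score <= total_score_max` (default -620 REU).
#' @param dg_max_stage2,dg_max_stage4 Binding-energy ceilings at the second
#'   and final gates (defaults 0 and -20 REU; strict `>` eliminates).
#' @param contact_cutoff Contact distance cutoff, Angstrom (default 5).
#' @param min_general_contacts,min_important_contacts Minimum contact counts
#'   (defaults 1 and 1; set to 0 to disable the corresponding gate).
#' @param important_residues Receptor residues counted as important contacts.
#' @param receptor_chain,peptide_chain Chain ids in decoy structures.
#' @param alpha Significance level for the reported cluster statistics.
#' @param rmsd_threshold Clustering radius in Angstrom for [cluster_decoys()].
#' @param top_k Number of final candidates to return (default 2).
#' @return A `triage_config` list.
#' @export
triage_config <- function(pop_min_stage1 = 50, pop_min_stage2 = 1000,
                          total_score_max = -620, dg_max_stage2 = 0,
                          dg_max_stage4 = -20, contact_cutoff = 5,
                          min_general_contacts = 1, min_important_contacts = 1,
                          important_residues = gnrh1r_important_residues(),
                          receptor_chain = "A", peptide_chain = "B",
                          alpha = 0.05, rmsd_threshold = 2, top_k = 2) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (contact_cutoff <= 0) abort("contact_cutoff must be positive")
  structure(
    list(pop_min_stage1 = pop_min_stage1, pop_min_stage2 = pop_min_stage2,
         total_score_max = total_score_max, dg_max_stage2 = dg_max_stage2,
         dg_max_stage4 = dg_max_stage4, contact_cutoff = contact_cutoff,
         min_general_contacts = min_general_contacts,
         min_important_contacts = min_important_contacts,
         important_residues = important_residues,
         receptor_chain = receptor_chain, peptide_chain = peptide_chain,
         alpha = alpha, rmsd_threshold = rmsd_threshold, top_k = top_k),
    class = "triage_config"
  )
}

#' Greedy centroid clustering of decoy structures
#'
#' A deterministic stand-in for energy-based decoy clustering: decoys are
#' visited in ascending total score; each is assigned to the first existing
#' cluster whose seed structure lies within `rmsd_threshold` (least-squares
#' superposed RMSD over shared backbone atoms, falling back to Calpha when a
#' full backbone is absent), otherwise it founds a new cluster seeded by
#' itself.
#'
#' @param decoys Tibble of decoy records (needs `decoy_id`, `total_score`).
#' @param structures Named list of `structure_model`s keyed by `decoy_id`,
#'   all sharing one atom ordering.
#' @param rmsd_threshold Clustering radius, Angstrom.
#' @return `decoys` with a `cluster_id` column (integer, in founding order).
#' @export
cluster_decoys <- function(decoys, structures, rmsd_threshold = 2) {
  ids <- decoys$decoy_id
  if (!all(ids %in% names(structures))) {
    abort("every decoy needs a structure in `structures`")
  }
  sel0 <- NULL
  coords <- lapply(ids, function(id) {
    m <- structures[[id]]
    sel <- select_atoms(m, elety = c("N", "CA", "C", "O"))
    if (length(sel) == 0) sel <- select_atoms(m, elety = "CA")
    as.vector(t(model_coords(m, sel)))
  })
  n_xyz <- lengths(coords)
  if (length(unique(n_xyz)) != 1) {
    abort("decoy structures have inconsistent atom counts")
  }
  ord <- order(decoys$total_score, decoys$decoy_id)
  seeds <- list()
  assignment <- integer(length(ids))
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(seeds)) {
      r <- bio3d::rmsd(seeds[[k]], coords[[i]], fit = TRUE)
      if (r <= rmsd_threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds[[length(seeds) + 1L]] <- coords[[i]]
      assignment[i] <- length(seeds)
    }
  }
  decoys$cluster_id <- assignment
  decoys
}

stage_report <- function(stage, label, survivors, eliminated, stats = NULL) {
  structure(
    list(stage = stage, label = label, survivors = survivors,
         eliminated = eliminated, stats = stats),
    class = "stage_report"
  )
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("<stage_report> stage %d (%s): %d survive, %d eliminated\n",
              x$stage, x$label, length(x$survivors), nrow(x$eliminated)))
  invisible(x)
}

#' Stage 1: cluster-population filter
#'
#' Eliminates every decoy belonging to a cluster whose population is strictly
#' below `pop_min_stage1`.
#'
#' @param decoys Tibble with `decoy_id` and `cluster_id`.
#' @param config A [triage_config()].
#' @return A `stage_report`.
#' @export
stage1_population_filter <- function(decoys, config = triage_config()) {
  if (nrow(decoys) == 0) abort("no decoys to filter")
  pops <- table(decoys$cluster_id)
  small <- as.integer(names(pops)[pops < config$pop_min_stage1])
  out <- decoys$cluster_id %in% small
  stage_report(
    1L, "cluster population",
    survivors = decoys$decoy_id[!out],
    eliminated = tibble(
      decoy_id = decoys$decoy_id[out],
      reason = sprintf("population<%g", config$pop_min_stage1)
    )
  )
}

#' Stage 2: population gate, cluster statistics and score filters
#'
#' Eliminates decoys in clusters whose population does not exceed
#' `pop_min_stage2`, then eliminates decoys with `total_score >
#' total_score_max` or `dg_binding > dg_max_stage2`.  For every pair of
#' surviving clusters and every score metric it also reports (without using
#' for elimination) the KS normality statistic per cluster, the two-sided
#' Mann-Whitney U with Bonferroni adjustment over the whole family
#' (pairs x metrics), and the rank-biserial effect size.
#'
#' @inheritParams stage1_population_filter
#' @return A `stage_report` whose `stats` element holds the pairwise test
#'   table (or `NULL` when fewer than two clusters survive the gate).
#' @export
stage2_statistical_filter <- function(decoys, config = triage_config()) {
  if (nrow(decoys) == 0) abort("no decoys to filter")
  pops <- table(decoys$cluster_id)
  small <- as.integer(names(pops)[pops <= config$pop_min_stage2])
  out_pop <- decoys$cluster_id %in% small
  surv <- decoys[!out_pop, , drop = FALSE]
  stats_tbl <- cluster_pair_stats(surv, config)
  out_ts <- !out_pop & decoys$total_score > config$total_score_max
  out_dg <- !out_pop & !out_ts & decoys$dg_binding > config$dg_max_stage2
  eliminated <- dplyr::bind_rows(
    tibble(decoy_id = decoys$decoy_id[out_pop],
           reason = sprintf("population<=%g", config$pop_min_stage2)),
    tibble(decoy_id = decoys$decoy_id[out_ts],
           reason = sprintf("total_score>%g", config$total_score_max)),
    tibble(decoy_id = decoys$decoy_id[out_dg],
           reason = sprintf("dg_binding>%g", config$dg_max_stage2))
  )
  stage_report(
    2L, "cluster statistics and score gates",
    survivors = setdiff(decoys$decoy_id, eliminated$decoy_id),
    eliminated = eliminated,
    stats = stats_tbl
  )
}

cluster_pair_stats <- function(decoys, config) {
  metrics <- c("total_score", "dg_binding", "dsasa")
  clusters <- sort(unique(decoys$cluster_id))
  if (length(clusters) < 2) return(NULL)
  pairs <- utils::combn(clusters, 2)
  m_family <- ncol(pairs) * length(metrics)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    c1 <- pairs[1, j]; c2 <- pairs[2, j]
    for (metric in metrics) {
      s1 <- decoys[[metric]][decoys$cluster_id == c1]
      s2 <- decoys[[metric]][decoys$cluster_id == c2]
      if (length(s1) < 2 || length(s2) < 2) {
        rows[[length(rows) + 1L]] <- tibble(
          cluster_a = c1, cluster_b = c2, metric = metric,
          U = NA_real_, p_raw = NA_real_, p_bonferroni = NA_real_,
          effect_size = NA_real_, ks_D_a = NA_real_, ks_D_b = NA_real_,
          skipped = TRUE
        )
        next
      }
      mw <- mann_whitney_u(s1, s2)
      ks_a <- if (length(s1) >= 4 && sd(s1) > 0) ks_normality(s1)$D else NA_real_
      ks_b <- if (length(s2) >= 4 && sd(s2) > 0) ks_normality(s2)$D else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        cluster_a = c1, cluster_b = c2, metric = metric,
        U = mw$U, p_raw = mw$p,
        p_bonferroni = bonferroni_adjust(mw$p, m_family),
        effect_size = effect_size(mw$U, mw$n1, mw$n2),
        ks_D_a = ks_a, ks_D_b = ks_b, skipped = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "m_family") <- m_family
  attr(out, "alpha") <- config$alpha
  out
}

#' Stage 3: general-contact filter
#'
#' Eliminates decoys with fewer than `min_general_contacts` inter-chain
#' contacts.
#'
#' @param decoys Tibble with `decoy_id` and `n_general` (see
#'   [add_contact_counts()]).
#' @param config A [triage_config()].
#' @return A `stage_report`.
#' @export
stage3_contact_filter <- function(decoys, config = triage_config()) {
  out <- decoys$n_general < config$min_general_contacts
  stage_report(
    3L, "general contacts",
    survivors = decoys$decoy_id[!out],
    eliminated = tibble(
      decoy_id = decoys$decoy_id[out],
      reason = sprintf("general_contacts<%g", config$min_general_contacts)
    )
  )
}

#' Stage 4: important contacts, binding-energy gate and candidate ranking
#'
#' Eliminates decoys with fewer than `min_important_contacts` important
#' contacts or `dg_binding > dg_max_stage4`, then ranks survivors by
#' important-contact count (descending), binding energy (ascending), total
#' score (ascending), and decoy id (lexicographic) and returns the top `k`.
#'
#' @param decoys Tibble with `decoy_id`, `dg_binding`, `total_score`,
#'   `n_important`.
#' @param config A [triage_config()].
#' @param k Number of candidates to keep (default `config$top_k`).
#' @return A `stage_report` with an additional `candidates` element (tibble,
#'   possibly empty, with a `rank` column).
#' @export
stage4_candidate_selection <- function(decoys, config = triage_config(),
                                       k = config$top_k) {
  out_imp <- if (config$min_important_contacts > 0) {
    decoys$n_important < config$min_important_contacts
  } else {
    rep(FALSE, nrow(decoys))
  }
  out_dg <- !out_imp & decoys$dg_binding > config$dg_max_stage4
  eliminated <- dplyr::bind_rows(
    tibble(decoy_id = decoys$decoy_id[out_imp],
           reason = sprintf("important_contacts<%g", config$min_important_contacts)),
    tibble(decoy_id = decoys$decoy_id[out_dg],
           reason = sprintf("dg_binding>%g", config$dg_max_stage4))
  )
  surv <- decoys[!(out_imp | out_dg), , drop = FALSE]
  surv <- dplyr::arrange(surv, dplyr::desc(.data$n_important),
                         .data$dg_binding, .data$total_score, .data$decoy_id)
  candidates <- head(surv, k)
  if (nrow(candidates) > 0) candidates$rank <- seq_len(nrow(candidates))
  rep4 <- stage_report(
    4L, "candidate selection",
    survivors = surv$decoy_id,
    eliminated = eliminated
  )
  rep4$candidates <- candidates
  rep4$status <- if (nrow(surv) == 0) "no survivors" else "ok"
  rep4
}

#' Attach contact counts to decoy records
#'
#' Computes [compute_contacts()] for each decoy and adds `n_general` and
#' `n_important` columns.  Decoys already carrying both columns are returned
#' unchanged.
#'
#' @param decoys Tibble of decoy records.
#' @param structures Named list of `structure_model`s keyed by decoy id.
#' @param config A [triage_config()].
#' @return `decoys` with contact-count columns.
#' @export
add_contact_counts <- function(decoys, structures, config = triage_config()) {
  if (all(c("n_general", "n_important") %in% names(decoys))) return(decoys)
  if (is.null(structures)) {
    abort("contact filtering needs decoy structures (or precomputed n_general/n_important columns)")
  }
  important <- config$important_residues
  if (is.data.frame(important)) important <- important$resno
  # decoy structures share one atom layout: resolve representative-atom
  # indices once on the first structure and reuse when layouts match
  first <- structures[[decoys$decoy_id[1]]]
  pep_idx <- rep_atom_indices(first, config$peptide_chain)
  rec_idx <- rep_atom_indices(first, config$receptor_chain)
  rec_imp <- first$atoms$resno[rec_idx] %in% important
  cutoff2 <- config$contact_cutoff^2
  layout <- paste(first$atoms$chain, first$atoms$resno, first$atoms$elety)
  counts <- vapply(decoys$decoy_id, function(id) {
    m <- structures[[id]]
    if (n_atoms(m) != n_atoms(first) ||
        !identical(paste(m$atoms$chain, m$atoms$resno, m$atoms$elety), layout)) {
      rep_ <- compute_contacts(
        m, peptide_chain = config$peptide_chain,
        receptor_chain = config$receptor_chain,
        contact_cutoff = config$contact_cutoff,
        important_residues = important
      )
      return(c(attr(rep_, "n_general"), attr(rep_, "n_important")))
    }
    pm <- cbind(m$atoms$x[pep_idx], m$atoms$y[pep_idx], m$atoms$z[pep_idx])
    rm_ <- cbind(m$atoms$x[rec_idx], m$atoms$y[rec_idx], m$atoms$z[rec_idx])
    d2 <- outer(rowSums(pm^2), rowSums(rm_^2), "+") - 2 * pm %*% t(rm_)
    hit <- d2 < cutoff2
    c(sum(hit), sum(hit[, rec_imp]))
  }, numeric(2))
  decoys$n_general <- counts[1, ]
  decoys$n_important <- counts[2, ]
  decoys
}

#' Run the full staged triage protocol
#'
#' Applies the four elimination stages in order -- cluster population,
#' population gate with cluster statistics and score filters, general
#' contacts, important contacts with binding-energy gate and ranking -- and
#' returns every stage report, the final ranked candidates, and a complete
#' audit log of eliminations with reasons.  Survivor sets are nested across
#' stages.  When both contact gates are disabled (minimum counts of 0) the
#' contact stages pass decoys through without needing structures.
#'
#' @param decoys Tibble of decoy records.  If `cluster_id` is absent,
#'   [cluster_decoys()] is run first (requires `structures`).
#' @param config A [triage_config()].
#' @param structures Named list of `structure_model`s keyed by decoy id
#'   (required for clustering and contact computation unless precomputed).
#' @return A `triage_result`: list with `stages`, `candidates`, `audit`,
#'   `decoys` (annotated input) and `config`.
#' @export
run_triage <- function(decoys, config = triage_config(), structures = NULL) {
  if (nrow(decoys) == 0) abort("empty decoy set")
  if (!"cluster_id" %in% names(decoys) || all(is.na(decoys$cluster_id))) {
    if (is.null(structures)) {
      abort("decoys carry no cluster_id; supply `structures` for clustering")
    }
    decoys <- cluster_decoys(decoys, structures, config$rmsd_threshold)
  }
  decoys <- dplyr::arrange(decoys, .data$decoy_id)

  s1 <- stage1_population_filter(decoys, config)
  d1 <- decoys[decoys$decoy_id %in% s1$survivors, , drop = FALSE]

  s2 <- stage2_statistical_filter(d1, config)
  d2 <- d1[d1$decoy_id %in% s2$survivors, , drop = FALSE]

  contact_gates_on <- config$min_general_contacts > 0 ||
    config$min_important_contacts > 0
  if (contact_gates_on) {
    d2 <- add_contact_counts(d2, structures, config)
  } else {
    if (!"n_general" %in% names(d2)) d2$n_general <- NA_real_
    if (!"n_important" %in% names(d2)) d2$n_important <- NA_real_
  }

  s3 <- if (config$min_general_contacts > 0) {
    stage3_contact_filter(d2, config)
  } else {
    stage_report(3L, "general contacts (disabled)", d2$decoy_id,
                 tibble(decoy_id = character(0), reason = character(0)))
  }
  d3 <- d2[d2$decoy_id %in% s3$survivors, , drop = FALSE]

  s4 <- stage4_candidate_selection(d3, config)

  audit <- dplyr::bind_rows(
    dplyr::mutate(s1$eliminated, stage = 1L, label = s1$label),
    dplyr::mutate(s2$eliminated, stage = 2L, label = s2$label),
    dplyr::mutate(s3$eliminated, stage = 3L, label = s3$label),
    dplyr::mutate(s4$eliminated, stage = 4L, label = s4$label)
  )
  structure(
    list(stages = list(s1, s2, s3, s4), candidates = s4$candidates,
         audit = audit, decoys = decoys, config = config,
         status = s4$status),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf(
    "<triage_result> %d decoys in, %d eliminated, %d candidate(s)\n",
    nrow(x$decoys), nrow(x$audit), nrow(x$candidates)
  ))
  for (s in x$stages) print(s)
  invisible(x)
}
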