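test_that("greedy clustering handles identical, separated, and planted structures", {
  atoms <- atom_table(rep(c("CA", "CB"), 3), rep("ALA", 6), "A", rep(1:3, each = 2))
  co <- matrix(rnorm(18), ncol = 3)
  mk <- function(shift) {
    # displace one residue only: an internal deformation that least-squares
    # superposition cannot remove (a whole-structure shift would be fitted out)
    a <- atoms
    a$x <- co[, 1]; a$y <- co[, 2]; a$z <- co[, 3]
    a$x[5:6] <- a$x[5:6] + shift
    new_structure_model(a)
  }
  # four identical structures -> one cluster
  decs <- tibble::tibble(decoy_id = paste0("d", 1:4), total_score = c(-5, -4, -3, -2))
  structs <- setNames(lapply(rep(0, 4), mk), decs$decoy_id)
  expect_equal(unique(cluster_decoys(decs, structs, 2)$cluster_id), 1L)
  # two structures 20 A apart with threshold 2 -> singletons
  decs2 <- tibble::tibble(decoy_id = c("a", "b"), total_score = c(-5, -4))
  structs2 <- setNames(list(mk(0), mk(20)), decs2$decoy_id)
  expect_equal(sort(cluster_decoys(decs2, structs2, 2)$cluster_id), c(1L, 2L))

  # planted three-cluster geometry: recovered partition equals ground truth
  out <- gen_decoy_set(decoy_plant_spec(populations = c(25L, 15L, 10L), seed = 6))
  cl <- cluster_decoys(out$decoys, out$structures, 2)
  truth <- out$ground_truth$cluster[match(cl$decoy_id, out$ground_truth$decoy_id)]
  tab <- table(cl$cluster_id, truth)
  # every recovered cluster maps to exactly one planted cluster and vice versa
  expect_equal(sum(tab > 0), 3)
  expect_equal(unname(apply(tab, 1, function(r) sum(r > 0))), rep(1L, 3))
})

test_that("population gates use the published strict inequalities", {
  decs <- tibble::tibble(
    decoy_id = sprintf("d%04d", 1:2121),
    cluster_id = rep(1:3, c(2022, 50, 49)),
    total_score = -700, dg_binding = -30, dsasa = 1000
  )
  s1 <- stage1_population_filter(decs, triage_config())
  gone <- unique(decs$cluster_id[decs$decoy_id %in% s1$eliminated$decoy_id])
  expect_equal(gone, 3L)                      # population 49 < 50 eliminated
  expect_equal(length(s1$survivors), 2072)    # 50 survives the strict gate
  expect_true(all(s1$eliminated$reason == "population<50"))
  # survivors and eliminated partition the input
  expect_setequal(c(s1$survivors, s1$eliminated$decoy_id), decs$decoy_id)

  all_big <- dplyr::mutate(decs, cluster_id = rep(1:2, c(1100, 1021)))
  expect_equal(nrow(stage1_population_filter(all_big, triage_config())$eliminated), 0)
})

test_that("score gates eliminate at the published thresholds", {
  decs <- tibble::tibble(
    decoy_id = c(sprintf("pad%04d", 1:1100), "hot", "warm", "good"),
    cluster_id = 1L,
    total_score = c(rep(-700, 1100), -600, -700, -700),
    dg_binding = c(rep(-30, 1100), -30, 5, -25),
    dsasa = 1000
  )
  s2 <- stage2_statistical_filter(decs, triage_config())
  el <- s2$eliminated
  expect_equal(el$reason[el$decoy_id == "hot"], "total_score>-620")
  expect_equal(el$reason[el$decoy_id == "warm"], "dg_binding>0")
  expect_true("good" %in% s2$survivors)
})

test_that("cluster statistics are reported for surviving cluster pairs", {
  set.seed(42)
  decs <- tibble::tibble(
    decoy_id = sprintf("d%05d", 1:2400),
    cluster_id = rep(1:2, each = 1200),
    total_score = rnorm(2400, rep(c(-700, -680), each = 1200), 10),
    dg_binding = rnorm(2400, rep(c(-35, -30), each = 1200), 3),
    dsasa = rnorm(2400, 1200, 60)
  )
  s2 <- stage2_statistical_filter(decs, triage_config())
  st <- s2$stats
  expect_equal(nrow(st), 3)  # one pair x three metrics
  expect_equal(attr(st, "m_family"), 3)
  expect_true(all(st$p_bonferroni >= st$p_raw))
  expect_true(all(abs(st$effect_size) <= 1))
  # clearly shifted metrics are flagged, the unshifted one is not
  expect_lt(st$p_bonferroni[st$metric == "total_score"], 0.05)
  expect_gt(st$p_bonferroni[st$metric == "dsasa"], 0.05)
})

test_that("mann_whitney_u matches exhaustive enumeration on tie-free samples", {
  # worked example: complete separation of two pairs
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(effect_size(mw$U, 2, 2), 1)

  set.seed(7)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      vals <- sample(seq_len(50), n1 + n2)  # tie-free
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      oracle <- mwu_enumeration_oracle(x, y)
      got <- mann_whitney_u(x, y)
      expect_equal(got$U, oracle$U, info = sprintf("n1=%d n2=%d", n1, n2))
      expect_equal(got$p, oracle$p, tolerance = 1e-10,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("mann_whitney_u degenerates and approximates sensibly", {
  expect_true(mann_whitney_u(rep(2, 3), rep(2, 4))$degenerate)
  expect_equal(mann_whitney_u(rep(2, 3), rep(2, 4))$p, 1)
  expect_gt(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
  # large-sample approximation close to the exact enumeration at n1=n2=8
  set.seed(13)
  vals <- sample(seq_len(100), 16)
  x <- vals[1:8]; y <- vals[9:16]
  exact <- mann_whitney_u(x, y)$p
  approx <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
  expect_lt(abs(exact - approx), 0.02)
})

test_that("bonferroni correction multiplies, caps, and validates m", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04)), c(0.4, 0.08))
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "smaller")
})

test_that("effect size modes behave as documented", {
  expect_equal(effect_size(12, 4, 6), 0)        # U = n1 n2 / 2
  expect_equal(effect_size(0, 3, 7), 1)         # complete separation
  expect_equal(effect_size(0, 5, 3, mode = "as_printed"), 1)
  expect_error(effect_size(0, 4, 4, mode = "as_printed"), "zero")
  # antisymmetry: swapping samples maps U -> n1 n2 - U and EF -> -EF
  for (u in c(0, 3, 7, 12)) {
    expect_equal(effect_size(u, 4, 5), -effect_size(4 * 5 - u, 5, 4))
  }
})

test_that("KS normality statistic matches a brute-force empirical-CDF computation", {
  grid <- qnorm(ppoints(100))
  res <- ks_normality(grid)
  expect_lt(res$D, 0.02)
  expect_identical(res$D, ks_normality(grid)$D)

  set.seed(5)
  bimodal <- c(rnorm(100, 0, 0.05), rnorm(100, 10, 0.05))
  rb <- ks_normality(bimodal)
  expect_lt(rb$p, 0.05)
  expect_equal(rb$D, ks_D_brute(bimodal), tolerance = 1e-12)
  expect_error(ks_normality(rep(1, 10)), "variance")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
})

test_that("contacts use representative atoms with the 5 A cutoff boundary", {
  atoms <- dplyr::bind_rows(
    atom_table(c("CA", "CB"), "TRP", "A", c(280, 280)),
    atom_table(c("CA", "CB"), "ALA", "A", c(401, 401)),
    atom_table(c("CA", "CB"), "TYR", "B", c(5, 5)),
    atom_table("CA", "GLY", "B", 6)
  )
  atoms$eleno <- seq_len(nrow(atoms))
  # receptor W280 CB at origin; peptide TYR CB at 4.9; GLY CA at 5.1 from A401 CB
  atoms$x <- c(-3, 0, 20, 20.5, -3, 4.9, 25.6)
  atoms$y <- 0; atoms$z <- 0
  m <- new_structure_model(atoms)
  rep_ <- compute_contacts(m)
  expect_equal(attr(rep_, "n_general"), 1)
  expect_equal(attr(rep_, "n_important"), 1)  # W280 is on the important list
  expect_equal(rep_$receptor_resno, 280)

  # at 5.1 A there is no contact
  atoms$x[6] <- 5.1
  expect_equal(attr(compute_contacts(new_structure_model(atoms)), "n_general"), 0)

  # glycine is represented by CA; a 4.9 A CA-CB pair counts
  atoms$x[7] <- 24.9  # GLY CA vs A401 CB at 20.5 -> 4.4 A
  rep2 <- compute_contacts(new_structure_model(atoms))
  expect_equal(rep2$peptide_resid, "GLY")
  expect_false(rep2$important)

  # a non-glycine residue without CB is an error, not a CA fallback
  atoms_bad <- atoms[-6, ]
  expect_error(compute_contacts(new_structure_model(atoms_bad)), "TYR")
})

test_that("contact and candidate gates apply the published boundaries", {
  decs <- tibble::tibble(
    decoy_id = c("none", "one"),
    n_general = c(0, 1), n_important = c(0, 1),
    dg_binding = c(-30, -30), total_score = c(-700, -700)
  )
  s3 <- stage3_contact_filter(decs, triage_config())
  expect_equal(s3$eliminated$decoy_id, "none")
  expect_equal(s3$survivors, "one")

  decs4 <- tibble::tibble(
    decoy_id = c("shallow", "deep", "deeper", "no_imp"),
    n_general = 2, n_important = c(1, 2, 2, 0),
    dg_binding = c(-19, -25, -30, -40), total_score = -700
  )
  s4 <- stage4_candidate_selection(decs4, triage_config(), k = 2)
  expect_setequal(s4$eliminated$decoy_id, c("shallow", "no_imp"))
  expect_equal(s4$candidates$decoy_id, c("deeper", "deep"))  # lowest dG first
})

test_that("candidate ties break deterministically and triage is order-invariant", {
  decs <- tibble::tibble(
    decoy_id = c("b", "a", "c"),
    n_general = 1, n_important = 1,
    dg_binding = c(-30, -30, -30),
    total_score = c(-700, -700, -690)
  )
  s4 <- stage4_candidate_selection(decs, triage_config(), k = 3)
  expect_equal(s4$candidates$decoy_id, c("a", "b", "c"))

  out <- gen_decoy_set(decoy_plant_spec(populations = c(40L, 20L, 10L), seed = 2))
  cfg <- triage_config(pop_min_stage1 = 5, pop_min_stage2 = 30)
  r1 <- run_triage(out$decoys, cfg, out$structures)
  shuffled <- out$decoys[rev(seq_len(nrow(out$decoys))), ]
  r2 <- run_triage(shuffled, cfg, out$structures)
  expect_equal(r1$candidates$decoy_id, r2$candidates$decoy_id)
  expect_equal(dplyr::arrange(r1$audit, decoy_id), dplyr::arrange(r2$audit, decoy_id))
})

test_that("triage nests survivor sets, partitions eliminations, and honours disabled gates", {
  out <- gen_decoy_set(decoy_plant_spec(populations = c(40L, 20L, 10L), seed = 11))
  cfg <- triage_config(pop_min_stage1 = 15, pop_min_stage2 = 30)
  res <- run_triage(out$decoys, cfg, out$structures)
  survivors <- lapply(res$stages, function(s) s$survivors)
  for (k in 2:4) {
    expect_true(all(survivors[[k]] %in% survivors[[k - 1]]))
  }
  expect_equal(sort(c(res$stages[[4]]$survivors, res$audit$decoy_id)),
               sort(out$decoys$decoy_id))
  expect_equal(anyDuplicated(res$audit$decoy_id), 0)
  top <- res$candidates$decoy_id[1]
  expect_true(out$ground_truth$is_native[match(top, out$ground_truth$decoy_id)])

  # all gates disabled: everything survives
  open_cfg <- triage_config(pop_min_stage1 = 0, pop_min_stage2 = 0,
                            total_score_max = Inf, dg_max_stage2 = Inf,
                            dg_max_stage4 = Inf, min_general_contacts = 0,
                            min_important_contacts = 0, top_k = 1000)
  res_open <- run_triage(out$decoys, open_cfg, out$structures)
  expect_setequal(res_open$stages[[4]]$survivors, out$decoys$decoy_id)
  expect_equal(nrow(res_open$audit), 0)

  # rerun determinism
  res_b <- run_triage(out$decoys, cfg, out$structures)
  expect_equal(res$candidates, res_b$candidates)
  expect_equal(res$audit, res_b$audit)
})
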