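test_that("panel validation enforces the reference/lineage contract", {
  p <- hub_panel()
  expect_setequal(p$myeloid, c("KIT", "HGF", "ANPEP", "CXCL2"))
  expect_equal(p$reference, "PROM1")
  expect_true("CXCL2" %in% p$B) # shared gene is legitimate
  expect_error(hub_panel(reference = "KIT"), "must not belong")
  expect_error(hub_panel(B = character(0)), "non-empty")
})

test_that("cohort-mean normalization has unit row means and scale invariance", {
  m <- rbind(G1 = c(2, 4), G2 = c(3, 3))
  colnames(m) <- c("S1", "S2")
  nm <- normalize_to_cohort_mean(m)
  expect_equal(unname(nm["G1", ]), c(2 / 3, 4 / 3))
  expect_equal(unname(nm["G2", ]), c(1, 1))
  expect_equal(unname(rowMeans(nm)), c(1, 1))
  scaled <- m; scaled["G1", ] <- m["G1", ] * 37
  expect_equal(normalize_to_cohort_mean(scaled), nm)
  bad <- m; bad["G1", 1] <- 0
  expect_error(normalize_to_cohort_mean(bad), "non-positive")
})

test_that("TES is the reference ratio and is exactly 1 for the reference", {
  m <- random_panel_matrix(10, seed = 2)
  nm <- normalize_to_cohort_mean(m)
  tes <- transformed_expression_scores(nm)
  expect_true(all(tes["PROM1", ] == 1))
  expect_equal(tes["KIT", "S03"], nm["KIT", "S03"] / nm["PROM1", "S03"],
               tolerance = 1e-15)
  # worked ratio: normalized 0.8 over reference 0.4 -> TES 2
  nm2 <- rbind(G = c(0.8, 1.2), PROM1 = c(0.4, 1.6))
  colnames(nm2) <- c("S1", "S2")
  tes2 <- transformed_expression_scores(nm2)
  expect_equal(unname(tes2["G", "S1"]), 2)
  expect_error(transformed_expression_scores(nm2[1, , drop = FALSE]), "absent")
})

test_that("lineage scores are the published geometric means", {
  tes <- c(KIT = 1, HGF = 1, ANPEP = 1, CXCL2 = 1, NT5E = 1, CDH2 = 1,
           CD33 = 1, IL1B = 1, PROM1 = 1)
  expect_equal(lineage_scores(tes),
               c(myeloid = 1, B = 1, T = 1, unidentified = 1))
  tes["KIT"] <- 16
  expect_equal(lineage_scores(tes)[["myeloid"]], 2) # 16^(1/4)
  tes["KIT"] <- 1; tes["NT5E"] <- 4
  sc <- lineage_scores(tes)
  expect_equal(sc[["B"]], 2) # 4^(1/2)
  expect_equal(sc[["myeloid"]], 1) # shared CXCL2 untouched
  tes["CDH2"] <- 3
  expect_equal(lineage_scores(tes)[["T"]], 3)
  expect_error(lineage_scores(tes[-1]), "missing TES")
})

test_that("geometric-mean scores are bounded by their panel TES range", {
  set.seed(9)
  panel <- hub_panel()
  for (i in 1:50) {
    tes <- stats::setNames(exp(rnorm(9)),
                           c("KIT", "HGF", "ANPEP", "CXCL2", "NT5E", "CDH2",
                             "CD33", "IL1B", "PROM1"))
    sc <- lineage_scores(tes, panel)
    for (l in c("myeloid", "B", "T", "unidentified")) {
      expect_gte(sc[[l]], min(tes[panel[[l]]]) - 1e-12)
      expect_lte(sc[[l]], max(tes[panel[[l]]]) + 1e-12)
    }
  }
})

test_that("raising one gene's TES raises exactly its lineages' scores", {
  base <- stats::setNames(rep(1, 9),
                          c("KIT", "HGF", "ANPEP", "CXCL2", "NT5E", "CDH2",
                            "CD33", "IL1B", "PROM1"))
  s0 <- lineage_scores(base)
  up <- base; up["CXCL2"] <- 2
  s1 <- lineage_scores(up)
  expect_gt(s1[["myeloid"]], s0[["myeloid"]])
  expect_gt(s1[["B"]], s0[["B"]])
  expect_equal(s1[["T"]], s0[["T"]])
  expect_equal(s1[["unidentified"]], s0[["unidentified"]])
})

test_that("lineage assignment follows the within-10%-of-maximum rule", {
  expect_equal(assign_lineages(c(myeloid = 2, B = 1, T = 1, unidentified = 1)),
               "myeloid")
  expect_setequal(
    assign_lineages(c(myeloid = 1, B = 0.95, T = 0.5, unidentified = 0.5)),
    c("myeloid", "B"))
  expect_setequal(assign_lineages(c(myeloid = 1, B = 1, T = 1, unidentified = 1)),
                  c("myeloid", "B", "T", "unidentified"))
  # boundary: exactly (1 - tolerance) * max is assigned
  expect_setequal(assign_lineages(c(myeloid = 1, B = 0.9, T = 0.1,
                                    unidentified = 0.1)),
                  c("myeloid", "B"))
  # absolute mode
  expect_equal(assign_lineages(c(myeloid = 5, B = 4.95, T = 1,
                                 unidentified = 1),
                               tolerance = 0.10, mode = "absolute"),
               c("myeloid", "B"))
  expect_error(assign_lineages(c(myeloid = 1, B = 1, T = 1, unidentified = 1),
                               tolerance = 1), "tolerance")
  expect_error(assign_lineages(c(myeloid = -1, B = 1, T = 1, unidentified = 1)),
               "positive")
})

test_that("cohort scoring composes the chain with exact invariants", {
  m <- random_panel_matrix(12, seed = 4)
  labels <- cohort_labels(colnames(m), rep(c("ETP", "NONETP"), each = 6))
  cards <- score_cohort(m, labels)
  expect_length(cards, 6)
  for (cd in cards) {
    expect_equal(cd$tes[["PROM1"]], 1)
    expect_true(all(cd$scores > 0))
    expect_true(length(cd$assigned) >= 1)
    expect_true(all(cd$scores[cd$assigned] >= 0.9 * max(cd$scores)))
  }
})

test_that("scorecards are invariant to per-gene rescaling and sample order", {
  m <- random_panel_matrix(10, seed = 6)
  labels <- cohort_labels(colnames(m), rep(c("ETP", "NONETP"), each = 5))
  cards <- score_cohort(m, labels)
  scaled <- m
  set.seed(1)
  scaled <- scaled * runif(nrow(m), 0.1, 10) # per-gene positive rescale
  cards2 <- score_cohort(scaled, labels)
  for (i in seq_along(cards)) {
    expect_equal(cards2[[i]]$scores, cards[[i]]$scores, tolerance = 1e-12)
    expect_equal(cards2[[i]]$assigned, cards[[i]]$assigned)
  }
  perm <- m[, sample(ncol(m))]
  cards3 <- score_cohort(perm, labels)
  ids3 <- vapply(cards3, `[[`, "", "sample_id")
  ids <- vapply(cards, `[[`, "", "sample_id")
  for (i in seq_along(cards)) {
    j <- match(ids[i], ids3)
    expect_equal(cards3[[j]]$scores, cards[[i]]$scores, tolerance = 1e-12)
  }
})

test_that("identical samples give identical all-lineage cards", {
  m <- random_panel_matrix(5, seed = 7)
  m[] <- rep(m[, 1], 5) # duplicate one sample
  labels <- cohort_labels(colnames(m), c(rep("ETP", 4), "NONETP"))
  cards <- score_cohort(m, labels)
  expect_setequal(cards[[1]]$assigned, c("myeloid", "B", "T", "unidentified"))
  for (cd in cards[-1]) expect_equal(cd$scores, cards[[1]]$scores)
})

test_that("planted lineages are recovered from boosted cohorts", {
  hit <- 0; tot <- 0
  for (s in 1:4) {
    co <- generate_cohort(cohort_sim_config(n_etp = 20, n_nonetp = 4,
                                            n_genes = 30, n_up = 0, n_down = 0,
                                            n_variance_inflated = 0,
                                            noise_sd = 0.25, lineage_boost = 2,
                                            seed = s))
    cards <- score_cohort(co$expr, co$labels)
    for (cd in cards) {
      tot <- tot + 1
      hit <- hit + (co$truth$sample_lineage[[cd$sample_id]] %in% cd$assigned)
    }
  }
  expect_gte(hit / tot, 0.9)
})

test_that("missing panel genes abort scoring with their names", {
  m <- random_panel_matrix(6, seed = 8)
  labels <- cohort_labels(colnames(m), rep(c("ETP", "NONETP"), each = 3))
  expect_error(score_cohort(m[rownames(m) != "KIT", ], labels), "KIT")
})
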