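test_that("welch t-test matches stats::t.test and a numeric-integration oracle", {
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    mine <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # hand example with an independent oracle: two-sided p by numerical
  # integration of the t density
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  p_oracle <- 2 * integrate(function(u) dt(u, res$df), abs(res$t), Inf)$value
  expect_equal(res$p, p_oracle, tolerance = 1e-6)
})

test_that("welch t-test symmetry and degenerate contracts", {
  x <- c(1, 2, 3, 7); y <- c(2, 1, 3, 7)
  a <- welch_t_test(x, y); b <- welch_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  flat <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  pooled <- welch_t_test(x, y, var_equal = TRUE)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$p, ref$p.value, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential expression applies both gates strictly", {
  set.seed(21)
  n <- 200
  expr <- matrix(rnorm(n * 20, 8, 0.3), n,
                 dimnames = list(sprintf("G%03d", 1:n), sprintf("S%02d", 1:20)))
  labels <- cohort_labels(colnames(expr), rep(c("ETP", "NONETP"), each = 10))
  # plant one strong up, one strong down, one significant-but-small shift
  expr["G001", 1:10] <- expr["G001", 1:10] + 3
  expr["G002", 1:10] <- expr["G002", 1:10] - 3
  expr["G003", 1:10] <- expr["G003", 1:10] + 0.9
  de <- differential_expression(expr, labels)
  expect_equal(de$status[de$gene == "G001"], "UP")
  expect_equal(de$status[de$gene == "G002"], "DOWN")
  # fold-change gate fails even though q is tiny
  g3 <- de[de$gene == "G003", ]
  expect_lt(g3$q, 0.001)
  expect_equal(g3$status, "NS")
  expect_equal(de$log2fc, de$mean_etp - de$mean_nonetp)
})

test_that("differential expression is invariant to row and column order", {
  co <- generate_cohort(cohort_sim_config(n_etp = 5, n_nonetp = 6,
                                          n_genes = 80, n_up = 6, n_down = 6,
                                          n_variance_inflated = 0, seed = 2))
  de1 <- differential_expression(co$expr, co$labels)
  set.seed(1)
  expr2 <- co$expr[sample(nrow(co$expr)), sample(ncol(co$expr))]
  de2 <- differential_expression(expr2, co$labels)
  de2 <- de2[match(de1$gene, de2$gene), ]
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  expect_equal(de1$status, de2$status)
})

test_that("zero-variance genes are reported NS with p = 1", {
  expr <- matrix(5, 3, 6, dimnames = list(c("A", "B", "C"), paste0("S", 1:6)))
  expr["B", ] <- c(9, 9, 9, 2, 2, 2) # flat within groups, shifted between
  expr["C", ] <- rnorm(6, 5, 0.1)
  labels <- cohort_labels(colnames(expr), rep(c("ETP", "NONETP"), each = 3))
  de <- differential_expression(expr, labels)
  expect_equal(de$p[de$gene == "A"], 1)
  expect_equal(de$status[de$gene == "A"], "NS")
  expect_equal(de$p[de$gene == "B"], 1) # zero variance in both groups
  expect_equal(de$status[de$gene == "B"], "NS")
})

test_that("variable-gene selection uses strict n-1 sd threshold", {
  expr <- matrix(c(0, 4, 1, 1, 5, 5, 0, 2 * sqrt(2) * 1 + 0), 4, 2,
                 byrow = TRUE,
                 dimnames = list(c("G1", "G2", "G3", "G4"), c("E1", "E2")))
  # G1: sd = 2.828 > 2 in ETP; G2 constant; G3 constant; G4 sd = 2 exactly
  expr["G4", ] <- c(0, 2 * 2 / sqrt(2))
  labels <- cohort_labels(c("E1", "E2"), c("ETP", "ETP"))
  vg <- select_variable_genes(expr, labels, "ETP", sd_thresh = 2)
  expect_equal(vg$gene, "G1")
  expect_equal(vg$sd, sd(c(0, 4)), tolerance = 1e-12)
  expect_equal(sd(expr["G4", ]), 2, tolerance = 1e-12) # boundary excluded
})

test_that("signature intersection obeys set algebra and error contract", {
  res <- intersect_signatures(c("A", "B"), "C", c("B", "C", "D"))
  expect_equal(res$up_variable, "B")
  expect_equal(res$down_variable, "C")
  expect_equal(res$union, c("B", "C"))
  empty <- intersect_signatures(c("A", "B"), "C", character(0))
  expect_length(empty$union, 0)
  expect_error(intersect_signatures("A", "A", "B"), "both UP and DOWN")
})

test_that("pairwise sample correlation matches the textbook formula", {
  expr <- matrix(c(1, 2, 3,
                   2, 4, 6,
                   5, 1, 3), nrow = 3, byrow = FALSE,
                 dimnames = list(c("G1", "G2", "G3"), c("S1", "S2", "S3")))
  cc <- pairwise_sample_correlation(expr)
  byhand <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cc["S1", "S2"], byhand(expr[, 1], expr[, 2]), tolerance = 1e-12)
  expect_equal(diag(cc), c(S1 = 1, S2 = 1, S3 = 1))
  expect_equal(cc, t(cc))
  dup <- cbind(expr, S4 = expr[, "S1"])
  expect_equal(pairwise_sample_correlation(dup)["S1", "S4"], 1)
  bad <- expr; bad[, 2] <- 7
  expect_error(pairwise_sample_correlation(bad), "S2")
})

test_that("intragroup correlation comparison returns k(k-1)/2 coefficients", {
  co <- generate_cohort(cohort_sim_config(n_etp = 5, n_nonetp = 7,
                                          n_genes = 100, n_up = 0, n_down = 0,
                                          n_variance_inflated = 0,
                                          lineage_boost = 0, seed = 6))
  cc <- pairwise_sample_correlation(co$expr)
  res <- intragroup_correlation_compare(cc, co$labels)
  expect_length(res$etp_coefficients, 5 * 4 / 2)
  expect_length(res$nonetp_coefficients, 7 * 6 / 2)
})

test_that("duplicated samples versus noise gives a decisive comparison", {
  set.seed(30)
  base <- rnorm(150, 8, 2)
  etp <- sapply(1:6, function(i) base + rnorm(150, 0, 0.01))
  non <- matrix(rnorm(150 * 6, 8, 2), 150)
  expr <- cbind(etp, non)
  dimnames(expr) <- list(sprintf("G%03d", 1:150), sprintf("S%02d", 1:12))
  labels <- cohort_labels(colnames(expr), rep(c("ETP", "NONETP"), each = 6))
  res <- intragroup_correlation_compare(pairwise_sample_correlation(expr),
                                        labels)
  expect_true(all(res$etp_coefficients > 0.99))
  expect_lt(res$p, 0.01)
})
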