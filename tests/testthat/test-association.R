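test_that("reference-group normalization matches hand division", {
  m <- rbind(G1 = c(2, 4, 6, 6), G2 = c(1, 3, 2, 2))
  colnames(m) <- c("R1", "R2", "E1", "E2")
  nm <- normalize_to_reference_group(m, c("G1", "G2"), c("R1", "R2"))
  expect_equal(unname(nm["G1", ]), c(2, 4, 6, 6) / 3)
  expect_equal(unname(nm["G2", ]), c(1, 3, 2, 2) / 2)
  # a reference sample at the reference mean normalizes to 1
  m2 <- m; m2["G1", "R1"] <- 3; m2["G1", "R2"] <- 3
  nm2 <- normalize_to_reference_group(m2, "G1", c("R1", "R2"))
  expect_equal(unname(nm2["G1", c("R1", "R2")]), c(1, 1))
  zero <- m; zero["G1", c("R1", "R2")] <- 0
  expect_error(normalize_to_reference_group(zero, "G1", c("R1", "R2")),
               "zero reference mean")
})

test_that("gene PCA map matches an eigendecomposition oracle", {
  set.seed(5)
  x <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  res <- pca_gene_map(x, n_components = 3)
  # oracle: eigendecomposition of the covariance of the row-centered data
  xc <- x - rowMeans(x)
  ev <- eigen(crossprod(xc))
  scores_oracle <- xc %*% ev$vectors
  for (j in 1:2) {
    agree <- max(abs(res$coordinates[, j] - scores_oracle[, j]))
    flipped <- max(abs(res$coordinates[, j] + scores_oracle[, j]))
    expect_lt(min(agree, flipped), 1e-10) # equal up to axis sign
  }
  expect_equal(res$explained_variance,
               ev$values / sum(ev$values), tolerance = 1e-10)
  expect_true(all(diff(res$explained_variance) <= 1e-12))
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-10)
})

test_that("PCA reconstruction and duplicate-row behavior", {
  set.seed(6)
  x <- matrix(rnorm(40, 5), 8, 5,
              dimnames = list(paste0("G", 1:8), paste0("S", 1:5)))
  x[2, ] <- x[1, ] # duplicated gene rows
  res <- pca_gene_map(x, n_components = 5)
  expect_equal(res$coordinates[1, ], res$coordinates[2, ], tolerance = 1e-10)
  recon <- res$coordinates %*% t(res$loadings)
  expect_equal(unname(recon), unname(x - rowMeans(x)), tolerance = 1e-10)
  const <- x; const[3, ] <- 2
  expect_error(pca_gene_map(const), "G3")
})

test_that("nearest-centroid lineage labels recover coherent clusters", {
  coords <- rbind(CD34 = c(0, 5), CEBPA = c(4, 0), CSF3R = c(5, 0),
                  KIT = c(4.4, 0.2), EBF1 = c(-4, 0), PAX5 = c(-5, 0),
                  NT5E = c(-4.5, 0.3))
  colnames(coords) <- c("PC1", "PC2")
  lab <- nearest_lineage_centroids(coords)
  expect_equal(lab$nearest_lineage[lab$gene == "KIT"], "myelomonocytic")
  expect_equal(lab$nearest_lineage[lab$gene == "NT5E"], "B")
  expect_equal(lab$nearest_lineage[lab$gene == "CD34"], "stemness")
})

test_that("cohort bisection splits strictly at the gene mean", {
  m <- rbind(G = c(1, 2, 3, 10))
  colnames(m) <- paste0("S", 1:4)
  bi <- bisect_cohort_by_gene(m, colnames(m), "G")
  expect_equal(bi$high, "S4") # mean 4
  expect_setequal(bi$low, c("S1", "S2", "S3"))
  flat <- rbind(G = rep(2, 4)); colnames(flat) <- paste0("S", 1:4)
  bf <- bisect_cohort_by_gene(flat, colnames(flat), "G")
  expect_length(bf$high, 0)
  expect_length(bf$low, 4)
  sym <- rbind(G = c(1, 3)); colnames(sym) <- c("S1", "S2")
  bs <- bisect_cohort_by_gene(sym, colnames(sym), "G")
  expect_equal(bs$high, "S2"); expect_equal(bs$low, "S1")
  expect_error(bisect_cohort_by_gene(m, colnames(m), "NOPE"), "absent")
})

test_that("bisect-then-compare on a non-constant gene separates the means", {
  set.seed(8)
  m <- matrix(runif(60, 4, 10), 3,
              dimnames = list(c("A", "B", "C"), sprintf("S%02d", 1:20)))
  bi <- bisect_cohort_by_gene(m, colnames(m), "B")
  cm <- compare_markers(m, bi$high, bi$low, "B")
  expect_gt(cm$mean_a, cm$mean_b)
})

test_that("marker comparison is symmetric and BH spans the marker list", {
  set.seed(9)
  m <- matrix(rnorm(40, 6), 4,
              dimnames = list(c("M1", "M2", "M3", "M4"), sprintf("S%02d", 1:10)))
  a <- paste0("S0", 1:5); b <- c("S06", "S07", "S08", "S09", "S10")
  r1 <- compare_markers(m, a, b, c("M1", "M2", "M3"))
  r2 <- compare_markers(m, b, a, c("M1", "M2", "M3"))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$mean_a, r2$mean_b)
  expect_equal(r1$q, oracle_bh(r1$p), tolerance = 1e-12)
  flat <- m; flat["M1", ] <- 5
  expect_equal(compare_markers(flat, a, b, "M1")$p, 1)
  expect_error(compare_markers(m, a, b, c("M1", "NOPE")), "NOPE")
})

test_that("planted marker shifts are detected with power", {
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    m <- matrix(rnorm(16 * 4, 6, 0.3), 4,
                dimnames = list(paste0("M", 1:4), sprintf("S%02d", 1:16)))
    m["M1", 1:8] <- m["M1", 1:8] + 3
    r <- compare_markers(m, sprintf("S%02d", 1:8), sprintf("S%02d", 9:16),
                         paste0("M", 1:4))
    hits <- hits + (r$q[r$gene == "M1"] < 0.05)
  }
  expect_gte(hits / 30, 0.99)
})

test_that("hypergeometric ORA matches closed forms and the enumeration oracle", {
  bg <- paste0("G", 1:10)
  sets <- list(S = bg[1:5])
  res <- ora_hypergeometric(bg[1:5], bg, sets, filter = FALSE)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  # query disjoint from the set: overlap 0, filtered out
  res2 <- ora_hypergeometric(bg[6:10], bg, sets)
  expect_equal(nrow(res2), 0)
  # set = background: p = 1 regardless of query
  res3 <- ora_hypergeometric(bg[1:3], bg, list(ALL = bg), filter = FALSE)
  expect_equal(res3$p, 1)
  expect_error(ora_hypergeometric(c("G1", "ZZ"), bg, sets), "outside background")

  set.seed(12)
  for (i in 1:30) {
    N <- sample(8:20, 1)
    bgx <- paste0("G", 1:N)
    K <- sample(2:(N - 1), 1); n <- sample(2:(N - 1), 1)
    sx <- list(S = sample(bgx, K))
    q <- sample(bgx, n)
    got <- ora_hypergeometric(q, bgx, sx, filter = FALSE)
    k <- length(intersect(sx$S, q))
    expect_equal(got$overlap, k)
    expect_equal(got$p, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
})
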