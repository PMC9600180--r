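test_that("Bray-Curtis matches its definition and vegan", {
  x <- matrix(c(0.25, 0.75, 0.75, 0.25), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  d <- bray_curtis(x)
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(diag(unclass(d)), c(s1 = 0, s2 = 0))
  same <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  expect_equal(bray_curtis(same)[1, 2], 0)
  disj <- cbind(s1 = c(1, 0), s2 = c(0, 3))
  expect_equal(bray_curtis(disj)[1, 2], 1)
  expect_error(bray_curtis(cbind(c(-1, 2), c(1, 1))), "negative")
  set.seed(8)
  m <- matrix(rgamma(60, 1), 10)
  colnames(m) <- paste0("s", 1:6)
  d2 <- unclass(bray_curtis(m))
  expect_true(all(d2 >= 0 & d2 <= 1) && isSymmetric(unname(d2)))
  skip_if_not_installed("vegan")
  expect_equal(d2[lower.tri(d2)],
               as.vector(vegan::vegdist(t(m), "bray")), tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean-compatible distances exactly", {
  # 3-4-5 right triangle
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 4
  d["b", "c"] <- d["c", "b"] <- 5
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$points))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(ord$prop_explained) <= 1e-12))
  # duplicated sample lands on identical coordinates
  d4 <- rbind(cbind(d, a2 = d[, "a"]), a2 = c(d["a", ], 0))
  ord4 <- pcoa(d4)
  expect_equal(ord4$points["a", ], ord4$points["a2", ], tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with classical MDS on Bray-Curtis data", {
  set.seed(12)
  m <- matrix(rgamma(80, 1), 10)
  colnames(m) <- paste0("s", 1:8)
  d <- bray_curtis(m)
  ord <- pcoa(d)
  ref <- cmdscale(as.dist(unclass(d)), k = 2, eig = TRUE)
  expect_equal(abs(ord$points[, 1:2]), abs(ref$points),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(ord$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-9)
  # lingoes correction makes all eigenvalues non-negative
  ordc <- pcoa(d, correction = "lingoes")
  expect_true(min(ordc$eigenvalues) > -1e-8)
})

test_that("PERMANOVA partitioning matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rgamma(160, 1), 10)
  colnames(m) <- paste0("s", 1:16)
  meta <- data.frame(tr = rep(c("A", "B"), each = 8),
                     tp = rep(c("t1", "t2"), 8))
  d <- bray_curtis(m)
  mine <- permanova(d, meta, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(unclass(d)) ~ tr + tp, data = meta,
                        permutations = 99, by = "terms")
  expect_equal(mine$SS, ref$SumOfSqs, tolerance = 1e-9)
  expect_equal(mine$R2, ref$R2, tolerance = 1e-9)
  expect_equal(mine$statistic[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(mine$df, ref$Df)
})

test_that("PERMANOVA permutation p agrees with exhaustive enumeration", {
  set.seed(31)
  m <- matrix(rgamma(24, 1), 6)
  colnames(m) <- paste0("s", 1:4)
  g <- c("A", "A", "B", "B")
  d <- bray_curtis(m)
  p_exact <- permanova_exact_p(unclass(d), g)
  p_mc <- permanova(d, data.frame(g = g), n_perm = 999, seed = 5)$p[1]
  # binomial error of the MC estimate around the exact p
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_mc - p_exact), 4 * se + 2 / 999)
})

test_that("perfectly separated groups reach the minimum attainable p", {
  m <- cbind(s1 = c(10, 0, 5), s2 = c(10, 0, 5),
             s3 = c(0, 10, 5), s4 = c(0, 10, 5))
  d <- bray_curtis(m)
  res <- permanova(d, data.frame(g = c("A", "A", "B", "B")),
                   n_perm = 999, seed = 2)
  # identical within-group profiles: observed F is maximal over permutations
  exact_min <- permanova_exact_p(unclass(d), c("A", "A", "B", "B"))
  expect_equal(exact_min, 1 / 3)  # 8 of 24 label permutations tie the max F
  expect_lt(res$p[1], 0.4)
})

test_that("SIMPER conserves the mean between-group dissimilarity", {
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rgamma(8 * 6, 1), 8)
    m <- sweep(m, 2, colSums(m), "/")
    colnames(m) <- paste0("s", 1:6)
    rownames(m) <- paste0("o", 1:8)
    g <- rep(c("A", "B"), each = 3)
    s <- simper(m, g)
    bc <- unclass(bray_curtis(m))
    mean_bc <- mean(bc[1:3, 4:6])
    expect_equal(s$overall, mean_bc, tolerance = 1e-12)
    expect_equal(sum(s$per_otu$contribution), mean_bc, tolerance = 1e-12)
    expect_equal(s$per_otu$contribution,
                 unname(simper_oracle(m, 1:3, 4:6)), tolerance = 1e-12)
  }
  # identical groups decompose to all-zero contributions
  m2 <- cbind(s1 = c(1, 2), s2 = c(1, 2), s3 = c(1, 2), s4 = c(1, 2))
  rownames(m2) <- c("o1", "o2")
  expect_equal(simper(m2, c("A", "A", "B", "B"))$per_otu$contribution, c(0, 0))
})

test_that("SIMPER per-OTU averages agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(43)
  m <- matrix(rgamma(10 * 8, 1), 10)
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(paste0("o", 1:10), paste0("s", 1:8))
  g <- rep(c("A", "B"), each = 4)
  mine <- simper(m, g)
  ref <- suppressWarnings(vegan::simper(t(m), g, permutations = 0))
  ref_avg <- ref$A_B$average[match(mine$per_otu$otu_id, ref$A_B$species)]
  expect_equal(mine$per_otu$contribution, unname(ref_avg), tolerance = 1e-9)
})

test_that("dissimilarity to initial excludes the self-pair and detects identity", {
  p <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.1, 0.9), 2)
  rel <- make_rel(p, timepoint = c("initial", "initial", "R0", "R0"))
  d <- dissimilarity_to_initial(rel)
  # sample 3 equals both initial replicates exactly
  expect_equal(d$dissimilarity[3], 0)
  expect_gt(d$dissimilarity[4], 0)
  # initial samples compare with peers only (identical peers here -> 0)
  expect_equal(d$dissimilarity[1], 0)
  rel_no_ini <- make_rel(p[, 3:4, drop = FALSE], timepoint = "R0")
  expect_error(dissimilarity_to_initial(rel_no_ini), "initial")
})
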