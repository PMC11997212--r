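test_that("Bray-Curtis: identical, disjoint, direct evaluation, zero-row
           guard", {
  X <- rbind(a = c(2, 0, 1), b = c(2, 0, 1))
  expect_equal(as.numeric(bray_curtis(X, log1p = FALSE)), 0)
  Y <- rbind(a = c(2, 3, 0), b = c(0, 0, 5))
  expect_equal(as.numeric(bray_curtis(Y, log1p = FALSE)), 1)
  Z <- rbind(a = c(2, 0, 1), b = c(1, 1, 0))
  expect_equal(as.numeric(bray_curtis(Z, log1p = FALSE)), 0.6)
  # log1p damps abundant species: distance computed on log1p scale
  expect_equal(as.numeric(bray_curtis(Z, log1p = TRUE)),
               as.numeric(vegan::vegdist(log1p(Z), "bray")))
  bad <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_error(bray_curtis(bad), "all-zero sites: a, b")
  expect_error(bray_curtis(-Z), "nonnegative")
})

test_that("presence-absence and Jaccard: direct case and the Bray-Curtis
           identity", {
  X <- rbind(a = c(3, 0, 0.2), b = c(0, 1, 4))
  Xb <- to_presence_absence(X)
  expect_true(all(Xb %in% c(0, 1)))
  expect_equal(Xb, rbind(a = c(1, 0, 1), b = c(0, 1, 1)))
  # rows 110 vs 011: a=1 shared, b=c=1 unique each -> 2/3
  J <- jaccard_distance(rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1)))
  expect_equal(as.numeric(J), 2 / 3)
  # J = 2 BC / (1 + BC) on binary data
  set.seed(17)
  B <- matrix(rbinom(60, 1, 0.5), 10, 6)
  B[rowSums(B) == 0, 1] <- 1
  bc <- as.numeric(bray_curtis(B, log1p = FALSE))
  expect_equal(as.numeric(jaccard_distance(B)), 2 * bc / (1 + bc),
               tolerance = 1e-12)
  expect_error(jaccard_distance(rbind(c(0.5, 1), c(1, 0))), "binary")
})

test_that("NMDS: embeddable configurations, tetrahedron floor, determinism,
           dimension monotonicity", {
  set.seed(23)
  pts <- cbind(rnorm(20), rnorm(20))
  D <- dist(pts)
  o <- nmds(D, k = 2, n_starts = 10, seed = 1)
  expect_lt(o$stress, 0.01)
  expect_equal(colMeans(o$points), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # a 4-d point cloud with distinct dissimilarity ranks cannot embed in the
  # plane without stress (all-equal dissimilarities would be tie-degenerate:
  # primary tie treatment fits them exactly)
  set.seed(99)
  D4 <- dist(matrix(rnorm(10 * 4), 10))
  expect_gt(nmds(D4, k = 2, n_starts = 10, seed = 2)$stress, 0)
  # same seed, same answer
  o2 <- nmds(D, k = 2, n_starts = 10, seed = 1)
  expect_identical(o$points, o2$points)
  # more dimensions never hurt the minimal stress
  set.seed(24)
  Dr <- dist(matrix(rnorm(12 * 5), 12))
  s1 <- nmds(Dr, k = 1, n_starts = 10, seed = 3)$stress
  s2 <- nmds(Dr, k = 2, n_starts = 10, seed = 3)$stress
  expect_gte(s1, s2)
  expect_error(nmds(dist(matrix(rnorm(8), 4)), k = 3), "smaller than")
})

test_that("stress is non-increasing with the iteration budget", {
  set.seed(25)
  D <- dist(matrix(rnorm(15 * 4), 15))
  init <- matrix(rnorm(30), 15, 2)
  path <- nmds_stress_path(D, k = 2, init = init,
                           maxits = c(1, 2, 5, 10, 25, 50, 100, 200))
  expect_true(all(diff(path) <= 1e-12))
})

test_that("rotation to a variable is rigid and aligns the fitted vector
           with axis 1", {
  set.seed(26)
  X <- matrix(rexp(25 * 10), 25, 10,
              dimnames = list(paste0("s", 1:25), paste0("sp", 1:10)))
  o <- nmds(bray_curtis(X), seed = 4, n_starts = 10)
  v <- o$points[, 1] * 0.8 + o$points[, 2] * 0.3 + rnorm(25, 0, 0.05)
  ro <- rotate_to_variable(o, v)
  # rigid: pairwise configuration distances unchanged
  expect_equal(as.numeric(dist(ro$points)), as.numeric(dist(o$points)),
               tolerance = 1e-10)
  expect_equal(ro$stress, o$stress)
  # the fitted direction of v is now (1, 0)
  ef <- env_fit(ro, data.frame(v = v), n_perm = 99, seed = 5)
  dir <- as.numeric(ef$vectors[1, c(2, 3)])
  expect_equal(abs(dir[1]), 1, tolerance = 1e-6)
  expect_equal(dir[2], 0, tolerance = 1e-6)
  # a variable already aligned with axis 1 rotates by identity up to sign
  ro2 <- rotate_to_variable(ro, ro$points[, 1])
  expect_equal(abs(ro2$points[, 1]), abs(ro$points[, 1]), tolerance = 1e-8)
  expect_error(rotate_to_variable(o, rep(1, 25)), "zero-variance")
})

test_that("environmental fit: perfect variable, factor clusters, constant
           guard", {
  set.seed(27)
  sc <- cbind(NMDS1 = rnorm(40), NMDS2 = rnorm(40))
  sc <- scale(sc, scale = FALSE)
  ef <- env_fit(sc, data.frame(v = sc[, 1]), n_perm = 199, seed = 6)
  expect_equal(ef$vectors$r2, 1, tolerance = 1e-10)
  expect_equal(abs(ef$vectors[1, 2]), 1, tolerance = 1e-8)
  expect_lte(ef$vectors$p, 0.05)
  # factor levels that perfectly partition well-separated clusters
  cl <- rep(c("A", "B"), each = 20)
  sc2 <- cbind(rnorm(40, ifelse(cl == "A", -5, 5), 0.2), rnorm(40, 0, 0.2))
  ef2 <- env_fit(sc2, data.frame(grp = factor(cl)), n_perm = 999, seed = 7)
  expect_gt(ef2$factor_r2$r2, 0.95)
  expect_lte(ef2$factor_r2$p, 0.001)
  # constant variable: r2 0, p 1, warning not error
  expect_warning(ef3 <- env_fit(sc, data.frame(v = sc[, 1], k = rep(2, 40)),
                                n_perm = 99, seed = 8), "constant")
  krow <- ef3$vectors[ef3$vectors$variable == "k", ]
  expect_equal(krow$r2, 0)
  expect_equal(krow$p, 1)
})

test_that("habitat assignment applies the reassignment rules", {
  traits <- data.frame(
    species = c("a", "b", "c", "d", "e", "f", "g", "h"),
    habitat = c("Rock", "Forest", "Riverine", "Wetland", "Grassland",
                "Shrubland", "Coastal", "Human Modified"))
  map <- assign_habitat(traits)
  expect_equal(unname(map[c("a", "g", "h")]),
               rep("human-modified", 3))
  expect_equal(unname(map["b"]), "forest")
  expect_equal(unname(map[c("c", "d")]), rep("aquatic", 2))
  expect_equal(unname(map[c("e", "f")]), rep("open", 2))
  expect_error(assign_habitat(data.frame(species = "x", habitat = "Lunar")),
               "unknown habitat")
  expect_error(assign_habitat(traits, community_species = c("a", "zz")),
               "missing from the trait table: zz")
})

test_that("Procrustes/PROTEST: exact match under similarity transforms and
           the t-m2 identity", {
  set.seed(28)
  A <- matrix(rnorm(30), 15, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  B <- 2.5 * A %*% R %*% diag(c(1, -1)) + 10  # rotation+reflection+scale+shift
  pp <- procrustes_protest(A, B, n_perm = 99, seed = 9)
  expect_lt(pp$m2, 1e-10)
  expect_equal(pp$t, 1, tolerance = 1e-6)
  # identity t^2 = 1 - m2 on unrelated configurations
  C <- matrix(rnorm(30), 15, 2)
  pp2 <- procrustes_protest(A, C, n_perm = 99, seed = 10)
  expect_equal(pp2$t^2, 1 - pp2$m2, tolerance = 1e-12)
  expect_error(procrustes_protest(A, C[1:10, ]), "same rows")
})

test_that("Mantel: self-correlation, lower-triangle oracle, size guard", {
  set.seed(29)
  D1 <- dist(matrix(rnorm(20 * 3), 20))
  expect_equal(mantel_test(D1, D1, n_perm = 99, seed = 11)$r, 1)
  D2 <- dist(matrix(rnorm(20 * 3), 20))
  r_oracle <- cor(as.numeric(D1), as.numeric(D2))
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 12)$r, r_oracle,
               tolerance = 1e-12)
  expect_error(mantel_test(D1, dist(matrix(rnorm(10), 5))), "size")
})

test_that("species scores are VAR-weighted averages of site scores", {
  set.seed(30)
  X <- matrix(rexp(20 * 6), 20, 6,
              dimnames = list(paste0("s", 1:20), paste0("sp", 1:6)))
  o <- nmds(bray_curtis(X), seed = 13, n_starts = 5)
  sp <- species_scores(o, X)
  # hand-computed weighted average for one species
  w <- X[, 3] / sum(X[, 3])
  expect_equal(unname(sp[3, ]), c(sum(w * o$points[, 1]),
                                  sum(w * o$points[, 2])),
               tolerance = 1e-10)
})
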