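test_that("Bray-Curtis toy values and vegan cross-check", {
  ft <- tiny_table(cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0)),
                   features = c("f1", "f2", "f3"),
                   samples = c("a", "b", "c"))
  d <- bray_curtis(ft)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)             # identical samples
  disjoint <- tiny_table(cbind(a = c(1, 0), b = c(0, 1)),
                         features = c("f1", "f2"), samples = c("a", "b"))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)

  skip_if_not_installed("vegan")
  set.seed(30)
  v <- matrix(rlnorm(20 * 6), 20, 6, dimnames = list(sprintf("f%d", 1:20),
                                                     sprintf("s%d", 1:6)))
  mine <- bray_curtis(feature_table(v, "gene"))
  ref <- as.matrix(vegan::vegdist(t(v), method = "bray"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
})

test_that("Bray-Curtis is invariant to joint rescaling and bounded in [0,1]", {
  set.seed(31)
  v <- matrix(rlnorm(30), 5, 6, dimnames = list(sprintf("f%d", 1:5),
                                                sprintf("s%d", 1:6)))
  d1 <- bray_curtis(feature_table(v, "gene"))
  d2 <- bray_curtis(feature_table(v * 41.3, "gene"))
  expect_equal(d1, d2)
  expect_true(all(d1 >= 0 & d1 <= 1))
  v[, 2] <- 0
  v[, 3] <- 0
  expect_error(bray_curtis(feature_table(v, "gene")), "all-zero")
})

test_that("PCoA reconstructs Euclidean geometry and flags rank", {
  set.seed(32)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:8), sprintf("s%d", 1:8))
  out <- pcoa(d)
  rec <- as.matrix(dist(out$coordinates))
  expect_lt(max(abs(rec - unname(d))), 1e-8)
  expect_true(all(diff(out$eigenvalues) <= 1e-8))  # descending
  # collinear points: a single meaningful axis
  line <- outer(c(0, 1, 2, 5), c(1, 0, 0))
  dl <- as.matrix(dist(line))
  dimnames(dl) <- list(sprintf("s%d", 1:4), sprintf("s%d", 1:4))
  ol <- pcoa(dl)
  expect_equal(ncol(ol$coordinates), 1)
  # all-zero distances give all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(z)$coordinates == 0))
})

test_that("Procrustes recovers exact superposition and matches vegan", {
  set.seed(33)
  x <- matrix(rnorm(16), 8, 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  y <- 3.2 * x %*% rot + matrix(c(5, -2), 8, 2, byrow = TRUE)
  fit <- procrustes_analysis(x, y)
  expect_lt(fit$m2, 1e-10)
  expect_equal(procrustes_analysis(x, x)$m2, 0, tolerance = 1e-12)
  expect_error(procrustes_analysis(x, matrix(1, 8, 2)), "degenerate")

  skip_if_not_installed("vegan")
  y2 <- matrix(rnorm(16), 8, 2)
  mine <- procrustes_analysis(x, y2)
  ref <- vegan::procrustes(x, y2, symmetric = TRUE)
  expect_equal(mine$m2, ref$ss, tolerance = 1e-9)
})

test_that("Procrustes M2 is invariant to pre-rotating either configuration", {
  set.seed(34)
  x <- matrix(rnorm(20), 10, 2)
  y <- matrix(rnorm(20), 10, 2)
  theta <- 1.1
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(procrustes_analysis(x, y)$m2,
               procrustes_analysis(x %*% rot, y)$m2, tolerance = 1e-12)
  expect_equal(procrustes_analysis(x, y)$m2,
               procrustes_analysis(x, y %*% rot)$m2, tolerance = 1e-12)
})

test_that("Mantel: self-comparison, determinism, and small-n guard", {
  set.seed(35)
  v <- matrix(rlnorm(48), 6, 8, dimnames = list(sprintf("f%d", 1:6),
                                                sprintf("s%d", 1:8)))
  d <- bray_curtis(feature_table(v, "gene"))
  self <- mantel(d, d, n_perm = 99, seed = 5)
  expect_equal(self$statistic, 1)
  expect_equal(self$p_value, 1 / 100)
  v2 <- matrix(rlnorm(48), 6, 8, dimnames = dimnames(v))
  d2 <- bray_curtis(feature_table(v2, "gene"))
  a <- mantel(d, d2, n_perm = 199, seed = 7)
  b <- mantel(d, d2, n_perm = 199, seed = 7)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$statistic, b$statistic)
  d3 <- d[1:3, 1:3]
  expect_error(mantel(d3, d3, seed = 1), "at least 4")
})

test_that("PERMANOVA separates planted clusters and rejects singletons", {
  set.seed(36)
  v <- cbind(matrix(rlnorm(40, 0, 0.1), 10, 4),
             matrix(rlnorm(40, 3, 0.1), 10, 4))
  dimnames(v) <- list(sprintf("f%d", 1:10), sprintf("s%d", 1:8))
  d <- bray_curtis(feature_table(v, "gene"))
  grp <- rep(c("a", "b"), each = 4)
  out <- permanova(d, grp, n_perm = 199, seed = 11)
  # only label permutations reproducing the planted partition can tie the
  # observed pseudo-F, so p stays at the few-in-a-hundred floor
  expect_lt(out$p_value, 0.05)
  expect_gt(out$statistic, 10)
  expect_error(permanova(d, c("a", rep("b", 7)), n_perm = 99, seed = 1),
               "singleton")
  expect_error(permanova(d, rep("a", 8), n_perm = 99, seed = 1), "two groups")
})

test_that("pseudo-F matches vegan::adonis2 on random data", {
  skip_if_not_installed("vegan")
  set.seed(37)
  v <- matrix(rlnorm(80), 10, 8, dimnames = list(sprintf("f%d", 1:10),
                                                 sprintf("s%d", 1:8)))
  d <- bray_curtis(feature_table(v, "gene"))
  grp <- rep(c("a", "b"), each = 4)
  mine <- permanova(d, grp, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(d) ~ grp, permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-9)
})

test_that("Friedman test matches stats::friedman.test with and without ties", {
  set.seed(38)
  m <- matrix(rnorm(24), 6, 4)
  mine <- friedman_rank_test(m)
  ref <- friedman.test(m)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # tied data
  mt <- matrix(sample(1:3, 24, TRUE), 6, 4)
  while (any(apply(mt, 1, function(r) length(unique(r))) == 1))
    mt <- matrix(sample(1:3, 24, TRUE), 6, 4)
  mine_t <- friedman_rank_test(mt)
  ref_t <- friedman.test(mt)
  expect_equal(mine_t$statistic, unname(ref_t$statistic), tolerance = 1e-10)
  # identical ranking in every block reaches the closed-form maximum
  ranked <- matrix(rep(1:5, each = 4), 4, 5) + 0.0
  maxstat <- friedman_rank_test(ranked)
  n <- 4; k <- 5
  expect_equal(maxstat$statistic, n * (k - 1))  # untied maximum
  # constant blocks give statistic 0 with a warning
  expect_warning(z <- friedman_rank_test(matrix(1, 3, 3)), "constant")
  expect_equal(z$statistic, 0)
})

test_that("distance matrices round-trip through TSV", {
  set.seed(39)
  v <- matrix(rlnorm(30), 5, 6, dimnames = list(sprintf("f%d", 1:5),
                                                sprintf("s%d", 1:6)))
  d <- bray_curtis(feature_table(v, "gene"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  expect_equal(read_distance_matrix(path), d)
})
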