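make_paired <- function(g, p) {
  list(genes = g, proteins = p)
}

test_that("paired Spearman hits the exact endpoints and matches stats::cor", {
  s <- sprintf("s%d", 1:8)
  g <- tiny_table(matrix(1:8, 1), features = "f1", samples = s)
  p_same <- tiny_table(matrix((1:8)^3, 1), layer = "protein",
                       features = "f1", samples = s)
  p_rev <- tiny_table(matrix(8:1, 1), layer = "protein",
                      features = "f1", samples = s)
  expect_equal(unname(paired_feature_spearman(make_paired(g, p_same))$rho), 1)
  expect_equal(unname(paired_feature_spearman(make_paired(g, p_rev))$rho), -1)

  set.seed(10)
  gv <- matrix(rlnorm(50 * 8), 50, 8,
               dimnames = list(sprintf("f%d", 1:50), s))
  pv <- matrix(rlnorm(50 * 8), 50, 8, dimnames = dimnames(gv))
  pv[sample(length(pv), 30)] <- NA
  cs <- paired_feature_spearman(make_paired(feature_table(gv, "gene"),
                                            feature_table(pv, "protein")))
  oracle <- sapply(1:50, function(i) {
    ok <- !is.na(pv[i, ])
    if (sum(ok) < 3) NA else cor(gv[i, ok], pv[i, ok], method = "spearman")
  })
  expect_equal(unname(cs$rho), oracle, tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  s <- sprintf("s%d", 1:8)
  gv <- matrix(rlnorm(20 * 8), 20, 8, dimnames = list(sprintf("f%d", 1:20), s))
  pv <- matrix(rlnorm(20 * 8), 20, 8, dimnames = dimnames(gv))
  base <- paired_feature_spearman(make_paired(feature_table(gv, "gene"),
                                              feature_table(pv, "protein")))
  warped <- paired_feature_spearman(make_paired(
    feature_table(exp(gv), "gene"),
    feature_table(pv^3, "protein")))
  expect_equal(base$rho, warped$rho)
})

test_that("rollup sums by category, multi-GO features count once per term", {
  s <- c("s1", "s2")
  ft <- tiny_table(matrix(c(1, 3, 2, 4, 10, 20), 3, 2, byrow = TRUE),
                   features = c("f1", "f2", "f3"), samples = s)
  ann <- tiny_annotation(c("f1", "f2", "f3"),
                         go = c("GO:1;GO:2", "GO:1", NA))
  out <- rollup_by_category(ft, ann, "GO")
  expect_equal(unname(out$values["GO:1", ]), c(3, 7))
  expect_equal(unname(out$values["GO:2", ]), c(1, 3))
  expect_equal(attr(out, "n_unannotated"), 1L)
  # single-annotation features conserve mass
  ann1 <- tiny_annotation(c("f1", "f2", "f3"), go = c("GO:1", "GO:2", "GO:2"))
  out1 <- rollup_by_category(ft, ann1, "GO")
  expect_equal(colSums(out1$values), colSums(ft$values))
})

test_that("rollup treats missing protein cells as zero contribution", {
  ft <- tiny_table(matrix(c(1, NA, 5, 6), 2, 2, byrow = TRUE),
                   layer = "protein", features = c("p1", "p2"))
  ann <- tiny_annotation(c("p1", "p2"), go = c("GO:1", "GO:1"))
  out <- rollup_by_category(ft, ann, "GO")
  expect_equal(unname(out$values["GO:1", ]), c(6, 6))
})

test_that("category_summed concordance equals Spearman on rolled-up tables", {
  set.seed(12)
  s <- sprintf("s%d", 1:8)
  gv <- matrix(rlnorm(30 * 8), 30, 8, dimnames = list(sprintf("f%d", 1:30), s))
  pv <- matrix(rlnorm(30 * 8), 30, 8, dimnames = dimnames(gv))
  ann <- tiny_annotation(sprintf("f%d", 1:30),
                         go = sample(c("GO:1", "GO:2", "GO:3"), 30, TRUE))
  g <- feature_table(gv, "gene"); p <- feature_table(pv, "protein")
  via_mode <- category_concordance(g, p, ann, "GO", mode = "category_summed")
  direct <- paired_feature_spearman(subset_shared_features(
    rollup_by_category(g, ann, "GO"), rollup_by_category(p, ann, "GO")))
  expect_equal(via_mode$rho, direct$rho)
  # single-feature category: both modes give that feature's rho
  ann1 <- tiny_annotation("f1", eggnog = "solo")
  g1 <- feature_table(gv[1, , drop = FALSE], "gene")
  p1 <- feature_table(pv[1, , drop = FALSE], "protein")
  per <- category_concordance(g1, p1, ann1, "eggNOG", "per_feature_grouped")
  summed <- category_concordance(g1, p1, ann1, "eggNOG", "category_summed")
  expect_equal(per$rho, unname(summed$rho))
})

test_that("dynamic range handles constants, zeros and scaling invariance", {
  ft <- tiny_table(matrix(c(2, 8, 3, 3, 0, 5, 0, 0), 4, 2, byrow = TRUE),
                   features = c("r42", "const", "withzero", "allzero"))
  dr <- dynamic_range(ft)
  expect_equal(dr$max_min_ratio[dr$item == "r42"], 4)
  expect_equal(dr$max_min_ratio[dr$item == "const"], 1)
  # zero minimum falls back to smallest nonzero value, flagged
  expect_equal(dr$max_min_ratio[dr$item == "withzero"], 1)
  expect_true(dr$zero_substituted[dr$item == "withzero"])
  expect_false("allzero" %in% dr$item)
  expect_equal(attr(dr, "n_excluded"), 1L)
  # invariant to global positive scaling
  dr2 <- dynamic_range(tiny_table(ft$values * 1e3,
                                  features = rownames(ft$values)))
  expect_equal(dr$max_min_ratio, dr2$max_min_ratio)
})

test_that("sd_profile matches a one-pass oracle and handles logs", {
  expect_equal(sd_profile(tiny_table(matrix(c(0, 2), 1),
                                     features = "f"))$sd, sqrt(2))
  expect_equal(sd_profile(tiny_table(matrix(c(3, 3, 3), 1),
                                     features = "f"))$sd, 0)
  set.seed(13)
  v <- matrix(rlnorm(40), 5, 8, dimnames = list(sprintf("f%d", 1:5),
                                                sprintf("s%d", 1:8)))
  got <- sd_profile(feature_table(v, "gene"))$sd
  oracle <- apply(v, 1, function(x) {
    n <- length(x)
    sqrt((sum(x^2) - n * mean(x)^2) / (n - 1))
  })
  expect_equal(got, unname(oracle), tolerance = 1e-12)
  logged <- sd_profile(feature_table(v, "gene"), log_transform = TRUE)$sd
  expect_equal(logged, unname(apply(log10(v), 1, sd)), tolerance = 1e-12)
})

test_that("top fluctuating categories rank by ratio with lexicographic ties", {
  prof <- dynamic_range(tiny_table(
    matrix(c(1, 10, 1, 5, 2, 10, 1, 2), 4, 2, byrow = TRUE),
    features = c("a", "b", "zeta", "alpha")), scope = "category")
  top <- top_fluctuating_categories(prof, 2)
  expect_equal(top$item, c("a", "b"))       # 10 then 5 (== zeta, a<z... )
  expect_equal(top_fluctuating_categories(prof, 99)$item[2:3],
               c("b", "zeta"))              # tie 5 vs 5: "b" before "zeta"
  expect_equal(nrow(top_fluctuating_categories(prof, 99)), 4)
})
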