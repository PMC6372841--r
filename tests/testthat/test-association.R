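test_that("biomarker extraction sums mapped subunits", {
  s <- c("s1", "s2")
  ft <- tiny_table(matrix(c(1, 2, 3, 4, 9, 9), 3, 2, byrow = TRUE),
                   layer = "protein", features = c("S100A8", "S100A9", "LYZ"),
                   samples = s)
  bio <- extract_biomarkers(ft, list(calprotectin = c("S100A8", "S100A9"),
                                     lysozyme = "LYZ"))
  expect_equal(unname(bio["calprotectin", ]), c(4, 6))
  expect_equal(unname(bio["lysozyme", ]), c(9, 9))
  expect_warning(extract_biomarkers(ft, list(calprotectin = "S100A8",
                                             CRP = "ABSENT")),
                 "CRP")
})

test_that("feature-vs-biomarker OLS matches lm on random instances", {
  set.seed(20)
  s <- sprintf("s%d", 1:8)
  v <- matrix(rlnorm(100 * 8), 100, 8, dimnames = list(sprintf("f%d", 1:100), s))
  v[sample(length(v), 40)] <- NA
  bio <- setNames(runif(8, 1, 3), s)
  res <- regress_features_vs_biomarker(feature_table(v, "protein"), bio, "bm")
  for (i in sample(nrow(res), 15)) {
    f <- res$feature_id[i]
    ok <- !is.na(v[f, ])
    fit <- lm(v[f, ok] ~ bio[ok])
    expect_equal(res$slope[i], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res$intercept[i], unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(res$r[i], unname(cor(bio[ok], v[f, ok])), tolerance = 1e-10)
    expect_equal(res$p_value[i], summary(fit)$coefficients[2, 4],
                 tolerance = 1e-8)
  }
  # exact proportionality gives r = +/-1
  prop <- feature_table(rbind(f_up = 2 * bio, f_dn = 10 - bio), "protein")
  r2 <- regress_features_vs_biomarker(prop, bio, "bm")
  expect_equal(r2$r, c(1, -1))
  expect_error(regress_features_vs_biomarker(prop, setNames(rep(1, 8), s)),
               "zero-variance")
})

test_that("select_strong partitions at the threshold and shrinks with tau", {
  res <- data.frame(feature_id = sprintf("f%d", 1:5), biomarker = "bm",
                    slope = 1, intercept = 0,
                    r = c(0.75, -0.8, 0.0, 0.7, NA),
                    n_used = 8, p_value = NA, stringsAsFactors = FALSE)
  out <- select_strong(res, 0.7)
  expect_equal(out$positive$feature_id, "f1")
  expect_equal(out$negative$feature_id, "f2")
  expect_equal(out$all$class[3:5], rep("none", 3))  # r = 0.70 is not > 0.70
  loose <- select_strong(res, 0.5)
  expect_true(all(out$positive$feature_id %in% loose$positive$feature_id))
  expect_true(all(out$negative$feature_id %in% loose$negative$feature_id))
})

test_that("composition log ratios recover planted fractions and antisymmetry", {
  pos <- sprintf("p%d", 1:100)   # 40 of genus X, 60 of genus Y
  neg <- sprintf("n%d", 1:100)   # 5 of genus X, 95 of genus Y
  ann <- tiny_annotation(c(pos, neg),
                         genus = c(rep("X", 40), rep("Y", 60),
                                   rep("X", 5), rep("Y", 95)))
  lr <- composition_log_ratio(pos, neg, ann, "genus")
  x <- lr[lr$category == "X", ]
  expect_equal(x$f_pos, 0.4)
  expect_equal(x$f_neg, 0.05)
  expect_equal(x$log_ratio, log2(0.405 / 0.055), tolerance = 1e-12) # eps = 0.005
  expect_equal(x$n_pos, 40L)
  swapped <- composition_log_ratio(neg, pos, ann, "genus")
  expect_equal(swapped$log_ratio, -lr$log_ratio)
  # identical compositions give zero everywhere
  same <- composition_log_ratio(pos, pos, ann, "genus")
  expect_true(all(same$log_ratio == 0))
  expect_error(composition_log_ratio(character(0), neg, ann, "genus"),
               "nonempty")
})

test_that("gram summary reports unknown separately and planted enrichment", {
  pos <- sprintf("p%d", 1:50)    # 40 gram-negative, 10 unknown
  neg <- sprintf("n%d", 1:50)    # 10 gram-negative, 40 positive
  ann <- tiny_annotation(c(pos, neg),
                         genus = rep("G", 100),
                         gram = c(rep("negative", 40), rep("unknown", 10),
                                  rep("negative", 10), rep("positive", 40)))
  gs <- gram_stain_summary(pos, neg, ann)
  neg_row <- gs[gs$category == "negative", ]
  expect_equal(neg_row$f_pos / neg_row$f_neg, 4)  # 0.8 vs 0.2
  expect_true("unknown" %in% gs$category)
})

test_that("association overlap counts shared (feature, biomarker, sign) tuples", {
  mk <- function(ids, bm, r) {
    select_strong(data.frame(feature_id = ids, biomarker = bm, slope = 1,
                             intercept = 0, r = r, n_used = 8, p_value = NA,
                             stringsAsFactors = FALSE), 0.7)$all
  }
  g <- rbind(mk(c("a", "b", "c"), "cal", c(0.9, 0.9, -0.9)),
             mk("a", "crp", 0.9))
  p <- rbind(mk(c("a", "b", "d"), "cal", c(0.9, -0.9, 0.9)))
  ov <- association_overlap(g, p, shared_features = c("a", "b", "c", "d"))
  # shared: only (a, cal, positive); b flips sign between layers
  expect_equal(ov$n_shared, 1L)
  expect_equal(ov$n_total, 6L)
  expect_equal(ov$shared_fraction, 1 / 6)
  venn_cal <- ov$venn[ov$venn$biomarker == "cal", ]
  expect_equal(venn_cal$shared, 1L)
  expect_equal(venn_cal$gene_only, 2L)
  expect_equal(venn_cal$protein_only, 2L)
  # identical strong sets share everything
  ov2 <- association_overlap(g, g, shared_features = c("a", "b", "c"))
  expect_equal(ov2$shared_fraction, 1)
  # disjoint sets share nothing
  ov3 <- association_overlap(mk("a", "cal", 0.9), mk("b", "cal", 0.9),
                             shared_features = c("a", "b"))
  expect_equal(ov3$n_shared, 0L)
})

test_that("planted 10% overlap fixture is counted exactly", {
  set.seed(21)
  mk <- function(ids) {
    data.frame(feature_id = ids, biomarker = "cal", slope = 1, intercept = 0,
               r = 0.9, n_used = 8, p_value = NA, class = "positive",
               stringsAsFactors = FALSE)
  }
  shared <- sprintf("sh%d", 1:10)
  g <- mk(c(shared, sprintf("g%d", 1:45)))
  p <- mk(c(shared, sprintf("p%d", 1:45)))
  ov <- association_overlap(g, p, shared_features = c(shared, sprintf("g%d", 1:45),
                                                      sprintf("p%d", 1:45)))
  expect_equal(ov$n_shared, 10L)
  expect_equal(ov$n_total, 100L)
  expect_equal(ov$shared_fraction, 0.1)
})

test_that("dysbiosis index: zero at equal sums, monotone, antisymmetric", {
  ft <- tiny_table(matrix(c(4, 2, 4, 6, 2, 1, 6, 7), 4, 2, byrow = TRUE),
                   features = c("Escherichia coli", "Fusobacterium nucleatum",
                                "Faecalibacterium prausnitzii",
                                "Bacteroides vulgatus"))
  inc <- c("Escherichia coli", "Fusobacterium nucleatum")
  dec <- c("Faecalibacterium prausnitzii", "Bacteroides vulgatus")
  di <- dysbiosis_index(ft, inc, dec)
  expect_equal(unname(di$index[1]), 0)         # 6 vs 6... (4+2) / (4+2)
  swapped <- dysbiosis_index(ft, dec, inc)
  expect_equal(swapped$index, -di$index)
  doubled <- dysbiosis_index(
    feature_table(ft$values * c(2, 2, 1, 1), "gene"), inc, dec)
  expect_true(all(doubled$index > di$index))
  expect_error(dysbiosis_index(ft, c("Missing species"), dec), "Missing species")
  # approximate scale invariance (eps effects only)
  scaled <- dysbiosis_index(feature_table(ft$values * 100, "gene"), inc, dec)
  expect_equal(scaled$index, di$index, tolerance = 1e-6)
})

test_that("dysbiosis forced arithmetic: 8 vs 2 gives about 2 bits", {
  # the small third taxon keeps the pseudocount negligible
  ft <- tiny_table(matrix(c(8, 2, 0.01), 3, 1),
                   features = c("Escherichia coli",
                                "Faecalibacterium prausnitzii",
                                "Blautia obeum"))
  di <- dysbiosis_index(ft, "Escherichia coli", "Faecalibacterium prausnitzii")
  expect_equal(unname(di$index[1]), 2, tolerance = 0.01)  # eps-perturbed
})

test_that("biomarker cross-correlation matches the covariance oracle", {
  set.seed(22)
  s <- matrix(rlnorm(4 * 8), 4, 8,
              dimnames = list(c("a", "b", "c", "flat"), sprintf("s%d", 1:8)))
  s["b", ] <- 10 - s["a", ]   # perfect anticorrelation
  s["flat", ] <- 5
  m <- biomarker_crosscorrelation(s)
  expect_equal(m["a", "b"], -1)
  expect_equal(diag(m), setNames(rep(1, 4), rownames(s)))
  oracle <- sum((s["a", ] - mean(s["a", ])) * (s["c", ] - mean(s["c", ]))) /
    ((8 - 1) * sd(s["a", ]) * sd(s["c", ]))
  expect_equal(m["a", "c"], oracle, tolerance = 1e-12)
  expect_true(is.na(m["flat", "a"]))
})
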