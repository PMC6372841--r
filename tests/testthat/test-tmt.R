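test_that("filter_psms applies the rules in order and logs first failures", {
  sn <- matrix(20, 6, 4, dimnames = list(NULL, c("126", "s1", "s2", "131")))
  sn[4, ] <- 8                       # mean S/N below 10
  psms <- tiny_psms(sn, peptides = sprintf("PEP%d", 1:6),
                    proteins = rep("A", 6),
                    confidence = c("high", "moderate", "ambiguous",
                                   "high", "high", "high"),
                    interference = c(5, 30, 30, 5, 30, 5))
  out <- filter_psms(psms)
  # row 2 fails confidence before its interference is even considered
  expect_equal(unname(out$rejection_log),
               c(1L, 1L, 1L, 1L))
  expect_equal(out$kept$peptide, c("PEP1", "PEP6"))
  expect_equal(nrow(out$kept) + sum(out$rejection_log), nrow(psms))
})

test_that("filter thresholds sit exactly at 25% interference and S/N 10", {
  sn <- matrix(10, 2, 4, dimnames = list(NULL, c("126", "s1", "s2", "131")))
  psms <- tiny_psms(sn, peptides = c("P1", "P2"), proteins = c("A", "B"),
                    interference = c(25, 25.01))
  out <- filter_psms(psms)
  expect_equal(out$kept$peptide, "P1")  # 25 passes, above 25 fails; S/N 10 passes
  empty <- filter_psms(psms[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_true(all(empty$rejection_log == 0))
})

test_that("shared peptides go to prior-holding, else longest, proteins", {
  sn <- matrix(50, 4, 4, dimnames = list(NULL, c("126", "s1", "s2", "131")))
  psms <- tiny_psms(sn, peptides = c("UNIQ_A", "SHARED_AB", "SHARED_CD", "DUP"),
                    proteins = c("A", "A;B", "C;D", "A"))
  psms <- rbind(psms, psms[4, ])      # exact duplicate record
  lens <- c(A = 120, B = 300, C = 200, D = 200)
  out <- resolve_shared_peptides(psms, lens)
  expect_equal(nrow(out), 4)          # duplicate collapsed
  got <- setNames(out$assigned_protein, out$peptide)
  expect_equal(unname(got["SHARED_AB"]), "A")  # prior beats length
  expect_equal(unname(got["SHARED_CD"]), "C")  # equal length -> lexicographic
  expect_equal(unname(got["UNIQ_A"]), "A")
  expect_error(resolve_shared_peptides(psms, lens[-2]), "unknown length")
})

test_that("rollup sums channel vectors per assigned protein", {
  sn <- matrix(c(1, 2, 3, 4,
                 3, 4, 5, 6,
                 10, 10, 10, 10), 3, byrow = TRUE,
               dimnames = list(NULL, c("126", "s1", "s2", "131")))
  psms <- tiny_psms(sn, peptides = c("P1", "P2", "P3"),
                    proteins = c("A", "A", "B"))
  psms$assigned_protein <- c("A", "A", "B")
  m <- rollup_psms_to_proteins(psms, tiny_plex())
  expect_equal(unname(m["A", ]), c(4, 6, 8, 10))
  expect_equal(unname(m["B", ]), c(10, 10, 10, 10))
})

test_that("bridge normalization is invariant to per-plex scaling", {
  sim <- simulate_psm_experiment(n_proteins = 25, noise_sd = 0.1, seed = 21)
  res <- resolve_shared_peptides(filter_psms(sim$psms)$kept, sim$protein_lengths)
  mats <- lapply(sim$designs, function(d) rollup_psms_to_proteins(res, d))
  a <- bridge_normalize(mats, sim$designs)
  mats2 <- mats
  mats2[[2]] <- mats2[[2]] * 13.7
  b <- bridge_normalize(mats2, sim$designs)
  expect_lt(max(abs(a$values - b$values), na.rm = TRUE), 1e-9)
  # global median of the final table is 1 by construction
  expect_equal(median(a$values, na.rm = TRUE), 1)
})

test_that("sample channels identical to the bridges normalize to exactly 1", {
  sn <- matrix(c(5, 5, 5, 5,
                 2, 2, 2, 2), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("126", "s1", "s2", "131")))
  out <- bridge_normalize(list(plex1 = sn), list(tiny_plex()))
  expect_true(all(out$values == 1))
})

test_that("zero bridge signal drops the protein in that plex and is logged", {
  sn <- matrix(c(0, 5, 9, 5,
                 2, 2, 7, 2), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("126", "s1", "s2", "131")))
  out <- bridge_normalize(list(plex1 = sn), list(tiny_plex()))
  expect_false("A" %in% rownames(out$values))
  log <- attr(out, "bridge_log")
  expect_equal(log$protein, "A")
})

test_that("LCA adjustment walks lineages to the deepest shared rank", {
  ann <- tiny_annotation(c("A", "B", "C"),
                         genus = c("Faecalibacterium", "Roseburia", "Roseburia"))
  sn <- matrix(50, 3, 4, dimnames = list(NULL, c("126", "s1", "s2", "131")))
  psms <- tiny_psms(sn, peptides = c("P1", "P2", "P3"),
                    proteins = c("B;C", "A;B", "B"))
  psms$assigned_protein <- c("B", "B", "B")
  out <- lca_adjust_taxonomy(psms, ann)
  # P1 agrees to genus, P2 only to family; protein B's LCA is family level
  expect_equal(out$family[out$feature_id == "B"], "fam")
  expect_true(is.na(out$genus[out$feature_id == "B"]))
})

test_that("LCA with no shared rank or no annotation yields unclassified", {
  ann <- tiny_annotation(c("A", "B"), genus = c("Roseburia", "Roseburia"))
  ann$domain <- c("Bacteria", "Archaea")
  ann$phylum <- c("Firmicutes", "Euryarchaeota")
  sn <- matrix(50, 2, 4, dimnames = list(NULL, c("126", "s1", "s2", "131")))
  psms <- tiny_psms(sn, peptides = c("P1", "P2"),
                    proteins = c("A;B", "Z"))
  psms$assigned_protein <- c("A", "Z")
  out <- lca_adjust_taxonomy(psms, ann)
  expect_true(is.na(out$domain[out$feature_id == "A"]))
  expect_equal(out$gram[out$feature_id == "Z"], "unknown")
})
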