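#!/usr/bin/env Rscript
# Distance/ordination/permutation layer: Bray-Curtis distances per layer
# (complete-case proteins), PCoA, Procrustes superposition of the two
# ordinations, Mantel association between the distance matrices, PERMANOVA
# of inflammation state, and Friedman tests of genus compositions.

suppressPackageStartupMessages(library(concordome))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20260927L
inp <- "results/inputs"
out <- "results/ordination"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_feature_table(file.path(inp, "gene_counts.tsv"), "gene")
proteins <- read_feature_table(file.path(inp, "protein_table.tsv"), "protein")
meta <- read_sample_metadata(file.path(inp, "metadata.tsv"))
ann <- read_annotation_table(file.path(inp, "annotation.tsv"))

genes <- collapse_replicates(cpm_normalize(counts$values), meta, "sum")
prot <- filter_complete_features(collapse_replicates(proteins, meta, "mean"))
cat(sprintf("complete-case proteins used for ordination: %d\n",
            nrow(prot$values)))

dg <- bray_curtis(genes)
dp <- bray_curtis(prot)
write_distance_matrix(dg, file.path(out, "bray_curtis_gene.tsv"))
write_distance_matrix(dp, file.path(out, "bray_curtis_protein.tsv"))

og <- pcoa(dg); op <- pcoa(dp)
write.table(data.frame(sample = rownames(og$coordinates), og$coordinates),
            file.path(out, "pcoa_gene.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = rownames(op$coordinates), op$coordinates),
            file.path(out, "pcoa_protein.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pr <- procrustes_analysis(og$coordinates, op$coordinates)
mt <- mantel(dg, dp, n_perm = 999, seed = seed)
cat(sprintf("Procrustes M2 = %.4f; Mantel r = %.3f (p = %.4g)\n",
            pr$m2, mt$statistic, mt$p_value))

date_state <- unique(meta[c("collection_date", "inflammation_state")])
grp <- date_state$inflammation_state[match(colnames(dg),
                                           date_state$collection_date)]
pg <- permanova(dg, grp, n_perm = 999, seed = seed)
pp <- permanova(dp, grp, n_perm = 999, seed = seed)
cat(sprintf("PERMANOVA vs inflammation state: pseudo-F %.3f (gene, p %.3f), %.3f (protein, p %.3f)\n",
            pg$statistic, pg$p_value, pp$statistic, pp$p_value))

comp <- function(ft) {
  v <- rollup_by_category(ft, ann, "genus")$values
  sweep(v, 2, colSums(v), "/")
}
fr_g <- friedman_rank_test(t(comp(genes)))
fr_p <- friedman_rank_test(t(comp(prot)))
cat(sprintf("Friedman genus compositions: chi2 %.2f (gene, p %.3g), chi2 %.2f (protein, p %.3g)\n",
            fr_g$statistic, fr_g$p_value, fr_p$statistic, fr_p$p_value))

jsonlite::write_json(list(procrustes_m2 = pr$m2, mantel_r = mt$statistic,
                          mantel_p = mt$p_value,
                          pseudo_F_gene = pg$statistic,
                          pseudo_F_protein = pp$statistic,
                          friedman_p_gene = fr_g$p_value,
                          friedman_p_protein = fr_p$p_value,
                          n_perm = 999, seed = seed),
                     file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
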