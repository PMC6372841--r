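#!/usr/bin/env Rscript
# Inter-omic concordance: CPM-normalizes the gene counts, collapses
# replicates (gene sums, protein means), aligns the shared ORFs, and
# computes per-feature Spearman correlations, category-level rollups,
# dynamic ranges and SD profiles.

suppressPackageStartupMessages(library(concordome))
inp <- "results/inputs"
out <- "results/concordance"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_feature_table(file.path(inp, "gene_counts.tsv"), "gene")
proteins <- read_feature_table(file.path(inp, "protein_table.tsv"), "protein")
meta <- read_sample_metadata(file.path(inp, "metadata.tsv"))
ann <- read_annotation_table(file.path(inp, "annotation.tsv"))

genes <- collapse_replicates(cpm_normalize(counts$values), meta, "sum")
prot <- collapse_replicates(proteins, meta, "mean")
paired <- subset_shared_features(genes, prot)
cs <- paired_feature_spearman(paired)
cat(sprintf("%d shared ORFs; per-feature Spearman mean %.3f, sd %.3f (%d omitted)\n",
            paired$n_shared, cs$mean, cs$sd, cs$n_omitted))
truth <- read_study_truth(file.path(inp, "study_truth.json"))
bg <- setdiff(names(cs$rho), unlist(truth$tracker_ids))
cat(sprintf("background ORFs only (excluding planted biomarker trackers): mean %.3f over %d\n",
            mean(cs$rho[bg], na.rm = TRUE), length(bg)))
write.table(data.frame(feature_id = names(cs$rho), rho = cs$rho),
            file.path(out, "paired_spearman.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cs$histogram, file.path(out, "spearman_histogram.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

go <- category_concordance(paired$genes, paired$proteins, ann, "GO",
                           mode = "category_summed")
cat(sprintf("summed-GO correlations: mean %.3f, sd %.3f over %d categories\n",
            go$mean, go$sd, go$n))
nog <- category_concordance(paired$genes, paired$proteins, ann, "eggNOG",
                            mode = "per_feature_grouped")
write.table(attr(nog, "by_category"), file.path(out, "eggnog_rho_by_category.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (layer in c("gene", "protein")) {
  tab <- if (layer == "gene") genes else prot
  dr <- dynamic_range(tab)
  sp <- sd_profile(tab, log_transform = TRUE)
  cat(sprintf("%s layer: median max/min %.2f (max %.3g), log10-SD variance %.3g\n",
              layer, median(dr$max_min_ratio), max(dr$max_min_ratio),
              attr(sp, "distribution_variance")))
  write.table(dr, file.path(out, paste0("dynamic_range_", layer, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
go_roll <- rollup_by_category(genes, ann, "GO")
top <- top_fluctuating_categories(dynamic_range(go_roll, "category"), 10)
write.table(top, file.path(out, "top_fluctuating_go.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("largest gene-layer GO fluctuation:", top$item[1],
    sprintf("(%.1f-fold)\n", top$max_min_ratio[1]))
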