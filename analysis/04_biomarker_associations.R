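#!/usr/bin/env Rscript
# Immune-biomarker associations: extracts the biomarker series from the
# protein table, regresses every feature in both layers against each
# biomarker, selects large effect sizes (|r| > 0.7), and summarizes the
# selected sets as genus/eggNOG/Gram composition log ratios, layer overlap
# and the microbial dysbiosis index.

suppressPackageStartupMessages(library(concordome))
inp <- "results/inputs"
out <- "results/associations"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_feature_table(file.path(inp, "gene_counts.tsv"), "gene")
proteins <- read_feature_table(file.path(inp, "protein_table.tsv"), "protein")
meta <- read_sample_metadata(file.path(inp, "metadata.tsv"))
ann <- read_annotation_table(file.path(inp, "annotation.tsv"))

genes <- collapse_replicates(cpm_normalize(counts$values), meta, "sum")
prot <- collapse_replicates(proteins, meta, "mean")
bio <- extract_biomarkers(prot, biomarker_protein_map())
write_biomarker_series(bio, file.path(out, "biomarkers.tsv"))
cc <- biomarker_crosscorrelation(bio)
cat(sprintf("calprotectin cross-correlations: lactoferrin %.2f, S-IgA %.2f\n",
            cc["calprotectin", "lactoferrin"], cc["calprotectin", "S-IgA"]))

run_layer <- function(tab, label) {
  res <- do.call(rbind, lapply(rownames(bio), function(b) {
    select_strong(regress_features_vs_biomarker(tab, bio[b, ], b), 0.7)$all
  }))
  write.table(res, file.path(out, paste0("associations_", label, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
res_g <- run_layer(genes, "gene")
res_p <- run_layer(prot, "protein")
cat(sprintf("strong associations: %d gene, %d protein\n",
            sum(res_g$class != "none"), sum(res_p$class != "none")))

cal_p <- res_p[res_p$biomarker == "calprotectin", ]
lr <- composition_log_ratio(cal_p[cal_p$class == "positive", ],
                            cal_p[cal_p$class == "negative", ], ann, "genus")
write.table(lr, file.path(out, "genus_log_ratios_calprotectin.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
topg <- lr[order(-abs(lr$log_ratio)), ][1, ]
cat(sprintf("strongest genus association with calprotectin: %s (log2 ratio %.2f)\n",
            topg$category, topg$log_ratio))
gs <- gram_stain_summary(cal_p[cal_p$class == "positive", ],
                         cal_p[cal_p$class == "negative", ], ann)
write.table(gs, file.path(out, "gram_log_ratios_calprotectin.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ov <- association_overlap(res_g, res_p,
                          intersect(rownames(genes$values),
                                    rownames(prot$values)))
jsonlite::write_json(ov[setdiff(names(ov), "venn")],
                     file.path(out, "overlap.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
write.table(ov$venn, file.path(out, "overlap_venn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("shared strong associations: %d/%d (%.1f%%); shared-namespace %.1f%%\n",
            ov$n_shared, ov$n_total, 100 * ov$shared_fraction,
            100 * ov$shared_namespace_fraction))

sp <- rollup_by_category(genes, ann, "species")
di <- dysbiosis_index(sp, dysbiosis_species_lists()$increased,
                      dysbiosis_species_lists()$decreased)
write.table(data.frame(sample = names(di$index), index = di$index),
            file.path(out, "dysbiosis_index.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("dysbiosis index range over dates: [%.2f, %.2f]\n",
            min(di$index), max(di$index)))
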