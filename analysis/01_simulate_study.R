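#!/usr/bin/env Rscript
# Generates the synthetic longitudinal study all downstream steps consume:
# a paired gene/protein table set over a shared ORF namespace (8 dates x 3
# technical replicates, planted gene-protein Spearman coupling around 0.32,
# layer-specific missingness), the five immune-biomarker series with
# planted tracker features, and a PSM-level TMT experiment. Ground truth is
# serialized next to the tables.

suppressPackageStartupMessages(library(concordome))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20260927L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base <- simulate_paired_omics(n_features = 2000, seed = seed)
bm <- simulate_biomarker_structure(base, n_strong = 600, noise_sd = 0.1,
                                   seed = seed + 1L)
write_feature_table(feature_table(bm$gene_counts + 0, "gene"),
                    file.path(out, "gene_counts.tsv"))
write_feature_table(bm$proteins, file.path(out, "protein_table.tsv"))
write_annotation_table(bm$annotation, file.path(out, "annotation.tsv"))
write_sample_metadata(bm$metadata, file.path(out, "metadata.tsv"))
write_biomarker_series(bm$biomarkers, file.path(out, "biomarker_truth.tsv"))
write_study_truth(bm$truth, file.path(out, "study_truth.json"))

tmt <- simulate_psm_experiment(n_proteins = 300, noise_sd = 0.1,
                               loading_error_range = c(0.8, 1.25),
                               violations = c(moderate_confidence = 40L,
                                              ambiguous = 25L,
                                              high_interference = 30L,
                                              low_sn = 35L),
                               shared_peptide_frac = 0.1, seed = seed + 2L)
write_psm_table(tmt$psms, file.path(out, "psms.tsv"))
write_plex_designs(tmt$designs, file.path(out, "plex_designs.json"))
write_study_truth(tmt$truth, file.path(out, "tmt_truth.json"))

cat(sprintf("wrote study inputs to %s: %d ORFs (+%d trackers), %d PSMs over %d plexes\n",
            out, nrow(base$gene_counts), length(bm$truth$tracker_ids),
            nrow(tmt$psms), length(tmt$designs)))
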