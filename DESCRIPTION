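Package: concordome
Title: Gene-Protein Concordance Analysis for Paired Metagenome-Metaproteome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing metagenomic gene abundances with TMT
    (tandem mass tag) metaproteomic protein abundances over a shared ORF
    namespace in longitudinal gut-microbiome studies. Implements
    counts-per-million normalization, PSM-level filtering and
    bridge-channel normalization of isobaric quantification data,
    paired gene-protein Spearman concordance and functional-category
    rollups, effect-size-thresholded association of features with fecal
    immune biomarkers summarized as compositional log ratios, a
    microbial dysbiosis index, and a self-contained
    distance/ordination/permutation statistics layer (Bray-Curtis,
    principal-coordinate analysis, Procrustes, Mantel, PERMANOVA,
    Friedman). A synthetic-data module generates PSM-level experiments
    and paired omic tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
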