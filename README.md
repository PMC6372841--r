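# concordome

Concordance analysis for paired metagenome–metaproteome studies of the gut
microbiome.

## The problem

Shotgun metagenomics counts microbial gene copies; tandem-mass-tag (TMT)
metaproteomics quantifies the proteins those genes express. In a
longitudinal study of a single subject with colonic Crohn's disease, both
layers can be quantified over a *shared ORF namespace* (a protein database
assembled from the subject's own reads), which makes gene-to-protein
comparison direct: the same identifier indexes a gene's counts-per-million
profile and its protein's normalized signal-to-noise profile across
collection dates. `concordome` implements that comparison end to end, for
anyone who has (or simulates) per-replicate gene counts, PSM-level TMT
quantification, feature annotations, and immune-biomarker measurements:

* **Quantification** — CPM normalization with explicit zero padding;
  PSM filtering (moderate-confidence/ambiguous assignments, isolation
  interference > 25%, mean reporter S/N < 10), deterministic shared-peptide
  resolution, per-protein rollup, and two-bridge normalization across
  plexes (channels 126/131 carry a pooled composite; per-protein bridge
  ratios are median-rescaled, averaged, and the table scaled to global
  median 1); optional lowest-common-ancestor taxonomy adjustment.
* **Concordance** — per-ORF Spearman ρ between gene and protein profiles
  across dates; rollups and correlations by GO/KO/eggNOG/genus/phylum;
  max/min dynamic ranges and SD profiles; top fluctuating categories.
* **Biomarker association** — OLS of every feature against calprotectin,
  CRP, lysozyme, lactoferrin and S-IgA; effect-size selection at |r| > 0.7;
  compositional log2 ratios of positive vs negative sets by genus,
  function and Gram stain; cross-layer overlap of (feature, biomarker,
  sign) triples; the microbial dysbiosis index
  log2(Σ CD-increased / Σ CD-decreased taxa).
* **Ordination** — self-contained Bray-Curtis, PCoA, Procrustes M²,
  Mantel, PERMANOVA pseudo-F (with exhaustive enumeration for small
  designs) and tie-corrected Friedman tests, all seeded and reproducible.
* **Synthetic studies** — generators for PSM-level TMT experiments and
  paired omic tables with known ground truth: planted per-feature Spearman
  targets (finite-n calibrated), layer-specific missingness (4% vs 52%
  complete features), biomarker correlation structure, tracker features
  with exact genus-enrichment folds, per-plex scale factors, loading
  errors and per-rule filter violations.

## Worked example

```r
library(concordome)

# a synthetic study: 500 shared ORFs, 8 dates x 3 replicates,
# planted mean gene-protein Spearman 0.32
sim   <- simulate_paired_omics(n_features = 500, seed = 7)
genes <- collapse_replicates(cpm_normalize(sim$gene_counts), sim$metadata, mode = "sum")
prot  <- collapse_replicates(sim$proteins, sim$metadata, mode = "mean")

cs <- paired_feature_spearman(subset_shared_features(genes, prot))
cs
#> correlation_summary: n = 500, mean rho = 0.293, sd = 0.364 (0 omitted)

mantel(bray_curtis(genes), bray_curtis(filter_complete_features(prot)),
       n_perm = 999, seed = 7)
#> Mantel r = -0.3724, p = 0.977 (999 permutations, seed 7)

di <- dysbiosis_index(rollup_by_category(genes, sim$annotation, "species"),
                      dysbiosis_species_lists()$increased,
                      dysbiosis_species_lists()$decreased)
di
#> dysbiosis_index over 8 samples (2 increased, 3 decreased taxa matched)
#> 2011-12-28 2012-06-15 2013-01-10 2013-08-20 2014-03-05 2014-11-18 2015-07-02
#>     -1.204     -0.611     -2.055     -1.587     -1.693     -1.623     -1.533
#> 2016-05-22
#>     -1.368
```

The mean per-feature ρ of 0.293 estimates the planted coupling of 0.32 at
500 features (the Monte-Carlo standard error at this size is ≈ 0.016, and
count rounding and planted zeros attenuate a little further). The Mantel
test is null here by design: the generator couples layers per feature, not
at the community scale, so the two distance matrices are independent. The
dysbiosis index is negative on every date because the synthetic genus pool
gives the three CD-decreased species more total abundance than the two
CD-increased ones.

## The analysis workflow

The numbered drivers under `analysis/` run the whole study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R        # inputs + ground truth
Rscript analysis/02_tmt_normalization.R     # PSM filters -> protein table
Rscript analysis/03_concordance.R           # per-ORF and per-category rho
Rscript analysis/04_biomarker_associations.R
Rscript analysis/05_ordination.R            # distances, PCoA, permutation tests
```

`run_pipeline()` executes the same stages from a single config list and
writes an md5 manifest; identical config + seed reproduces every output
bitwise.

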