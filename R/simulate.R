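#' Reference pools used by the synthetic study generators
#'
#' A small panel of gut genera with phylum and Gram-stain labels (and a
#' representative species each), the eggNOG-style functional categories,
#' and the default immune-biomarker -> human-protein subunit map
#' (calprotectin is the S100A8 + S100A9 heterodimer).
#'
#' @return `genus_reference()` returns a data.frame with columns
#'   `genus`, `phylum`, `gram`, `species`; `biomarker_protein_map()` a
#'   named list; `dysbiosis_species_lists()` a list with `increased` and
#'   `decreased` species vectors (taxa reported up- and down-shifted in
#'   Crohn's disease).
#' @export
genus_reference <- function() {
  data.frame(
    genus = c("Escherichia", "Bacteroides", "Faecalibacterium", "Alistipes",
              "Akkermansia", "Anaerostipes", "Butyricicoccus", "Lachnospira",
              "Blautia", "Roseburia", "Prevotella", "Eubacterium",
              "Fusobacterium", "Bifidobacterium"),
    phylum = c("Proteobacteria", "Bacteroidetes", "Firmicutes", "Bacteroidetes",
               "Verrucomicrobia", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Bacteroidetes", "Firmicutes",
               "Fusobacteria", "Actinobacteria"),
    gram = c("negative", "negative", "positive", "negative",
             "negative", "positive", "positive", "positive",
             "positive", "positive", "negative", "positive",
             "negative", "positive"),
    species = c("Escherichia coli", "Bacteroides vulgatus",
                "Faecalibacterium prausnitzii", "Alistipes putredinis",
                "Akkermansia muciniphila", "Anaerostipes hadrus",
                "Butyricicoccus pullicaecorum", "Lachnospira pectinoschiza",
                "Blautia obeum", "Roseburia intestinalis",
                "Prevotella copri", "Eubacterium rectale",
                "Fusobacterium nucleatum", "Bifidobacterium longum"),
    stringsAsFactors = FALSE)
}

eggnog_categories <- function() {
  c("Energy production and conversion",
    "Carbohydrate transport and metabolism",
    "Translation, ribosomal structure and biogenesis",
    "Amino acid transport and metabolism",
    "Cell wall/membrane/envelope biogenesis",
    "Posttranslational modification, protein turnover, chaperones",
    "Nucleotide transport and metabolism",
    "Inorganic ion transport and metabolism",
    "Cell cycle control, cell division, chromosome partitioning",
    "Replication, recombination and repair")
}

#' @rdname genus_reference
#' @export
biomarker_protein_map <- function() {
  list(calprotectin = c("HUMAN_S100A8", "HUMAN_S100A9"),
       CRP = "HUMAN_CRP",
       lysozyme = "HUMAN_LYZ",
       lactoferrin = "HUMAN_LTF",
       `S-IgA` = "HUMAN_IGHA1")
}

#' @rdname genus_reference
#' @export
dysbiosis_species_lists <- function() {
  list(increased = c("Escherichia coli", "Fusobacterium nucleatum"),
       decreased = c("Faecalibacterium prausnitzii", "Eubacterium rectale",
                     "Bacteroides vulgatus"))
}

study_dates <- function(n_dates = 8) {
  base <- c("2011-12-28", "2012-06-15", "2013-01-10", "2013-08-20",
            "2014-03-05", "2014-11-18", "2015-07-02", "2016-05-22")
  if (n_dates <= 8) return(base[seq_len(n_dates)])
  c(base, format(as.Date("2016-05-22") + 180 * seq_len(n_dates - 8)))
}

#' Study sample metadata for the default longitudinal design
#'
#' @param n_dates,n_reps Collection dates and technical replicates
#'   (default 8 x 3, mirroring the study design).
#' @param high_dates Optional character vector of dates labeled
#'   high-inflammation; by default the first half of the dates.
#' @return A [sample_metadata()] data.frame with sample ids
#'   `d<dd>_r<r>`.
#' @export
make_study_metadata <- function(n_dates = 8, n_reps = 3, high_dates = NULL) {
  dates <- study_dates(n_dates)
  if (is.null(high_dates)) high_dates <- dates[seq_len(ceiling(n_dates / 2))]
  grid <- expand.grid(rep = seq_len(n_reps), date_i = seq_len(n_dates))
  sample_metadata(data.frame(
    sample_id = sprintf("d%02d_r%d", grid$date_i, grid$rep),
    collection_date = dates[grid$date_i],
    replicate_index = grid$rep,
    inflammation_state = ifelse(dates[grid$date_i] %in% high_dates,
                                "high", "low"),
    stringsAsFactors = FALSE))
}

#' Expected sample Spearman coefficient under a Gaussian copula
#'
#' For bivariate normal data with latent correlation `rho_lat`, the
#' expectation of the sample Spearman coefficient at sample size n is
#' (6 / (pi (n + 1))) (asin(rho_lat) + (n - 2) asin(rho_lat / 2)).
#' `latent_rho_for_spearman()` inverts this to find the latent
#' correlation whose expected sample Spearman equals a target — the
#' finite-n correction matters at n = 8, where the naive large-n
#' inversion would undershoot the target by about 0.03.
#'
#' @param rho_lat Latent (Pearson) correlation of the Gaussian copula.
#' @param n Sample size.
#' @return Expected value of the sample Spearman coefficient.
#' @export
expected_spearman <- function(rho_lat, n) {
  6 / (pi * (n + 1)) * (asin(rho_lat) + (n - 2) * asin(rho_lat / 2))
}

#' @rdname expected_spearman
#' @param target Desired expected sample Spearman, in (-1, 1).
#' @export
latent_rho_for_spearman <- function(target, n) {
  hi <- expected_spearman(0.9999995, n)
  vapply(target, function(t) {
    if (t >= hi) return(1)
    if (t <= -hi) return(-1)
    stats::uniroot(function(r) expected_spearman(r, n) - t,
                   lower = -0.9999995, upper = 0.9999995, tol = 1e-10)$root
  }, numeric(1))
}

random_annotation <- function(feature_ids, seed_state_ok = TRUE) {
  ref <- genus_reference()
  n <- length(feature_ids)
  gi <- sample.int(nrow(ref), n, replace = TRUE)
  go_pool <- sprintf("GO:%07d", seq(5000, 5000 + 29))
  ko_pool <- sprintf("K%05d", seq_len(40))
  nog <- eggnog_categories()
  go <- vapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) NA_character_ else
      paste(sample(go_pool, k), collapse = ";")
  }, character(1))
  annotation_table(data.frame(
    feature_id = feature_ids,
    domain = "Bacteria",
    phylum = ref$phylum[gi],
    class = paste0(ref$phylum[gi], "_class"),
    order = paste0(ref$phylum[gi], "_order"),
    family = paste0(ref$genus[gi], "_family"),
    genus = ref$genus[gi],
    species = ref$species[gi],
    go_terms = go,
    ko = ifelse(stats::runif(n) < 0.6, sample(ko_pool, n, replace = TRUE),
                NA_character_),
    eggnog = ifelse(stats::runif(n) < 0.8, sample(nog, n, replace = TRUE),
                    NA_character_),
    gram = ref$gram[gi],
    stringsAsFactors = FALSE))
}

#' Simulate a paired gene/protein study with planted concordance
#'
#' Generates a gene count matrix and a protein abundance table over a
#' shared ORF namespace for the default 8-dates x 3-replicates design,
#' with a latent-Gaussian rank coupling per feature calibrated (via
#' [latent_rho_for_spearman()]) so that the expected date-level sample
#' Spearman correlation equals that feature's target, drawn around
#' `rho_mean`. Layer-specific missingness is planted cellwise: gene
#' absences become zero counts, protein absences become `NA`, at rates
#' chosen so the expected fraction of fully complete features matches
#' `gene_complete_frac` and `protein_complete_frac`.
#'
#' @param n_features Number of shared ORFs (default 2000).
#' @param n_dates,n_reps Study shape (default 8 x 3).
#' @param rho_mean Target mean per-feature Spearman (default 0.32).
#' @param rho_sd Between-feature dispersion of targets (default 0.15).
#' @param gene_complete_frac,protein_complete_frac Expected fraction of
#'   features with no missing cell per layer (defaults 0.04 and 0.52,
#'   the study's completeness contrast).
#' @param replicate_cv Lognormal coefficient of variation of technical
#'   replicate noise (default 0.05; 0 makes replicates exact copies).
#' @param category_rho Optional named numeric vector of per-category
#'   target mean Spearman values; features are then assigned to these
#'   eggNOG-style categories in equal blocks (`features_per_category`
#'   each) with targets drawn around the category's value.
#' @param features_per_category Block size when `category_rho` is given.
#' @param seed Integer seed; all output is a pure function of the
#'   configuration and seed.
#' @return List: `gene_counts` (integer matrix features x replicate
#'   samples), `proteins` (`feature_table`), `annotation`
#'   (`annotation_table`), `metadata` ([sample_metadata()]), and `truth`
#'   (per-feature targets, latent correlations, planted masks, rates).
#' @export
simulate_paired_omics <- function(n_features = 2000, n_dates = 8, n_reps = 3,
                                  rho_mean = 0.32, rho_sd = 0.15,
                                  gene_complete_frac = 0.04,
                                  protein_complete_frac = 0.52,
                                  replicate_cv = 0.05,
                                  category_rho = NULL,
                                  features_per_category = 200,
                                  seed) {
  stopifnot(rho_mean >= -1, rho_mean <= 1)
  with_seed(seed, {
    meta <- make_study_metadata(n_dates, n_reps)
    n_samp <- n_dates * n_reps
    fid <- sprintf("ORF_%05d", seq_len(n_features))

    if (is.null(category_rho)) {
      target <- pmin(pmax(stats::rnorm(n_features, rho_mean, rho_sd), -1), 1)
      cat_of <- NULL
    } else {
      n_features <- length(category_rho) * features_per_category
      fid <- sprintf("ORF_%05d", seq_len(n_features))
      cat_of <- rep(names(category_rho), each = features_per_category)
      target <- pmin(pmax(stats::rnorm(n_features,
                                       rep(unname(category_rho),
                                           each = features_per_category),
                                       rho_sd), -1), 1)
    }
    rho_lat <- latent_rho_for_spearman(target, n_dates)

    # date-level latent coupling
    u <- matrix(stats::rnorm(n_features * n_dates), n_features, n_dates)
    e <- matrix(stats::rnorm(n_features * n_dates), n_features, n_dates)
    zg <- u
    zp <- rho_lat * u + sqrt(1 - rho_lat^2) * e

    mu_g <- stats::rnorm(n_features, 7, 1.2)
    sig_g <- stats::runif(n_features, 0.8, 1.5)
    mu_p <- stats::rnorm(n_features, 0, 1.0)
    sig_p <- stats::runif(n_features, 0.6, 1.2)
    lam_g <- exp(mu_g + sig_g * zg)       # date-level expected counts
    lam_p <- exp(mu_p + sig_p * zp)       # date-level protein abundance

    rep_noise <- function() {
      if (replicate_cv == 0) return(matrix(1, n_features, n_samp))
      matrix(exp(stats::rnorm(n_features * n_samp, 0, replicate_cv)),
             n_features, n_samp)
    }
    date_idx <- rep(seq_len(n_dates), each = n_reps)
    gene_counts <- round(lam_g[, date_idx] * rep_noise())
    prot <- lam_p[, date_idx] * rep_noise()
    dimnames(gene_counts) <- dimnames(prot) <- list(fid, meta$sample_id)

    q_g <- 1 - gene_complete_frac^(1 / n_samp)
    q_p <- 1 - protein_complete_frac^(1 / n_samp)
    gene_mask <- matrix(stats::runif(n_features * n_samp) < q_g,
                        n_features, n_samp)
    prot_mask <- matrix(stats::runif(n_features * n_samp) < q_p,
                        n_features, n_samp)
    gene_counts[gene_mask] <- 0L
    prot[prot_mask] <- NA_real_
    storage.mode(gene_counts) <- "integer"

    ann <- random_annotation(fid)
    if (!is.null(cat_of)) ann$eggnog <- cat_of

    truth <- list(rho_target = stats::setNames(target, fid),
                  rho_latent = stats::setNames(rho_lat, fid),
                  category = if (is.null(cat_of)) NULL else
                    stats::setNames(cat_of, fid),
                  gene_zero_rate = q_g, protein_na_rate = q_p,
                  gene_complete_frac = gene_complete_frac,
                  protein_complete_frac = protein_complete_frac,
                  n_dates = n_dates, n_reps = n_reps, seed = as.integer(seed))
    list(gene_counts = gene_counts,
         proteins = feature_table(prot, layer = "protein"),
         annotation = ann, metadata = meta, truth = truth)
  })
}

default_biomarker_correlation <- function() {
  b <- c("calprotectin", "CRP", "lysozyme", "lactoferrin", "S-IgA")
  m <- diag(5)
  dimnames(m) <- list(b, b)
  m["calprotectin", "lactoferrin"] <- m["lactoferrin", "calprotectin"] <- 0.96
  m["calprotectin", "S-IgA"] <- m["S-IgA", "calprotectin"] <- 0.50
  m["lactoferrin", "S-IgA"] <- m["S-IgA", "lactoferrin"] <- 0.50
  m["calprotectin", "CRP"] <- m["CRP", "calprotectin"] <- 0.30
  m["lactoferrin", "CRP"] <- m["CRP", "lactoferrin"] <- 0.30
  m["S-IgA", "CRP"] <- m["CRP", "S-IgA"] <- 0.20
  m["lysozyme", "calprotectin"] <- m["calprotectin", "lysozyme"] <- 0.20
  m["lysozyme", "lactoferrin"] <- m["lactoferrin", "lysozyme"] <- 0.20
  m
}

#' Simulate biomarker series and biomarker-tracking features
#'
#' Draws the five immune-biomarker series from a Gaussian copula with a
#' stated pairwise Pearson structure (default: the strong
#' calprotectin-lactoferrin and moderate calprotectin-S-IgA coupling
#' seen in stool), adds the human biomarker subunit proteins to the
#' protein table so [extract_biomarkers()] can recover them, and plants
#' `n_strong` tracker features in both omic layers whose profiles are
#' affine in the tracked biomarker (positive or negative) plus noise.
#' Tracker genus labels are drawn with a stated enrichment fold for one
#' genus among positive vs negative trackers.
#'
#' @param omics Output of [simulate_paired_omics()] to augment.
#' @param biomarker_cor Biomarker correlation matrix (must be positive
#'   semidefinite).
#' @param n_strong Number of tracker features (default 600; half
#'   positive, half negative).
#' @param tracked Biomarker the trackers follow (default calprotectin).
#' @param noise_sd Tracker noise, as a fraction of the biomarker's
#'   standard deviation (default 0.1; 0 gives |r| = 1 trackers).
#' @param enriched_genus Genus enriched among positive trackers
#'   (default "Akkermansia").
#' @param enrichment_fold Fold enrichment of that genus among positive
#'   vs negative trackers (default 8).
#' @param base_genus_prob Probability of the enriched genus among
#'   negative trackers (default 0.05).
#' @param seed Integer seed.
#' @return List: `biomarkers` (5 x dates matrix), `gene_counts`,
#'   `proteins`, `annotation`, `metadata` (augmented copies), `id_map`,
#'   and `truth` (tracker ids, signs, genus labels, parameters).
#' @export
simulate_biomarker_structure <- function(omics,
                                         biomarker_cor = default_biomarker_correlation(),
                                         n_strong = 600,
                                         tracked = "calprotectin",
                                         noise_sd = 0.1,
                                         enriched_genus = "Akkermansia",
                                         enrichment_fold = 8,
                                         base_genus_prob = 0.05,
                                         seed) {
  ev <- eigen(biomarker_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("biomarker correlation matrix is not positive semidefinite")
  if (n_strong > nrow(omics$gene_counts))
    stop("requested more strong features than total features")
  with_seed(seed, {
    meta <- omics$metadata
    dates <- sort(unique(meta$collection_date))
    n_dates <- length(dates)
    nb <- nrow(biomarker_cor)
    ch <- chol(biomarker_cor + diag(1e-10, nb))
    z <- matrix(stats::rnorm(n_dates * nb), n_dates, nb) %*% ch
    # shifted-Gaussian marginals keep the requested Pearson structure exact
    bio <- pmax(1 + 0.25 * t(z), 0)
    dimnames(bio) <- list(rownames(biomarker_cor), dates)

    # replicate-level profiles of the human subunit proteins
    id_map <- biomarker_protein_map()
    date_idx <- match(meta$collection_date, dates)
    sub_rows <- list()
    for (b in names(id_map)) {
      ids <- id_map[[b]]
      for (p in ids) sub_rows[[p]] <- bio[b, date_idx] / length(ids)
    }
    human <- do.call(rbind, sub_rows)
    colnames(human) <- meta$sample_id

    # tracker features, affine in the tracked biomarker
    y <- bio[tracked, ]
    n_pos <- ceiling(n_strong / 2)
    signs <- rep(c(1, -1), c(n_pos, n_strong - n_pos))
    tid <- sprintf("TRK_%05d", seq_len(n_strong))
    slope <- exp(stats::rnorm(n_strong, 0, 0.5))
    make_layer <- function() {
      prof <- matrix(NA_real_, n_strong, length(meta$sample_id),
                     dimnames = list(tid, meta$sample_id))
      for (i in seq_len(n_strong)) {
        base <- signs[i] * slope[i] * y[date_idx]
        base <- base - min(base) + 0.05 * abs(mean(base))
        noise <- stats::rnorm(length(base), 0,
                              noise_sd * slope[i] * stats::sd(y))
        prof[i, ] <- pmax(base + noise, 0)
      }
      prof
    }
    trk_prot <- make_layer()
    trk_gene <- round(make_layer() * 1000)

    # genus labels with planted enrichment among positive trackers
    ref <- genus_reference()
    others <- setdiff(ref$genus, enriched_genus)
    p_pos <- min(enrichment_fold * base_genus_prob, 0.9)
    # the enrichment fold is planted with exact counts; only the filler
    # genera are drawn at random
    draw_genus <- function(p_target, n) {
      k <- round(p_target * n)
      sample(c(rep(enriched_genus, k), sample(others, n - k, replace = TRUE)))
    }
    genus <- character(n_strong)
    genus[signs > 0] <- draw_genus(p_pos, sum(signs > 0))
    genus[signs < 0] <- draw_genus(base_genus_prob, sum(signs < 0))
    gi <- match(genus, ref$genus)
    trk_ann <- annotation_table(data.frame(
      feature_id = tid, domain = "Bacteria", phylum = ref$phylum[gi],
      class = paste0(ref$phylum[gi], "_class"),
      order = paste0(ref$phylum[gi], "_order"),
      family = paste0(genus, "_family"), genus = genus,
      species = ref$species[gi],
      go_terms = NA_character_, ko = NA_character_,
      eggnog = sample(eggnog_categories(), n_strong, replace = TRUE),
      gram = ref$gram[gi], stringsAsFactors = FALSE))

    prot_v <- rbind(omics$proteins$values, trk_prot, human)
    gene_v <- rbind(omics$gene_counts, trk_gene,
                    matrix(0L, nrow(human), ncol(human),
                           dimnames = dimnames(human)))
    human_ann <- annotation_table(data.frame(
      feature_id = rownames(human), domain = NA_character_,
      phylum = NA_character_, class = NA_character_, order = NA_character_,
      family = NA_character_, genus = NA_character_, species = NA_character_,
      go_terms = NA_character_, ko = NA_character_, eggnog = NA_character_,
      gram = "unknown", stringsAsFactors = FALSE))
    ann <- annotation_table(rbind(as.data.frame(omics$annotation),
                                  as.data.frame(trk_ann),
                                  as.data.frame(human_ann)))

    truth <- list(tracker_ids = tid,
                  tracker_sign = stats::setNames(signs, tid),
                  tracker_genus = stats::setNames(genus, tid),
                  tracked = tracked, noise_sd = noise_sd,
                  enriched_genus = enriched_genus,
                  enrichment_fold = enrichment_fold,
                  p_pos = p_pos, p_neg = base_genus_prob,
                  biomarker_cor = biomarker_cor, seed = as.integer(seed))
    list(biomarkers = bio,
         gene_counts = gene_v,
         proteins = feature_table(prot_v, layer = "protein"),
         annotation = ann, metadata = meta, id_map = id_map, truth = truth)
  })
}

#' Simulate a PSM-level TMT experiment with known truth
#'
#' Emulates the study's quantification layout: `n_plexes` 10-plex runs,
#' each carrying one technical replicate of every collection date in its
#' eight sample channels plus two bridge channels ("126", "131") loaded
#' with the same pooled composite (the mean of all samples), scaled by a
#' per-plex factor. Per-channel loading errors, lognormal measurement
#' noise, shared peptides, and planted filter-rule violations
#' (moderate-confidence, ambiguous, high-interference, low
#' signal-to-noise PSMs) are all configurable and recorded in the truth
#' object.
#'
#' @param n_proteins Number of microbial proteins (default 60).
#' @param n_plexes Number of plexes = technical replicates (default 3).
#' @param n_dates Collection dates (default 8; channels = dates + 2).
#' @param psms_per_protein Mean PSMs per protein per plex (default 3).
#' @param noise_sd Lognormal sd of per-measurement noise (default 0).
#' @param plex_scale Per-plex global scale factors (default drawn
#'   uniformly from \[0.5, 2\]).
#' @param loading_error_range Range of per-channel loading factors
#'   (default `c(1, 1)`, i.e. none; the study-like setting is
#'   `c(0.8, 1.25)`).
#' @param violations Named integer vector: planted PSM counts violating
#'   each rule (`moderate_confidence`, `ambiguous`, `high_interference`,
#'   `low_sn`), each violating only that rule.
#' @param shared_peptide_frac Fraction of PSMs whose peptide lists a
#'   second candidate protein (default 0).
#' @param seed Integer seed.
#' @return List: `psms` (one data.frame across plexes), `designs` (list
#'   of [plex_design()]), `protein_lengths`, `metadata`, and `truth`
#'   (`relative_abundance` = per-protein profiles normalized to the
#'   pooled-composite mean, `plex_scale`, `loading`, planted violation
#'   counts).
#' @export
simulate_psm_experiment <- function(n_proteins = 60, n_plexes = 3, n_dates = 8,
                                    psms_per_protein = 3, noise_sd = 0,
                                    plex_scale = NULL,
                                    loading_error_range = c(1, 1),
                                    violations = c(moderate_confidence = 0L,
                                                   ambiguous = 0L,
                                                   high_interference = 0L,
                                                   low_sn = 0L),
                                    shared_peptide_frac = 0,
                                    seed) {
  with_seed(seed, {
    meta <- make_study_metadata(n_dates, n_plexes)
    dates <- study_dates(n_dates)
    channels <- default_channels(10)[seq_len(n_dates + 2)]
    bridges <- c("126", "131")
    stopifnot(all(bridges %in% channels))
    pid <- sprintf("PROT_%04d", seq_len(n_proteins))
    lengths <- stats::setNames(round(stats::runif(n_proteins, 100, 1000)), pid)
    if (is.null(plex_scale)) plex_scale <- stats::runif(n_plexes, 0.5, 2)

    # true abundances per protein per date; technical replicates are
    # aliquots of the same sample, so they share the date's true value
    mu <- stats::rnorm(n_proteins, 0, 1)
    tru_date <- matrix(exp(mu + stats::rnorm(n_proteins * n_dates, 0, 1)),
                       n_proteins, n_dates,
                       dimnames = list(pid, study_dates(n_dates)))
    date_of <- match(meta$collection_date, study_dates(n_dates))
    tru <- tru_date[, date_of, drop = FALSE]
    colnames(tru) <- meta$sample_id
    bridge_true <- rowMeans(tru)                     # pooled composite
    rel_truth <- tru / bridge_true

    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    pep_counter <- 0L
    new_pep <- function(n) {
      out <- vapply(seq_len(n), function(i) {
        paste(sample(aa, 12, replace = TRUE), collapse = "")
      }, character(1))
      paste0(out, sprintf("%05d", pep_counter + seq_len(n)))
    }

    designs <- list()
    rows <- list()
    base_sn <- 200  # keeps mean S/N comfortably above the filter threshold
    for (p in seq_len(n_plexes)) {
      plex_id <- sprintf("plex%d", p)
      smp <- sprintf("d%02d_r%d", seq_len(n_dates), p)
      sample_ch <- setdiff(channels, bridges)
      assign_ch <- stats::setNames(sample(smp), sample_ch)
      designs[[plex_id]] <- plex_design(plex_id, channels, bridges, assign_ch)
      loading <- stats::setNames(stats::runif(length(channels),
                                              loading_error_range[1],
                                              loading_error_range[2]), channels)
      channel_value <- function(i) {
        # relative to the pooled composite, so every protein's bridge is 1
        v <- numeric(length(channels))
        names(v) <- channels
        v[bridges] <- 1
        v[sample_ch] <- tru[i, assign_ch[sample_ch]] / bridge_true[i]
        v * loading * plex_scale[p]
      }
      for (i in seq_len(n_proteins)) {
        k <- max(1L, stats::rpois(1, psms_per_protein))
        phi <- exp(stats::rnorm(k, 0, 0.4))
        peps <- new_pep(k)
        pep_counter <- pep_counter + k
        for (q in seq_len(k)) {
          sn <- base_sn * phi[q] * channel_value(i)
          if (noise_sd > 0)
            sn <- sn * exp(stats::rnorm(length(sn), 0, noise_sd))
          cands <- pid[i]
          if (shared_peptide_frac > 0 && stats::runif(1) < shared_peptide_frac)
            cands <- paste(sort(c(pid[i], sample(setdiff(pid, pid[i]), 1))),
                           collapse = ";")
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = peps[q], proteins = cands, confidence = "high",
            interference_pct = stats::runif(1, 0, 20), plex = plex_id,
            t(sn), stringsAsFactors = FALSE, check.names = FALSE)
        }
      }
      # planted violations, each failing exactly its own rule
      plant <- function(n, mutate) {
        for (q in seq_len(n)) {
          i <- sample.int(n_proteins, 1)
          sn <- base_sn * channel_value(i)
          rec <- data.frame(peptide = new_pep(1), proteins = pid[i],
                            confidence = "high",
                            interference_pct = stats::runif(1, 0, 20),
                            plex = plex_id, t(sn),
                            stringsAsFactors = FALSE, check.names = FALSE)
          pep_counter <<- pep_counter + 1L
          rows[[length(rows) + 1L]] <<- mutate(rec)
        }
      }
      per_plex <- function(total) {
        # spread planted counts over plexes, remainder to the first ones
        base <- total %/% n_plexes + as.integer(p <= total %% n_plexes)
        base
      }
      plant(per_plex(violations[["moderate_confidence"]]), function(r) {
        r$confidence <- "moderate"; r
      })
      plant(per_plex(violations[["ambiguous"]]), function(r) {
        r$confidence <- "ambiguous"; r
      })
      plant(per_plex(violations[["high_interference"]]), function(r) {
        r$interference_pct <- stats::runif(1, 26, 95); r
      })
      plant(per_plex(violations[["low_sn"]]), function(r) {
        snc <- setdiff(names(r), c("peptide", "proteins", "confidence",
                                   "interference_pct", "plex"))
        v <- as.numeric(r[snc])
        r[snc] <- as.list(v / mean(v) * stats::runif(1, 1, 9))
        r
      })
    }
    psms <- do.call(rbind, rows)
    sn_idx <- which(!names(psms) %in%
                      c("peptide", "proteins", "confidence",
                        "interference_pct", "plex"))
    names(psms)[sn_idx] <- sn_cols(channels)
    truth <- list(relative_abundance = rel_truth, plex_scale = plex_scale,
                  protein_lengths = lengths,
                  violations = violations, noise_sd = noise_sd,
                  loading_error_range = loading_error_range,
                  seed = as.integer(seed))
    list(psms = psms, designs = designs, protein_lengths = lengths,
         metadata = meta, truth = truth)
  })
}

#' Serialize a study-truth object to JSON and back
#'
#' Matrices are stored with their dimnames so the round trip is
#' lossless.
#'
#' @param truth A truth list from one of the simulators.
#' @param path File path.
#' @export
write_study_truth <- function(truth, path) {
  enc <- function(x) {
    if (is.matrix(x)) {
      list(.matrix = TRUE, rownames = rownames(x), colnames = colnames(x),
           values = as.vector(x))
    } else if (is.list(x)) {
      lapply(x, enc)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)  # keep names through JSON objects
    } else x
  }
  jsonlite::write_json(enc(truth), path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_study_truth
#' @export
read_study_truth <- function(path) {
  dec <- function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$values), length(x$rownames),
                  dimnames = list(unlist(x$rownames), unlist(x$colnames)))
      m
    } else if (is.list(x)) lapply(x, dec) else x
  }
  dec(jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE))
}
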