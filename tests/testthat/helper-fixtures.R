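# small in-code fixtures shared across test files

tiny_table <- function(values, layer = "gene", features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% sprintf("f%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  feature_table(m, layer = layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_annotation <- function(feature_id, genus = NULL, phylum = NULL,
                            species = NULL, go = NULL, eggnog = NULL,
                            gram = NULL, ko = NULL) {
  n <- length(feature_id)
  fill <- function(x, default) if (is.null(x)) rep(default, length.out = n) else x
  genus <- fill(genus, NA_character_)
  annotation_table(data.frame(
    feature_id = feature_id,
    domain = ifelse(is.na(genus), NA_character_, "Bacteria"),
    phylum = fill(phylum, ifelse(is.na(genus), NA_character_, "Firmicutes")),
    class = ifelse(is.na(genus), NA_character_, "c"),
    order = ifelse(is.na(genus), NA_character_, "o"),
    family = ifelse(is.na(genus), NA_character_, "fam"),
    genus = genus,
    species = fill(species, ifelse(is.na(genus), NA_character_,
                                   paste(genus, "sp"))),
    go_terms = fill(go, NA_character_),
    ko = fill(ko, NA_character_),
    eggnog = fill(eggnog, NA_character_),
    gram = fill(gram, "unknown"),
    stringsAsFactors = FALSE))
}

tiny_metadata <- function(n_dates = 2, n_reps = 3) {
  make_study_metadata(n_dates, n_reps)
}

# one-plex PSM fixture: proteins x channels values supplied directly
tiny_psms <- function(sn_matrix, peptides, proteins, confidence = "high",
                      interference = 5, plex = "plex1") {
  n <- nrow(sn_matrix)
  df <- data.frame(peptide = peptides, proteins = proteins,
                   confidence = rep(confidence, length.out = n),
                   interference_pct = rep(interference, length.out = n),
                   plex = rep(plex, length.out = n),
                   stringsAsFactors = FALSE)
  sn <- as.data.frame(sn_matrix)
  names(sn) <- paste0("sn_", colnames(sn_matrix))
  cbind(df, sn)
}

tiny_plex <- function(plex_id = "plex1", n_samples = 2) {
  channels <- c("126", paste0("s", seq_len(n_samples)), "131")
  plex_design(plex_id, channels, c("126", "131"),
              stats::setNames(sprintf("d%02d_r1", seq_len(n_samples)),
                              paste0("s", seq_len(n_samples))))
}
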