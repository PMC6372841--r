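#' Feature annotation tables
#'
#' One row per feature, carrying an ordered taxonomic lineage
#' (domain, phylum, class, order, family, genus, species — any suffix of
#' ranks may be absent, but no rank may be present below an absent one),
#' a set of GO terms (semicolon-separated in the TSV), optional KO and
#' eggNOG category assignments, and a Gram-stain label.
#'
#' @param df Data frame with columns `feature_id`, the seven lineage
#'   ranks, `go_terms`, `ko`, `eggnog`, `gram`. Missing entries are `NA`
#'   (`gram` may also be `"unknown"`).
#' @return A validated data.frame of class `annotation_table`.
#' @export
annotation_table <- function(df) {
  req <- c("feature_id", lineage_ranks(), "go_terms", "ko", "eggnog", "gram")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id in annotation table")
  df$gram[is.na(df$gram)] <- "unknown"
  if (!all(df$gram %in% c("positive", "negative", "unknown")))
    stop("gram must be positive/negative/unknown")
  lin <- as.matrix(df[lineage_ranks()])
  present <- !is.na(lin) & lin != ""
  # no rank present below an absent rank
  for (i in seq_len(nrow(lin))) {
    p <- present[i, ]
    if (any(p) && any(!p[seq_len(max(which(p)))]))
      stop("inconsistent lineage (gap in ranks) for feature ", df$feature_id[i])
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

lineage_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' @rdname annotation_table
#' @param path File path for the tab-separated serialization.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  annotation_table(df)
}

#' @rdname annotation_table
#' @param ann An `annotation_table`.
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Map features to the categories of an annotation level
#'
#' @param ann An `annotation_table`.
#' @param level One of `"GO"`, `"KO"`, `"eggNOG"`, `"genus"`, `"phylum"`,
#'   `"species"`, `"gram"`. GO maps a feature to possibly several terms;
#'   all other levels map to at most one category.
#' @return Named list: feature_id -> character vector of categories
#'   (length 0 if unannotated at that level).
#' @export
annotation_categories <- function(ann, level) {
  level <- match.arg(level, c("GO", "KO", "eggNOG", "genus", "phylum",
                              "species", "gram"))
  col <- switch(level, GO = "go_terms", KO = "ko", eggNOG = "eggnog",
                genus = "genus", phylum = "phylum", species = "species",
                gram = "gram")
  vals <- ann[[col]]
  out <- lapply(vals, function(v) {
    if (is.na(v) || v == "") return(character(0))
    if (col == "go_terms") strsplit(v, ";", fixed = TRUE)[[1]] else v
  })
  names(out) <- ann$feature_id
  out
}

#' Sample metadata for the longitudinal design
#'
#' Eight collection dates in technical triplicate by default. `(date,
#' replicate)` pairs must be unique; `inflammation_state` labels each
#' date high/low/unknown for the PERMANOVA grouping.
#'
#' @param df Data frame with columns `sample_id`, `collection_date`
#'   (ISO-8601 string), `replicate_index`, `inflammation_state`.
#' @return Validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "collection_date", "replicate_index", "inflammation_state")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df[c("collection_date", "replicate_index")]))
    stop("(date, replicate) pairs must be unique")
  if (!all(df$inflammation_state %in% c("high", "low", "unknown")))
    stop("inflammation_state must be high/low/unknown")
  df$collection_date <- as.character(df$collection_date)
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path File path.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname sample_metadata
#' @param meta A `sample_metadata`.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Biomarker series input/output
#'
#' A set of immune-biomarker series (calprotectin, CRP, lysozyme,
#' lactoferrin, S-IgA) is a nonnegative numeric matrix with biomarker
#' names in rows and sample/date ids in columns.
#'
#' @param path File path (TSV, first column `biomarker`).
#' @return `read_biomarker_series()` returns the matrix.
#' @export
read_biomarker_series <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_biomarker_series
#' @param series Biomarker x sample matrix.
#' @export
write_biomarker_series <- function(series, path) {
  df <- data.frame(biomarker = rownames(series), series,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxon list (one lineage string per line, `#` comments)
#'
#' Used for the increased/decreased species lists of the dysbiosis
#' index.
#'
#' @param path File path.
#' @return Character vector of taxon names.
#' @export
read_taxon_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}
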