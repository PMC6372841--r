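#' Construct a feature abundance table
#'
#' A `feature_table` is the central container of the package: a numeric
#' matrix of nonnegative abundances with features (ORFs/proteins or
#' categories) in rows and samples in columns, tagged with the omic layer
#' it came from. Missing cells are `NA`. For the gene layer, absences are
#' represented as explicit zeros after counts-per-million (CPM)
#' normalization, so a CPM table carries no `NA`; for the protein layer,
#' cells not quantified in a plex stay `NA` and are excluded from means
#' and correlations downstream.
#'
#' @param values Numeric matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids). `NA` marks missing cells.
#' @param layer `"gene"` or `"protein"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, layer = c("gene", "protein")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have feature ids as rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have sample ids as colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be nonnegative")
  structure(list(values = values, layer = layer), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  v <- x$values
  cat(sprintf("feature_table [%s]: %d features x %d samples (%.1f%% missing)\n",
              x$layer, nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Counts-per-million normalization of a gene count matrix
#'
#' Scales each sample column to one million, the library-size
#' normalization used for shotgun gene quantification. Features absent in
#' a sample are explicit zeros ("missing values padded as zeroes"), so
#' the returned gene table has no missing cells.
#'
#' @param counts Nonnegative numeric matrix of read counts
#'   (features x samples) with dimnames; `NA` cells are treated as
#'   unobserved and padded to zero.
#' @return A `feature_table` with `layer = "gene"` whose columns each sum
#'   to 1e6.
#' @export
cpm_normalize <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop("counts must be nonnegative")
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(counts, 2, cs, "/") * 1e6
  feature_table(cpm, layer = "gene")
}

#' Collapse technical replicates to one column per collection date
#'
#' Genes are summed over replicates (count semantics: a missing replicate
#' contributes 0) and proteins are averaged (ratio semantics: missing
#' replicate cells are excluded from the mean), following the
#' metagenome-sums / metaproteome-averages convention.
#'
#' @param table A `feature_table` with one column per replicate sample.
#' @param meta Sample metadata data.frame with columns `sample_id`,
#'   `collection_date`, `replicate_index` (see [read_sample_metadata()]).
#' @param mode `"sum"` or `"mean"`; defaults to `"sum"` for the gene
#'   layer and `"mean"` for the protein layer.
#' @return A `feature_table` keyed by ISO-8601 date, columns in
#'   chronological order. A cell whose replicates are all missing is `NA`
#'   under `mean` and 0 under `sum`.
#' @export
collapse_replicates <- function(table, meta, mode = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(mode)) mode <- if (table$layer == "gene") "sum" else "mean"
  mode <- match.arg(mode, c("sum", "mean"))
  sid <- sample_ids(table)
  idx <- match(sid, meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(sid[is.na(idx)], collapse = ", "))
  dates <- as.character(meta$collection_date[idx])
  udates <- sort(unique(dates))
  v <- table$values
  out <- matrix(NA_real_, nrow(v), length(udates),
                dimnames = list(rownames(v), udates))
  for (j in seq_along(udates)) {
    cols <- v[, dates == udates[j], drop = FALSE]
    if (ncol(cols) == 0) stop("date with zero replicates: ", udates[j])
    out[, j] <- if (mode == "sum") {
      rowSums(cols, na.rm = TRUE)
    } else {
      m <- rowMeans(cols, na.rm = TRUE)
      m[!is.finite(m)] <- NA_real_  # all replicates missing
      m
    }
  }
  feature_table(out, layer = table$layer)
}

#' Keep only features quantified in every sample
#'
#' Retains the features with no missing cell, the complete-case subset
#' the ordination layer requires ("only the proteins common to all
#' samples"). For a gene CPM table, zeros are values, not missingness,
#' so zero rows are retained.
#'
#' @param table A `feature_table`.
#' @return A `feature_table` with zero missing cells (possibly empty).
#' @export
filter_complete_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  keep <- rowSums(is.na(table$values)) == 0
  feature_table(table$values[keep, , drop = FALSE], layer = table$layer)
}

#' Align a gene table and a protein table over their shared ORFs
#'
#' Subsets both layers to the intersection of their feature identifiers
#' (the shared ORF namespace of a personalized database) in a common,
#' sorted order.
#'
#' @param genes,proteins `feature_table`s over the same identifier
#'   namespace.
#' @return A list with elements `genes` and `proteins`, both
#'   `feature_table`s with identical feature order, and `n_shared`.
#' @export
subset_shared_features <- function(genes, proteins) {
  stopifnot(inherits(genes, "feature_table"), inherits(proteins, "feature_table"))
  shared <- sort(intersect(feature_ids(genes), feature_ids(proteins)))
  if (length(shared) == 0)
    warning("no features shared between the two layers")
  list(
    genes = feature_table(genes$values[shared, , drop = FALSE], layer = genes$layer),
    proteins = feature_table(proteins$values[shared, , drop = FALSE], layer = proteins$layer),
    n_shared = length(shared)
  )
}

#' Read and write feature tables as TSV
#'
#' Tab-separated, header row of sample ids, feature ids in the first
#' column (`feature_id`), `NA` for missing cells, UTF-8. Values
#' round-trip via full precision.
#'
#' @param path File path.
#' @param layer Layer tag for the table being read.
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, layer = c("gene", "protein")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  feature_table(m, layer = layer)
}

#' @rdname read_feature_table
#' @param table A `feature_table` to serialize.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  chr <- matrix(formatC(v, format = "g", digits = 17), nrow(v),
                dimnames = dimnames(v))
  chr[is.na(v)] <- "NA"
  df <- data.frame(feature_id = feature_ids(table),
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
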