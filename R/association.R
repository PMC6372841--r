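#' Extract immune-biomarker series from the protein table
#'
#' A biomarker's per-sample abundance is the sum of its mapped protein
#' subunits (e.g. calprotectin = S100A8 + S100A9). Biomarkers with no
#' mapped protein present in the table are omitted with a warning.
#'
#' @param proteins A protein `feature_table` (collapsed to dates).
#' @param id_map Named list: biomarker name -> character vector of
#'   protein ids.
#' @return Biomarker x sample numeric matrix.
#' @export
extract_biomarkers <- function(proteins, id_map) {
  v <- proteins$values
  rows <- lapply(names(id_map), function(b) {
    ids <- intersect(id_map[[b]], rownames(v))
    if (length(ids) == 0) {
      warning("biomarker with no mapped protein present: ", b)
      return(NULL)
    }
    sub <- v[ids, , drop = FALSE]
    sub[is.na(sub)] <- 0
    colSums(sub)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no biomarker could be extracted")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(id_map)[keep]
  out
}

#' Regress every feature against a biomarker series
#'
#' Ordinary least squares of each feature's abundance on the biomarker
#' abundance across samples, with the Pearson correlation as effect
#' size, vectorized over features. Features with fewer than three
#' complete pairs are skipped and counted.
#'
#' @param table A `feature_table` collapsed to the biomarker's samples.
#' @param biomarker Named numeric vector (sample -> abundance), one row
#'   of [extract_biomarkers()]'s output.
#' @param biomarker_name Optional label recorded in the result.
#' @return Data.frame (`feature_id`, `biomarker`, `slope`, `intercept`,
#'   `r`, `n_used`, `p_value`) with attribute `n_skipped`. `p_value` is
#'   the two-sided OLS slope test, reported but not used for selection.
#' @export
regress_features_vs_biomarker <- function(table, biomarker,
                                          biomarker_name = "biomarker") {
  v <- table$values
  common <- intersect(colnames(v), names(biomarker))
  if (length(common) < 3) stop("fewer than 3 shared samples")
  v <- v[, common, drop = FALSE]
  y <- biomarker[common]
  if (stats::sd(y) == 0) stop("zero-variance biomarker series")
  res <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3) return(NULL)
    xb <- y[ok]           # predictor: biomarker
    yb <- x[ok]           # response: feature abundance
    sxx <- sum((xb - mean(xb))^2)
    sxy <- sum((xb - mean(xb)) * (yb - mean(yb)))
    syy <- sum((yb - mean(yb))^2)
    slope <- sxy / sxx
    intercept <- mean(yb) - slope * mean(xb)
    r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
    p <- if (is.na(r) || abs(r) >= 1 || n <= 2) NA_real_ else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    data.frame(feature_id = rownames(v)[i], biomarker = biomarker_name,
               slope = slope, intercept = intercept, r = r, n_used = n,
               p_value = p, stringsAsFactors = FALSE)
  })
  keep <- !vapply(res, is.null, logical(1))
  df <- if (any(keep)) do.call(rbind, res[keep]) else
    data.frame(feature_id = character(0), biomarker = character(0),
               slope = numeric(0), intercept = numeric(0), r = numeric(0),
               n_used = integer(0), p_value = numeric(0))
  rownames(df) <- NULL
  attr(df, "n_skipped") <- sum(!keep)
  df
}

#' Select large-effect associations
#'
#' Partitions association results by the effect-size rule |r| > tau
#' (default 0.7): positive if r > tau, negative if r < -tau.
#'
#' @param results Data.frame from [regress_features_vs_biomarker()].
#' @param tau Effect-size threshold in (0, 1).
#' @return List with data.frames `positive` and `negative`, and the
#'   full table with a `class` column added.
#' @export
select_strong <- function(results, tau = 0.7) {
  stopifnot(tau > 0, tau < 1)
  cls <- rep("none", nrow(results))
  cls[!is.na(results$r) & results$r > tau] <- "positive"
  cls[!is.na(results$r) & results$r < -tau] <- "negative"
  results$class <- cls
  list(positive = results[cls == "positive", , drop = FALSE],
       negative = results[cls == "negative", , drop = FALSE],
       all = results)
}

#' Compositional log ratio of positive vs negative association sets
#'
#' Within each set, each annotated feature counts once per category it
#' carries; category fractions are computed over annotated features, and
#' the enrichment is log((f_pos + eps) / (f_neg + eps)) with
#' eps = 0.5 / max(|pos|, |neg|). Composition counts features, not
#' abundance mass. Unannotated features are excluded from the
#' denominators and counted.
#'
#' @param pos,neg Character vectors of feature ids (or data.frames with
#'   a `feature_id` column) for the positively and negatively associated
#'   sets.
#' @param ann An [annotation_table()].
#' @param level Annotation level (see [annotation_categories()]).
#' @param base Logarithm base (default 2).
#' @return Data.frame (`category`, `f_pos`, `f_neg`, `log_ratio`,
#'   `n_pos`, `n_neg`) with attributes `n_unannotated_pos`/`_neg`.
#' @export
composition_log_ratio <- function(pos, neg, ann, level, base = 2) {
  if (is.data.frame(pos)) pos <- pos$feature_id
  if (is.data.frame(neg)) neg <- neg$feature_id
  if (length(pos) == 0 || length(neg) == 0)
    stop("both association sets must be nonempty")
  cats <- annotation_categories(ann, level)
  count_side <- function(ids) {
    cc <- cats[ids]
    cc[vapply(cc, is.null, logical(1))] <- list(character(0))
    n_unann <- sum(lengths(cc) == 0)
    tab <- table(unlist(cc, use.names = FALSE))
    list(tab = tab, n_ann = length(ids) - n_unann, n_unann = n_unann)
  }
  p <- count_side(pos)
  n <- count_side(neg)
  if (p$n_ann == 0 || n$n_ann == 0)
    stop("no annotated features in one of the sets at level ", level)
  all_cats <- sort(union(names(p$tab), names(n$tab)))
  n_pos <- as.integer(p$tab[all_cats]); n_pos[is.na(n_pos)] <- 0L
  n_neg <- as.integer(n$tab[all_cats]); n_neg[is.na(n_neg)] <- 0L
  f_pos <- n_pos / p$n_ann
  f_neg <- n_neg / n$n_ann
  eps <- 0.5 / max(p$n_ann, n$n_ann)
  df <- data.frame(category = all_cats, f_pos = f_pos, f_neg = f_neg,
                   log_ratio = log((f_pos + eps) / (f_neg + eps), base = base),
                   n_pos = n_pos, n_neg = n_neg, stringsAsFactors = FALSE)
  attr(df, "n_unannotated_pos") <- p$n_unann
  attr(df, "n_unannotated_neg") <- n$n_unann
  attr(df, "eps") <- eps
  df
}

#' Overlap of strong associations between omic layers
#'
#' A strong association is the tuple (feature, biomarker, sign). Shared
#' means the same tuple is strong in both layers. Reports per-biomarker
#' Venn counts, the shared fraction over the union of all strong
#' associations, and the same fraction restricted to features
#' quantified in both layers.
#'
#' @param gene_results,protein_results Classified association tables
#'   (the `all` element of [select_strong()], possibly row-bound over
#'   biomarkers).
#' @param shared_features Character vector of feature ids quantified in
#'   both layers.
#' @return List with `venn` (data.frame per biomarker: gene_only,
#'   protein_only, shared), `n_shared`, `n_total`, `shared_fraction`,
#'   `n_shared_namespace`, `n_total_namespace`,
#'   `shared_namespace_fraction`.
#' @export
association_overlap <- function(gene_results, protein_results, shared_features) {
  strong <- function(df) {
    df <- df[df$class %in% c("positive", "negative"), , drop = FALSE]
    paste(df$feature_id, df$biomarker, df$class, sep = "\r")
  }
  gs <- strong(gene_results)
  ps <- strong(protein_results)
  shared <- intersect(gs, ps)
  split_key <- function(keys) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(feature_id = vapply(parts, `[`, "", 1),
               biomarker = vapply(parts, `[`, "", 2),
               class = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
  }
  bio <- sort(unique(c(gene_results$biomarker, protein_results$biomarker)))
  venn <- do.call(rbind, lapply(bio, function(b) {
    g <- gs[grepl(paste0("\r", b, "\r"), gs, fixed = TRUE)]
    p <- ps[grepl(paste0("\r", b, "\r"), ps, fixed = TRUE)]
    s <- length(intersect(g, p))
    data.frame(biomarker = b, gene_only = length(g) - s,
               protein_only = length(p) - s, shared = s,
               stringsAsFactors = FALSE)
  }))
  in_ns <- function(keys) keys[split_key(keys)$feature_id %in% shared_features]
  gs_ns <- in_ns(gs); ps_ns <- in_ns(ps)
  shared_ns <- intersect(gs_ns, ps_ns)
  n_total <- length(union(gs, ps))
  n_total_ns <- length(union(gs_ns, ps_ns))
  list(venn = venn,
       n_shared = length(shared), n_total = n_total,
       shared_fraction = if (n_total) length(shared) / n_total else NA_real_,
       n_shared_namespace = length(shared_ns), n_total_namespace = n_total_ns,
       shared_namespace_fraction =
         if (n_total_ns) length(shared_ns) / n_total_ns else NA_real_)
}

#' Gram-stain composition summary of association sets
#'
#' [composition_log_ratio()] at the Gram-stain level; features without a
#' Gram label appear as the `"unknown"` category.
#'
#' @inheritParams composition_log_ratio
#' @return As [composition_log_ratio()], with categories
#'   positive/negative/unknown.
#' @export
gram_stain_summary <- function(pos, neg, ann, base = 2) {
  composition_log_ratio(pos, neg, ann, level = "gram", base = base)
}

#' Microbial dysbiosis index
#'
#' Per-sample log ratio of the summed abundances of taxa increased in
#' Crohn's disease over taxa decreased in it:
#' log2((sum increased + eps) / (sum decreased + eps)), with eps half
#' the smallest nonzero value in the table. Taxa are matched by exact
#' row name (use a species-level [rollup_by_category()] table).
#'
#' @param table A `feature_table` whose rows are taxa (species-level
#'   rollup).
#' @param increased,decreased Character vectors of taxon names.
#' @param base Logarithm base (default 2).
#' @return List of class `dysbiosis_index`: per-sample `index`, the
#'   matched/unmatched taxa per list, and `eps`.
#' @export
dysbiosis_index <- function(table, increased, decreased, base = 2) {
  v <- table$values
  inc <- intersect(increased, rownames(v))
  dec <- intersect(decreased, rownames(v))
  if (length(inc) == 0)
    stop("no increased-list taxon present; missing: ",
         paste(increased, collapse = ", "))
  if (length(dec) == 0)
    stop("no decreased-list taxon present; missing: ",
         paste(decreased, collapse = ", "))
  nz <- v[!is.na(v) & v > 0]
  eps <- if (length(nz)) min(nz) / 2 else .Machine$double.eps
  s_inc <- colSums(v[inc, , drop = FALSE], na.rm = TRUE)
  s_dec <- colSums(v[dec, , drop = FALSE], na.rm = TRUE)
  idx <- log((s_inc + eps) / (s_dec + eps), base = base)
  structure(list(index = idx, increased_matched = inc, decreased_matched = dec,
                 increased_missing = setdiff(increased, inc),
                 decreased_missing = setdiff(decreased, dec), eps = eps),
            class = "dysbiosis_index")
}

#' @export
print.dysbiosis_index <- function(x, ...) {
  cat(sprintf("dysbiosis_index over %d samples (%d increased, %d decreased taxa matched)\n",
              length(x$index), length(x$increased_matched),
              length(x$decreased_matched)))
  print(round(x$index, 3))
  invisible(x)
}

#' Pearson cross-correlation matrix of biomarker series
#'
#' @param series Biomarker x sample matrix.
#' @return Symmetric Pearson correlation matrix with unit diagonal;
#'   rows/columns with zero variance give `NA` off-diagonal entries.
#' @export
biomarker_crosscorrelation <- function(series) {
  if (ncol(series) < 3) stop("need at least 3 samples")
  sds <- apply(series, 1, stats::sd)
  m <- suppressWarnings(stats::cor(t(series)))
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m) <- 1
  m
}
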