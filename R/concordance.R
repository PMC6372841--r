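#' Spearman rank correlation with pairwise-complete handling
#'
#' Average ranks for ties, then the Pearson product-moment correlation
#' of the ranks; pairs with a missing value in either vector are
#' dropped. Returns `NA` when fewer than `min_pairs` complete pairs
#' remain or either ranked vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_pairs Minimum complete pairs (default 3).
#' @return Spearman rho, or `NA`.
#' @keywords internal
spearman_pair <- function(x, y, min_pairs = 3) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  sx <- stats::sd(rx)
  sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(rx) - 1) * sx * sy)
}

new_correlation_summary <- function(rho, n_omitted) {
  rho_ok <- rho[!is.na(rho)]
  breaks <- seq(-1, 1, length.out = 51)
  h <- if (length(rho_ok)) {
    tabulate(findInterval(pmin(pmax(rho_ok, -1), 1), breaks,
                          rightmost.closed = TRUE, all.inside = TRUE), 50)
  } else integer(50)
  structure(list(rho = rho, mean = if (length(rho_ok)) mean(rho_ok) else NA_real_,
                 sd = if (length(rho_ok) > 1) stats::sd(rho_ok) else NA_real_,
                 n = length(rho_ok), n_omitted = n_omitted,
                 histogram = data.frame(lower = breaks[-51], upper = breaks[-1],
                                        count = h)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("correlation_summary: n = %d, mean rho = %.3f, sd = %.3f (%d omitted)\n",
              x$n, x$mean, x$sd, x$n_omitted))
  invisible(x)
}

#' Per-feature Spearman concordance between paired omic layers
#'
#' For each shared feature, the Spearman correlation between its gene
#' and protein abundance profiles across the collapsed samples, using
#' average-rank ties and pairwise-complete samples. Features with fewer
#' than three complete pairs (or a constant profile) are omitted and
#' counted.
#'
#' @param paired A list with `feature_table`s `genes` and `proteins`
#'   over identical features and samples (see
#'   [subset_shared_features()]).
#' @return A `correlation_summary` with per-feature `rho`, the mean and
#'   standard deviation of the distribution, a 50-bin histogram over
#'   \[-1, 1\], and the omitted-feature count.
#' @export
paired_feature_spearman <- function(paired) {
  g <- paired$genes$values
  p <- paired$proteins$values
  if (!identical(rownames(g), rownames(p)))
    stop("gene and protein tables must share feature order; use subset_shared_features()")
  common <- intersect(colnames(g), colnames(p))
  if (length(common) < 3) stop("fewer than 3 shared samples")
  g <- g[, common, drop = FALSE]
  p <- p[, common, drop = FALSE]
  rho <- vapply(seq_len(nrow(g)), function(i) spearman_pair(g[i, ], p[i, ]),
                numeric(1))
  names(rho) <- rownames(g)
  if (all(is.na(rho))) stop("no feature with enough complete pairs")
  new_correlation_summary(rho, n_omitted = sum(is.na(rho)))
}

#' Sum a feature table into annotation categories
#'
#' Category abundance per sample is the sum over the features annotated
#' to it; a feature carrying several GO terms contributes to each of
#' them, and missing cells contribute zero. Unannotated features are
#' dropped and counted in the `n_unannotated` attribute.
#'
#' @param table A `feature_table`.
#' @param ann An [annotation_table()].
#' @param level Annotation level: `"GO"`, `"KO"`, `"eggNOG"`,
#'   `"genus"`, `"phylum"`, or `"species"`.
#' @return A `feature_table` over categories (same layer), with
#'   attribute `n_unannotated`.
#' @export
rollup_by_category <- function(table, ann, level) {
  stopifnot(inherits(table, "feature_table"))
  cats <- annotation_categories(ann, level)
  v <- table$values
  v0 <- v
  v0[is.na(v0)] <- 0
  fid <- rownames(v)
  feat_cats <- cats[fid]
  names(feat_cats) <- fid
  feat_cats[vapply(feat_cats, is.null, logical(1))] <- list(character(0))
  n_per <- lengths(feat_cats)
  n_unann <- sum(n_per == 0)
  if (all(n_per == 0)) {
    out <- matrix(numeric(0), 0, ncol(v), dimnames = list(character(0), colnames(v)))
  } else {
    long_feat <- rep(fid, n_per)
    long_cat <- unlist(feat_cats, use.names = FALSE)
    out <- rowsum(v0[long_feat, , drop = FALSE], group = long_cat)
    out <- out[sort(rownames(out)), , drop = FALSE]
  }
  ft <- feature_table(out, layer = table$layer)
  attr(ft, "n_unannotated") <- n_unann
  ft
}

#' Gene-protein concordance within or across functional categories
#'
#' Two views of category-level concordance: `per_feature_grouped`
#' computes each shared feature's Spearman rho and groups the values by
#' the feature's category (the per-eggNOG box-plot view);
#' `category_summed` first sums both layers by category and correlates
#' the category totals (the summed-GO view).
#'
#' @param genes,proteins Aligned `feature_table`s over shared features.
#' @param ann An [annotation_table()].
#' @param level Annotation level (see [rollup_by_category()]).
#' @param mode `"per_feature_grouped"` or `"category_summed"`.
#' @return For `per_feature_grouped`, a data.frame
#'   (`feature_id`, `category`, `rho`) plus a per-category summary
#'   data.frame as attribute `by_category`; for `category_summed`, a
#'   `correlation_summary` whose `rho` is named by category.
#' @export
category_concordance <- function(genes, proteins, ann, level,
                                 mode = c("per_feature_grouped", "category_summed")) {
  mode <- match.arg(mode)
  if (mode == "category_summed") {
    gc <- rollup_by_category(genes, ann, level)
    pc <- rollup_by_category(proteins, ann, level)
    paired <- subset_shared_features(gc, pc)
    return(paired_feature_spearman(paired))
  }
  cs <- paired_feature_spearman(list(genes = genes, proteins = proteins))
  cats <- annotation_categories(ann, level)
  rows <- lapply(names(cs$rho), function(f) {
    cf <- cats[[f]]
    if (is.null(cf) || length(cf) == 0) return(NULL)
    data.frame(feature_id = f, category = cf, rho = cs$rho[[f]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(feature_id = character(0), category = character(0),
                     rho = numeric(0), stringsAsFactors = FALSE)
  df <- df[!is.na(df$rho), , drop = FALSE]
  agg <- if (nrow(df)) {
    sp <- split(df$rho, df$category)
    sp <- sp[lengths(sp) >= 1]
    data.frame(category = names(sp),
               n = lengths(sp),
               mean_rho = vapply(sp, mean, numeric(1)),
               sd_rho = vapply(sp, function(z) if (length(z) > 1) stats::sd(z) else NA_real_,
                               numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(category = character(0), n = integer(0),
               mean_rho = numeric(0), sd_rho = numeric(0))
  }
  attr(df, "by_category") <- agg
  df
}

#' Max/min dynamic range per feature or category
#'
#' The maximum present value divided by the minimum, computed over
#' strictly positive values. Items whose minimum present value is zero
#' fall back to the smallest nonzero value and are flagged
#' (`zero_substituted`); items that are all zero, or have fewer than two
#' present values, are excluded and counted.
#'
#' @param table A `feature_table` (raw features or a category rollup).
#' @param scope Label recorded in the result: `"feature"` or
#'   `"category"`.
#' @return A data.frame of class `fluctuation_profile` with columns
#'   `item`, `max_min_ratio`, `log10_ratio`, `zero_substituted`;
#'   attribute `n_excluded`.
#' @export
dynamic_range <- function(table, scope = c("feature", "category")) {
  scope <- match.arg(scope)
  v <- table$values
  res <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    x <- x[!is.na(x)]
    if (length(x) < 2 || all(x == 0)) return(NULL)
    pos <- x[x > 0]
    flagged <- any(x == 0)
    ratio <- max(x) / min(pos)
    data.frame(item = rownames(v)[i], max_min_ratio = ratio,
               log10_ratio = log10(ratio), zero_substituted = flagged,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(res, is.null, logical(1))
  df <- if (any(keep)) do.call(rbind, res[keep]) else
    data.frame(item = character(0), max_min_ratio = numeric(0),
               log10_ratio = numeric(0), zero_substituted = logical(0))
  rownames(df) <- NULL
  attr(df, "n_excluded") <- sum(!keep)
  attr(df, "scope") <- scope
  class(df) <- c("fluctuation_profile", "data.frame")
  df
}

#' Per-item standard deviation profile
#'
#' Sample standard deviation (n - 1 denominator) of each feature or
#' category across its present values, optionally on log10-transformed
#' values (nonpositive values are excluded from the log transform).
#'
#' @param table A `feature_table`.
#' @param log_transform Logical; transform to log10 first.
#' @return Data.frame (`item`, `sd`, `n_used`) with attribute
#'   `distribution_variance`, the variance of the reported standard
#'   deviations.
#' @export
sd_profile <- function(table, log_transform = FALSE) {
  v <- table$values
  rows <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    x <- x[!is.na(x)]
    if (log_transform) x <- log10(x[x > 0])
    if (length(x) < 2) return(NULL)
    data.frame(item = rownames(v)[i], sd = stats::sd(x), n_used = length(x),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  df <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(item = character(0), sd = numeric(0), n_used = integer(0))
  rownames(df) <- NULL
  attr(df, "distribution_variance") <-
    if (nrow(df) > 1) stats::var(df$sd) else NA_real_
  df
}

#' Rank categories by dynamic range
#'
#' @param profile A `fluctuation_profile` at category scope.
#' @param k Number of categories to return (all if fewer available).
#' @return The top-`k` rows ordered by decreasing max/min ratio, ties
#'   broken lexicographically by category label.
#' @export
top_fluctuating_categories <- function(profile, k) {
  ord <- order(-profile$max_min_ratio, profile$item)
  profile[ord[seq_len(min(k, nrow(profile)))], , drop = FALSE]
}
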