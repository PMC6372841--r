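#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a single integer `seed` is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

new_permutation_result <- function(statistic, statistic_name, p_value,
                                   n_perm = NA_integer_, seed = NA_integer_,
                                   extra = list()) {
  structure(c(list(statistic = statistic, statistic_name = statistic_name,
                   p_value = p_value, n_perm = n_perm, seed = seed), extra),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g", x$statistic_name, x$statistic, x$p_value))
  if (!is.na(x$n_perm)) cat(sprintf(" (%d permutations, seed %d)", x$n_perm, x$seed))
  cat("\n")
  invisible(x)
}

check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

#' Bray-Curtis dissimilarity between sample columns
#'
#' d(i, j) = 1 - 2 * sum(min(x_i, x_j)) / (sum(x_i) + sum(x_j)),
#' computed over a complete (no missing cells) nonnegative table —
#' apply [filter_complete_features()] to a protein table first.
#'
#' @param table A `feature_table` with no missing cells.
#' @return Symmetric sample x sample matrix in \[0, 1\] with zero
#'   diagonal.
#' @export
bray_curtis <- function(table) {
  v <- table$values
  if (anyNA(v))
    stop("missing cells present; apply filter_complete_features() first")
  cs <- colSums(v)
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- cs[i] + cs[j]
      if (tot == 0)
        stop("Bray-Curtis undefined for all-zero samples: ",
             colnames(v)[i], ", ", colnames(v)[j])
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(v[, i], v[, j])) / tot
    }
  }
  d
}

#' Principal-coordinate analysis (classical scaling)
#'
#' Double-centers -0.5 * D^2, eigendecomposes, and returns coordinates
#' scaled by the square roots of the positive eigenvalues. Negative
#' eigenvalues (non-Euclidean input) are reported, not corrected.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param tol Eigenvalues below `tol * max(|eigenvalue|)` are treated
#'   as zero.
#' @return List of class `pcoa_result`: `coordinates`
#'   (samples x positive axes), `eigenvalues` (all, descending),
#'   `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(d, tol = 1e-9) {
  check_dist(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- e$values
  thresh <- tol * max(abs(ev), 1e-300)
  pos <- which(ev > thresh)
  if (length(pos) == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "PC1"))
    prop <- NA_real_
  } else {
    coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
    dimnames(coords) <- list(rownames(d), paste0("PC", seq_along(pos)))
    prop <- ev[pos] / sum(ev[pos])
  }
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' Procrustes superimposition of two configurations
#'
#' Both configurations are centered and scaled to unit trace
#' (sum of squares 1), then Y is rotated (orthogonal) and rescaled to
#' minimize the residual sum of squares against X. The reported M^2 is
#' that minimized residual, in \[0, 1\].
#'
#' @param x,y Numeric coordinate matrices with matching row (sample)
#'   order; the narrower one is padded with zero columns.
#' @return List of class `procrustes_result`: `m2`, `rotation`,
#'   `scaling`, `y_aligned` (in x's centered frame plus x's centroid).
#' @export
procrustes_analysis <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("configurations must have the same sample count")
  k <- max(ncol(x), ncol(y))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  x <- pad(x); y <- pad(y)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("degenerate (zero-variance) configuration")
  xs <- xc / sx; ys <- yc / sy
  sv <- svd(crossprod(xs, ys))
  rot <- sv$v %*% t(sv$u)
  scaling <- sum(sv$d)
  m2 <- 1 - scaling^2
  y_aligned <- sweep(scaling * ys %*% rot * sx, 2, cx, "+")
  structure(list(m2 = m2, rotation = rot, scaling = scaling,
                 y_aligned = y_aligned),
            class = "procrustes_result")
}

upper_tri_vec <- function(d) d[upper.tri(d)]

#' Mantel test of association between two distance matrices
#'
#' Statistic: Pearson correlation of the off-diagonal upper triangles.
#' Significance: rows/columns of the second matrix are permuted jointly;
#' p = (1 + #permuted r >= observed) / (n_perm + 1), one-sided.
#'
#' @param d1,d2 Distance matrices over the same samples (matching
#'   order).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (required; permutations are reproducible).
#' @return A `permutation_test_result` with `statistic` = Mantel r.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed) {
  check_dist(d1); check_dist(d2)
  n <- nrow(d1)
  if (nrow(d2) != n) stop("distance matrices must match")
  if (n < 4) stop("Mantel test needs at least 4 samples")
  v1 <- upper_tri_vec(d1)
  obs <- stats::cor(v1, upper_tri_vec(d2))
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(v1, upper_tri_vec(d2[p, p])) >= obs
    }, logical(1)))
  })
  new_permutation_result(obs, "Mantel r", (1 + count) / (n_perm + 1),
                         n_perm, as.integer(seed))
}

permanova_f <- function(d, grouping) {
  n <- nrow(d)
  d2 <- d^2
  groups <- split(seq_len(n), grouping)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- sum(vapply(groups, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  a <- length(groups)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' PERMANOVA pseudo-F with permutation p-value
#'
#' One-way permutational multivariate analysis of variance on a
#' distance matrix: pseudo-F from among- vs within-group sums of
#' squared distances, significance by permuting group labels.
#'
#' @param d Distance matrix.
#' @param grouping Factor-like group labels, one per sample; at least
#'   two groups, each with at least two samples.
#' @param n_perm Number of permutations (default 999); ignored when
#'   `exhaustive = TRUE`.
#' @param seed Integer seed (required unless `exhaustive = TRUE`).
#' @param exhaustive If `TRUE`, enumerate every distinct assignment of
#'   the label multiset to samples and report the exact permutation
#'   p-value (feasible for small designs only).
#' @return A `permutation_test_result` with `statistic` = pseudo-F.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed, exhaustive = FALSE) {
  check_dist(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != nrow(d)) stop("one group label per sample required")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  obs <- permanova_f(d, grouping)
  if (exhaustive) {
    perms <- multiset_assignments(as.character(grouping))
    f_all <- vapply(perms, function(g) permanova_f(d, factor(g)), numeric(1))
    return(new_permutation_result(obs, "pseudo-F",
                                  mean(f_all >= obs - 1e-12),
                                  length(perms), NA_integer_))
  }
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_f(d, sample(grouping)) >= obs
    }, logical(1)))
  })
  new_permutation_result(obs, "pseudo-F", (1 + count) / (n_perm + 1),
                         n_perm, as.integer(seed))
}

# every distinct assignment of the label multiset to positions
multiset_assignments <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- table(labels)[uniq]
  n <- length(labels)
  out <- list()
  recurse <- function(positions, remaining, current) {
    if (length(remaining) == 1) {
      current[positions] <- names(remaining)[1]
      out[[length(out) + 1L]] <<- current
      return(invisible())
    }
    lab <- names(remaining)[1]
    k <- remaining[[1]]
    for (combo in utils::combn(seq_along(positions), k, simplify = FALSE)) {
      cur <- current
      cur[positions[combo]] <- lab
      recurse(positions[-combo], remaining[-1], cur)
    }
  }
  recurse(seq_len(n), as.list(stats::setNames(as.integer(counts), uniq)),
          character(n))
  out
}

#' Friedman rank test for blocked compositions
#'
#' Nonparametric test that treatment (category) values differ across
#' blocks (samples): within-block average ranks, chi-squared statistic
#' with tie correction, asymptotic p-value on k - 1 degrees of freedom.
#'
#' @param mat Numeric matrix, blocks (samples) x treatments
#'   (categories); no missing cells, at least 3 blocks and 2 treatments.
#' @return A `permutation_test_result` with `statistic` = Friedman
#'   chi-squared and `extra` field `df`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("no missing cells allowed")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop("need at least 3 blocks")
  if (k < 2) stop("need at least 2 treatments")
  r <- t(apply(mat, 1, rank))
  rj <- colSums(r)
  dev <- sum((rj - n * (k + 1) / 2)^2)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom == 0) {
    warning("all blocks are constant; statistic is 0")
    return(new_permutation_result(0, "Friedman chi-squared", 1,
                                  extra = list(df = k - 1L)))
  }
  stat <- (k - 1) * dev / denom
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  new_permutation_result(stat, "Friedman chi-squared", p,
                         extra = list(df = k - 1L))
}

#' Distance-matrix TSV input/output
#'
#' Square matrix with a header row and sample ids in the first column.
#'
#' @param path File path.
#' @return `read_distance_matrix()` returns the validated matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  check_dist(m)
  m
}

#' @rdname read_distance_matrix
#' @param d Distance matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d),
                   matrix(formatC(d, format = "g", digits = 17), nrow(d),
                          dimnames = dimnames(d)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
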