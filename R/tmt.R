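#' TMT plex design
#'
#' Describes one isobaric-labeling experiment: its channel labels, which
#' two channels carry the pooled bridge composite, and which sample each
#' remaining channel was labeled with. The study default is a 10-plex
#' with bridges "126" and "131" and eight sample channels.
#'
#' @param plex_id Identifier for the mass-spectrometry run.
#' @param channels Character vector of channel labels, in column order
#'   of the PSM table's `sn_<channel>` columns.
#' @param bridge_channels Exactly two channel labels used as bridges.
#' @param sample_assignments Named character vector mapping each
#'   non-bridge channel label to a sample id.
#' @return A list of class `plex_design`.
#' @export
plex_design <- function(plex_id, channels, bridge_channels, sample_assignments) {
  if (length(bridge_channels) != 2)
    stop("a plex must have exactly two bridge channels")
  if (!all(bridge_channels %in% channels))
    stop("bridge channels must be among the plex channels")
  smp <- setdiff(channels, bridge_channels)
  if (!setequal(names(sample_assignments), smp))
    stop("every sample channel must map to a sample")
  structure(list(plex_id = plex_id, channels = channels,
                 bridge_channels = bridge_channels,
                 sample_assignments = sample_assignments[smp]),
            class = "plex_design")
}

default_channels <- function(n = 10) {
  stopifnot(n %in% c(10, 11))
  ch <- c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
          "130C", "131")
  if (n == 11) ch <- c(ch, "131C")
  ch
}

sn_cols <- function(channels) paste0("sn_", channels)

#' Read and write PSM quantification tables
#'
#' Tab-separated with columns `peptide`, `proteins` (candidate protein
#' ids, semicolon-separated), `confidence`
#' (high/moderate/ambiguous), `interference_pct`, `plex`, and one
#' `sn_<channel>` signal-to-noise column per channel.
#'
#' @param path File path.
#' @return A data.frame of PSM records.
#' @export
read_psm_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_psm_table
#' @param psms PSM data.frame.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write plex designs as JSON
#'
#' One record per plex: channel labels, the two bridge channels, and the
#' channel-to-sample assignments.
#'
#' @param designs List of [plex_design()]s.
#' @param path File path.
#' @return `read_plex_designs()` returns a list of `plex_design`s.
#' @export
write_plex_designs <- function(designs, path) {
  enc <- lapply(designs, function(d) {
    list(plex_id = d$plex_id, channels = d$channels,
         bridge_channels = d$bridge_channels,
         sample_assignments = as.list(d$sample_assignments))
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plex_designs
#' @export
read_plex_designs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    plex_design(d$plex_id, unlist(d$channels), unlist(d$bridge_channels),
                unlist(d$sample_assignments))
  })
}

#' Stringent PSM filtering
#'
#' Applies the quantification filters in fixed order and rejects each
#' PSM at its first failing rule: (1) moderate confidence, (2) ambiguous
#' assignment, (3) isolation interference above 25%, (4) mean reporter
#' signal-to-noise below 10 (arithmetic mean over all channels of the
#' PSM's plex, bridges included). Proteins left with a single surviving
#' high-confidence PSM are deliberately retained downstream.
#'
#' @param psms PSM data.frame (see [read_psm_table()]).
#' @param interference_max Maximum tolerated isolation interference, in
#'   percent (default 25).
#' @param min_mean_sn Minimum mean signal-to-noise (default 10).
#' @return List with `kept` (the surviving rows) and `rejection_log`, a
#'   named integer vector of per-rule rejection counts.
#' @export
filter_psms <- function(psms, interference_max = 25, min_mean_sn = 10) {
  log <- c(moderate_confidence = 0L, ambiguous = 0L,
           high_interference = 0L, low_sn = 0L)
  if (nrow(psms) == 0)
    return(list(kept = psms, rejection_log = log))
  sn <- as.matrix(psms[, grep("^sn_", names(psms)), drop = FALSE])
  mean_sn <- rowMeans(sn)
  r1 <- psms$confidence == "moderate"
  r2 <- !r1 & psms$confidence == "ambiguous"
  r3 <- !r1 & !r2 & psms$interference_pct > interference_max
  r4 <- !r1 & !r2 & !r3 & mean_sn < min_mean_sn
  log["moderate_confidence"] <- sum(r1)
  log["ambiguous"] <- sum(r2)
  log["high_interference"] <- sum(r3)
  log["low_sn"] <- sum(r4)
  list(kept = psms[!(r1 | r2 | r3 | r4), , drop = FALSE], rejection_log = log)
}

#' Resolve shared peptides to single proteins
#'
#' Collapses exact duplicate records (same peptide sequence within a
#' plex) and then assigns each peptide to one protein by an iterative
#' greedy rule: a peptide whose candidate set contains a protein that
#' already holds an assigned peptide goes to that protein (the longest
#' such, ties broken lexicographically by id); otherwise, once no
#' further prior-based assignment is possible, the first unresolved
#' peptide in input order is assigned to its longest candidate, and the
#' pass repeats to a fixed point.
#'
#' @param psms PSM data.frame.
#' @param protein_lengths Named numeric vector of protein lengths (aa)
#'   covering every candidate id.
#' @return The PSM data.frame with duplicates removed and an
#'   `assigned_protein` column set.
#' @export
resolve_shared_peptides <- function(psms, protein_lengths) {
  dup <- duplicated(psms[c("peptide", "plex")])
  psms <- psms[!dup, , drop = FALSE]
  cand <- strsplit(psms$proteins, ";", fixed = TRUE)
  all_cand <- unique(unlist(cand))
  unknown <- setdiff(all_cand, names(protein_lengths))
  if (length(unknown))
    stop("candidate protein(s) with unknown length: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  assigned <- rep(NA_character_, nrow(psms))
  n_assigned <- integer(0)  # named per-protein assigned-peptide counts

  bump <- function(p) {
    cur <- n_assigned
    cur[p] <- (if (p %in% names(cur)) cur[[p]] else 0L) + 1L
    n_assigned <<- cur
  }
  pick_longest <- function(ids) {
    len <- protein_lengths[ids]
    ids <- ids[len == max(len)]
    sort(ids)[1]
  }
  # unique-candidate peptides seed the priors
  for (i in seq_along(cand)) {
    if (length(cand[[i]]) == 1) {
      assigned[i] <- cand[[i]]
      bump(cand[[i]])
    }
  }
  repeat {
    progress <- FALSE
    for (i in seq_along(cand)) {
      if (!is.na(assigned[i])) next
      with_prior <- intersect(cand[[i]], names(n_assigned)[n_assigned > 0])
      if (length(with_prior)) {
        assigned[i] <- pick_longest(with_prior)
        bump(assigned[i])
        progress <- TRUE
      }
    }
    if (all(!is.na(assigned))) break
    if (!progress) {
      i <- which(is.na(assigned))[1]
      assigned[i] <- pick_longest(cand[[i]])
      bump(assigned[i])
    }
  }
  psms$assigned_protein <- assigned
  psms
}

#' Sum PSM signal-to-noise to a protein-by-channel matrix
#'
#' @param psms Assigned PSM data.frame for one plex.
#' @param design The plex's [plex_design()].
#' @return Numeric matrix, proteins x channels, summed signal-to-noise.
#' @export
rollup_psms_to_proteins <- function(psms, design) {
  stopifnot(inherits(design, "plex_design"))
  psms <- psms[psms$plex == design$plex_id, , drop = FALSE]
  if (is.null(psms$assigned_protein) || anyNA(psms$assigned_protein))
    stop("all PSMs must be assigned before rollup")
  cols <- sn_cols(design$channels)
  missing_cols <- setdiff(cols, names(psms))
  if (length(missing_cols))
    stop("PSM table lacks channel column(s): ", paste(missing_cols, collapse = ", "))
  sn <- as.matrix(psms[, cols, drop = FALSE])
  prot <- sort(unique(psms$assigned_protein))
  out <- rowsum(sn, group = psms$assigned_protein)[prot, , drop = FALSE]
  colnames(out) <- design$channels
  out
}

#' Bridge-channel normalization across plexes
#'
#' For each protein in each plex, channel signal-to-noise is divided by
#' each of the two bridge-channel values; each per-bridge ratio set is
#' rescaled by the median of that bridge's ratios (per plex by default);
#' the two rescaled ratios are averaged; and the assembled table is
#' finally divided by the median over the entire data set, yielding
#' normalized summed signal-to-noise ratios per protein per sample with
#' global median 1. A protein whose bridge signal is zero or absent in a
#' plex is recorded missing for that plex's samples and logged.
#'
#' @param matrices Named list (by plex id) of protein x channel matrices
#'   from [rollup_psms_to_proteins()].
#' @param designs List of [plex_design()]s matching `matrices`.
#' @param median_scope `"plex"` (default) rescales each bridge's ratios
#'   by its plex-wide median; `"study"` uses one median per bridge over
#'   all plexes.
#' @param channel_median Logical (default `FALSE`). If `TRUE`, each
#'   sample channel is additionally divided by its own median across
#'   proteins before the global-median step, correcting per-channel
#'   loading differences (the "amounts of protein labeled" adjustment).
#'   Off by default because it rescales columns and therefore breaks
#'   the exact proportionality of the plain bridge ratios to the
#'   underlying relative abundances.
#' @return A `feature_table` (`layer = "protein"`) over all samples,
#'   with attribute `bridge_log`, a data.frame of proteins dropped per
#'   plex for zero/absent bridge signal.
#' @export
bridge_normalize <- function(matrices, designs, median_scope = c("plex", "study"),
                             channel_median = FALSE) {
  median_scope <- match.arg(median_scope)
  ids <- vapply(designs, function(d) d$plex_id, character(1))
  if (!setequal(names(matrices), ids))
    stop("matrices and designs must cover the same plex ids")
  designs <- designs[match(names(matrices), ids)]

  ratio_sets <- list()  # per plex: list(r1, r2, samples)
  log_rows <- list()
  for (k in seq_along(matrices)) {
    d <- designs[[k]]
    m <- matrices[[k]]
    b <- d$bridge_channels
    smp_ch <- names(d$sample_assignments)
    bad <- !is.finite(m[, b[1]]) | m[, b[1]] <= 0 |
           !is.finite(m[, b[2]]) | m[, b[2]] <= 0
    if (any(bad))
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(plex = d$plex_id, protein = rownames(m)[bad],
                   reason = "zero_bridge_signal", stringsAsFactors = FALSE)
    m <- m[!bad, , drop = FALSE]
    r1 <- m[, smp_ch, drop = FALSE] / m[, b[1]]
    r2 <- m[, smp_ch, drop = FALSE] / m[, b[2]]
    ratio_sets[[d$plex_id]] <- list(r1 = r1, r2 = r2,
                                    samples = unname(d$sample_assignments[smp_ch]))
  }

  if (median_scope == "study") {
    m1 <- stats::median(unlist(lapply(ratio_sets, function(s) s$r1)), na.rm = TRUE)
    m2 <- stats::median(unlist(lapply(ratio_sets, function(s) s$r2)), na.rm = TRUE)
  }
  all_samples <- unlist(lapply(ratio_sets, function(s) s$samples))
  if (anyDuplicated(all_samples))
    stop("a sample may appear in only one plex")
  all_prot <- sort(unique(unlist(lapply(ratio_sets, function(s) rownames(s$r1)))))
  out <- matrix(NA_real_, length(all_prot), length(all_samples),
                dimnames = list(all_prot, all_samples))
  for (s in ratio_sets) {
    if (median_scope == "plex") {
      m1 <- stats::median(s$r1, na.rm = TRUE)
      m2 <- stats::median(s$r2, na.rm = TRUE)
    }
    vals <- (s$r1 / m1 + s$r2 / m2) / 2
    out[rownames(vals), s$samples] <- vals
  }
  if (channel_median) {
    cm <- apply(out, 2, stats::median, na.rm = TRUE)
    out <- sweep(out, 2, cm, "/")
  }
  gm <- stats::median(out, na.rm = TRUE)
  out <- out / gm
  ft <- feature_table(out, layer = "protein")
  attr(ft, "bridge_log") <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(plex = character(0), protein = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  ft
}

#' Lowest-common-ancestor taxonomy adjustment
#'
#' Reassigns each multi-candidate peptide's taxonomy to the deepest
#' lineage rank shared by all of its candidate proteins, then replaces
#' each protein's lineage by the LCA over the labels of the peptides
#' assigned to it. Peptides with no annotated candidate contribute an
#' unclassified (all-`NA`) lineage.
#'
#' @param psms Assigned PSM data.frame (after
#'   [resolve_shared_peptides()]).
#' @param ann An [annotation_table()] covering the candidate proteins.
#' @return An `annotation_table` for the assigned proteins with
#'   LCA-adjusted lineages (other columns carried over from `ann` where
#'   available).
#' @export
lca_adjust_taxonomy <- function(psms, ann) {
  if (is.null(psms$assigned_protein) || anyNA(psms$assigned_protein))
    stop("PSMs must be assigned before LCA adjustment")
  ranks <- lineage_ranks()
  lin <- as.matrix(ann[ranks])
  rownames(lin) <- ann$feature_id

  lca_of <- function(mat) {
    # deepest rank on which all rows agree and are non-missing
    out <- rep(NA_character_, length(ranks))
    for (j in seq_along(ranks)) {
      v <- mat[, j]
      if (any(is.na(v)) || length(unique(v)) != 1) break
      out[j] <- v[1]
    }
    out
  }
  cand <- strsplit(psms$proteins, ";", fixed = TRUE)
  pep_lin <- t(vapply(cand, function(ids) {
    known <- intersect(ids, rownames(lin))
    if (length(known) == 0) return(rep(NA_character_, length(ranks)))
    lca_of(lin[known, , drop = FALSE])
  }, character(length(ranks))))

  prot_ids <- sort(unique(psms$assigned_protein))
  prot_lin <- t(vapply(prot_ids, function(p) {
    lca_of(pep_lin[psms$assigned_protein == p, , drop = FALSE])
  }, character(length(ranks))))
  colnames(prot_lin) <- ranks

  idx <- match(prot_ids, ann$feature_id)
  out <- data.frame(feature_id = prot_ids, prot_lin,
                    go_terms = ifelse(is.na(idx), NA_character_, ann$go_terms[idx]),
                    ko = ifelse(is.na(idx), NA_character_, ann$ko[idx]),
                    eggnog = ifelse(is.na(idx), NA_character_, ann$eggnog[idx]),
                    gram = ifelse(is.na(idx), "unknown", ann$gram[idx]),
                    stringsAsFactors = FALSE)
  annotation_table(out)
}
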