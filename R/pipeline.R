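#' Run the full gene-protein concordance pipeline
#'
#' Orchestrates the stages end to end: TMT quantification (PSM filter,
#' shared-peptide resolution, rollup, bridge normalization) or a
#' pre-quantified protein table; CPM normalization and replicate
#' collapse; inter-omic concordance; biomarker association with
#' compositional log ratios and the dysbiosis index; and the
#' distance/ordination/permutation layer. Every artifact is written
#' under `config$out_dir` as TSV/JSON and checksummed into
#' `manifest.json`; identical config + seed yields an identical
#' manifest. A failing stage aborts with the stage named and leaves a
#' `FAILED` marker alongside any partial outputs.
#'
#' @param config A list:
#' \describe{
#'   \item{gene_counts}{Path to the gene count TSV (features x replicate
#'     samples).}
#'   \item{psms, designs, protein_lengths}{PSM TSV path, list of
#'     [plex_design()]s, and named length vector — or instead}
#'   \item{proteins}{path to an already-normalized protein table TSV.}
#'   \item{annotation, metadata}{Paths to the annotation and metadata
#'     TSVs.}
#'   \item{biomarker_map}{Named list biomarker -> protein ids (default
#'     [biomarker_protein_map()]).}
#'   \item{increased_taxa, decreased_taxa}{Species lists for the
#'     dysbiosis index (default [dysbiosis_species_lists()]).}
#'   \item{tau, log_base, n_perm, seed, out_dir}{Effect-size threshold
#'     (0.7), log-ratio base (2), permutation count (999), RNG seed
#'     (required), output directory.}
#' }
#' @return Invisibly, a list with the key in-memory results and the
#'   manifest (file -> md5) data.frame.
#' @export
run_pipeline <- function(config) {
  req <- c("gene_counts", "annotation", "metadata", "seed", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(config$psms) && is.null(config$proteins))
    stop("config must provide either `psms` (+ designs, protein_lengths) or `proteins`")
  tau <- config$tau %||% 0.7
  log_base <- config$log_base %||% 2
  n_perm <- config$n_perm %||% 999
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  meta <- stage("inputs", read_sample_metadata(config$metadata))
  ann <- stage("inputs", read_annotation_table(config$annotation))

  # --- tmt_quant -----------------------------------------------------
  proteins <- stage("tmt_quant", {
    if (!is.null(config$psms)) {
      psms <- read_psm_table(config$psms)
      flt <- filter_psms(psms)
      res <- resolve_shared_peptides(flt$kept, config$protein_lengths)
      mats <- lapply(config$designs, function(d) rollup_psms_to_proteins(res, d))
      names(mats) <- vapply(config$designs, function(d) d$plex_id, character(1))
      ft <- bridge_normalize(mats, config$designs)
      utils::write.table(
        data.frame(rule = names(flt$rejection_log),
                   n_rejected = as.integer(flt$rejection_log)),
        emit(file.path(out, "psm_rejection_log.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      note("tmt_quant: %d PSMs in, %d kept, %d proteins quantified",
           nrow(psms), nrow(res), nrow(ft$values))
      write_feature_table(ft, emit(file.path(out, "protein_table.tsv")))
      ft
    } else {
      read_feature_table(config$proteins, layer = "protein")
    }
  })

  # --- data_model ----------------------------------------------------
  collapsed <- stage("data_model", {
    counts <- read_feature_table(config$gene_counts, layer = "gene")$values
    genes_cpm <- cpm_normalize(counts)
    g <- collapse_replicates(genes_cpm, meta, mode = "sum")
    p <- collapse_replicates(proteins, meta, mode = "mean")
    write_feature_table(g, emit(file.path(out, "genes_by_date.tsv")))
    write_feature_table(p, emit(file.path(out, "proteins_by_date.tsv")))
    note("data_model: %d genes, %d proteins collapsed to %d dates",
         nrow(g$values), nrow(p$values), ncol(g$values))
    list(genes = g, proteins = p)
  })

  # --- concordance ---------------------------------------------------
  conc <- stage("concordance", {
    paired <- subset_shared_features(collapsed$genes, collapsed$proteins)
    cs <- paired_feature_spearman(paired)
    utils::write.table(
      data.frame(feature_id = names(cs$rho), rho = cs$rho),
      emit(file.path(out, "paired_spearman.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    go <- category_concordance(paired$genes, paired$proteins, ann, "GO",
                               mode = "category_summed")
    dr_g <- dynamic_range(collapsed$genes)
    dr_p <- dynamic_range(collapsed$proteins)
    go_roll <- rollup_by_category(collapsed$genes, ann, "GO")
    top_go <- top_fluctuating_categories(dynamic_range(go_roll, "category"), 10)
    utils::write.table(top_go, emit(file.path(out, "top_go_fluctuations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(n_shared = paired$n_shared,
                    mean_rho = cs$mean, sd_rho = cs$sd,
                    n_omitted = cs$n_omitted,
                    go_summed_mean_rho = go$mean, go_summed_sd_rho = go$sd,
                    gene_sd_var = attr(sd_profile(collapsed$genes, TRUE),
                                       "distribution_variance"),
                    gene_max_ratio = if (nrow(dr_g)) max(dr_g$max_min_ratio) else NA,
                    protein_max_ratio = if (nrow(dr_p)) max(dr_p$max_min_ratio) else NA)
    jsonlite::write_json(summary, emit(file.path(out, "concordance_summary.json")),
                         digits = NA, auto_unbox = TRUE, na = "null")
    note("concordance: %d shared features, mean rho %.3f", paired$n_shared, cs$mean)
    list(paired = paired, spearman = cs, summary = summary)
  })

  # --- association ---------------------------------------------------
  assoc <- stage("association", {
    bm_map <- config$biomarker_map %||% biomarker_protein_map()
    bio <- extract_biomarkers(collapsed$proteins, bm_map)
    write_biomarker_series(bio, emit(file.path(out, "biomarkers.tsv")))
    run_layer <- function(tab) {
      do.call(rbind, lapply(rownames(bio), function(b) {
        select_strong(regress_features_vs_biomarker(tab, bio[b, ], b), tau)$all
      }))
    }
    res_g <- run_layer(collapsed$genes)
    res_p <- run_layer(collapsed$proteins)
    utils::write.table(res_g, emit(file.path(out, "associations_gene.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res_p, emit(file.path(out, "associations_protein.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    first_bio <- rownames(bio)[1]
    res_p1 <- res_p[res_p$biomarker == first_bio, ]
    lr <- tryCatch(
      composition_log_ratio(res_p1[res_p1$class == "positive", ],
                            res_p1[res_p1$class == "negative", ],
                            ann, "genus", base = log_base),
      error = function(e) NULL)
    if (!is.null(lr))
      utils::write.table(lr, emit(file.path(out, "genus_log_ratios.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- association_overlap(res_g, res_p,
                              intersect(rownames(collapsed$genes$values),
                                        rownames(collapsed$proteins$values)))
    jsonlite::write_json(ov[setdiff(names(ov), "venn")],
                         emit(file.path(out, "association_overlap.json")),
                         digits = NA, auto_unbox = TRUE, na = "null")
    sp <- rollup_by_category(collapsed$genes, ann, "species")
    lists <- list(increased = config$increased_taxa %||%
                    dysbiosis_species_lists()$increased,
                  decreased = config$decreased_taxa %||%
                    dysbiosis_species_lists()$decreased)
    di <- tryCatch(dysbiosis_index(sp, lists$increased, lists$decreased,
                                   base = log_base),
                   error = function(e) NULL)
    if (!is.null(di))
      utils::write.table(data.frame(sample = names(di$index), index = di$index),
                         emit(file.path(out, "dysbiosis_index.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    note("association: %d/%d strong gene/protein associations",
         sum(res_g$class != "none"), sum(res_p$class != "none"))
    list(biomarkers = bio, gene = res_g, protein = res_p, overlap = ov,
         genus_log_ratio = lr, dysbiosis = di,
         crosscor = biomarker_crosscorrelation(bio))
  })

  # --- ordination_stats ----------------------------------------------
  ordn <- stage("ordination", {
    g_ft <- collapsed$genes
    p_ft <- filter_complete_features(collapsed$proteins)
    dg <- bray_curtis(g_ft)
    dp <- bray_curtis(p_ft)
    write_distance_matrix(dg, emit(file.path(out, "bray_curtis_gene.tsv")))
    write_distance_matrix(dp, emit(file.path(out, "bray_curtis_protein.tsv")))
    og <- pcoa(dg)
    op <- pcoa(dp)
    pr <- procrustes_analysis(og$coordinates, op$coordinates)
    mt <- mantel(dg, dp, n_perm = n_perm, seed = config$seed)
    date_state <- unique(meta[c("collection_date", "inflammation_state")])
    grp <- date_state$inflammation_state[
      match(colnames(dg), date_state$collection_date)]
    pf <- list(gene = NA_real_, protein = NA_real_)
    pv <- list(gene = NA_real_, protein = NA_real_)
    if (length(unique(grp)) >= 2 && all(table(grp) >= 2)) {
      pg <- permanova(dg, grp, n_perm = n_perm, seed = config$seed)
      pp <- permanova(dp, grp, n_perm = n_perm, seed = config$seed)
      pf <- list(gene = pg$statistic, protein = pp$statistic)
      pv <- list(gene = pg$p_value, protein = pp$p_value)
    }
    genus_g <- rollup_by_category(g_ft, ann, "genus")
    genus_p <- rollup_by_category(p_ft, ann, "genus")
    comp <- function(ft) {
      v <- ft$values
      sweep(v, 2, colSums(v), "/")
    }
    fr_g <- friedman_rank_test(t(comp(genus_g)))
    fr_p <- friedman_rank_test(t(comp(genus_p)))
    summary <- list(procrustes_m2 = pr$m2,
                    mantel_r = mt$statistic, mantel_p = mt$p_value,
                    pseudo_F_gene = pf$gene, pseudo_F_protein = pf$protein,
                    permanova_p_gene = pv$gene, permanova_p_protein = pv$protein,
                    friedman_chisq_gene = fr_g$statistic,
                    friedman_p_gene = fr_g$p_value,
                    friedman_chisq_protein = fr_p$statistic,
                    friedman_p_protein = fr_p$p_value,
                    n_perm = n_perm, seed = config$seed)
    jsonlite::write_json(summary, emit(file.path(out, "ordination_summary.json")),
                         digits = NA, auto_unbox = TRUE, na = "null")
    note("ordination: Mantel r %.3f (p %.4f), Procrustes M2 %.4f",
         mt$statistic, mt$p_value, pr$m2)
    summary
  })

  writeLines(log_lines, emit(file.path(out, "run_log.txt")))
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(out_dir = out, manifest = manifest, collapsed = collapsed,
                 concordance = conc, association = assoc, ordination = ordn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
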