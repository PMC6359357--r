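#' Run the full synthetic regeneration analysis end to end
#'
#' Generates a synthetic experiment and runs every stage: quality control,
#' filtering, TMM normalization, surrogate-variable estimation, mixed-control
#' differential expression at every timepoint, phase grouping, fuzzy
#' temporal clustering, spatial localization from ranked location profiles,
#' gene-set enrichment per cluster, miRNA-target validation and hub
#' grouping, and the cross-species differentiation analysis. All tables are
#' written as TSV (plus GraphML for the networks) under `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param sva Estimate surrogate variables (default TRUE).
#' @param n_clusters Number of temporal clusters (default 5).
#' @param membership_min Hard-assignment threshold (default 0.7).
#' @param fdr_max,lfc_min DEG thresholds.
#' @param group_p Hub-grouping hypergeometric threshold (default 0.01).
#' @return Invisible list with every intermediate result (`sim`, `qc`,
#'   `norm`, `de`, `phases`, `assign`, `weights`, `enrichment`, `validated`,
#'   `hubs`, `hub_report`, `cross_species`, `screen`, `files`).
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         sva = TRUE, n_clusters = 5, membership_min = 0.7,
                         fdr_max = 0.01, lfc_min = 1, group_p = 0.01) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, df) {
    if (is.null(out_dir) || is.null(df)) return(NA_character_)
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character()

  sim <- simulate_experiment(config)

  # --- preprocessing -------------------------------------------------------
  qc <- qc_flag_samples(sim$mrna)
  keep <- qc$sample[!qc$flagged]
  exp_m <- subset_experiment(sim$mrna, samples = keep)
  exp_m <- filter_low_counts(exp_m)
  norm <- tmm_normalize(exp_m)
  if (sva) norm <- estimate_surrogate_variables(norm, seed = config$seed + 7L)
  else norm$sv <- matrix(0, ncol(exp_m$counts), 0)
  pca <- pca_view(norm)
  files["qc"] <- emit("qc_report.tsv", qc)
  files["pca"] <- emit("pca_scores.tsv",
                       data.frame(sample = rownames(pca$scores), pca$scores))

  # --- mixed-control differential expression ------------------------------
  schedule <- control_schedule()
  de <- run_de(norm, schedule, fdr_max = fdr_max, lfc_min = lfc_min)
  phases <- tryCatch(phase_cluster(de), error = function(e) NULL)
  files["de"] <- emit("de_results.tsv", de)

  # --- temporal clustering -------------------------------------------------
  z <- zscore_trajectories(de)
  assign <- fuzzy_cmeans(z, c = n_clusters, seed = config$seed + 11L,
                         membership_min = membership_min)
  files["membership"] <- emit("cluster_membership.tsv",
                              data.frame(gene = rownames(assign$membership),
                                         assign$membership,
                                         hard = assign$hard))
  files["centroids"] <- emit("cluster_centroids.tsv",
                             data.frame(cluster = rownames(assign$centroids),
                                        assign$centroids, check.names = FALSE))

  # --- spatial localization ------------------------------------------------
  ranks <- simulate_location_ranks(sim$truth)
  weights <- suppressWarnings(location_weights(assign, ranks))
  files["weights"] <- emit("location_weights.tsv", weights)

  # --- enrichment ----------------------------------------------------------
  gs <- simulate_genesets(sim$truth)
  universe <- rownames(norm$logcpm)
  enrichment <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
    q <- cluster_genes(assign, i)
    if (!length(q)) return(NULL)
    cbind(cluster = i, fisher_enrichment(q, gs$sets, universe))
  }))
  files["enrichment"] <- emit("cluster_enrichment.tsv", enrichment)
  if (!is.null(out_dir)) {
    gml <- file.path(out_dir, "cluster_network.graphml")
    suppressWarnings(export_cluster_graph(enrichment, gs$sets, weights, gml))
    files["graph"] <- gml
  }

  # --- miRNA integration ---------------------------------------------------
  validated <- NULL; hubs <- NULL; hub_report <- NULL
  if (!is.null(sim$mirna)) {
    exp_mi <- filter_low_counts(sim$mirna)
    norm_mi <- tmm_normalize(exp_mi)
    interactions <- simulate_interaction_table(sim$truth)
    cand <- filter_context(interactions[, c("mirna_id", "gene_id",
                                            "context_score")])
    cand <- correlate_pairs(cand, norm$logcpm, norm_mi$logcpm)
    assigned <- names(assign$hard)[!is.na(assign$hard)]
    validated <- validate_interactions(cand, assigned_genes = assigned,
                                       expressed_mirnas = rownames(norm_mi$logcpm))
    files["interactions"] <- emit("validated_interactions.tsv", validated)
    if (sum(validated$valid) > 0 &&
        length(unique(validated$mirna_id[validated$valid])) >= 2) {
      hubs <- group_mirnas(validated, p_max = group_p,
                           universe = length(assigned))
      hub_report <- top_hubs(hubs, k = 10, assign = assign)
      files["hubs"] <- emit("top_hubs.tsv", hub_report)
      if (!is.null(out_dir)) {
        hg <- file.path(out_dir, "hub_targets.graphml")
        export_hub_graph(hubs, hg)
        files["hub_graph"] <- hg
      }
    }
  }

  # --- cross-species validation -------------------------------------------
  homology <- simulate_homology(sim$truth)
  series <- simulate_differentiation_series(sim$truth, homology)
  ct <- contrast_stage(series$mrna)
  xs <- association_with_cluster(ct$down, assign,
                                 homology[, c("gene_a", "gene_b")])
  ct_mi <- contrast_stage(series$mirna)
  hom2 <- homology$gene_b[homology$gene_a %in% cluster_genes(assign, 2)]
  screen <- NULL
  if (!is.null(sim$mirna)) {
    true_pairs <- simulate_interaction_table(sim$truth, n_decoys = 0)
    xs_int <- data.frame(mirna_id = true_pairs$mirna_id,
                         gene_id = paste0("rn_", true_pairs$gene_id))
    screen <- suppressWarnings(
      stagewise_correlation_screen(series$mrna, series$mirna, xs_int,
                                   restrict_genes = hom2,
                                   restrict_mirnas = ct_mi$up))
    if (!is.null(screen) && nrow(screen))
      files["screen"] <- emit("differentiation_screen.tsv", screen)
  }
  files["cross_species"] <- emit(
    "cross_species_association.tsv",
    data.frame(statistic = if (is.null(xs)) NA else xs$statistic,
               p = if (is.null(xs)) NA else xs$p))

  invisible(list(sim = sim, qc = qc, norm = norm, pca = pca,
                 schedule = schedule, de = de, phases = phases,
                 assign = assign, ranks = ranks, weights = weights,
                 genesets = gs, enrichment = enrichment,
                 validated = validated, hubs = hubs, hub_report = hub_report,
                 cross_species = xs, screen = screen,
                 files = files[!is.na(files)]))
}
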