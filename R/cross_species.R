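#' Differential expression between two stages of a differentiation series
#'
#' Negative-binomial likelihood-ratio test (uniform observation weights, no
#' mixed control) of `stage_b` vs `stage_a`, with TMM effective library
#' sizes as offsets and BH FDR across genes. Returns both direction sets at
#' the given thresholds.
#'
#' @param series A [count_experiment()] whose metadata has a `stage` column.
#' @param stage_a,stage_b Reference and test stages (default undiff vs d5).
#' @param fdr_max,lfc_min Thresholds (defaults 0.01 and 1; down-regulated
#'   means `log2fc < -lfc_min`).
#' @param prior_df Dispersion-shrinkage prior df.
#' @return List with `table` (gene, log2fc, p, fdr), `down`, `up` gene sets.
#' @export
contrast_stage <- function(series, stage_a = "undiff", stage_b = "d5",
                           fdr_max = 0.01, lfc_min = 1, prior_df = 10) {
  meta <- series$samples
  if (is.null(meta$stage)) stop("series metadata needs a stage column")
  sa <- meta$sample[meta$stage == stage_a]
  sb <- meta$sample[meta$stage == stage_b]
  if (length(sa) < 2 || length(sb) < 2)
    stop("need at least 2 replicates per stage")
  samples <- c(sa, sb)
  counts <- series$counts[, samples, drop = FALSE]
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  offsets <- log(colSums(counts) * f)
  X <- cbind(`(Intercept)` = 1, stage = as.numeric(samples %in% sb))
  w <- rep(1, length(samples))
  phi <- estimate_dispersions(counts, X, weights = w, offsets = offsets,
                              prior_df = prior_df)
  res <- t(vapply(seq_len(nrow(counts)), function(g) {
    full <- fit_nb_glm(counts[g, ], X, phi[g], w, offsets)
    red <- fit_nb_glm(counts[g, ], X[, 1, drop = FALSE], phi[g], w, offsets)
    c(full$coef[2] / log(2), max(0, 2 * (full$loglik - red$loglik)))
  }, numeric(2)))
  pvals <- calibrated_lrt_pvalues(res[, 2])
  tab <- data.frame(gene = rownames(counts), log2fc = res[, 1], p = pvals,
                    fdr = bh_fdr(pvals), row.names = NULL)
  list(table = tab,
       down = tab$gene[tab$fdr < fdr_max & tab$log2fc < -lfc_min],
       up = tab$gene[tab$fdr < fdr_max & tab$log2fc > lfc_min])
}

#' Association of a cross-species gene set with a temporal cluster
#'
#' Maps a gene set from the second species to zebrafish through the
#' homologue table (many-to-many resolved by the any-match rule: a zebrafish
#' gene counts as "in the set" if any of its homologues is), cross-tabulates
#' membership against cluster assignment over the chosen universe, and tests
#' independence with the Pearson chi-squared test.
#'
#' @param geneset Character vector of second-species gene identifiers.
#' @param assign A `cluster_assignment` of zebrafish genes.
#' @param homology Data frame `gene_a` (zebrafish), `gene_b` (other species).
#' @param cluster Cluster of interest (default 2, the sustained early-peak
#'   proliferation-like group).
#' @param universe `"assigned"` (default) restricts the margin to
#'   hard-assigned genes; `"all"` uses every clustered gene.
#' @return List with the 2x2 `table`, `statistic`, `p`; or `NULL` (with a
#'   warning) when nothing maps.
#' @export
association_with_cluster <- function(geneset, assign, homology, cluster = 2,
                                     universe = c("assigned", "all")) {
  universe <- match.arg(universe)
  if (!nrow(homology)) {
    warning("empty homologue map; no association computed")
    return(NULL)
  }
  zf <- if (universe == "assigned") names(assign$hard)[!is.na(assign$hard)]
  else names(assign$hard)
  hom <- homology[homology$gene_a %in% zf, , drop = FALSE]
  if (!nrow(hom)) {
    warning("no mappable genes; no association computed")
    return(NULL)
  }
  in_set <- tapply(hom$gene_b %in% geneset, hom$gene_a, any)
  genes <- names(in_set)
  in_cl <- !is.na(assign$hard[genes]) & assign$hard[genes] == cluster
  tab <- table(factor(in_set, levels = c(TRUE, FALSE)),
               factor(in_cl, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(set = c("in_set", "out_set"),
                        cluster = c(paste0("cluster", cluster), "other"))
  res <- chi2_independence(as.matrix(tab))
  list(table = tab, statistic = res$statistic, p = res$p)
}

#' Stage-averaged anti-correlation screen in a differentiation series
#'
#' Replicates within each stage are averaged (on log2-CPM) first, then the
#' Pearson correlation of each predicted miRNA-target pair is computed over
#' the stage means. With only a handful of stages no FDR is applied: a pair
#' is valid when `rho < rho_max` alone (the asymmetric rule relative to the
#' full time course). The screen is restricted to the supplied gene and
#' miRNA universes (e.g. homologues of the proliferation cluster and miRNAs
#' up-regulated at the final stage).
#'
#' @param mrna_series,mirna_series [count_experiment()]s with a `stage`
#'   metadata column.
#' @param interactions Interaction table (`mirna_id`, `gene_id`).
#' @param rho_max Strict correlation threshold (default -0.4).
#' @param restrict_genes,restrict_mirnas Universes; `NULL` keeps all.
#' @return Interaction table with `rho` and `valid`; flat profiles excluded.
#' @export
stagewise_correlation_screen <- function(mrna_series, mirna_series,
                                         interactions, rho_max = -0.4,
                                         restrict_genes = NULL,
                                         restrict_mirnas = NULL) {
  stage_means <- function(series, stages) {
    st <- series$samples$stage
    if (is.null(st)) stop("series metadata needs a stage column")
    if (!setequal(st, stages)) stop("series disagree on stage labels")
    lc <- cpm(series$counts, log = TRUE)
    vapply(stages, function(s)
      rowMeans(lc[, st == s, drop = FALSE]), numeric(nrow(lc)))
  }
  # one shared stage order for both assays, so stage means stay aligned
  stages <- unique(mrna_series$samples$stage)
  if (length(stages) < 3) stop("need at least 3 stages")
  mr <- stage_means(mrna_series, stages)
  mi <- stage_means(mirna_series, stages)
  tab <- interactions
  if (!is.null(restrict_genes))
    tab <- tab[tab$gene_id %in% restrict_genes, , drop = FALSE]
  if (!is.null(restrict_mirnas))
    tab <- tab[tab$mirna_id %in% restrict_mirnas, , drop = FALSE]
  tab <- tab[tab$gene_id %in% rownames(mr) & tab$mirna_id %in% rownames(mi), ,
             drop = FALSE]
  if (!nrow(tab)) {
    warning("no interactions to screen after restriction")
    tab$rho <- numeric(0); tab$valid <- logical(0)
    return(tab)
  }
  x <- mr[tab$gene_id, , drop = FALSE]
  y <- mi[tab$mirna_id, , drop = FALSE]
  sx <- apply(x, 1, stats::sd); sy <- apply(y, 1, stats::sd)
  ok <- sx > 0 & sy > 0
  if (any(!ok)) message(sum(!ok), " flat-profile pair(s) excluded")
  tab <- tab[ok, , drop = FALSE]
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  tab$rho <- pmin(pmax(rowSums(xc * yc) /
                         sqrt(rowSums(xc^2) * rowSums(yc^2)), -1), 1)
  tab$valid <- tab$rho < rho_max
  rownames(tab) <- NULL
  tab
}
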