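#' Filter predicted interactions by context score
#'
#' Keeps rows with `context_score` strictly below `score_max` (more negative
#' scores = stronger predicted binding efficacy). Rows with a missing score
#' are dropped with a warning.
#'
#' @param table Interaction table with columns `mirna_id`, `gene_id`,
#'   `context_score`.
#' @param score_max Strict upper bound (default -0.2).
#' @return Filtered table.
#' @export
filter_context <- function(table, score_max = -0.2) {
  miss <- is.na(table$context_score)
  if (any(miss)) {
    warning(sum(miss), " row(s) without context score dropped")
    table <- table[!miss, , drop = FALSE]
  }
  out <- table[table$context_score < score_max, , drop = FALSE]
  message(nrow(out), " of ", nrow(table) + sum(miss),
          " interactions pass context score < ", score_max)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of predicted miRNA-target pairs
#'
#' For each interaction row, the Pearson correlation of miRNA and mRNA
#' log2-CPM across the matched samples (samples with both assays), with a
#' two-sided p-value from the t-transform and BH FDR across all tested
#' pairs. Pairs involving a zero-variance profile, or a feature absent from
#' either matrix, are excluded (logged).
#'
#' @param table Interaction table (`mirna_id`, `gene_id`).
#' @param mrna_logcpm,mirna_logcpm Log2-CPM matrices (features x samples).
#' @param samples Matched sample names; default the column intersection.
#' @return The table restricted to testable pairs with added `rho`, `rho_p`,
#'   `rho_fdr`.
#' @export
correlate_pairs <- function(table, mrna_logcpm, mirna_logcpm,
                            samples = intersect(colnames(mrna_logcpm),
                                                colnames(mirna_logcpm))) {
  if (length(samples) < 4)
    stop("need at least 4 matched samples, got ", length(samples))
  mr <- mrna_logcpm[, samples, drop = FALSE]
  mi <- mirna_logcpm[, samples, drop = FALSE]
  present <- table$gene_id %in% rownames(mr) & table$mirna_id %in% rownames(mi)
  if (any(!present))
    message(sum(!present), " pair(s) with unmeasured feature(s) excluded")
  tab <- table[present, , drop = FALSE]
  x <- mr[tab$gene_id, , drop = FALSE]
  y <- mi[tab$mirna_id, , drop = FALSE]
  sx <- apply(x, 1, stats::sd); sy <- apply(y, 1, stats::sd)
  ok <- sx > 0 & sy > 0
  if (any(!ok)) message(sum(!ok), " pair(s) with zero-variance profile excluded")
  tab <- tab[ok, , drop = FALSE]
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  n <- length(samples)
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  rho <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  tab$rho <- rho
  tab$rho_p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tab$rho_fdr <- bh_fdr(tab$rho_p)
  rownames(tab) <- NULL
  tab
}

#' Validate interactions by anti-correlation within the analysis universe
#'
#' Restricts the correlated table to cluster-assigned genes and expressed
#' miRNAs, recomputes the BH FDR within that restricted set (restriction
#' precedes the multiplicity correction), and flags rows as valid when
#' `rho < rho_max` and `rho_fdr < fdr_max` (and, if a context score column is
#' present, `context_score < score_max`).
#'
#' @param table Output of [correlate_pairs()].
#' @param rho_max Strict correlation threshold (default -0.4).
#' @param fdr_max FDR threshold (default 0.05).
#' @param assigned_genes,expressed_mirnas Analysis universes; `NULL` keeps
#'   all.
#' @param score_max Context-score threshold applied if the column exists.
#' @return Restricted table with recomputed `rho_fdr` and a `valid` flag.
#' @export
validate_interactions <- function(table, rho_max = -0.4, fdr_max = 0.05,
                                  assigned_genes = NULL,
                                  expressed_mirnas = NULL,
                                  score_max = -0.2) {
  tab <- table
  if (!is.null(assigned_genes))
    tab <- tab[tab$gene_id %in% assigned_genes, , drop = FALSE]
  if (!is.null(expressed_mirnas))
    tab <- tab[tab$mirna_id %in% expressed_mirnas, , drop = FALSE]
  if (!nrow(tab)) {
    warning("no interactions left after restriction to the analysis universe")
    tab$valid <- logical(0)
    return(tab)
  }
  tab$rho_fdr <- bh_fdr(tab$rho_p)
  tab$valid <- tab$rho < rho_max & tab$rho_fdr < fdr_max
  if ("context_score" %in% names(tab))
    tab$valid <- tab$valid & tab$context_score < score_max
  rownames(tab) <- NULL
  tab
}

#' Group miRNAs into hubs by shared validated targets
#'
#' Pairwise one-sided hypergeometric tests of target-set overlap against the
#' restricted gene universe; miRNA pairs with `p < p_max` are linked and
#' hubs are the connected components of that graph (so e.g. family members
#' sharing most targets merge transitively). Hubs are ranked by the size of
#' their target union, ties broken by the alphabetically first member.
#'
#' @param valid Interaction table with a `valid` flag (see
#'   [validate_interactions()]); only valid rows are used.
#' @param p_max Pair-significance threshold (default 0.01).
#' @param universe Size of the gene universe (or a gene identifier vector).
#' @return List of hubs, each a list with `members`, `targets`, `size`;
#'   ordered by decreasing `size`.
#' @export
group_mirnas <- function(valid, p_max = 0.01, universe) {
  if (!is.numeric(universe)) universe <- length(unique(universe))
  vt <- valid[valid$valid, , drop = FALSE]
  targets <- split(vt$gene_id, vt$mirna_id)
  targets <- lapply(targets, unique)
  targets <- targets[lengths(targets) > 0]
  if (length(targets) < 2)
    stop("need at least 2 miRNAs with at least 1 valid target")
  if (any(lengths(targets) > universe))
    stop("universe smaller than a target set")
  ids <- sort(names(targets))
  pairs <- utils::combn(ids, 2)
  linked <- apply(pairs, 2, function(pr) {
    a <- targets[[pr[1]]]; b <- targets[[pr[2]]]
    k <- length(intersect(a, b))
    k > 0 && hypergeom_overlap_p(k, length(a), length(b), universe) < p_max
  })
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = ids, to = ids),                # isolated vertices
          data.frame(from = pairs[1, linked], to = pairs[2, linked])),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  hubs <- lapply(split(names(comp), comp), function(members) {
    members <- sort(members)
    tg <- sort(unique(unlist(targets[members])))
    list(members = members, targets = tg, size = length(tg))
  })
  sizes <- vapply(hubs, `[[`, numeric(1), "size")
  first <- vapply(hubs, function(h) h$members[1], character(1))
  hubs <- hubs[order(-sizes, first)]
  names(hubs) <- vapply(hubs, function(h) paste(h$members, collapse = "/"),
                        character(1))
  hubs
}

#' Top regulator hubs with target-cluster composition
#'
#' @param hubs Hub list from [group_mirnas()] (already ranked).
#' @param k Number of hubs to report (all if fewer exist).
#' @param assign Optional `cluster_assignment`: adds each hub's dominant
#'   temporal cluster among its targets.
#' @return Data frame per hub: `hub`, `members`, `n_targets`,
#'   `dominant_cluster` (NA without `assign`).
#' @export
top_hubs <- function(hubs, k = 10, assign = NULL) {
  hubs <- hubs[seq_len(min(k, length(hubs)))]
  if (!length(hubs))
    return(data.frame(hub = character(), members = character(),
                      n_targets = integer(), dominant_cluster = integer()))
  rows <- lapply(names(hubs), function(nm) {
    h <- hubs[[nm]]
    dom <- NA_integer_
    if (!is.null(assign)) {
      cl <- assign$hard[h$targets]
      cl <- cl[!is.na(cl)]
      if (length(cl)) {
        tb <- table(cl)
        dom <- as.integer(names(tb)[which.max(tb)])
      }
    }
    data.frame(hub = nm, members = paste(h$members, collapse = ","),
               n_targets = h$size, dominant_cluster = dom)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the hub-target bipartite graph as GraphML
#'
#' @param hubs Hub list from [group_mirnas()].
#' @param path Output path.
#' @return The igraph object, invisibly.
#' @export
export_hub_graph <- function(hubs, path) {
  edf <- do.call(rbind, lapply(names(hubs), function(nm)
    data.frame(from = nm, to = hubs[[nm]]$targets)))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
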