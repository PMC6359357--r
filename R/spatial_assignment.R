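#' Validate a location-ranks table
#'
#' @param ranks Data frame with columns `location`, `gene`, `rank`; within
#'   each location the ranks must be a permutation of 1..N (rank 1 = highest
#'   absolute expression) and gene identifiers unique.
#' @return The validated data frame (invisibly usable downstream).
#' @export
validate_location_ranks <- function(ranks) {
  stopifnot(all(c("location", "gene", "rank") %in% names(ranks)))
  for (loc in unique(ranks$location)) {
    r <- ranks[ranks$location == loc, ]
    if (anyDuplicated(r$gene))
      stop("duplicate gene identifiers in location ", loc)
    if (!setequal(r$rank, seq_len(nrow(r))))
      stop("ranks in location ", loc, " are not a permutation of 1..N")
  }
  ranks
}

#' Location weights per temporal cluster from ranked expression profiles
#'
#' For every (cluster i, location j) the default statistic is the
#' observed-over-expected share of the cluster's hard-assigned genes inside
#' the location's top `top_frac` best-expressed genes:
#' `w_ij = |{g in cluster i : rank_j(g) <= top_frac * N_j}| /
#' (top_frac * |cluster i in list j|)`. Uniformly ranked clusters give
#' weights near 1; a cluster concentrated in a location's top ranks gets a
#' large weight. `literal = TRUE` instead computes the literal ratio
#' `max(ranks_ij) / max(top-20%-subset of ranks_ij)` of the cluster's ranks,
#' retained for comparison (its printed algebra cannot express "many genes
#' ranked high"; see the methods vignette).
#'
#' @param assign A `cluster_assignment` (see [fuzzy_cmeans()]).
#' @param ranks Location ranks table (`location`, `gene`, `rank`).
#' @param top_frac Top fraction of each list considered "high" (default 0.2).
#' @param literal Use the literal max-ratio statistic.
#' @return Data frame per (cluster, location): `cluster`, `location`,
#'   `n_genes`, `n_top`, `weight`, `share` (row-normalized within cluster).
#' @export
location_weights <- function(assign, ranks, top_frac = 0.2, literal = FALSE) {
  if (top_frac <= 0 || top_frac >= 1) stop("top_frac must lie in (0, 1)")
  ranks <- validate_location_ranks(ranks)
  clusters <- seq_len(ncol(assign$membership))
  locs <- unique(ranks$location)
  rows <- list()
  for (j in locs) {
    rj <- ranks[ranks$location == j, ]
    Nj <- nrow(rj)
    cutoff <- floor(top_frac * Nj)
    rank_of <- stats::setNames(rj$rank, rj$gene)
    for (i in clusters) {
      gi <- intersect(cluster_genes(assign, i), rj$gene)
      n <- length(gi)
      if (n == 0) {
        warning("cluster ", i, " has no hard-assigned gene in location ", j,
                "; weight set to 0")
        rows[[length(rows) + 1]] <-
          data.frame(cluster = i, location = j, n_genes = 0, n_top = 0,
                     weight = 0)
        next
      }
      ri <- rank_of[gi]
      k <- sum(ri <= cutoff)
      w <- if (literal) {
        top <- ri[ri <= cutoff]
        if (!length(top)) 0 else max(ri) / max(top)
      } else {
        k / (top_frac * n)
      }
      rows[[length(rows) + 1]] <-
        data.frame(cluster = i, location = j, n_genes = n, n_top = k,
                   weight = w)
    }
  }
  out <- do.call(rbind, rows)
  tot <- tapply(out$weight, out$cluster, sum)
  out$share <- ifelse(tot[as.character(out$cluster)] > 0,
                      out$weight / tot[as.character(out$cluster)], 0)
  rownames(out) <- NULL
  out
}

#' Export the cluster / gene-set / location network as GraphML
#'
#' Nodes are temporal clusters, gene sets and locations. Edges: cluster to
#' gene set where the enrichment is significant (thresholded Fisher p with
#' the overlap rule), gene set to gene set where the overlap fraction
#' (relative to the smaller set) reaches `overlap_frac`, and cluster to
#' location weighted by [location_weights()]. An empty graph is written with
#' a warning.
#'
#' @param enrichment Data frame with columns `cluster`, `set`, `p`,
#'   `overlap`, `significant` (e.g. stacked [fisher_enrichment()] results).
#' @param sets Named list of gene sets (for set-set overlap edges).
#' @param weights Location weight table from [location_weights()] (optional).
#' @param path Output GraphML path.
#' @param overlap_frac Minimum shared-gene fraction for set-set edges.
#' @return The igraph object, invisibly.
#' @export
export_cluster_graph <- function(enrichment, sets = NULL, weights = NULL,
                                 path, overlap_frac = 0.4) {
  edges <- list()
  nodes <- character()
  if (!is.null(enrichment) && nrow(enrichment)) {
    nodes <- c(nodes, paste0("cluster", unique(enrichment$cluster)),
               unique(enrichment$set[enrichment$significant]))
    sig <- enrichment[enrichment$significant, , drop = FALSE]
    if (nrow(sig))
      edges[[length(edges) + 1]] <-
        data.frame(from = paste0("cluster", sig$cluster), to = sig$set,
                   weight = -log10(pmax(sig$p, 1e-300)), type = "enrichment")
  }
  if (!is.null(sets) && length(sets) > 1) {
    nm <- names(sets)
    for (a in seq_along(sets)) for (b in seq_len(a - 1)) {
      ov <- length(intersect(sets[[a]], sets[[b]])) /
        min(length(sets[[a]]), length(sets[[b]]))
      if (ov >= overlap_frac)
        edges[[length(edges) + 1]] <-
          data.frame(from = nm[a], to = nm[b], weight = ov, type = "overlap")
    }
  }
  if (!is.null(weights) && nrow(weights)) {
    nodes <- c(nodes, paste0("cluster", unique(weights$cluster)),
               unique(weights$location))
    pos <- weights[weights$weight > 0, , drop = FALSE]
    if (nrow(pos))
      edges[[length(edges) + 1]] <-
        data.frame(from = paste0("cluster", pos$cluster), to = pos$location,
                   weight = pos$weight, type = "location")
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               weight = numeric(), type = character())
  nodes <- unique(c(nodes, edf$from, edf$to))
  if (!nrow(edf)) warning("cluster graph has no edges")
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = if (length(nodes))
                                       data.frame(name = nodes) else NULL)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
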