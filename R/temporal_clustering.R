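#' Z-score log2FC trajectories of differentially expressed genes
#'
#' Builds the genes x timepoints log2FC matrix for genes flagged as
#' differentially expressed at at least one timepoint (or a supplied gene
#' set) and standardizes each gene's trajectory to mean 0, sd 1. Genes with a
#' constant trajectory (sd 0) are dropped with a warning.
#'
#' @param de DE table from [run_de()].
#' @param genes Genes to include; default: DEG in any timepoint.
#' @return Standardized matrix (genes x timepoints).
#' @export
zscore_trajectories <- function(de, genes = NULL) {
  if (is.null(genes)) genes <- unique(de$gene[de$deg])
  if (!length(genes)) stop("no genes to standardize")
  m <- lfc_matrix(de[de$gene %in% genes, , drop = FALSE])
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " gene(s) with constant trajectory dropped")
    m <- m[sds > 0, , drop = FALSE]
  }
  t(scale(t(m)))
}

#' Estimate the fuzzy c-means fuzzifier from data dimensions
#'
#' Closed-form fuzzifier estimate
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`
#' for N trajectories over D timepoints, clipped to \[1.05, 4\]. Fewer than
#' 10 trajectories fall back to the default 1.25.
#'
#' @param z Standardized trajectory matrix (genes x timepoints).
#' @return The fuzzifier m (> 1).
#' @export
estimate_fuzzifier <- function(z) {
  N <- nrow(z); D <- ncol(z)
  if (N < 10) return(1.25)
  m <- 1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  min(max(m, 1.05), 4)
}

#' Fuzzy c-means clustering of temporal trajectories
#'
#' Standard alternating-optimization fuzzy c-means with Euclidean distance:
#' memberships `u_ik = 1 / sum_j (d_ik/d_jk)^(2/(m-1))`, centroids the
#' membership^m-weighted means. The best of `n_starts` random initializations
#' (by final objective) is returned; within each run the objective is
#' asserted non-increasing. Cluster labels are canonicalized by the peak time
#' of the centroids (earliest peak = cluster 1) so cluster identities are
#' reproducible. A gene sitting exactly on a centroid gets membership 1 for
#' that cluster.
#'
#' @param z Standardized trajectory matrix (genes x timepoints).
#' @param c Number of clusters (default 5 dynamic response groups).
#' @param m Fuzzifier; default [estimate_fuzzifier()].
#' @param seed Seed for the initializations.
#' @param n_starts Number of random starts.
#' @param tol Relative objective change declaring convergence.
#' @param max_iter Iteration cap per start.
#' @param membership_min Hard-assignment threshold (default 0.7).
#' @return Object of class `cluster_assignment`: `membership`
#'   (genes x c, rows sum to 1), `hard` (named integer, `NA` below the
#'   threshold), `centroids` (c x timepoints), `objective`,
#'   `objective_trace`, `m`, `membership_min`.
#' @export
fuzzy_cmeans <- function(z, c = 5, m = NULL, seed = 1, n_starts = 20,
                         tol = 1e-8, max_iter = 300, membership_min = 0.7) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (c >= n) stop("need more trajectories than clusters")
  if (is.null(m)) m <- estimate_fuzzifier(z)
  if (m <= 1) stop("fuzzifier must exceed 1")

  run_once <- function() {
    cent <- z[sample.int(n, c), , drop = FALSE]
    obj_trace <- numeric(0)
    obj <- obj_old <- Inf
    u <- NULL
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(z^2), rep(1, c)) - 2 * z %*% t(cent) +
        outer(rep(1, n), rowSums(cent^2))
      d2 <- pmax(d2, 0)
      u <- membership_from_d2(d2, m)
      um <- u^m
      cent_new <- (t(um) %*% z) / colSums(um)
      if (anyDuplicated(round(cent_new, 10))) {
        # degenerate collapse of centroids: restart this run
        cent <- z[sample.int(n, c), , drop = FALSE]
        obj_old <- Inf; obj_trace <- numeric(0)
        next
      }
      obj <- sum(um * d2)
      obj_trace <- c(obj_trace, obj)
      if (obj > obj_old * (1 + 1e-10))
        stop("fuzzy c-means objective increased; numerical failure")
      if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj, 1e-300)) {
        cent <- cent_new
        break
      }
      obj_old <- obj
      cent <- cent_new
    }
    list(u = u, cent = cent, obj = obj, trace = obj_trace)
  }

  best <- with_local_seed(seed, {
    runs <- lapply(seq_len(n_starts), function(i) run_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "obj"))]]
  })

  # canonical labels: order centroids by their peak timepoint, then peak value
  peak_t <- apply(best$cent, 1, which.max)
  peak_v <- apply(best$cent, 1, max)
  ord <- order(peak_t, -peak_v)
  u <- best$u[, ord, drop = FALSE]
  cent <- best$cent[ord, , drop = FALSE]
  colnames(u) <- rownames(cent) <- paste0("cluster", seq_len(c))
  rownames(u) <- rownames(z)
  colnames(cent) <- colnames(z)

  mx <- apply(u, 1, max)
  hard <- ifelse(mx > membership_min, apply(u, 1, which.max), NA_integer_)
  names(hard) <- rownames(z)
  structure(list(membership = u, hard = hard, centroids = cent,
                 objective = best$obj, objective_trace = best$trace,
                 m = m, membership_min = membership_min),
            class = "cluster_assignment")
}

# memberships from squared distances; exact zero distances get one-hot rows
# (split equally if a point coincides with several centroids)
membership_from_d2 <- function(d2, m) {
  pw <- d2^(-1 / (m - 1))
  u <- pw / rowSums(pw)
  zero <- d2 <= .Machine$double.eps * 100
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d genes, %d clusters (m = %.3f); %d hard-assigned at > %.0f%%\n",
              nrow(x$membership), ncol(x$membership), x$m,
              sum(!is.na(x$hard)), 100 * x$membership_min))
  invisible(x)
}

#' Hard-assigned genes of one cluster
#'
#' @param assign A `cluster_assignment`.
#' @param cluster Cluster index.
#' @return Character vector of gene identifiers.
#' @export
cluster_genes <- function(assign, cluster) {
  names(assign$hard)[!is.na(assign$hard) & assign$hard == cluster]
}
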