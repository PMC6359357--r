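#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment; `NA`/`NaN` entries are excluded from the ranking
#' (they do not count toward the number of tests) and propagated as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (over-representation) Fisher test of each set against the query
#' within the universe, with the additional overlap rule: a set is
#' significant iff `p < p_max` and the overlap holds at least `min_overlap`
#' genes. Sets and query are trimmed to the universe first (trimmed genes are
#' counted in the result).
#'
#' @param query Character vector of query genes.
#' @param collection Named list of gene sets.
#' @param universe Background gene identifiers.
#' @param p_max Significance threshold on the raw p-value.
#' @param min_overlap Minimum overlap for significance.
#' @param fdr If `TRUE`, add a BH-adjusted column (thresholding still uses
#'   the raw p, matching the overlap rule).
#' @return Data frame per set: `set`, `set_size`, `overlap`, `odds_ratio`,
#'   `p`, (optional `fdr`), `significant`.
#' @export
fisher_enrichment <- function(query, collection, universe, p_max = 0.05,
                              min_overlap = 4, fdr = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  n_u <- length(universe)
  query <- unique(intersect(query, universe))
  res <- lapply(names(collection), function(nm) {
    s <- unique(intersect(collection[[nm]], universe))
    a <- length(intersect(query, s))
    b <- length(query) - a
    cc <- length(s) - a
    d <- n_u - a - b - cc
    # one-sided hypergeometric upper tail == Fisher "greater"
    p <- stats::phyper(a - 1, length(s), n_u - length(s), length(query),
                       lower.tail = FALSE)
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set = nm, set_size = length(s), overlap = a,
               odds_ratio = or, p = p)
  })
  res <- do.call(rbind, res)
  if (fdr) res$fdr <- bh_fdr(res$p)
  res$significant <- res$p < p_max & res$overlap >= min_overlap
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation p for a set overlap
#'
#' Upper-tail probability of observing an overlap at least as large as `k`
#' between sets of sizes `m` and `n` drawn from a universe of size `N`.
#'
#' @param k Observed overlap.
#' @param m,n Set sizes.
#' @param N Universe size.
#' @return One-sided p-value.
#' @export
hypergeom_overlap_p <- function(k, m, n, N) {
  if (m > N || n > N) stop("universe smaller than a set")
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Pearson chi-squared without continuity correction by default, df = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param correct Apply Yates continuity correction.
#' @return List with `statistic` and `p`.
#' @export
chi2_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Read / write gene sets in GMT format
#'
#' @param path File path.
#' @return `read_gmt` returns a named list of gene identifier vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of gene identifier vectors.
#' @param descriptions Optional second-column descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
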