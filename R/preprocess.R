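#' Counts per million
#'
#' @param counts Count matrix (features x samples).
#' @param lib_sizes Library sizes; default column sums.
#' @param log If `TRUE`, return log2-CPM with `prior_count` added to counts
#'   (and 1 to library sizes) to keep values finite.
#' @param prior_count Prior count for the log transform.
#' @return Matrix of (log2-)CPM values.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts), log = FALSE,
                prior_count = 0.5) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (log)
    log2(t(t(counts + prior_count) / (lib_sizes + 1)) * 1e6)
  else
    t(t(counts) / lib_sizes) * 1e6
}

#' Filter low-count features
#'
#' Keeps features with CPM strictly above `cpm_min` in at least `min_samples`
#' samples; feature order is preserved.
#'
#' @param exp A [count_experiment()].
#' @param cpm_min CPM threshold (strict).
#' @param min_samples Minimum number of samples passing.
#' @return Filtered [count_experiment()].
#' @export
filter_low_counts <- function(exp, cpm_min = 1, min_samples = 3) {
  x <- cpm(exp$counts)
  keep <- rowSums(x > cpm_min) >= min_samples
  if (!any(keep))
    stop(sprintf("all features removed by CPM > %g in >= %d samples",
                 cpm_min, min_samples))
  subset_experiment(exp, features = which(keep))
}

#' Collapse features sharing a target identifier
#'
#' When several source features map to one target identifier, the source row
#' with the largest inter-quartile range of log2-CPM across samples is kept
#' (ties broken by the lexicographically smallest source identifier, for
#' determinism), and the kept row is renamed to the target identifier.
#'
#' @param exp A [count_experiment()].
#' @param id_map Data frame with columns `source`, `target` (many-to-one), or
#'   a named character vector `target` names = source ids. Sources absent from
#'   the map are dropped; an empty map returns the input with a warning.
#' @return Collapsed [count_experiment()].
#' @export
collapse_feature_ids <- function(exp, id_map) {
  if (is.character(id_map) && !is.null(names(id_map)))
    id_map <- data.frame(source = names(id_map), target = unname(id_map))
  if (NROW(id_map) == 0) {
    warning("empty identifier map: returning experiment unchanged")
    return(exp)
  }
  stopifnot(all(c("source", "target") %in% names(id_map)))
  id_map <- id_map[id_map$source %in% rownames(exp$counts), , drop = FALSE]
  if (nrow(id_map) == 0) stop("no map source matches a feature identifier")
  lc <- cpm(exp$counts, log = TRUE)
  iqr <- apply(lc, 1, stats::IQR)
  id_map$iqr <- iqr[id_map$source]
  # best source per target: max IQR, ties -> smallest source id
  id_map <- id_map[order(id_map$target, -id_map$iqr, id_map$source), ]
  best <- id_map[!duplicated(id_map$target), ]
  counts <- exp$counts[best$source, , drop = FALSE]
  rownames(counts) <- best$target
  counts <- counts[order(match(best$source, rownames(exp$counts))), , drop = FALSE]
  count_experiment(counts, exp$samples)
}

#' TMM normalization to a normalized experiment
#'
#' Trimmed-mean-of-M-values scaling factors (computed against the sample
#' whose upper quartile is closest to the mean upper quartile), rescaled to
#' geometric mean 1; expression is reported as log2-CPM on effective library
#' sizes with a prior count of 0.5.
#'
#' @param exp A [count_experiment()].
#' @param trim_logratio,trim_abs Trim fractions for log-ratios and absolute
#'   intensities (the method's standard defaults).
#' @param prior_count Prior count for log2-CPM.
#' @return Object of class `normalized_experiment`: `logcpm`, `norm_factors`,
#'   `eff_lib_sizes`, `samples`, `sv` (surrogate variables, initially `NULL`),
#'   `qc` (initially `NULL`).
#' @export
tmm_normalize <- function(exp, trim_logratio = 0.3, trim_abs = 0.05,
                          prior_count = 0.5) {
  if (ncol(exp$counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(exp$counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(exp$counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(exp$counts, method = "TMM",
                              logratioTrim = trim_logratio,
                              sumTrim = trim_abs)
  eff <- lib * f
  structure(list(
    logcpm = cpm(exp$counts, lib_sizes = eff, log = TRUE,
                 prior_count = prior_count),
    norm_factors = stats::setNames(f, colnames(exp$counts)),
    eff_lib_sizes = stats::setNames(eff, colnames(exp$counts)),
    samples = exp$samples,
    counts = exp$counts,
    sv = NULL,
    qc = NULL
  ), class = "normalized_experiment")
}

#' @export
print.normalized_experiment <- function(x, ...) {
  cat(sprintf("normalized_experiment: %d features x %d samples, %d surrogate variable(s)\n",
              nrow(x$logcpm), ncol(x$logcpm), if (is.null(x$sv)) 0 else ncol(x$sv)))
  invisible(x)
}

#' Estimate surrogate variables from known-design residuals
#'
#' A deliberately simple surrogate-variable estimator: log2-CPM is residualized
#' against the known design, and the leading principal components of the
#' residual matrix are taken as surrogate variables. The dimension is chosen
#' by permutation parallel analysis: the k-th singular value must exceed the
#' `1 - alpha` quantile of its null distribution obtained by permuting each
#' feature's residuals across samples. Surrogate variables live in the
#' orthogonal complement of the design by construction.
#'
#' @param norm A `normalized_experiment`.
#' @param design Known-covariate model matrix (samples x p), including an
#'   intercept. Defaults to condition/timepoint group indicators.
#' @param k Number of surrogate variables, or `"auto"` for parallel analysis.
#' @param n_perm Number of permutations for `"auto"`.
#' @param alpha Per-component significance level for `"auto"`.
#' @param seed Seed for the permutations.
#' @return The `normalized_experiment` with `sv` set (samples x k matrix;
#'   zero columns if none found).
#' @export
estimate_surrogate_variables <- function(norm, design = NULL, k = "auto",
                                         n_perm = 100, alpha = 0.05, seed = 1) {
  if (is.null(design)) design <- default_design(norm$samples)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("design columns are linearly dependent")
  n <- nrow(design)
  resid_df <- n - qr_d$rank
  if (!identical(k, "auto") && k >= resid_df)
    stop("k must be below the residual degrees of freedom (", resid_df, ")")
  E <- qr.resid(qr_d, t(norm$logcpm))      # samples x features
  sv_all <- svd(E, nu = min(n, 20), nv = 0)
  if (identical(k, "auto")) {
    kmax <- min(resid_df - 1, 10)
    # variance proportions: re-residualizing the permuted matrix shrinks all
    # column norms by the same projection factor, which cancels in the
    # proportion, so observed and null statistics are comparable
    prop_of <- function(M) {
      d2 <- svd(M, nu = 0, nv = 0)$d^2
      d2[seq_len(kmax)] / sum(d2)
    }
    p_obs <- prop_of(E)
    null_p <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        prop_of(qr.resid(qr_d, apply(E, 2, sample)))
      }, numeric(kmax))
    })
    thr <- apply(matrix(null_p, nrow = kmax), 1, stats::quantile,
                 probs = 1 - alpha)
    k <- 0
    for (j in seq_len(kmax)) {
      if (p_obs[j] > thr[j]) k <- j else break
    }
  }
  sv <- if (k > 0) sv_all$u[, seq_len(k), drop = FALSE] else
    matrix(0, n, 0)
  if (k > 0) colnames(sv) <- paste0("SV", seq_len(k))
  rownames(sv) <- rownames(design) %||% colnames(norm$logcpm)
  norm$sv <- sv
  norm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default known design: intercept plus condition:timepoint group indicators.
default_design <- function(samples) {
  grp <- interaction(samples$condition,
                     ifelse(is.na(samples$dpi), samples$doa, samples$dpi),
                     drop = TRUE)
  mm <- stats::model.matrix(~grp)
  rownames(mm) <- samples$sample
  mm
}

#' Rule-based sample quality control
#'
#' Six computable per-sample criteria replace visual inspection:
#' (1) log10 library size z-score within +/-3; (2) detected-feature fraction
#' z-score within +/-3; (3) median Spearman correlation to same-group samples
#' >= 0.8 (singleton groups pass); (4) TMM factor within \[0.5, 2\];
#' (5) squared Mahalanobis leverage in the top-2 PC space below the 99th
#' percentile of a chi-squared(2) reference; (6) fraction of counts in the
#' 100 most abundant features z-score within +/-3. A sample is flagged iff it
#' fails at least 4 of the 6 criteria.
#'
#' @param exp A [count_experiment()].
#' @param fail_min Number of failed criteria that flags a sample.
#' @return Data frame per sample: metric values, pass/fail per criterion,
#'   `n_failed`, `flagged`.
#' @export
qc_flag_samples <- function(exp, fail_min = 4) {
  counts <- exp$counts
  n <- ncol(counts)
  lib <- colSums(counts)
  zsafe <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z_lib <- zsafe(log10(lib + 1))
  det_frac <- colMeans(counts > 0)
  z_det <- zsafe(det_frac)

  grp <- interaction(exp$samples$condition,
                     ifelse(is.na(exp$samples$dpi), exp$samples$doa,
                            exp$samples$dpi), drop = TRUE)
  lc <- cpm(counts, log = TRUE)
  med_cor <- vapply(seq_len(n), function(i) {
    mates <- setdiff(which(grp == grp[i]), i)
    if (!length(mates)) return(1)
    stats::median(vapply(mates, function(j)
      stats::cor(lc[, i], lc[, j], method = "spearman"), numeric(1)))
  }, numeric(1))

  f <- tryCatch(edgeR::calcNormFactors(counts, method = "TMM"),
                error = function(e) rep(NA_real_, n))

  pcs <- stats::prcomp(t(lc), center = TRUE, scale. = FALSE)
  kpc <- min(2, ncol(pcs$x))
  sc <- pcs$x[, seq_len(kpc), drop = FALSE]
  sdev <- pcs$sdev[seq_len(kpc)]
  lev <- if (all(sdev > 1e-12)) rowSums(sweep(sc, 2, sdev, "/")^2) else rep(0, n)

  top100 <- vapply(seq_len(n), function(i) {
    s <- sort(counts[, i], decreasing = TRUE)
    sum(s[seq_len(min(100, length(s)))]) / max(lib[i], 1)
  }, numeric(1))
  z_top <- zsafe(top100)

  pass <- cbind(
    lib_size = abs(z_lib) <= 3,
    detected = abs(z_det) <= 3,
    group_cor = med_cor >= 0.8,
    tmm_factor = !is.na(f) & f >= 0.5 & f <= 2,
    pca_leverage = lev <= stats::qchisq(0.99, df = kpc),
    top100_frac = abs(z_top) <= 3
  )
  n_failed <- rowSums(!pass)
  data.frame(sample = colnames(counts),
             log10_lib = log10(lib + 1), detected_frac = det_frac,
             median_group_spearman = med_cor, tmm_factor = f,
             pca_leverage = lev, top100_frac = top100,
             pass, n_failed = n_failed,
             flagged = n_failed >= fail_min, row.names = NULL)
}

#' Principal-component view of a normalized experiment
#'
#' PCA of centered (not scaled) log2-CPM over samples. Component signs are
#' fixed by making the largest-magnitude feature loading positive, so
#' coordinates are deterministic.
#'
#' @param norm A `normalized_experiment`.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x k), `explained` (variance
#'   fractions), and `loadings`.
#' @export
pca_view <- function(norm, n_components = 5) {
  if (ncol(norm$logcpm) < 3) stop("PCA view needs at least 3 samples")
  p <- stats::prcomp(t(norm$logcpm), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  tot <- sum(p$sdev^2)
  expl <- if (tot > 0) p$sdev[seq_len(k)]^2 / tot else rep(0, k)
  list(scores = scores, explained = expl, loadings = loadings)
}
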