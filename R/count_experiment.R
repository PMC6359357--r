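#' Construct a count experiment
#'
#' The pipeline's universal carrier: a non-negative integer count matrix
#' (features x samples) plus per-sample metadata. Conditions follow the
#' cryoinjury study design: `cryo` and `sham` samples carry a days-post-injury
#' (`dpi`) label, `healthy` samples a days-of-age (`doa`) label.
#'
#' @param counts Non-negative integer matrix, features in rows, samples in
#'   columns. Must have row and column names.
#' @param sample_meta Data frame with one row per sample (matched to columns of
#'   `counts` by the `sample` column) and columns `sample`, `condition`
#'   (one of `"cryo"`, `"sham"`, `"healthy"`), `dpi`, `doa`, `replicate`, and
#'   optionally `batch` and `assay` (`"mRNA"` or `"miRNA"`).
#' @return An object of class `count_experiment` with elements `counts` and
#'   `samples`.
#' @export
count_experiment <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature (row) and sample (column) names")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample names in counts")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature identifiers in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample", "condition", "replicate")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stop("sample_meta lacks columns: ", paste(miss, collapse = ", "))
  if (!all(colnames(counts) %in% sample_meta$sample))
    stop("every count column needs a sample_meta row")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- sample_meta$sample
  bad <- setdiff(unique(sample_meta$condition), c("cryo", "sham", "healthy"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (is.null(sample_meta$dpi)) sample_meta$dpi <- NA_real_
  if (is.null(sample_meta$doa)) sample_meta$doa <- NA_real_
  injured <- sample_meta$condition != "healthy"
  if (any(injured & is.na(sample_meta$dpi)))
    stop("cryo/sham samples must carry a dpi")
  if (any(!injured & !is.na(sample_meta$dpi)))
    stop("healthy samples must not carry a dpi")
  structure(list(counts = counts, samples = sample_meta),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("count_experiment: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$samples$condition)),
                                   table(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

#' Subset a count experiment by features and/or samples
#'
#' @param x A `count_experiment`.
#' @param features,samples Character vectors (or index vectors) selecting rows
#'   and columns; `NULL` keeps all.
#' @return A `count_experiment`.
#' @export
subset_experiment <- function(x, features = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  count_experiment(counts, x$samples[colnames(counts), , drop = FALSE])
}

#' Write / read a count experiment as TSV
#'
#' Counts go to `<prefix>_counts.tsv` (features x samples, first column
#' `feature_id`), metadata to `<prefix>_samples.tsv`.
#'
#' @param x A `count_experiment`.
#' @param prefix Path prefix for the two files.
#' @return `write_experiment_tsv` returns the two paths invisibly;
#'   `read_experiment_tsv` returns a `count_experiment`.
#' @export
write_experiment_tsv <- function(x, prefix) {
  cf <- paste0(prefix, "_counts.tsv")
  mf <- paste0(prefix, "_samples.tsv")
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cf, samples = mf))
}

#' @rdname write_experiment_tsv
#' @export
read_experiment_tsv <- function(prefix) {
  cf <- paste0(prefix, "_counts.tsv")
  mf <- paste0(prefix, "_samples.tsv")
  df <- utils::read.delim(cf, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature_id
  count_experiment(counts, utils::read.delim(mf))
}

#' Write a count experiment as MatrixMarket MTX with sidecar TSVs
#'
#' @param x A `count_experiment`.
#' @param prefix Path prefix; writes `<prefix>.mtx`, `<prefix>_features.tsv`
#'   and `<prefix>_samples.tsv`.
#' @return Paths, invisibly.
#' @export
write_experiment_mtx <- function(x, prefix) {
  mm <- paste0(prefix, ".mtx")
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), mm)
  utils::write.table(data.frame(feature_id = rownames(x$counts)),
                     paste0(prefix, "_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, paste0(prefix, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mm)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
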