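# Shared fixture builders; everything is generated in code at test time.

# A tiny hand-sized experiment with controllable counts and a standard
# cryo/sham/healthy layout (one sample per group unless widened).
toy_experiment <- function(counts) {
  n <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(n))
  cond <- rep(c("cryo", "sham", "healthy"), length.out = n)
  meta <- data.frame(
    sample = colnames(counts),
    condition = cond,
    dpi = ifelse(cond == "healthy", NA, 1),
    doa = ifelse(cond == "healthy", 300, NA),
    replicate = seq_len(n)
  )
  count_experiment(counts, meta)
}

# Experiment with explicit library sizes: a filler feature absorbs the
# remaining counts so column sums hit `lib` exactly.
experiment_with_libs <- function(feature_counts, lib = 1e6) {
  counts <- rbind(feature_counts,
                  filler = lib - colSums(feature_counts))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  toy_experiment(counts)
}

# Small default simulation for pipeline-level tests.
quick_sim <- function(seed = 1, n_genes = 400, n_mirnas = 60, ...) {
  simulate_experiment(simulation_config(seed = seed, n_genes = n_genes,
                                        n_mirnas = n_mirnas, ...))
}

# Independent brute-force BH step-up (straight from the definition).
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Independent hypergeometric upper tail by explicit term summation.
hyper_tail_brute <- function(k, m, n, N) {
  ks <- k:min(m, n)
  sum(exp(lchoose(m, ks) + lchoose(N - m, n - ks) - lchoose(N, n)))
}
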