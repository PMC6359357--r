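test_that("low-count filter applies the CPM rule per sample", {
  feats <- rbind(allzero = c(0, 0, 0, 0),
                 three = c(2, 2, 2, 0),
                 two = c(2, 2, 0, 0))
  exp <- experiment_with_libs(feats, lib = 1e6)
  # CPM of a count of 2 at depth 1e6 is exactly 2 > 1
  kept <- filter_low_counts(exp, cpm_min = 1, min_samples = 3)
  expect_true("three" %in% rownames(kept$counts))
  expect_false(any(c("allzero", "two") %in% rownames(kept$counts)))
  expect_error(filter_low_counts(exp, cpm_min = 1e9), "all features removed")
})

test_that("CPM is invariant to doubling every count and library size", {
  set.seed(1)
  counts <- matrix(rpois(60, 50), 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(cpm(counts), cpm(2L * counts))
})

test_that("feature collapse keeps the largest-IQR source, ties lexicographic", {
  set.seed(3)
  base <- rpois(6, 200)
  wide <- round(base * 2^c(-2, -1, 0, 0, 1, 2))   # large spread
  narrow <- round(base * 2^c(-0.1, 0, 0, 0, 0, 0.1))
  counts <- rbind(srcA = narrow, srcB = wide, other = rpois(6, 100))
  colnames(counts) <- paste0("s", 1:6)
  exp <- toy_experiment(counts)
  map <- data.frame(source = c("srcA", "srcB", "other"),
                    target = c("T1", "T1", "T2"))
  out <- collapse_feature_ids(exp, map)
  expect_identical(unname(out$counts["T1", ]), unname(wide))
  # one-to-one map renames only
  one <- collapse_feature_ids(exp, data.frame(source = rownames(counts),
                                              target = paste0("n_", rownames(counts))))
  expect_equal(unname(one$counts), unname(exp$counts))
  # exact tie: duplicate rows -> smaller source id wins
  tie <- toy_experiment(rbind(bbb = wide, aaa = wide))
  tied <- collapse_feature_ids(tie, data.frame(source = c("bbb", "aaa"),
                                               target = c("T", "T")))
  expect_identical(unname(tied$counts["T", ]), unname(tie$counts["aaa", ]))
  expect_warning(collapse_feature_ids(exp, data.frame(source = character(),
                                                      target = character())),
                 "empty")
})

test_that("TMM factors behave on identical, doubled and scaled columns", {
  set.seed(5)
  base <- rpois(50, 200) + 1
  same <- cbind(s1 = base, s2 = base, s3 = base)
  exp_same <- toy_experiment(same)
  norm <- tmm_normalize(exp_same)
  expect_equal(unname(norm$norm_factors), rep(1, 3), tolerance = 1e-8)
  # doubling a column changes depth, not composition: factor stays ~1
  doubled <- cbind(s1 = base, s2 = base, s3 = 2L * base)
  nd <- tmm_normalize(toy_experiment(doubled))
  expect_equal(unname(nd$norm_factors), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(nd$eff_lib_sizes["s3"] / nd$eff_lib_sizes["s1"]), 2,
               tolerance = 1e-6)
  # normalization contract: geometric mean of factors is 1
  set.seed(6)
  messy <- matrix(rnbinom(300, mu = 100, size = 5), 50,
                  dimnames = list(NULL, paste0("s", 1:6)))
  rownames(messy) <- paste0("g", 1:50)
  nm <- tmm_normalize(toy_experiment(messy))
  expect_equal(exp(mean(log(nm$norm_factors))), 1, tolerance = 1e-8)
  zero <- toy_experiment(cbind(s1 = base, s2 = 0L * base))
  expect_error(tmm_normalize(zero), "zero library")
})

test_that("surrogate variables recover a planted batch and stay orthogonal", {
  sim <- quick_sim(seed = 2, n_genes = 500, n_mirnas = 0, n_hubs = 0,
                   batch_sd_log2 = 1)
  norm <- tmm_normalize(filter_low_counts(sim$mrna))
  norm <- estimate_surrogate_variables(norm, seed = 1)
  expect_gte(ncol(norm$sv), 1)
  batch <- as.numeric(factor(norm$samples$batch))
  expect_gt(abs(cor(norm$sv[, 1], batch)), 0.8)
  # zero projection on the design
  design <- regenflow:::default_design(norm$samples)
  proj <- t(design) %*% norm$sv
  expect_lt(max(abs(proj)) / nrow(design), 1e-8)
})

test_that("automatic dimension choice returns zero on unstructured data", {
  set.seed(21)
  hits <- replicate(40, {
    lc <- matrix(rnorm(24 * 200), 24)
    norm <- structure(list(logcpm = t(lc),
                           samples = data.frame(sample = paste0("s", 1:24),
                                                condition = "healthy",
                                                dpi = NA, doa = 300,
                                                replicate = 1:24)),
                      class = "normalized_experiment")
    rownames(norm$samples) <- norm$samples$sample
    colnames(norm$logcpm) <- norm$samples$sample
    rownames(norm$logcpm) <- paste0("g", 1:200)
    des <- matrix(1, 24, 1, dimnames = list(norm$samples$sample, "(Intercept)"))
    sv <- estimate_surrogate_variables(norm, design = des, n_perm = 50,
                                       seed = 99)
    ncol(sv$sv) == 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("surrogate-variable estimation validates its inputs", {
  sim <- quick_sim(seed = 4, n_genes = 120, n_mirnas = 0, n_hubs = 0)
  norm <- tmm_normalize(filter_low_counts(sim$mrna))
  des <- regenflow:::default_design(norm$samples)
  expect_error(estimate_surrogate_variables(norm, design = cbind(des, des[, 2])),
               "linearly dependent")
  expect_error(estimate_surrogate_variables(norm, design = des, k = 1e3),
               "residual degrees of freedom")
})

test_that("sample QC flags only constructed failures and ignores order", {
  sim <- quick_sim(seed = 5, n_genes = 300, n_mirnas = 0, n_hubs = 0)
  qc <- qc_flag_samples(sim$mrna)
  expect_false(any(qc$flagged))
  # wreck one sample: 100x lower depth concentrated in a handful of features
  bad <- sim$mrna
  s <- 4
  wrecked <- integer(nrow(bad$counts))
  wrecked[1:5] <- as.integer(colSums(bad$counts)[s] / 500)
  bad$counts[, s] <- wrecked
  qc_bad <- qc_flag_samples(bad)
  expect_true(qc_bad$flagged[s])
  expect_gte(qc_bad$n_failed[s], 4)
  # permutation invariance
  perm <- sample(ncol(bad$counts))
  qc_perm <- qc_flag_samples(subset_experiment(bad, samples = perm))
  expect_identical(qc_perm$flagged[match(qc_bad$sample, qc_perm$sample)],
                   qc_bad$flagged)
})

test_that("PCA view is deterministic, bounded and separates planted groups", {
  sim <- quick_sim(seed = 6, n_genes = 300, n_mirnas = 0, n_hubs = 0)
  norm <- tmm_normalize(filter_low_counts(sim$mrna))
  pv <- pca_view(norm)
  expect_lte(sum(pv$explained), 1 + 1e-8)
  expect_identical(pv$scores, pca_view(norm)$scores)
  # identical samples: zero variance everywhere
  flat <- toy_experiment(matrix(50L, 20, 4,
                                dimnames = list(paste0("g", 1:20),
                                                paste0("s", 1:4))))
  pv0 <- pca_view(tmm_normalize(flat))
  expect_equal(unname(pv0$explained), rep(0, length(pv0$explained)))
  expect_error(
    pca_view(structure(list(logcpm = matrix(0, 5, 2)),
                       class = "normalized_experiment")), "3 samples")
  # a large planted two-group shift lands on PC1 with clean separation
  set.seed(8)
  counts <- matrix(rnbinom(200 * 12, mu = 100, size = 10), 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  counts[1:50, 7:12] <- counts[1:50, 7:12] * 8L
  pv2 <- pca_view(tmm_normalize(toy_experiment(counts)))
  grp <- rep(1:2, each = 6)
  x <- pv2$scores[, 1]
  sil <- vapply(1:12, function(i) {
    a <- mean(abs(x[i] - x[grp == grp[i]][-which(which(grp == grp[i]) == i)]))
    b <- mean(abs(x[i] - x[grp != grp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("filter, collapse and TMM commute with consistent permutations", {
  sim <- quick_sim(seed = 9, n_genes = 200, n_mirnas = 0, n_hubs = 0)
  exp <- sim$mrna
  fperm <- sample(nrow(exp$counts))
  sperm <- sample(ncol(exp$counts))
  permuted <- subset_experiment(exp, features = fperm, samples = sperm)
  a <- tmm_normalize(filter_low_counts(exp))
  b <- tmm_normalize(filter_low_counts(permuted))
  common <- intersect(rownames(a$logcpm), rownames(b$logcpm))
  expect_setequal(rownames(a$logcpm), rownames(b$logcpm))
  expect_equal(a$logcpm[common, colnames(b$logcpm)],
               b$logcpm[common, ], tolerance = 1e-10)
})
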