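test_that("the generator is deterministic given its seed", {
  cfg <- simulation_config(seed = 7, n_genes = 80, n_mirnas = 20,
                           n_hubs = 2, targets_per_hub = 5)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$mrna$counts, b$mrna$counts)
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(a$truth$gene_archetype, b$truth$gene_archetype)
  expect_identical(simulate_interaction_table(a$truth),
                   simulate_interaction_table(b$truth))
  expect_identical(simulate_location_ranks(a$truth),
                   simulate_location_ranks(b$truth))
  expect_identical(simulate_homology(a$truth), simulate_homology(b$truth))
})

test_that("the config rejects inconsistent designs", {
  expect_error(simulation_config(archetype_fractions = rep(0.3, 5)),
               "sum to")
  expect_error(simulation_config(timepoints_dpi = c(1, 4, 4)),
               "strictly increasing")
  expect_error(simulation_config(archetype_fractions = rep(0, 5), n_hubs = 2),
               "hubs")
  expect_error(simulation_config(n_replicates = 0), "positive")
})

test_that("zero effect sizes plant no true fold changes", {
  cfg <- simulation_config(seed = 3, n_genes = 100, n_mirnas = 0, n_hubs = 0,
                           effect_size_log2 = 0)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$trajectories == 0))
})

test_that("sham samples exist at 1 dpi only and healthy at each age", {
  sim <- quick_sim(seed = 2, n_genes = 50, n_mirnas = 10, n_hubs = 1,
                   targets_per_hub = 3)
  meta <- sim$mrna$samples
  expect_true(all(meta$dpi[meta$condition == "sham"] == 1))
  expect_setequal(unique(meta$doa[meta$condition == "healthy"]),
                  c(154, 302, 378, 463))
  # matched assays share sample names
  expect_identical(colnames(sim$mrna$counts), colnames(sim$mirna$counts))
})

test_that("per-gene sample means track the generative means (n = 200)", {
  cfg <- simulation_config(seed = 13, n_genes = 50, n_mirnas = 0, n_hubs = 0,
                           timepoints_dpi = c(4), n_replicates = 200,
                           healthy_ages_doa = 302)
  sim <- simulate_experiment(cfg)
  cryo <- sim$mrna$samples$sample[sim$mrna$samples$condition == "cryo"]
  obs <- rowMeans(sim$mrna$counts[, cryo])
  expected <- rowMeans(sim$truth$mu_mrna[, cryo])
  se <- apply(sim$mrna$counts[, cryo], 1, sd) / sqrt(length(cryo))
  expect_true(all(abs(obs - expected) <= 3 * se + 1e-9))
})

test_that("planted archetype fold changes are recovered on average", {
  # empirical log2FC of sustained-early-peak genes at their peak vs healthy
  # baseline, averaged over 50 seeds, against the generative mean of 2
  lfc <- vapply(1:50, function(s) {
    cfg <- simulation_config(seed = s, n_genes = 300, n_mirnas = 0, n_hubs = 0,
                             archetype_fractions = c(0, 0.1, 0, 0, 0),
                             timepoints_dpi = c(1, 4, 7),
                             batch_sd_log2 = 0)
    sim <- simulate_experiment(cfg)
    # TMM effective libraries: 10% planted up-regulation inflates raw
    # library sizes (composition bias), which plain CPM would fold into
    # every gene's fold change
    nrm <- tmm_normalize(sim$mrna)
    x <- cpm(sim$mrna$counts, lib_sizes = nrm$eff_lib_sizes)
    meta <- sim$mrna$samples
    a2 <- names(sim$truth$gene_archetype)[which(sim$truth$gene_archetype == 2)]
    peak <- rowMeans(x[a2, meta$sample[meta$condition == "cryo" & meta$dpi == 4],
                       drop = FALSE])
    base <- rowMeans(x[a2, meta$sample[meta$condition == "healthy"],
                       drop = FALSE])
    mean(log2(peak / base))
  }, numeric(1))
  expect_lt(abs(mean(lfc) - 2), 0.15)
})

test_that("interaction tables contain all planted pairs below the score cut", {
  sim <- quick_sim(seed = 4, n_genes = 200, n_mirnas = 40, n_hubs = 3,
                   targets_per_hub = 8)
  tab0 <- simulate_interaction_table(sim$truth, n_decoys = 0)
  expect_equal(nrow(tab0), sum(lengths(sim$truth$hub_targets)))
  expect_true(all(tab0$context_score < -0.2))
  # decoys straddling the threshold: the survivor fraction matches the
  # uniform mass below -0.2 on (-0.5, 0), i.e. 0.6
  tab <- simulate_interaction_table(sim$truth, n_decoys = 4000)
  dec <- tab[!tab$planted, ]
  frac <- mean(dec$context_score < -0.2)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(dec)))
  # with all decoys above the cut, context filtering leaves truth only
  hi <- tab
  hi$context_score[!hi$planted] <- runif(sum(!hi$planted), -0.19, 0)
  kept <- suppressMessages(filter_context(hi))
  expect_true(all(kept$planted))
})

test_that("location ranks favour the enriched archetype as the odds dictate", {
  sim <- quick_sim(seed = 5, n_genes = 1000, n_mirnas = 0, n_hubs = 0,
                   archetype_fractions = c(0, 0.1, 0, 0, 0))
  a2 <- names(sim$truth$gene_archetype)[which(sim$truth$gene_archetype == 2)]
  # odds 1: uniform everywhere
  r1 <- simulate_location_ranks(sim$truth, enrichment_odds = 1)
  inj <- r1[r1$location == "injury", ]
  mean_rank <- mean(inj$rank[inj$gene %in% a2])
  expect_lt(abs(mean_rank - (1000 + 1) / 2),
            3 * (1000 / sqrt(12)) / sqrt(length(a2)))
  # odds -> infinity: archetype genes occupy the top of the enriched list
  rInf <- simulate_location_ranks(sim$truth, enrichment_odds = 1e9)
  injInf <- rInf[rInf$location == "injury", ]
  expect_setequal(injInf$gene[injInf$rank <= length(a2)], a2)
  # odds 9: expected top-20% occupancy from an independent Gumbel-race
  # Monte-Carlo oracle of the same weighted-order scheme
  set.seed(99)
  n <- 1000; k <- length(a2)
  mc <- replicate(1e4, {
    score <- rexp(n) / c(rep(9, k), rep(1, n - k))
    mean(rank(score)[1:k] <= 200)
  })
  obs <- vapply(1:30, function(s) {
    r <- simulate_location_ranks(sim$truth, enrichment_odds = 9, seed = 1000 + s)
    ri <- r[r$location == "injury", ]
    mean(ri$rank[ri$gene %in% a2] <= 200)
  }, numeric(1))
  se <- sqrt(var(mc) / length(obs) + var(obs) / length(obs))
  expect_lt(abs(mean(obs) - mean(mc)), 4 * se)
})

test_that("planted gene sets are maximally enriched, random sets are not", {
  sim <- quick_sim(seed = 6, n_genes = 1500, n_mirnas = 0, n_hubs = 0)
  gs <- simulate_genesets(sim$truth, n_random = 200)
  a2 <- names(sim$truth$gene_archetype)[which(sim$truth$gene_archetype == 2)]
  res <- fisher_enrichment(a2, gs$sets, sim$truth$genes)
  expect_lt(res$p[res$set == "planted_archetype2"], 1e-20)
  # random sets against a random query: valid (conservative) p-values
  set.seed(31)
  query <- sample(sim$truth$genes, 150)
  rand <- res <- fisher_enrichment(query,
                                   gs$sets[!gs$planted], sim$truth$genes)
  grid <- seq(0.05, 0.95, by = 0.05)
  emp <- vapply(grid, function(x) mean(rand$p <= x), numeric(1))
  expect_true(all(emp <= grid + 3 * sqrt(grid * (1 - grid) / nrow(rand))))
})

test_that("homology and differentiation series carry the conserved program", {
  sim <- quick_sim(seed = 8, n_genes = 300, n_mirnas = 40, n_hubs = 2,
                   targets_per_hub = 10)
  hom <- simulate_homology(sim$truth)
  a2 <- names(sim$truth$gene_archetype)[which(sim$truth$gene_archetype == 2)]
  expect_setequal(unique(hom$gene_a[hom$conserved]), a2)
  expect_false(any(hom$gene_a == hom$gene_b))
  series <- simulate_differentiation_series(sim$truth, hom)
  expect_setequal(unique(series$mrna$samples$stage),
                  c("undiff", "d0", "d2", "d5"))
  # conserved genes decline by ~2 log2 units at the final stage
  lc <- cpm(series$mrna$counts)
  st <- series$mrna$samples$stage
  drop <- log2(rowMeans(lc[series$conserved_genes, st == "d5"]) /
                 rowMeans(lc[series$conserved_genes, st == "undiff"]))
  expect_lt(abs(mean(drop) + 2), 0.3)
})
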