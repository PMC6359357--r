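test_that("beta calibration solves the two printed anchors in closed form", {
  sched <- control_schedule()
  expect_equal(sched$beta, log(20) / 159, tolerance = 1e-12)
  expect_equal(sched$beta, 0.0188411, tolerance = 1e-6)
  # w_late = 1/e over a span of 100 days gives beta = 0.01 exactly
  s2 <- control_schedule(t_anchor_early = 0, t_anchor_late = 100,
                         w_late = exp(-1))
  expect_equal(s2$beta, 0.01, tolerance = 1e-12)
  # direct evaluation of the closed form at an off-grid time
  expect_equal(sched$w_sham(80.5), exp(-sched$beta * 79.5), tolerance = 1e-12)
  expect_equal(sched$w_sham(80.5), 0.05^(79.5 / 159), tolerance = 1e-12)
  expect_error(control_schedule(w_late = 0), "strictly between")
  expect_error(control_schedule(w_late = 1.2), "strictly between")
})

test_that("beta decreases as the late sham weight increases", {
  set.seed(17)
  for (i in 1:25) {
    early <- runif(1, 0, 5)
    late <- early + runif(1, 10, 300)
    w <- sort(runif(2, 0.001, 0.999))
    b_low <- control_schedule(t_anchor_early = early, t_anchor_late = late,
                              w_late = w[1])$beta
    b_high <- control_schedule(t_anchor_early = early, t_anchor_late = late,
                               w_late = w[2])$beta
    expect_gt(b_low, b_high)
    # monotone decay of the sham weight itself
    ts <- sort(runif(5, early, late * 2))
    sch <- control_schedule(t_anchor_early = early, t_anchor_late = late,
                            w_late = w[1])
    expect_true(all(diff(sch$w_sham(ts)) <= 0))
    expect_equal(sch$w_sham(early), 1)
  }
})

test_that("control weights implement the sham/healthy mixture exactly", {
  sched <- control_schedule()
  sham <- paste0("sh", 1:3)
  healthy <- paste0("he", 1:12)
  w1 <- control_weights(sched, 1, sham, healthy)
  expect_equal(unname(w1[sham]), rep(1 / 3, 3))
  expect_equal(unname(w1[healthy]), rep(0, 12))
  w160 <- control_weights(sched, 160, sham, healthy)
  expect_equal(sum(w160[sham]), 0.05, tolerance = 1e-12)
  expect_equal(sum(w160[healthy]), 0.95, tolerance = 1e-12)
  for (t in c(1, 4, 33.3, 160, 700))
    expect_equal(sum(control_weights(sched, t, sham, healthy)), 1)
  expect_error(control_weights(sched, 0.5, sham, healthy), "anchor")
  expect_error(control_weights(sched, 4, character(), healthy), "at least one")
})

test_that("dispersion estimation is calibrated on Poisson and NB data", {
  set.seed(23)
  n <- 12
  grp <- factor(rep(c("a", "b"), each = n / 2))
  mu <- exp(rnorm(1000, log(200), 1))
  pois <- t(vapply(mu, function(m) rpois(n, m), numeric(n)))
  rownames(pois) <- paste0("g", 1:1000)
  phi_pois <- estimate_dispersions(pois, grp)
  expect_lt(median(phi_pois), 0.02)
  nb <- t(vapply(mu, function(m) rnbinom(n, mu = m, size = 10), numeric(n)))
  rownames(nb) <- paste0("g", 1:1000)
  phi_nb <- estimate_dispersions(nb, grp)
  expect_gt(mean(phi_nb), 0.07)
  expect_lt(mean(phi_nb), 0.13)
  # infinite prior df collapses every gene onto the common value
  phi_inf <- estimate_dispersions(nb, grp, prior_df = 1e12)
  expect_lt(diff(range(phi_inf)), 1e-6)
})

test_that("healthy samples are inert at 1 dpi and sham inert at late times", {
  cfg <- simulation_config(seed = 31, n_genes = 250, n_mirnas = 0, n_hubs = 0,
                           timepoints_dpi = c(1, 740),
                           archetype_fractions = c(0, 0.08, 0, 0, 0))
  sim <- simulate_experiment(cfg)
  norm <- tmm_normalize(filter_low_counts(sim$mrna))
  norm$sv <- matrix(0, ncol(norm$logcpm), 0,
                    dimnames = list(colnames(norm$logcpm), NULL))
  sched <- control_schedule()
  scramble <- function(norm, cond) {
    out <- norm
    idx <- which(out$samples$condition == cond)
    set.seed(1)
    for (i in idx) out$counts[, i] <- sample(out$counts[, i])
    out
  }
  # at 1 dpi the healthy weight is exactly zero: scrambling healthy counts
  # cannot change anything (sham-only comparison)
  d1a <- test_timepoint(norm, sched, 1)
  d1b <- test_timepoint(scramble(norm, "healthy"), sched, 1)
  expect_equal(d1a$log2fc, d1b$log2fc, tolerance = 1e-12)
  expect_equal(d1a$p, d1b$p, tolerance = 1e-12)
  # far beyond the late anchor the sham weight is < 1e-6: effectively a
  # healthy-only comparison
  expect_lt(sched$w_sham(740), 1e-6)
  d2a <- test_timepoint(norm, sched, 740)
  d2b <- test_timepoint(scramble(norm, "sham"), sched, 740)
  expect_equal(d2a$log2fc, d2b$log2fc, tolerance = 1e-3)
  expect_equal(cor(d2a$p, d2b$p), 1, tolerance = 1e-6)
})

test_that("log2FC is antisymmetric under swapping injured and control labels", {
  cfg <- simulation_config(seed = 37, n_genes = 250, n_mirnas = 0, n_hubs = 0,
                           timepoints_dpi = c(1),
                           archetype_fractions = c(0, 0.08, 0, 0, 0))
  sim <- simulate_experiment(cfg)
  norm <- tmm_normalize(filter_low_counts(sim$mrna))
  norm$sv <- matrix(0, ncol(norm$logcpm), 0,
                    dimnames = list(colnames(norm$logcpm), NULL))
  sched <- control_schedule()
  fwd <- test_timepoint(norm, sched, 1)
  swapped <- norm
  cond <- swapped$samples$condition
  swapped$samples$condition[cond == "cryo"] <- "sham"
  swapped$samples$condition[cond == "sham"] <- "cryo"
  rev <- test_timepoint(swapped, sched, 1)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-6)
})

test_that("strong planted effects are detected with few false calls", {
  cfg <- simulation_config(seed = 41, n_genes = 400, n_mirnas = 0, n_hubs = 0,
                           archetype_fractions = c(0, 0.1, 0, 0, 0))
  sim <- simulate_experiment(cfg)
  norm <- tmm_normalize(filter_low_counts(sim$mrna))
  norm <- estimate_surrogate_variables(norm, seed = 41)
  de <- test_timepoint(norm, control_schedule(), 7)
  planted <- names(sim$truth$gene_archetype)[!is.na(sim$truth$gene_archetype)]
  called <- de$gene[de$deg]
  expect_gt(mean(intersect(planted, de$gene) %in% called), 0.6)
  if (length(called)) expect_lt(mean(!called %in% planted), 0.1)
  expect_true(all(de$fdr >= de$p, na.rm = TRUE))
  expect_error(test_timepoint(norm, control_schedule(), 999), "no cryo")
})

test_that("phase grouping recovers planted contiguous blocks", {
  set.seed(43)
  tps <- c(1, 4, 7, 14, 21, 30, 45, 60, 120)
  blocks <- list(1:3, 4:6, 7:9)
  genes <- paste0("g", 1:60)
  m <- matrix(0, 60, 9, dimnames = list(genes, tps))
  for (b in blocks) {
    z <- rnorm(60, sd = 2)
    m[, b] <- z + matrix(rnorm(60 * length(b), sd = 0.05), 60)
  }
  de <- data.frame(gene = rep(genes, 9), dpi = rep(tps, each = 60),
                   log2fc = as.vector(m))
  pc <- phase_cluster(de)
  expect_true(pc$contiguous)
  expect_equal(unname(pc$phases[as.character(tps)]), rep(1:3, each = 3))
  # invariant to gene order
  de2 <- de[sample(nrow(de)), ]
  expect_equal(phase_cluster(de2)$phases, pc$phases)
  # identical timepoints collapse at height zero
  de_same <- data.frame(gene = rep(genes, 9), dpi = rep(tps, each = 60),
                        log2fc = rep(rnorm(60, sd = 1), 9))
  pc0 <- phase_cluster(de_same)
  expect_true(all(pc0$hclust$height < 1e-12))
  # constant profile at one timepoint is an error
  de_bad <- de
  de_bad$log2fc[de_bad$dpi == 4] <- 1
  expect_error(phase_cluster(de_bad), "constant")
})
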