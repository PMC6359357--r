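#' Simulation configuration for the synthetic regeneration experiment
#'
#' Bundles and validates all knobs of the synthetic study. Defaults emulate
#' the cryoinjury time-course design: cryoinjured hearts sampled at ten
#' timepoints between 1 and 160 days post injury (dpi) in triplicate,
#' sham-operated controls at 1 dpi only, and healthy controls at four ages
#' (days of age, doa) to absorb age-related variance.
#'
#' @param seed Integer seed; all outputs are deterministic given it.
#' @param n_genes,n_mirnas Number of mRNA / miRNA features.
#' @param timepoints_dpi Strictly increasing integer dpi vector.
#' @param n_replicates Replicates per group.
#' @param healthy_ages_doa Ages of the healthy control groups.
#' @param archetype_fractions Length-5 vector: fraction of genes following
#'   each temporal archetype; the remainder are null genes. Must sum to <= 1.
#' @param effect_size_log2 Peak |log2FC| per archetype (recycled to length 5).
#' @param dispersion Negative-binomial dispersion phi (variance mu + phi mu^2).
#'   May be a single value or per-gene vector; 0 gives Poisson counts.
#' @param library_size_range Range of expected library sizes (uniform draw).
#' @param n_batches Number of technical batches, assigned round-robin.
#' @param batch_sd_log2 SD of the additive per-batch log2 offset.
#' @param n_hubs Number of planted hub miRNAs.
#' @param targets_per_hub Targets repressed by each hub.
#' @param repression_strength Scaling of the hub miRNA trajectory relative to
#'   the (negated) trajectory of its targets' archetype.
#' @param surgery_frac Fraction of genes carrying a surgery signature shared
#'   by sham fish and (exponentially decaying) by injured fish.
#' @param surgery_effect_log2 Magnitude of the surgery signature at 1 dpi.
#' @param drift_frac Fraction of genes with a linear age drift in healthy fish.
#' @param age_drift_log2_per_day Slope of that drift (log2 per day of age).
#' @param baseline_sd_log2 SD of log2 baseline abundance across features.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 2000,
                              n_mirnas = 300,
                              timepoints_dpi = c(1, 4, 7, 14, 21, 30, 45, 60, 120, 160),
                              n_replicates = 3,
                              healthy_ages_doa = c(154, 302, 378, 463),
                              archetype_fractions = rep(0.04, 5),
                              effect_size_log2 = 2,
                              dispersion = 0.1,
                              library_size_range = c(8e5, 1.2e6),
                              n_batches = 2,
                              batch_sd_log2 = 0.3,
                              n_hubs = 3,
                              targets_per_hub = 25,
                              repression_strength = 1,
                              surgery_frac = 0.05,
                              surgery_effect_log2 = 1,
                              drift_frac = 0.05,
                              age_drift_log2_per_day = 0.002,
                              baseline_sd_log2 = 1.5) {
  stopifnot(length(archetype_fractions) == 5)
  if (any(archetype_fractions < 0) || sum(archetype_fractions) > 1 + 1e-12)
    stop("archetype fractions must be non-negative and sum to <= 1")
  if (n_genes < 1 || n_mirnas < 0 || n_replicates < 1 || n_batches < 1)
    stop("all counts must be positive")
  if (any(diff(timepoints_dpi) <= 0))
    stop("timepoints_dpi must be strictly increasing")
  if (any(library_size_range <= 0) || diff(library_size_range) < 0)
    stop("invalid library_size_range")
  if (batch_sd_log2 < 0) stop("batch_sd_log2 must be non-negative")
  effect_size_log2 <- rep_len(effect_size_log2, 5)
  if (n_hubs > 0 && sum(archetype_fractions * effect_size_log2) == 0)
    stop("planted hubs need planted differentially expressed targets: ",
         "set archetype fractions/effects > 0 or n_hubs = 0")
  structure(as.list(environment()), class = "simulation_config")
}

# Piecewise-linear temporal archetype templates (unit peak height), knots in
# (dpi, log2FC) pairs. Shapes: 1 sharp early peak; 2 sustained early peak;
# 3 dip then late rise; 4 slow intermediate peak, still elevated late;
# 5 early dip returning to baseline.
archetype_knots <- list(
  a1 = cbind(c(1, 4, 21, 160),          c(0, 1, 0, 0)),
  a2 = cbind(c(1, 4, 7, 45, 160),       c(0, 1, 1, 0, 0)),
  a3 = cbind(c(1, 4, 7, 21, 160),       c(0, -1, -1, 0, 0.5)),
  a4 = cbind(c(1, 7, 21, 30, 160),      c(0, 0.3, 1, 1, 0.4)),
  a5 = cbind(c(1, 4, 7, 60, 160),       c(0, -1, -1, 0, 0))
)

#' Temporal archetype trajectories
#'
#' Evaluates the five piecewise-linear log2FC archetypes at the given
#' timepoints, scaled by per-archetype peak effects.
#'
#' @param timepoints_dpi Numeric dpi vector.
#' @param effect_size_log2 Peak |log2FC| per archetype (recycled to 5).
#' @return 5 x length(timepoints) matrix of log2 fold changes.
#' @export
archetype_trajectories <- function(timepoints_dpi, effect_size_log2 = 2) {
  effect_size_log2 <- rep_len(effect_size_log2, 5)
  vals <- vapply(seq_along(archetype_knots), function(k) {
    kn <- archetype_knots[[k]]
    effect_size_log2[k] *
      stats::approx(kn[, 1], kn[, 2], xout = timepoints_dpi, rule = 2)$y
  }, numeric(length(timepoints_dpi)))
  matrix(vals, nrow = 5, ncol = length(timepoints_dpi), byrow = TRUE)
}

nb_draw <- function(n, mu, phi) {
  if (length(phi) == 1 && phi <= 0) return(stats::rpois(n, mu))
  phi <- rep_len(phi, n)
  out <- integer(n)
  pois <- phi <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = 1 / phi[!pois])
  out
}

#' Simulate the full cryoinjury experiment with planted ground truth
#'
#' Draws matched mRNA and miRNA count experiments. Counts are negative
#' binomial with mean `lib_s * q_g * 2^(trajectory_g(t_s) + batch_s)`.
#' Planted structure: five temporal archetypes in the injured fish, a surgery
#' signature shared by sham fish and decaying exponentially in injured fish,
#' a linear age drift in healthy fish, and hub miRNAs whose trajectories are
#' the negated (scaled) trajectories of their target genes' archetype.
#'
#' @param config A [simulation_config()].
#' @return List with elements `mrna` and `mirna` (both [count_experiment()]s
#'   sharing sample names) and `truth`, a list holding the planted
#'   gene-to-archetype map, true log2FC trajectories, hub target sets, the
#'   location enrichment plan, and the gene subsets used for the surgery and
#'   age-drift signals. `truth` is a test oracle only; the pipeline never
#'   reads it.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
    mirnas <- if (cfg$n_mirnas > 0) sprintf("mir%04d", seq_len(cfg$n_mirnas)) else character()
    tps <- cfg$timepoints_dpi

    # sample sheet: cryo at every timepoint, sham at 1 dpi, healthy per age
    # replicate varies fastest so round-robin batches vary within every
    # condition-timepoint group instead of confounding with it
    meta <- rbind(
      expand.grid(condition = "cryo", replicate = seq_len(cfg$n_replicates),
                  t = tps, stringsAsFactors = FALSE),
      expand.grid(condition = "sham", replicate = seq_len(cfg$n_replicates),
                  t = 1, stringsAsFactors = FALSE),
      expand.grid(condition = "healthy", replicate = seq_len(cfg$n_replicates),
                  t = cfg$healthy_ages_doa, stringsAsFactors = FALSE)
    )
    meta$dpi <- ifelse(meta$condition == "healthy", NA, meta$t)
    meta$doa <- ifelse(meta$condition == "healthy", meta$t, NA)
    meta$sample <- ifelse(meta$condition == "healthy",
                          sprintf("healthy_a%d_r%d", meta$t, meta$replicate),
                          sprintf("%s_d%d_r%d", meta$condition, meta$t, meta$replicate))
    meta$batch <- sprintf("b%d", (seq_len(nrow(meta)) - 1) %% cfg$n_batches + 1)
    meta <- meta[, c("sample", "condition", "dpi", "doa", "replicate", "batch")]
    n_samp <- nrow(meta)

    # gene roles: archetypes, then surgery / drift signatures from the rest
    n_arch <- round(cfg$archetype_fractions * cfg$n_genes)
    arch <- rep(NA_integer_, cfg$n_genes)
    pool <- sample.int(cfg$n_genes)
    at <- 0
    for (k in 1:5) {
      if (n_arch[k] > 0) arch[pool[at + seq_len(n_arch[k])]] <- k
      at <- at + n_arch[k]
    }
    rest <- pool[-seq_len(at)]
    n_surg <- min(round(cfg$surgery_frac * cfg$n_genes), length(rest))
    surgery_genes <- genes[rest[seq_len(n_surg)]]
    rest <- rest[-seq_len(max(n_surg, 0))]
    n_drift <- min(round(cfg$drift_frac * cfg$n_genes), length(rest))
    drift_genes <- genes[rest[seq_len(n_drift)]]
    names(arch) <- genes

    templ <- archetype_trajectories(tps, cfg$effect_size_log2)
    traj <- matrix(0, cfg$n_genes, length(tps), dimnames = list(genes, paste0("dpi", tps)))
    ok <- !is.na(arch)
    traj[ok, ] <- templ[arch[ok], , drop = FALSE]

    beta_true <- log(20) / 159   # surgery recovery rate assumed by the design
    surg_sign <- sample(c(-1, 1), n_surg, replace = TRUE) * cfg$surgery_effect_log2
    names(surg_sign) <- surgery_genes
    drift_slope <- sample(c(-1, 1), n_drift, replace = TRUE) * cfg$age_drift_log2_per_day
    names(drift_slope) <- drift_genes

    # per-sample log2 offsets (genes x samples)
    delta <- matrix(0, cfg$n_genes, n_samp, dimnames = list(genes, meta$sample))
    for (s in seq_len(n_samp)) {
      cond <- meta$condition[s]
      if (cond == "cryo") {
        ti <- match(meta$dpi[s], tps)
        delta[, s] <- traj[, ti]
        delta[surgery_genes, s] <- delta[surgery_genes, s] +
          surg_sign * exp(-beta_true * (meta$dpi[s] - 1))
      } else if (cond == "sham") {
        delta[surgery_genes, s] <- surg_sign
      } else {
        delta[drift_genes, s] <- drift_slope *
          (meta$doa[s] - mean(cfg$healthy_ages_doa))
      }
    }

    # gene-specific batch signatures (a uniform offset would be confounded
    # with library size and vanish under CPM), centered across batches
    batch_off <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches, 0,
                                     cfg$batch_sd_log2),
                        cfg$n_genes, cfg$n_batches,
                        dimnames = list(genes, sprintf("b%d", seq_len(cfg$n_batches))))
    batch_off <- batch_off - rowMeans(batch_off)

    q <- 2^stats::rnorm(cfg$n_genes, 0, cfg$baseline_sd_log2)
    q <- q / sum(q)
    libs <- stats::runif(n_samp, cfg$library_size_range[1], cfg$library_size_range[2])

    counts <- matrix(0L, cfg$n_genes, n_samp, dimnames = list(genes, meta$sample))
    mu_mrna <- matrix(0, cfg$n_genes, n_samp, dimnames = list(genes, meta$sample))
    for (s in seq_len(n_samp)) {
      mu <- libs[s] * q * 2^(delta[, s] + batch_off[, meta$batch[s]])
      mu_mrna[, s] <- mu
      counts[, s] <- nb_draw(cfg$n_genes, mu, cfg$dispersion)
    }
    meta_m <- meta; meta_m$assay <- "mRNA"
    mrna <- count_experiment(counts, meta_m)

    # miRNAs: hubs mirror (negated) their target archetype's trajectory
    hub_targets <- list(); mirna_arch <- integer(0); mirna <- NULL
    if (cfg$n_mirnas > 0) {
      arch_with_genes <- which(n_arch > 0 & cfg$effect_size_log2 > 0)
      hubs <- if (cfg$n_hubs > 0) sample(mirnas, cfg$n_hubs) else character()
      mtraj <- matrix(0, cfg$n_mirnas, length(tps), dimnames = list(mirnas, paste0("dpi", tps)))
      mirna_arch <- stats::setNames(rep(NA_integer_, cfg$n_mirnas), mirnas)
      for (h in seq_along(hubs)) {
        k <- arch_with_genes[(h - 1) %% length(arch_with_genes) + 1]
        gk <- genes[which(arch == k)]
        hub_targets[[hubs[h]]] <- sort(sample(gk, min(cfg$targets_per_hub, length(gk))))
        mirna_arch[hubs[h]] <- k
        mtraj[hubs[h], ] <- -cfg$repression_strength * templ[k, ]
      }
      qm <- 2^stats::rnorm(cfg$n_mirnas, 0, cfg$baseline_sd_log2)
      qm <- qm / sum(qm)
      mbatch_off <- matrix(stats::rnorm(cfg$n_mirnas * cfg$n_batches, 0,
                                        cfg$batch_sd_log2),
                           cfg$n_mirnas, cfg$n_batches)
      mbatch_off <- mbatch_off - rowMeans(mbatch_off)
      libs_m <- stats::runif(n_samp, cfg$library_size_range[1], cfg$library_size_range[2])
      mcounts <- matrix(0L, cfg$n_mirnas, n_samp, dimnames = list(mirnas, meta$sample))
      for (s in seq_len(n_samp)) {
        d <- if (meta$condition[s] == "cryo") mtraj[, match(meta$dpi[s], tps)] else 0
        bi <- match(meta$batch[s], sprintf("b%d", seq_len(cfg$n_batches)))
        mu <- libs_m[s] * qm * 2^(d + mbatch_off[, bi])
        mcounts[, s] <- nb_draw(cfg$n_mirnas, mu, cfg$dispersion)
      }
      meta_mi <- meta; meta_mi$assay <- "miRNA"
      mirna <- count_experiment(mcounts, meta_mi)
    }

    truth <- list(
      seed = cfg$seed,
      gene_archetype = arch,
      trajectories = traj,
      hub_targets = hub_targets,
      mirna_archetype = mirna_arch,
      location_enriched = c(injury = 2L, border = NA_integer_, myocardium = 3L),
      surgery_genes = surgery_genes,
      drift_genes = drift_genes,
      mu_mrna = mu_mrna,
      timepoints_dpi = tps,
      genes = genes,
      mirnas = mirnas
    )
    list(mrna = mrna, mirna = mirna, truth = truth)
  })
}

#' Simulate a predicted miRNA-target interaction table
#'
#' Emulates a sequence-based target prediction: every planted hub-target pair
#' is present with a context score below -0.2 (more negative = stronger
#' predicted repression); decoy pairs are drawn uniformly with context scores
#' spanning the given range. The `planted` flag is a test oracle and is never
#' used by the pipeline.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param n_decoys Number of decoy rows.
#' @param context_score_range Range of decoy context scores.
#' @param seed Seed (defaults to a stream derived from the truth's seed).
#' @return Data frame with columns `mirna_id`, `gene_id`, `context_score`,
#'   `planted`.
#' @export
simulate_interaction_table <- function(truth, n_decoys = 2000,
                                       context_score_range = c(-0.5, 0),
                                       seed = truth$seed + 101L) {
  with_local_seed(seed, {
    true_rows <- do.call(rbind, lapply(names(truth$hub_targets), function(h) {
      tg <- truth$hub_targets[[h]]
      data.frame(mirna_id = h, gene_id = tg,
                 context_score = stats::runif(length(tg), -0.6, -0.2000001),
                 planted = TRUE)
    }))
    if (is.null(true_rows))
      true_rows <- data.frame(mirna_id = character(), gene_id = character(),
                              context_score = numeric(), planted = logical())
    decoys <- NULL
    if (n_decoys > 0) {
      decoys <- data.frame(
        mirna_id = sample(truth$mirnas, n_decoys, replace = TRUE),
        gene_id = sample(truth$genes, n_decoys, replace = TRUE),
        context_score = stats::runif(n_decoys, context_score_range[1],
                                     context_score_range[2]),
        planted = FALSE)
    }
    tab <- rbind(true_rows, decoys)
    # one row per (miRNA, gene): planted rows win, then first occurrence
    tab <- tab[order(!tab$planted), ]
    tab <- tab[!duplicated(tab[, c("mirna_id", "gene_id")]), ]
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate ranked spatial expression profiles per heart location
#'
#' For each location flagged in `truth$location_enriched`, genes of the
#' enriched archetype receive systematically better ranks through
#' Plackett-Luce sampling with the given odds; other locations rank genes
#' uniformly at random. Rank 1 = highest absolute expression.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param locations Location names; must match names of
#'   `truth$location_enriched` (extra names get uniform ranks).
#' @param enrichment_odds Odds multiplier for enriched-archetype genes
#'   (1 = uniform).
#' @param seed Seed.
#' @return Data frame with columns `location`, `gene`, `rank`.
#' @export
simulate_location_ranks <- function(truth,
                                    locations = c("injury", "border", "myocardium"),
                                    enrichment_odds = 9,
                                    seed = truth$seed + 202L) {
  if (anyDuplicated(truth$genes)) stop("duplicate gene identifiers")
  if (enrichment_odds <= 0) stop("enrichment_odds must be positive")
  with_local_seed(seed, {
    out <- lapply(locations, function(loc) {
      k <- truth$location_enriched[loc]
      w <- rep(1, length(truth$genes))
      if (!is.na(k) && any(truth$gene_archetype == k, na.rm = TRUE))
        w[which(truth$gene_archetype == k)] <- enrichment_odds
      ord <- sample(truth$genes, prob = w)
      data.frame(location = loc, gene = ord, rank = seq_along(ord))
    })
    do.call(rbind, out)
  })
}

#' Simulate a gene-set collection with planted enrichment
#'
#' One planted set per non-empty archetype (exactly that archetype's genes)
#' plus random decoy sets drawn uniformly from the gene universe.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param n_random Number of random decoy sets.
#' @param size_range Size range of decoy sets.
#' @param seed Seed.
#' @return List with `sets` (named list of gene vectors) and `planted`
#'   (named logical flags).
#' @export
simulate_genesets <- function(truth, n_random = 50, size_range = c(10, 60),
                              seed = truth$seed + 303L) {
  with_local_seed(seed, {
    sets <- list()
    for (k in 1:5) {
      gk <- truth$genes[which(truth$gene_archetype == k)]
      if (length(gk) >= 2) sets[[sprintf("planted_archetype%d", k)]] <- gk
    }
    planted <- rep(TRUE, length(sets))
    for (i in seq_len(n_random)) {
      sz <- sample(size_range[1]:size_range[2], 1)
      sets[[sprintf("random_set%03d", i)]] <- sort(sample(truth$genes, sz))
      planted <- c(planted, FALSE)
    }
    names(planted) <- names(sets)
    list(sets = sets, planted = planted)
  })
}

#' Simulate a cross-species homologue map
#'
#' Maps every gene one-to-one to a second-species identifier (a small
#' fraction receives an extra paralogue to exercise many-to-many handling);
#' homologues of the chosen archetype are flagged as the conserved program.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param conserved_archetype Archetype whose homologues form the conserved
#'   proliferation program (default 2, the sustained early-peak group).
#' @param prefix Identifier prefix for the second species.
#' @param paralog_frac Fraction of genes given a second homologue.
#' @param seed Seed.
#' @return Data frame `gene_a` (zebrafish), `gene_b` (other species),
#'   `conserved` flag (test oracle).
#' @export
simulate_homology <- function(truth, conserved_archetype = 2L, prefix = "rn",
                              paralog_frac = 0.02, seed = truth$seed + 404L) {
  with_local_seed(seed, {
    map <- data.frame(gene_a = truth$genes,
                      gene_b = paste0(prefix, "_", truth$genes),
                      conserved = !is.na(truth$gene_archetype) &
                        truth$gene_archetype == conserved_archetype)
    extra <- truth$genes[stats::runif(length(truth$genes)) < paralog_frac]
    if (length(extra))
      map <- rbind(map, data.frame(gene_a = extra,
                                   gene_b = paste0(prefix, "_", extra, "_p2"),
                                   conserved = FALSE))
    rownames(map) <- NULL
    map
  })
}

#' Simulate a myoblast differentiation series in the second species
#'
#' Emulates a proliferating-to-differentiated cell-line time course
#' (stages undiff, d0, d2, d5 in triplicate): genes of the conserved program
#' decline linearly in log2 to `down_log2fc` at the last stage; conserved hub
#' miRNAs rise by the mirrored amount; everything else is flat.
#'
#' @param truth Ground truth from [simulate_experiment()].
#' @param homology Map from [simulate_homology()].
#' @param stages Ordered stage labels.
#' @param n_replicates Replicates per stage.
#' @param down_log2fc Log2FC of conserved genes at the final stage vs first.
#' @param dispersion,library_size_range Count-model parameters.
#' @param seed Seed.
#' @return List with `mrna` and `mirna` [count_experiment()]s carrying a
#'   `stage` metadata column, plus `conserved_genes` / `conserved_mirnas`
#'   oracles.
#' @export
simulate_differentiation_series <- function(truth, homology,
                                            stages = c("undiff", "d0", "d2", "d5"),
                                            n_replicates = 3,
                                            down_log2fc = -2,
                                            dispersion = 0.05,
                                            library_size_range = c(8e5, 1.2e6),
                                            seed = truth$seed + 505L) {
  with_local_seed(seed, {
    genes_b <- unique(homology$gene_b)
    conserved_b <- unique(homology$gene_b[homology$conserved])
    cons_arch <- unique(truth$mirna_archetype[names(truth$hub_targets)])
    conserved_mirnas <- names(truth$mirna_archetype)[
      !is.na(truth$mirna_archetype) &
        truth$mirna_archetype %in% truth$gene_archetype[homology$gene_a[homology$conserved]]]
    frac <- seq(0, 1, length.out = length(stages))

    make_series <- function(feats, up_feats, sign_fc, assay) {
      meta <- expand.grid(stage = stages, replicate = seq_len(n_replicates),
                          stringsAsFactors = FALSE)
      meta$sample <- sprintf("%s_%s_r%d", assay, meta$stage, meta$replicate)
      meta$condition <- "healthy"; meta$dpi <- NA; meta$doa <- NA
      meta$assay <- assay
      q <- 2^stats::rnorm(length(feats), 0, 1.5); q <- q / sum(q)
      names(q) <- feats
      counts <- matrix(0L, length(feats), nrow(meta),
                       dimnames = list(feats, meta$sample))
      libs <- stats::runif(nrow(meta), library_size_range[1], library_size_range[2])
      for (s in seq_len(nrow(meta))) {
        d <- rep(0, length(feats)); names(d) <- feats
        d[up_feats] <- sign_fc * frac[match(meta$stage[s], stages)]
        counts[, s] <- nb_draw(length(feats), libs[s] * q * 2^d, dispersion)
      }
      count_experiment(counts, meta)
    }
    mrna <- make_series(genes_b, conserved_b, down_log2fc, "mRNA")
    mirna <- if (length(truth$mirnas))
      make_series(truth$mirnas, conserved_mirnas, -down_log2fc, "miRNA")
    else NULL
    list(mrna = mrna, mirna = mirna,
         conserved_genes = conserved_b, conserved_mirnas = conserved_mirnas,
         stages = stages)
  })
}
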