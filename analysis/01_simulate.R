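#!/usr/bin/env Rscript
# Generate the synthetic cryoinjury study: matched mRNA/miRNA counts,
# predicted interactions, location rank profiles, gene sets, homologue map
# and the rat differentiation series. Writes everything (plus the planted
# truth, which no later step reads) under results/data/.

library(regenflow)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1)
sim <- simulate_experiment(cfg)
cat(sprintf("simulated %d genes x %d samples (mRNA), %d miRNAs\n",
            nrow(sim$mrna$counts), ncol(sim$mrna$counts),
            nrow(sim$mirna$counts)))

write_experiment_tsv(sim$mrna, file.path(out, "mrna"))
write_experiment_mtx(sim$mrna, file.path(out, "mrna"))
write_experiment_tsv(sim$mirna, file.path(out, "mirna"))

interactions <- simulate_interaction_table(sim$truth)
write.table(interactions[, c("mirna_id", "gene_id", "context_score")],
            file.path(out, "interactions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ranks <- simulate_location_ranks(sim$truth)
write.table(ranks, file.path(out, "location_ranks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

gs <- simulate_genesets(sim$truth)
write_gmt(gs$sets, file.path(out, "genesets.gmt"))

hom <- simulate_homology(sim$truth)
write.table(hom[, c("gene_a", "gene_b")], file.path(out, "homology.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

series <- simulate_differentiation_series(sim$truth, hom)
write_experiment_tsv(series$mrna, file.path(out, "h9c2_mrna"))
write_experiment_tsv(series$mirna, file.path(out, "h9c2_mirna"))

# planted truth: test oracle only, never read by the pipeline steps
truth_tab <- data.frame(gene = names(sim$truth$gene_archetype),
                        archetype = sim$truth$gene_archetype)
write.table(truth_tab, file.path(out, "truth_gene_archetype.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
hub_tab <- do.call(rbind, lapply(names(sim$truth$hub_targets), function(h)
  data.frame(mirna = h, target = sim$truth$hub_targets[[h]])))
write.table(hub_tab, file.path(out, "truth_hub_targets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("inputs written to", out, "\n")
cat(sprintf("planted: %d archetype genes, %d hub miRNAs, %d predicted pairs\n",
            sum(!is.na(sim$truth$gene_archetype)),
            length(sim$truth$hub_targets), nrow(interactions)))
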