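#!/usr/bin/env Rscript
# Cross-species validation: are the genes that shut down during rat myoblast
# differentiation the homologues of the zebrafish proliferation cluster?

library(regenflow)

out <- "results"
dat <- "results/data"

series_m <- read_experiment_tsv(file.path(dat, "h9c2_mrna"))
series_mi <- read_experiment_tsv(file.path(dat, "h9c2_mirna"))
hom <- read.delim(file.path(dat, "homology.tsv"))
mem <- read.delim(file.path(out, "cluster_membership.tsv"))
assign <- structure(list(membership = as.matrix(mem[, grep("^cluster", names(mem))]),
                         hard = setNames(mem$hard, mem$gene),
                         membership_min = 0.7),
                    class = "cluster_assignment")
rownames(assign$membership) <- mem$gene

ct <- contrast_stage(series_m)
cat(sprintf("d5 vs undiff: %d down-, %d up-regulated genes (FDR < 0.01, |log2FC| > 1)\n",
            length(ct$down), length(ct$up)))

res <- association_with_cluster(ct$down, assign, hom)
cat("association of down-regulated rat genes with zebrafish cluster 2:\n")
print(res$table)
cat(sprintf("chi-squared = %.1f, p = %.3g\n", res$statistic, res$p))
write.table(data.frame(statistic = res$statistic, p = res$p),
            file.path(out, "cross_species_association.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# stage-averaged anti-correlation screen restricted to cluster-2 homologues
# and miRNAs up-regulated at d5
ct_mi <- contrast_stage(series_mi)
interactions <- read.delim(file.path(dat, "interactions.tsv"))
pairs <- data.frame(mirna_id = interactions$mirna_id,
                    gene_id = paste0("rn_", interactions$gene_id))
hom2 <- hom$gene_b[hom$gene_a %in% cluster_genes(assign, 2)]
scr <- stagewise_correlation_screen(series_m, series_mi, pairs,
                                    restrict_genes = hom2,
                                    restrict_mirnas = ct_mi$up)
write.table(scr, file.path(out, "differentiation_screen.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(scr)) {
  tallies <- sort(table(scr$mirna_id[scr$valid]), decreasing = TRUE)
  cat(sprintf("%d of %d screened pairs valid (rho < -0.4 over stage means)\n",
              sum(scr$valid), nrow(scr)))
  cat("top differentiation-screen miRNAs:\n")
  print(head(tallies, 5))
} else cat("no screened pairs after restriction\n")
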