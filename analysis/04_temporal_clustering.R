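#!/usr/bin/env Rscript
# Soft-cluster z-scored log2FC trajectories of genes that are DEG at at
# least one timepoint into five dynamic response groups (70% rule).

library(regenflow)

out <- "results"
de <- read.delim(file.path(out, "de_results.tsv"))

z <- zscore_trajectories(de)
cat(sprintf("%d genes DEG in at least one timepoint enter clustering\n",
            nrow(z)))

m <- estimate_fuzzifier(z)
cat(sprintf("fuzzifier m = %.3f (N = %d trajectories, D = %d timepoints)\n",
            m, nrow(z), ncol(z)))

assign <- fuzzy_cmeans(z, c = 5, m = m, seed = 11)
print(assign)

write.table(data.frame(gene = rownames(assign$membership), assign$membership,
                       hard = assign$hard),
            file.path(out, "cluster_membership.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster = rownames(assign$centroids),
                       assign$centroids, check.names = FALSE),
            file.path(out, "cluster_centroids.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- table(assign$hard)
cat("hard assignments per cluster (peak-time order):\n")
print(tab)
cat(sprintf("%d of %d genes assigned with > %.0f%% membership\n",
            sum(tab), nrow(z), 100 * assign$membership_min))
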