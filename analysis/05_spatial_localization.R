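#!/usr/bin/env Rscript
# Assign each temporal cluster a weight per heart location from the ranked
# location profiles, run per-cluster gene-set enrichment, and export the
# cluster / gene-set / location network.

library(regenflow)

out <- "results"
dat <- "results/data"

mem <- read.delim(file.path(out, "cluster_membership.tsv"))
u <- as.matrix(mem[, grep("^cluster", names(mem))])
rownames(u) <- mem$gene
assign <- structure(list(membership = u,
                         hard = setNames(mem$hard, mem$gene),
                         membership_min = 0.7),
                    class = "cluster_assignment")

ranks <- read.delim(file.path(dat, "location_ranks.tsv"))
weights <- location_weights(assign, ranks)
write.table(weights, file.path(out, "location_weights.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in sort(unique(weights$cluster))) {
  wi <- weights[weights$cluster == i, ]
  cat(sprintf("cluster %d: strongest in %-11s (share %.2f)\n",
              i, wi$location[which.max(wi$share)], max(wi$share)))
}

sets <- read_gmt(file.path(dat, "genesets.gmt"))
universe <- unique(read.delim(file.path(out, "mrna_filtered_counts.tsv"))$feature_id)
enr <- do.call(rbind, lapply(sort(unique(na.omit(assign$hard))), function(i) {
  q <- cluster_genes(assign, i)
  if (!length(q)) return(NULL)
  cbind(cluster = i, fisher_enrichment(q, sets, universe))
}))
write.table(enr, file.path(out, "cluster_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d significant cluster-set enrichments (p < 0.05, overlap >= 4)\n",
            sum(enr$significant)))

export_cluster_graph(enr, sets, weights,
                     file.path(out, "cluster_network.graphml"))
cat("network written to results/cluster_network.graphml\n")
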