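#!/usr/bin/env Rscript
# Validate predicted miRNA-mRNA interactions by expression anti-correlation,
# group miRNAs sharing targets into hubs, and report the top regulators.

library(regenflow)

out <- "results"
dat <- "results/data"

mrna_f <- read_experiment_tsv(file.path(out, "mrna_filtered"))
mirna_f <- read_experiment_tsv(file.path(out, "mirna_filtered"))
norm_m <- tmm_normalize(mrna_f)
norm_mi <- tmm_normalize(mirna_f)

interactions <- read.delim(file.path(dat, "interactions.tsv"))
cand <- filter_context(interactions)             # context score < -0.2
cand <- correlate_pairs(cand, norm_m$logcpm, norm_mi$logcpm)

mem <- read.delim(file.path(out, "cluster_membership.tsv"))
assigned <- mem$gene[!is.na(mem$hard)]
val <- validate_interactions(cand, assigned_genes = assigned,
                             expressed_mirnas = rownames(norm_mi$logcpm))
write.table(val, file.path(out, "validated_interactions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d interactions valid (rho < -0.4, FDR < 0.05) between %d miRNAs and %d mRNAs\n",
            sum(val$valid), length(unique(val$mirna_id[val$valid])),
            length(unique(val$gene_id[val$valid]))))

assign <- structure(list(membership = as.matrix(mem[, grep("^cluster", names(mem))]),
                         hard = setNames(mem$hard, mem$gene),
                         membership_min = 0.7),
                    class = "cluster_assignment")
rownames(assign$membership) <- mem$gene

hubs <- group_mirnas(val, p_max = 0.01, universe = length(assigned))
report <- top_hubs(hubs, k = 10, assign = assign)
write.table(report, file.path(out, "top_hubs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top regulator hubs (by validated target count):\n")
print(report)
export_hub_graph(hubs[seq_len(min(10, length(hubs)))],
                 file.path(out, "hub_targets.graphml"))
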