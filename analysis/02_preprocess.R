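#!/usr/bin/env Rscript
# QC, filtering, TMM normalization and surrogate-variable estimation for the
# mRNA and miRNA experiments written by 01_simulate.R.

library(regenflow)

dat <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE)

mrna <- read_experiment_tsv(file.path(dat, "mrna"))
mirna <- read_experiment_tsv(file.path(dat, "mirna"))

qc <- qc_flag_samples(mrna)
write.table(qc, file.path(out, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("QC: %d of %d samples flagged (>= 4 of 6 criteria failed)\n",
            sum(qc$flagged), nrow(qc)))

keep <- qc$sample[!qc$flagged]
mrna_f <- filter_low_counts(subset_experiment(mrna, samples = keep))
cat(sprintf("mRNA filter: %d -> %d features (CPM > 1 in >= 3 samples)\n",
            nrow(mrna$counts), nrow(mrna_f$counts)))
write_experiment_tsv(mrna_f, file.path(out, "mrna_filtered"))

norm <- tmm_normalize(mrna_f)
norm <- estimate_surrogate_variables(norm, seed = 8)
cat(sprintf("TMM factors in [%.3f, %.3f]; %d surrogate variable(s)\n",
            min(norm$norm_factors), max(norm$norm_factors), ncol(norm$sv)))
write.table(data.frame(sample = names(norm$norm_factors),
                       norm_factor = norm$norm_factors,
                       eff_lib_size = norm$eff_lib_sizes, norm$sv),
            file.path(out, "normalization.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pca <- pca_view(norm)
write.table(data.frame(sample = rownames(pca$scores), pca$scores,
                       check.names = FALSE),
            file.path(out, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))

mirna_f <- filter_low_counts(mirna)
write_experiment_tsv(mirna_f, file.path(out, "mirna_filtered"))
cat(sprintf("miRNA filter: %d -> %d features\n",
            nrow(mirna$counts), nrow(mirna_f$counts)))
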