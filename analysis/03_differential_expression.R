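#!/usr/bin/env Rscript
# Mixed-control differential expression at every injured timepoint, plus the
# early/intermediate/late phase grouping of timepoints.

library(regenflow)

out <- "results"
mrna_f <- read_experiment_tsv(file.path(out, "mrna_filtered"))
norm <- tmm_normalize(mrna_f)
norm <- estimate_surrogate_variables(norm, seed = 8)

sched <- control_schedule()
print(sched)

de <- run_de(norm, sched)
write_de_tsv(de, file.path(out, "de_results.tsv"))

deg_tp <- with(de, tapply(deg, dpi, sum))
cat("DEGs per timepoint (FDR < 0.01, |log2FC| > 1):\n")
print(deg_tp)
cat(sprintf("peak response at %s dpi with %d DEGs\n",
            names(which.max(deg_tp)), max(deg_tp)))

phases <- phase_cluster(de)
cat("timepoint phases (1 - Pearson, average linkage, k = 3):\n")
print(phases$phases)
if (phases$contiguous)
  cat("phases are contiguous in time: early / intermediate / late\n")
write.table(data.frame(dpi = names(phases$phases), phase = phases$phases),
            file.path(out, "timepoint_phases.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
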