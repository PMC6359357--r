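# regenflow

Time-course transcriptomics of zebrafish heart regeneration, as a tested R
pipeline. After cryoinjury — a cooled probe applied to the ventricle,
modelling myocardial infarction — zebrafish rebuild their myocardium over
roughly five months. Bulk mRNA and miRNA profiles along that time course
confound three signals: the regeneration program itself, the
transcriptional shock of the surgery, and ordinary aging. `regenflow`
implements the full analysis chain that separates them, for anyone who
wants to analyse such a design or to study the statistical behaviour of the
method on data with known ground truth.

## The model

Differential expression at `t` days post injury (dpi) is tested against a
time-weighted **mixed control**:

```
control(t) = w_sham(t) * Sham + w_healthy(t) * Healthy
w_sham(t)  = exp(-beta * (t - 1)),   w_healthy(t) = 1 - w_sham(t)
```

with `beta` calibrated in closed form so that `w_sham(1) = 1` and
`w_sham(160) = 0.05` (`beta = log(20)/159 ≈ 0.01884/day`) — sham-operated
fish are the right control just after surgery, healthy fish months later,
and exponential decay (the empirical law of wound closure) bridges the two.
Per gene and timepoint, a weighted negative-binomial GLM with
likelihood-ratio test (mixture weights on the control arm, log effective
library sizes as offsets, surrogate variables as covariates, tagwise
dispersions shrunk toward a pooled common value, genome-wide calibration of
the test statistics) yields log2FC, p and BH FDR; DEGs are `FDR < 0.01 &
|log2FC| > 1`.

Downstream, z-scored DEG trajectories are soft-clustered into five dynamic
groups by fuzzy c-means (genes assigned at > 70% membership), clusters are
localized to the injury site / border zone / uninjured myocardium by a
top-20% rank-occupancy weight, predicted miRNA targets are validated by
anti-correlation (context score < −0.2, ρ < −0.4, FDR < 0.05) and grouped
into regulator hubs by hypergeometric target-sharing (p < 0.01, connected
components), and the proliferation cluster is checked across species in a
differentiating myoblast series (χ² association of down-regulated genes
with cluster-2 homologues).

Every input can be generated synthetically with planted truth
(`simulate_experiment()` and friends), so the whole chain is testable
offline. See the methods vignette (`vignettes/regenflow-methods.Rmd`) for
the statistical details and design choices.

## Worked example

```r
library(regenflow)

cfg <- simulation_config(seed = 1, n_genes = 600, n_mirnas = 120)
res <- run_pipeline(cfg, out_dir = "results/demo")

with(res$de, tapply(deg, dpi, sum))        # DEGs per timepoint
#>   1   4   7  14  21  30  45  60 120 160
#>   0  95  88  52  58  34  26  25  14  11
res$phases$phases                          # timepoint phase grouping
#>   1   4   7  14  21  30  45  60 120 160
#>   1   2   2   2   3   3   3   3   3   3
head(res$hub_report, 3)                    # top miRNA regulator hubs
#>       hub members n_targets dominant_cluster
#> 1 mir0016 mir0016        24                4
#> 2 mir0030 mir0030        24                2
#> 3 mir0098 mir0098        22                1
res$cross_species$p                        # conserved proliferation program
#> [1] 2.870676e-27
```

Reading the output: the DEG counts peak at 4–7 dpi and decay — the injured
hearts drift back toward the control mixture as regeneration completes; the
phase grouping splits the time course into early / intermediate / late
responses; the three planted hub miRNAs top the regulator ranking with
their full target sets; and the χ² p-value confirms that genes shut down
during myoblast differentiation are enriched for homologues of the
proliferation cluster.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `07_cross_species.R`), each a thin narrative
wrapper over the package functions that writes its tables under `results/`.

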