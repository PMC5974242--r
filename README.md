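# spliceScore

Detection of alternatively spliced exons from probe-level exon and junction
microarray data, for transcriptomics analysts working with exon/junction
array platforms (arrays that measure each exonic region with a probe set
and each exon–exon boundary with junction probes).

## What it computes

**Step 1 — exon and array scores.** Each gene (transcript cluster) is
fitted with the mixed model

```
log2(PM_ijk) = p_j + c_i + b_ik + e_ijk,   b_ik ~ N(0, tau_k^2),  e ~ N(0, sigma^2)
```

where `p_j` are fixed probe affinities, `c_i` fixed array effects (which
absorb gene-level differential expression), and `b_ik` the random deviation
of exon `k` on array `i`. The *exon score* of exon `k` is the intra-cluster
correlation `rho_k = tau_k^2 / (sigma^2 + tau_k^2)`: the fraction of its
variability lying between arrays. Scores above 0.5 flag candidate
alternatively spliced exons; the predicted `b_ik` (*array scores*) are
tested between the two biological groups (Welch or paired t-test) with
Benjamini–Hochberg correction across all retained probe sets. Fitting is
REML (EM on Henderson's mixed-model equations plus a quasi-Newton polish
with analytic score equations).

**Step 2 — junction evidence.** Linking junctions (sharing an anchor with
the candidate) are tested with a rank-based interaction F-test against the
*median profile* of their two anchor probe sets: a junction that tracks the
profile supports the link, a significant interaction contests it.
Exclusion junctions (spanning over the candidate) are assessed by
detection-above-background (per-probe empirical p-values combined by
Fisher's method): presence in any sample supports the splicing call. Each
candidate is then classified as `supported_by_all`,
`supported_by_at_least_one`, `not_supported`, or `no_linking_junctions`,
and optionally typed (`cassette_exon`, `mutually_exclusive`, `alt_first`,
`alt_last`, `alt_5prime`, `alt_3prime`, `intron_retention`,
`complex_event`) from isoform composition.

A synthetic-data generator (`simulate_dataset()`) plants ground-truth AS
exons and agree/conflict/absent junctions so the whole pipeline is testable
without array downloads.

## Worked example

```r
library(spliceScore)

sim <- simulate_dataset(sim_config(n_genes = 30, seed = 7))  # 6 planted AS exons
res <- run_pipeline(sim$probes, sim$groups,
                    annotation = sim$annotation,
                    isoforms   = sim$isoforms,
                    background = sim$background)

head(res$candidates, 3)
#>   transcript_cluster_id probe_set_id exon_score     p_value p_adjusted
#> 1                TC0001   PSR0001_06  0.9844684 0.003583119 0.01074936
#> 2                TC0003   PSR0003_04  0.9839319 0.002813438 0.01074936
#> 3                TC0004   PSR0004_02  0.9807919 0.113949123 0.11394912
#>   mean_diff     direction
#> 1  2.885063 enriched_in_A
#> 2  2.745817 enriched_in_A
#> 3  1.986192 enriched_in_A

table(res$support$category)
#>          supported_by_all supported_by_at_least_one
#>                         4                         2
subset(res$events, probe_set_id == "PSR0001_06")$event_type
#> [1] "cassette_exon"
```

The exon scores near 0.98 say almost all of those exons' variability is
between arrays; the signed `mean_diff` (log2 array-score difference between
the groups) gives the direction of exon usage. All six planted cassette
exons come back as candidates: four supported by every annotated junction,
two by at least one, and the top candidate is typed as a cassette event.
(Output shown is exactly what the commands above print at seed 7.)

A thin CLI over the same functions lives at `inst/cli/splicescore.R`
(subcommands `simulate`, `preprocess`, `run`).

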