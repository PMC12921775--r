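# dapsize

Differential protein abundance and empirical-null effect size for
two-group DIA proteomics experiments, as used in aquaculture feeding
trials.

## The problem

A label-free DIA experiment comparing two treatments (here: two commercial
fish diets, 8 biological replicates each, across brain, liver and
intestine) will always report *some* differentially abundant proteins
(DAPs) — biological and technical noise alone push a fraction of proteins
past any fixed threshold rule. `dapsize` quantifies how much of the
observed differential abundance is a real treatment effect by running the
identical pipeline on an **empirical null**: each group's replicates are
split into halves and compared against themselves.

For each comparison (A vs A, B vs B, A vs B; always 4 vs 4 samples) the
pipeline is:

1. detection filter — keep proteins quantified in ≥ 3 of 4 replicates of
   a group;
2. variance-stabilizing normalization — per-sample calibration
   `h_s(x) = asinh(a_s x + b_s)/ln 2`, robustly fitted against the
   row-median reference profile;
3. maximum-likelihood (EM) imputation of missing intensities under a
   multivariate normal over samples;
4. empirical-Bayes moderated t-test — per-protein pooled variance `s²` on
   `n₁+n₂−2` df shrunk toward an inverse-chi-square prior estimated from
   all proteins (trigamma moment matching);
   `t = Δlog₂ / sqrt(s²_post (1/n₁ + 1/n₂))`;
5. DAP call — `increased` iff fold change `2^Δlog₂ ≥ 1.3` and `p < 0.05`,
   `decreased` iff `≤ 0.76` and `p < 0.05` (unadjusted p; BH-adjusted
   values are reported alongside).

The effect size is the gap between the DAP percentage of the between-group
comparison and the mean of the within-group comparisons.

The package also provides NIPALS PLS-DA with confidence ellipses, PRM
(parallel reaction monitoring) transition roll-up with DIA/PRM direction
concordance, the aquaculture production indices SGR / FCR / RFI, readers
and writers for the DIA-NN `report.pg_matrix` TSV dialect, and a
ground-truth synthetic-data generator used throughout the test suite.

## Worked example

```r
library(dapsize)

cfg  <- sim_config(seed = 7, n_proteins = 2000)   # two diets x 8 replicates
acfg <- analysis_config(seed = 7)
sim  <- generate_matrix(cfg)                       # matrix + design + truth
sim$matrix
#> protein_matrix: 2000 proteins x 16 samples [raw scale]
#>   missing cells: 421 (1.3%)

report <- effect_size_analysis(sim$matrix, sim$design, acfg)
report$comparisons
#>       label total n_increased n_decreased n_changed pct_changed
#> 1 within_g1  1999          37          25        62        3.10
#> 2 within_g2  1996          35          48        83        4.16
#> 3   between  1999         137         120       257       12.86
report
#> effect-size report over 3 comparisons
#>   mean within-group DAP%:  3.6
#>   mean between-group DAP%: 12.9
#>   between/within ratio:    3.54
```

Reading: with 10% of proteins planted at ±1.5 log2 (the generator's
default), noise alone makes ~3.6% of proteins cross the DAP thresholds in
the self-comparisons, while the between-diet comparison flags 12.9% — a
~3.5-fold enrichment attributable to the treatment. `run_comparison(...,
keep_details = TRUE)` exposes the per-protein fit and call tables
(including volcano coordinates); `read_pg_matrix()` / `read_design()` run
the same analysis on a DIA-NN export.

Production indices from a feeding trial's intake/weight records:

```r
fcr(864.35, 683.25)          # feed intake / weight gain  -> 1.265
fcr(827.85, 683.72)          #                            -> 1.211
sgr(513.92, 1197.17, 84)     # %/day over a 12-week trial -> 1.007
```

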