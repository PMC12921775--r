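---
title: "Quantifying dietary effect size in DIA proteomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dietary effect size in DIA proteomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapsize)
```

## The problem

A two-group label-free proteomics experiment — here, fish fed two commercial
diets, with eight biological replicates per diet and three tissues — always
yields *some* differentially abundant proteins (DAPs), because biological and
technical variability alone push a fraction of proteins past any fixed
p-value/fold-change rule. The question this package answers is: **how much of
the observed differential abundance is attributable to the treatment rather
than to that baseline variability?**

The approach is an empirical null. Each diet's eight replicates are split
into two halves of four, and the full differential-abundance pipeline is run
on three comparisons:

* `within_g1`: half 1 vs half 2 of diet A — same treatment on both sides;
* `within_g2`: half 1 vs half 2 of diet B — same;
* `between`: half 1 of diet A vs half 1 of diet B.

The within-diet comparisons estimate the DAP percentage produced by noise
alone. The dietary effect size is read off as the gap (or ratio) between the
between-diet percentage and the within-diet average. Because every
comparison runs the identical pipeline on the identical number of
replicates, pipeline-induced inflation cancels.

## The per-comparison pipeline

Each comparison runs, on the raw protein-group matrix restricted to its
eight samples:

1. **Detection filter** (`filter_by_detection`). A protein is kept when it
   is quantified in at least `min_detect = 3` of the 4 replicates of at
   least one group (`detection_scope = "any_group"`; `"all_groups"` is
   available). The retained row count is the comparison's *Total* — totals
   legitimately differ across comparisons because different sample subsets
   have different detection patterns.
2. **Variance-stabilizing normalization** (`vsn_normalize`). Each sample is
   calibrated with `h_s(x) = asinh(a_s x + b_s) / ln 2`, which is log2-like
   at high intensity and linear near zero. Parameters are fitted per sample
   against the across-sample row-median reference profile by a trimmed
   (10%) profile likelihood that includes the transform's log-Jacobian —
   the Jacobian term is what makes the fit a variance-stabilization
   criterion; a plain trimmed least-squares fit has a degeneracy in which
   inflating the offset squashes the low-intensity range and "improves"
   residuals while distorting exactly the proteins it should protect. Two
   alternating reference/parameter passes are used. By default only the
   scale factors `a_s` are fitted and the offsets stay 0: MaxLFQ-style DIA
   intensities are ratio-scale without an additive background, so a free
   offset is informed only by the few lowest-intensity rows and can only
   harm them. `fit_offset = TRUE` enables the full affine fit for data
   with genuine additive background. Trimming keeps the calibration robust
   to the minority of truly diet-responsive proteins.
3. **Maximum-likelihood imputation** (`mle_impute`). A multivariate normal
   over the sample dimension is fitted by EM (proteins are observations,
   samples variables); each missing cell is replaced by its conditional
   mean given the protein's observed cells. Observed values are never
   altered; rows entirely missing within the comparison are dropped with a
   logged count. Tolerance is `1e-8` relative log-likelihood change, at
   most 100 iterations (non-convergence is an error carrying the
   likelihood trace). The observed-data log-likelihood is checked to be
   non-decreasing; when a singular covariance block forces a ridge (added
   only on Cholesky failure, escalating from `1e-8` times the mean
   diagonal), the check is relaxed because the computed likelihood then
   belongs to a perturbed model. Regularizing only on failure keeps exact
   degenerate cases — e.g. perfectly correlated samples — exactly
   reproduced by their closed-form conditional means.
4. **Moderated two-group test** (`moderated_fit`). Per protein: group means
   on the log2-like scale, `log2fc = mean_g2 − mean_g1`, pooled variance
   `s2` on `n1 + n2 − 2` df. An inverse-chi-square prior `(s2_prior,
   df_prior)` is estimated from all proteins by moment matching of
   `log s2` under the scaled-F model (trigamma inversion); the posterior
   variance `s2_post = (df_prior·s2_prior + df·s2)/(df_prior + df)` gives
   `t_mod = log2fc / sqrt(s2_post (1/n1 + 1/n2))`, referred to Student-t
   with `df + df_prior` degrees of freedom. When the log-variances show no
   excess spread beyond chi-square sampling noise, the prior df is
   infinite and `s2_prior` is the arithmetic mean of the variances (their
   MLE under equality). `df_prior = 0` disables moderation (ordinary
   pooled t); the implementation is checked in the test suite against
   limma's `eBayes` to 1e-10, and against a from-first-principles pooled-t
   oracle.
5. **DAP calling** (`call_daps`). `increased` iff raw fold change
   `2^log2fc ≥ 1.3` *and* `p < 0.05`; `decreased` iff `≤ 0.76` and
   `p < 0.05`. Fold-change boundaries are inclusive; the p boundary is
   exclusive. Calling uses the *unadjusted* p-value — with n = 4 per
   group, FDR adjustment costs too much power and mainly produces false
   negatives — while Benjamini–Hochberg adjusted values are computed
   (via `stats::p.adjust`) and reported alongside. Volcano coordinates are
   `(log2fc, −log10 p)`.

`summarize_effect_size` then averages `100 · n_changed / total` over the
within and between comparisons (percentages rounded half-even to 2
decimals, means reported to 1 decimal).

## Half-splitting

When the design table carries no `half` column, halves are assigned by a
seeded shuffle (`analysis_config(seed = )`), so a run is reproducible given
its seed; `method = "by_replicate"` gives the fixed split (replicates 1–4
vs 5–8) for exact reproducibility across environments. Only one split is
evaluated per run — averaging over all 35 possible splits would shrink the
null's variance but answers a different question and is deliberately not
done.

## Thresholds and defaults

| parameter | default | meaning |
|---|---|---|
| `p_cut` | 0.05 | unadjusted two-sided p-value threshold (exclusive) |
| `fc_up` / `fc_down` | 1.3 / 0.76 | raw-scale fold-change bounds (inclusive) |
| `min_detect` | 3 | detected replicates required per group |
| `group_size` | 4 | replicates per side of each comparison |
| `detection_scope` | `any_group` | which groups must reach `min_detect` |

Note `0.76 ≠ 1/1.3`, so increased/decreased calls are not exactly
label-swap symmetric; with a reciprocal configuration
(`fc_down = 1/fc_up`) the symmetry is exact, which the test suite uses.

## The synthetic-data generator

`sim_config()` / `generate_matrix()` emulate the data this pipeline
consumes; the generator is first-class, tested code because every
distributional claim about the pipeline is established on its output.

* Log2 baseline abundances are `N(20, 2)` — MaxLFQ-like intensities
  spanning roughly 1e4–1e8.
* Per-protein residual SDs follow a scaled inverse-chi-square
  (`protein_sd_shape = 4`, `protein_sd_scale = 0.25` log2 units), typical
  of tissue-level label-free replicates and exactly the model the
  empirical-Bayes moderation assumes.
* A fraction `pi_dap = 0.1` of proteins receives a diet effect of
  `±effect_log2fc` (default 1.5) with random sign.
* Per-sample log2 shifts `N(0, 0.5)` create up to ~4× loading/instrument
  scale differences for the normalization to remove.
* Missingness is MNAR: a cell of (post-shift) log2 intensity `z` is
  detected with probability `plogis((z − 14) / 1)`, giving a few percent
  missingness concentrated at low abundance, applied after sample scaling
  because instrument detection acts on observed, not latent, intensity.

Two diets × 8 replicates and ~3 tissues of ~4000 proteins reproduce the
shape of the feeding-trial tables. What the generator does *not* emulate:
correlated missingness across samples of a run batch, interference/shared
peptides between protein groups, retention-time drift, and non-normal
heavy-tailed outlier proteins. Passing tests therefore demonstrate
correctness of the statistical machinery under its stated model, not
robustness to every pathology of real DIA data.

`generate_prm()` derives a transition-level PRM table from the same ground
truth (2–4 peptides/protein, 3–6 transitions/peptide, fixed response
factors, lognormal noise), so DIA/PRM concordance can be validated against
a shared truth; `generate_growth()` emits per-fish growth records with
`gain = final − initial` by construction.

## Multivariate view and targeted validation

`plsda_fit` implements two-class PLS-DA as NIPALS PLS1 on the centered ±1
class indicator (equivalent to the dummy-matrix PLS2 formulation for two
classes and easier to verify), with autoscaling by default to match common
metabolomics-tool behavior. Weight vectors are unit-norm with the
largest-magnitude element made positive, a convention that pins the
otherwise arbitrary component signs. Explained X-variance per component is
`(tᵀt)(pᵀp)/‖X‖²`; it need not decrease across components for PLS.
`confidence_ellipse` draws the bivariate-normal region from the score
mean and covariance scaled by `qchisq(level, 2)`.

`summarize_prm` sums transition areas per peptide and sample and takes
log2 (zero totals are non-detections, hence missing); proteins are rolled
up as the unweighted mean of their peptides' values — peptide response
factors cancel in between-group differences, and the unweighted mean is
robust to peptide count. Group comparison uses the pooled Student's
t-test; a shift with zero within-group variance is reported as the limit
`t = ±Inf, p = 0`.

## Numerical choices and degenerate inputs

* Zeros in input matrices are non-detections and parse to missing; raw
  intensities must otherwise be strictly positive.
* Scale tags (`raw → log2/normalized`) are enforced so the pipeline order
  (filter → normalize → impute → fit) cannot be silently violated.
* VSN's 1-D scale fits use golden-section search (`stats::optimize`,
  tol 1e-10) started from median-ratio initial values, which already
  solve pure scaling exactly; the optional 2-D affine fit uses
  Nelder–Mead on dimensionless `(log a, b/(a·q10))`.
* `student_ttest` with zero pooled variance returns `t = 0, p = 1` for
  equal means and errors for unequal means (no finite statistic exists).
* Tied group means give `t_mod = 0, p = 1` even when the posterior
  variance is 0.
* Result files are tab-separated with numerics at 17 significant digits,
  so write/read round-trips are bitwise.

## Problem sizes used in the checks

The simulation-based checks use 4000 proteins for single-dataset p-value
calibration (matching the real matrices' size) and 20 replicate datasets
of 1000 proteins for the within/between equivalence and
parameter-recovery properties — large enough that the Monte-Carlo bounds
quoted in the tests are meaningful, small enough to run routinely.

## Known limitations

* The empirical null consumes half the replicates per side; with n = 4
  per side the within-diet DAP percentage is itself noisy, so effect-size
  ratios should be read as order-of-magnitude statements.
* Imputation assumes multivariate normality across samples and ignores
  the censoring mechanism; under strong MNAR the imputed values are
  biased upward toward the conditional mean of detected data.
* PLS-DA is used descriptively (scores and ellipses); no cross-validated
  classification performance is computed.
* One half-split per run (see above).
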