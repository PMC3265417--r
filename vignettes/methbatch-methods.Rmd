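---
title: "Normalization and empirical Bayes batch correction for Infinium methylation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization and empirical Bayes batch correction for Infinium methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbatch)
```

## The problem

Infinium-style methylation BeadChips report, for each CpG site, a pair of
fluorescence intensities: `A` from the unmethylated-allele probe and `B`
from the methylated-allele probe. The methylation level is summarized as
the *average beta*,

$$\beta = \frac{B}{A + B + 100},$$

a regularized methylated fraction bounded in $[0, 1)$. The offset of 100
stabilizes the ratio at low total intensity and reproduces the vendor
software's computation; it is exposed as a parameter (`offset`, default
100) but there is rarely a reason to change it.

Because chips hold only 12 samples, any study of realistic size spreads
its samples over several chips, often processed on different days or
from different reagent lots. The resulting *batch effects* — systematic
intensity and beta shifts shared by all samples on a chip — can dwarf
the biology: on affected datasets, one-way ANOVA of each CpG against the
chip label can flag half or more of all CpGs at $p < 0.01$, and the
first principal component separates the chips cleanly. methbatch
implements a two-step remedy — global normalization, then covariate-aware
empirical Bayes (EB) batch adjustment — together with the quantitative
diagnostics needed to judge whether either step was sufficient.

## Quantile normalization strategies

All three strategies share one engine, `quantile_normalize()`. The
reference distribution is the per-rank mean of the column-sorted values;
every entry is replaced by the reference value at its within-column
rank. Three implementation choices matter and are worth stating
precisely:

* **Ties.** Beta matrices pile up near 0 and 1, so ties are common. The
  default `average_ties` policy assigns tied entries the mean of the
  reference values spanning their rank range, which keeps tied inputs
  tied on output. `sorted_assign` instead distributes the sorted
  reference over tied entries in order of appearance, reproducing the
  classic sort/assign algorithm bit for bit; it is provided for
  compatibility experiments.
* **Missing values.** A column with missing entries is ranked over its
  non-missing values against a reference linearly interpolated to that
  length, and contributes to the reference through the same
  interpolation. Nothing is imputed: missing stays missing.
* **Invariants.** For complete matrices the engine preserves the grand
  mean, preserves within-column rank order, and is idempotent. The test
  suite checks these properties and checks exact agreement with an
  independently coded sort/average oracle on random small matrices.

The three user-facing strategies are:

1. **`qn_beta()`** — quantile normalization directly on the beta matrix.
   The most aggressive option: it forces every sample's beta
   distribution to be identical regardless of the source of the
   difference. Appropriate when samples are biologically comparable and
   batch effects are severe.
2. **`abnorm()`** — the A and B signal matrices are quantile-normalized
   independently across samples, then beta is recomputed from the
   normalized signals. This corrects intensity bias at its source,
   before the nonlinear signal-to-beta transform obscures it.
3. **`lumi_norm()`** — per-sample color-channel adjustment followed by
   quantile normalization of the pooled signal matrix. Step 1 maps each
   dye channel's intensities (pooled A and B values of that sample) onto
   the sample's combined-channel distribution by monotone quantile
   mapping; step 2 stacks adjusted A over adjusted B into a
   $(2G) \times N$ matrix and quantile-normalizes it across samples;
   step 3 recomputes beta. The color step here is a plain monotone
   quantile map to the per-sample combined distribution — a deliberate,
   documented simplification of the smoothed-quantile variant found in
   expression-array tooling. Probes without channel annotation are
   pooled but not adjusted; if no probe has a known channel the step is
   skipped with a warning.

Normalization operates on exactly the probes it is given; any probe
filtering (for example removal of chrX/Y probes with `filter_probes()`
to keep male/female differences out of mixed-sex analyses) must happen
first.

## The empirical Bayes batch model

Global normalization equalizes whole distributions; it cannot fix probes
that individual batches push in different directions. The second step
adjusts each CpG individually. For CpG $g$, sample $j$ in batch $i$:

$$y_{ijg} = \alpha_g + X_j \beta_g + \gamma_{ig} + \delta_{ig}\,
\varepsilon_{ijg}, \qquad \varepsilon_{ijg} \sim N(0, \sigma_g^2),$$

where $X$ holds the biological covariates of interest (the case/control
outcome, and anything else passed via `covariates`), $\gamma_{ig}$ is an
additive and $\delta^2_{ig}$ a multiplicative batch effect. Fitting
proceeds exactly as in the ComBat tradition:

1. Per CpG, least squares on `[batch indicators | covariates]`; the
   grand location $\hat\alpha_g$ is the **batch-size-weighted** mean of
   the per-batch fits, so unbalanced chips (8/4 splits) do not bias it.
2. Standardize: $z = (y - \hat\alpha_g - X\hat\beta_g)/\hat\sigma_g$
   with $\hat\sigma_g^2$ the pooled residual variance.
3. Per batch, $\hat\gamma_{ig}$ = mean and $\hat\delta^2_{ig}$ =
   variance of $z$ over the batch's samples.
4. Parametric priors — $\gamma_{ig} \sim N(\bar\gamma_i, \tau_i^2)$,
   $\delta^2_{ig} \sim \text{InvGamma}(\lambda_i, \theta_i)$ — with
   hyperparameters estimated from all CpGs by method of moments.
5. The coupled conditional posterior means $\gamma^*_{ig}$,
   $\delta^{2*}_{ig}$ are iterated to convergence (tolerance $10^{-6}$
   on the maximum absolute change, capped at 500 iterations; both
   configurable).
6. `apply_eb()` removes the shrunken batch location and scale and adds
   the protected fit back:
   $y^{adj} = \hat\sigma_g (z - \gamma^*_{ig})/\delta^*_{ig} +
   \hat\alpha_g + X_j\hat\beta_g$.

Shrinking the per-CpG batch estimates toward their batch-level priors
borrows strength across the ~27k CpGs, which is what makes per-CpG
adjustment feasible with only 12 samples per chip. Setting
`shrink = FALSE` in `fit_eb()` disables the pooling and uses the raw
location/scale estimates, which is occasionally useful for debugging
and is exercised by the algebraic tests.

Numerical and design choices:

* **Bounds.** Beta values live in $[0, 1]$; an adjustment that leaves
  the interval would be nonsense downstream. The default
  `clip_policy = "clip01"` clamps and counts offending entries
  (`attr(out, "n_clipped")`). An optional logit-scale mode
  (`transform = "logit"` in `correct_batch()`) adjusts on the logit
  scale and can never leave bounds, but it is off by default because
  the beta scale is where the procedure is defined and evaluated here.
* **Identifiability.** With the weighted grand mean, per-batch
  locations are identified only relative to that mean: injecting a
  $+0.1$ shift into one of two equal batches yields
  $\gamma^*_2 \approx +0.05$, $\gamma^*_1 \approx -0.05$ in beta units.
  Tests and the acceptance script therefore report the estimable
  between-batch contrast
  $(\gamma^*_2 - \gamma^*_1)\,\hat\sigma_g \approx 0.1$.
* **Degenerate CpGs.** A CpG with zero pooled variance, or with any
  missing value, is flagged and passed through unadjusted. A CpG
  constant within a single batch has its scale floored to the smallest
  positive within-batch scale observed, with a warning.
* **Confounding.** If the covariates are confounded with batch (the
  design matrix is rank-deficient — the extreme case being all cases on
  one chip and all controls on another), batch and biology cannot be
  separated and `fit_eb()` refuses with an explanation rather than
  silently removing signal.

## Diagnostics

`batch_report()` bundles the quantitative assessments, each also
available separately:

* per-sample beta quantiles (`qc_summary()`), for box/density-style
  inspection;
* unsupervised hierarchical clustering of samples on
  $1 - r_{\text{Pearson}}$ with average linkage
  (`hcluster_batch()`), made quantitative by the adjusted Rand index
  between the $k$-cluster cut ($k$ = number of batches) and the chip
  labels;
* PCA of the probe-centered matrix (`beta_pca()`), with per-component
  variance fractions;
* association of the first 10 components with the chip label
  (`pc_batch_association()`): exact two-sample Wilcoxon rank-sum for
  two batches (the exact null is used whenever sample sizes permit and
  there are no ties; the normal approximation with continuity and tie
  correction otherwise), Kruskal–Wallis for more than two;
* the fraction of CpGs with one-way ANOVA $p < 0.01$ against batch
  (`per_cpg_anova()` + `count_significant()`). The threshold is strict
  (`<`), and no multiple-testing correction is applied anywhere —
  counting raw $p < 0.01$ *is* the metric.

Performance evaluation uses the same machinery against the outcome
label, plus two tools specific to assay quality:
`replicate_errors()` summarizes per-CpG differences within technical
replicate pairs by the mean error (systematic shift) and the average
absolute deviation from zero (spread); `ma_lowess()` fits robust lowess
curves of each sample's deviation from the per-CpG mean against that
mean, the standard visualization of intensity-dependent bias.
`control_panel_eval()` checks a positive panel (probes expected
differential) and a negative panel (probes expected null) at a given
$\alpha$, reporting the expected false-positive count
$\mathrm{round}(\alpha\,n_{\text{neg}})$ — 18 for the conventional
358-probe housekeeping panel at $\alpha = 0.05$ — and a
Kolmogorov–Smirnov uniformity statistic for the negative panel.

## The synthetic data generator

No suitable public dataset ships with the package, so `sim_config()` /
`simulate_methylation()` generate Infinium-27k-like two-signal data for
testing and calibration. Defaults describe the study conditions the
package is built around, chosen once:

* 27,578 CpGs, of which 1,092 annotate to chrX/Y (so the sex-chromosome
  filter leaves 26,486), red/green channels split evenly;
* two chips of 12 samples with a 6/6 case/control split each
  (configurable per chip, e.g. 8/4 vs 4/8 for partial confounding);
* baseline beta drawn from a bimodal Beta mixture (60% from
  Beta(2, 10), mode ≈ 0.1; 40% from Beta(12, 3), mode ≈ 0.85),
  reproducing the characteristic two-peak methylation density;
* log-normal total intensity per probe (meanlog $\log 4000$, sdlog 0.3)
  with a small per-sample wobble; signals are constructed as
  $B = \beta T$, $A = (1-\beta) T$, so recomputed beta differs from the
  intended value only by the offset-induced bias
  $\le 100/(T + 100)$;
* per-CpG between-sample beta noise SD 0.02, and replicate noise SD
  0.01 — replicate differences then have SD well under 0.05, matching
  the variability technical replicates show in practice;
* batch effects per chip: an additive beta-scale shift and/or
  additive, multiplicative, or intensity-dependent signal-scale biases,
  on a configurable CpG fraction. `sim_regime()` provides presets:
  `"null"`, `"minor"` (0.02 shift on 30% of CpGs), `"shift"` (0.1 shift
  on all CpGs — a distribution displacement), `"scale"` (methylated
  signal damped 30% on one chip — upper-quartile compression with
  little median movement);
* outcome effects: $\Delta\beta$ with random sign on a configurable CpG
  fraction of case samples, recorded with the batch assignments in a
  truth table;
* a mandatory seed; the entire dataset is a deterministic function of
  the configuration.

Two generator behaviours deserve emphasis. First, technical replicates
re-assay the source sample's per-probe totals with fresh beta-scale
noise, and with zero noise they duplicate the source columns exactly —
so replicate metrics have an exact zero baseline. Because replicates
share their source's chip, chip-level effects cancel in replicate
differences; the generator has no per-sample dye or scanner bias, so
(unlike on real arrays) normalization barely changes synthetic
replicate errors. Second, beta is bounded: the generator clamps values
into $[0.001, 0.999]$, so an additive shift injected near the upper
mode is truncated and the *realized* effect is smaller than the nominal
one. Parameter-recovery experiments therefore inject shifts into a
low-methylation baseline (`weight_low = 1`) where the shift is
faithfully representable; this is experiment design, not tolerance.

What passing tests on this generator do **not** show about real data:
real batch effects are probe-dependent in ways no low-dimensional
parameterization captures; detection p-values are simulated as small
uniforms, not from bead-level physics; intensity distributions are a
log-normal stand-in; and a strictly uniform beta shift is invisible to
Pearson-correlation clustering (adding a constant to a sample's profile
does not change its correlations), so the clustering concordance metric
only reacts to probe-heterogeneous batch effects.

## The pipeline and problem sizes

`run_pipeline()` executes the sequential procedure — assess, normalize,
correct, re-assess — and returns a stage-by-metric comparison table; the
procedure is deliberately sequential (normalization first, EB second),
not a joint model. A thin command-line wrapper
(`inst/cli/methbatch.R`) exposes `simulate` / `assess` / `normalize` /
`correct` / `run` subcommands over the same functions, with YAML run
configuration.

The test suite runs its simulations at 100–2,000 CpGs with two
12-sample chips (the EB calibration checks use the 1,000-CpG, 2 × 12
design; the ANOVA-uniformity check uses 10,000 CpGs), sizes at which
every property under test is already stable. The acceptance script
(`scripts/acceptance.R`) runs the headline pipeline at full platform
scale (27,578 CpGs) and the calibration and recovery analyses at 5,000
CpGs. All randomness derives from the `--seed` argument.

## Known limitations

* The EB step assumes normal residuals on the beta scale; for CpGs
  pinned near 0 or 1 this is approximate, which is why out-of-bounds
  adjustments are counted rather than assumed away.
* The color-channel step is a plain monotone quantile map, not a
  smoothed variant; with very few probes per channel the mapping is
  coarse.
* Nonparametric EB priors, surrogate-variable approaches, and
  distance-weighted discrimination are out of scope, as are IDAT
  parsing and 450k-specific probe-type handling.
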