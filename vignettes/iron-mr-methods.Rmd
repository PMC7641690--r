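---
title: "Methods: two-sample Mendelian randomization of iron status and vascular disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of iron status and vascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The design

ironmr implements a two-sample Mendelian randomization (MR) analysis of
genetically predicted iron status against a panel of vascular-disease
outcomes. Iron status is instrumented by three SNPs — rs1800562 and
rs1799945 near the hemochromatosis (HFE) gene and rs855791 in TMPRSS6 —
each associated at genome-wide significance with all four serum iron
biomarkers: iron, ferritin, transferrin, and transferrin saturation. Higher
iron, ferritin, and transferrin saturation mark higher systemic iron
status; higher transferrin marks *lower* iron status, which the pipeline
records as a direction annotation on transferrin rows rather than flipping
any estimate.

The two samples are non-overlapping: SNP–biomarker associations come from a
consortium meta-analysis of roughly 49,000 Europeans, SNP–disease
associations from biobank-scale scans of roughly 361,000 British subjects
(overall and, for seven of the twelve outcomes, split by sex). Everything
operates on summary statistics — per-SNP betas and standard errors — never
individual-level data.

## Statistical model

Write $\hat\gamma_j \sim N(\gamma_j, \sigma_{\gamma j}^2)$ for the observed
SNP–exposure association of variant $j$ and
$\hat\Gamma_j \sim N(\theta\gamma_j + \alpha_j, \sigma_{\Gamma j}^2)$ for
its SNP–outcome association, where $\theta$ is the causal effect of the
exposure on the outcome and $\alpha_j$ is a direct (pleiotropic) effect of
the variant. A valid instrument has $\alpha_j = 0$.

**Wald ratio.** Each SNP identifies $\hat\theta_j = \hat\Gamma_j /
\hat\gamma_j$. Two delta-method standard errors are offered:

* `full_delta` (default):
  $\mathrm{se}(\hat\theta_j) = \sqrt{\sigma_{\Gamma j}^2/\hat\gamma_j^2 +
  \hat\Gamma_j^2\sigma_{\gamma j}^2/\hat\gamma_j^4}$, which propagates both
  sampling errors;
* `first_order`: $\sigma_{\Gamma j}/|\hat\gamma_j|$, which treats the
  exposure association as known. The exposure-side variance term is tiny
  here (per-SNP F statistics in the hundreds to thousands), so the two modes
  differ little for this instrument; both are surfaced because only the
  first-order form makes IVW algebraically identical to weighted regression
  through the origin. The mode used is echoed in run metadata.

**Fixed-effect IVW** (the primary estimator) pools the ratios with weights
$w_j = 1/\mathrm{se}(\hat\theta_j)^2$:
$\hat\theta = \sum w_j\hat\theta_j / \sum w_j$,
$\mathrm{se}(\hat\theta) = (\sum w_j)^{-1/2}$. The fixed-effect choice
assumes one common causal effect across SNPs, and the estimators assume
uncorrelated instruments (the three SNPs are in low linkage
disequilibrium; no correlation structure is modelled).

**Median estimators** (sensitivity). The simple median of the
$\hat\theta_j$ is consistent when at least half the instruments are valid;
the weighted median, when valid instruments carry at least half the total
weight. The weighted median sorts the ratios, forms standardized cumulative
weights $s_j = \sum_{i\le j} w_i - w_j/2$ (weights normalized to sum 1),
and linearly interpolates the ratio where $s$ crosses $1/2$. Standard
errors come from a seeded parametric bootstrap (default $B = 5000$): for
the simple median each replicate draws
$\hat\theta_j^* \sim N(\hat\theta_j, \mathrm{se}(\hat\theta_j)^2)$; for the
weighted median each replicate re-draws $\hat\gamma_j^*$ and
$\hat\Gamma_j^*$ at the summary level and recomputes ratios, their SEs, and
hence the weights, since ratio-level draws could never move the weights. A
seed is mandatory, so bootstrap SEs are bit-reproducible.

**MR-Egger** (pleiotropy check). Weighted least squares of $\hat\Gamma_j$
on $\hat\gamma_j$ with an unconstrained intercept, weights
$1/\sigma_{\Gamma j}^2$, after orienting every SNP exposure-increasing
(the intercept is only identified under that convention). The slope is a
pleiotropy-adjusted causal estimate; the intercept estimates the mean
directional pleiotropic effect, with validity resting on the InSIDE
condition (pleiotropy independent of instrument strength). Inference uses
normal quantiles on the *unscaled* WLS covariance $(X'WX)^{-1}$ — the
fixed-effect convention consistent with known per-SNP outcome SEs and with
the fixed-effect IVW choice. Two consequences are worth knowing: with
$J = 3$ only one residual degree of freedom remains, so the result carries a
`low_df` flag; and when balanced pleiotropy is present the unscaled
covariance understates the intercept's variance by the factor
$1 + \tau^2/\sigma_\Gamma^2$, making the intercept test anticonservative —
mild while $\tau \ll \sigma_\Gamma$, substantial otherwise.

An exploratory male-vs-female z-test,
$z = (\hat\theta_m - \hat\theta_f)/\sqrt{se_m^2 + se_f^2}$, is attached for
every outcome with both sex strata. It is deliberately not
multiplicity-corrected and is labelled exploratory in the outputs.

## Allele harmonization

The two studies need not report each SNP on the same strand or with the
same effect allele. For each instrument SNP found in the outcome scan:
matching allele pairs pass through; swapped pairs flip the outcome beta's
sign and complement its frequency; pairs that match only after strand
complementation (A↔T, C↔G) are complemented and re-matched; anything else
is an error naming the SNP. Every action is written to an orientation log.

Palindromic SNPs (A/T or C/G alleles, identical under strand
complementation) cannot be resolved from alleles alone. The default policy,
`eaf_resolve`, orients them by comparing effect-allele frequencies: if both
studies' frequencies sit on the same side of 0.5 the orientation is
concordant, otherwise flipped. A frequency within 0.08 of 0.5 (or missing)
is treated as uninformative — if *either* side is uninformative the SNP is
dropped, because one ambiguous frequency already makes the comparison
unreliable. The threshold matters here: rs1799945 is C/G palindromic with a
strongly skewed European frequency (≈0.14), so the default policy retains
the published three-SNP instrument while refusing genuinely ambiguous
cases. `keep` (trust same-strand reporting) and `drop` (exclude all
palindromic SNPs) are available; `drop` would silently shrink this
instrument to two SNPs, which is why it is not the default.

SNPs absent from an outcome file are dropped with a logged warning rather
than an error: the sex-stratified releases cover only seven outcomes and may
omit variants, and every estimator is defined for $J \ge 1$ (Egger needs
$J \ge 3$).

## The analysis grid and multiplicity

`run_grid()` crosses every exposure with every outcome and available
stratum, harmonizes, orients, checks instrument strength ($F_j =
(\hat\gamma_j/\sigma_{\gamma j})^2$, flag below 10), and computes IVW plus
the configured sensitivity estimators, attaching the Egger intercept
p-value to each cell. Per-cell failures are recorded and the grid
continues; rows are emitted for null results too.

The primary multiplicity family is the overall grid: with 4 exposures and
12 outcomes at family-wise level 0.05 the per-test Bonferroni threshold is
$0.05/48 \approx 1.04\times10^{-3}$. The taxonomy is `significant` below
that threshold, `potential` between it and the nominal 0.05, `null`
otherwise. Sex-stratified rows are labelled with the same taxonomy but are
not counted in the 48-test family — their `potential` class is the
nominal-0.05 reading used for sex-specific findings; both thresholds are
recorded in the run metadata so the convention is auditable.

Determinism: bootstrap seeds are derived per cell from the base seed and
the cell's identity (exposure, outcome, stratum), not from traversal order,
so a rerun — or a run with outcomes permuted — reproduces every record
exactly.

## The synthetic-data generator

`simulate_cell()` / `simulate_study()` draw summary statistics directly
from the model above: exposure-side and outcome-side errors independent
(two non-overlapping samples), pleiotropy
$\alpha_j \sim N(\mu_\alpha, \tau^2)$ drawn independently of $\gamma_j$
(InSIDE holds by construction). Defaults describe the targeted study
conditions: $J = 3$ instruments with true exposure effects 0.33, 0.19, 0.19
SD per allele and per-SNP F near 1000 (the consortium scale), outcome SEs
of $2\times10^{-3}$ (the scale of linear-model betas for uncommon binary
outcomes in a ~361,000-subject biobank), fixed allele metadata matching the
real instrument — including the palindromic C/G rs1799945 with skewed
frequency — and a null causal effect unless specified. Alleles and true
frequencies are properties of the variant, shared by every file of a study;
observed frequencies jitter (SD 0.01) around the truth in each sample.
`allele_scramble` randomizes the effect/other labelling of outcome rows
and, for non-palindromic SNPs, the reported strand; a strand flip of a
palindromic SNP is mathematically unidentifiable and therefore never
generated. Each study writes a YAML ground-truth manifest (seed, per-cell
$\theta$, pleiotropy draws, scrambles) sufficient to regenerate every file
byte-for-byte.

`fixture_iron_study()` pins a seeded study shaped like the real one — 4
exposures × 12 outcomes, sex strata for 7 — with a qualitative effect
pattern: iron status raises varicose-vein risk in both sexes
($\theta = 0.016$) and protects against coronary atherosclerosis mainly in
males ($\theta = -0.020$ male, $-0.010$ overall, $0$ female), all other
cells null. Exposures marked as inverse iron markers (transferrin) get
sign-flipped true exposure effects, so their implied causal effect is
$-\theta$ — reproducing the direction pattern without any special-casing in
the pipeline. All fixture values are synthetic stand-ins, not consortium or
biobank numbers.

What the generator does *not* emulate: linkage disequilibrium between
instruments, case-control ascertainment, winner's-curse in instrument
selection, sample overlap, and the approximation error of exponentiating
linear-model betas into odds ratios. Tests passing on synthetic data
therefore validate the estimators and plumbing under the assumed sampling
model, not the biology or the data-cleaning of any real release.

## Numerical choices and verification scales

* Odds-scale reporting: $OR = e^\beta$ with Wald interval
  $e^{\beta \pm z_{0.975}\,se}$. For binary outcomes scanned with linear
  models these are approximate ORs; the transform is applied uniformly and
  the caveat documented rather than corrected.
* p-values are never truncated to zero; they are carried at full double
  precision and written in scientific notation.
* Ties and degenerate inputs: a zero exposure beta is a hard error (the
  Wald ratio is undefined and orientation ambiguous); an exactly-zero
  estimate counts as direction-concordant in the sensitivity check.
* Verification scales used by the test-suite and acceptance script, chosen
  to make Monte-Carlo error small relative to the property margins:
  parameter recovery and CI coverage over 1000 simulated cells; IVW type-I
  error over 2000 null cells; Egger intercept calibration over 1000
  replicates at $J = 10$, $\tau = 5\times10^{-4}$ (where the expected
  rejection rate is $2\Phi(-1.96/\sqrt{1+\tau^2/\sigma_\Gamma^2})
  \approx 0.057$); weighted-median robustness over 200 replicates with 4 of
  10 instruments directionally pleiotropic.

## A worked example

```{r example}
study <- fixture_iron_study()
cfg <- study$config
cfg$bootstrap_B <- 500
grid <- run_grid(cfg)
subset(grid, method == "ivw_fixed" & stratum == "all" &
         outcome == "varicose_veins_lower_extremities",
       select = c(exposure, or_point, ci_low, ci_high, pvalue,
                  significance_class))
```

## Known limitations

MR-Egger with three instruments has essentially no power and one residual
degree of freedom; its role here is a directional-pleiotropy alarm, not an
estimator of record. The fixed-effect intercept test is anticonservative
under heavy balanced pleiotropy (above). The harmonization policy for
palindromic SNPs is a documented convention, not a recovered fact about how
any particular published analysis aligned its files. And with a three-SNP
instrument drawn from two genes, the median estimators' "majority valid"
protection is weak — which is exactly why the package reports them as
sensitivity companions to IVW rather than alternatives.
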