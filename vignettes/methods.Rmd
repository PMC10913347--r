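---
title: "Models and methods: frailty-index epidemiology and summary-statistic genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpfrailty)
```

# Scope

`crpfrailty` studies the relationship between a circulating inflammation
marker — high-sensitivity C-reactive protein (hs-CRP, mg/L) — and frailty in
middle-aged and older adults, from two complementary angles:

* **Observational**: a two-wave cohort in which frailty is measured by a
  deficit-accumulation frailty index (FI), and hs-CRP tertiles predict
  incident frailty and pre-frailty progression/regression through logistic
  models.
* **Genetic**: GWAS summary statistics for CRP and for a frailty index,
  analyzed with LD-score regression (heritability, genetic correlation), a
  composite-null pleiotropy scan based on the product of z-scores, and a
  two-sample Mendelian randomization (MR) suite.

Individual-level cohort data and real GWAS downloads are deliberately out of
scope. Instead a synthetic-data module generates both kinds of input with
known ground truth, so every downstream stage is testable end to end.

# The frailty index and its categories

The FI of a subject is the number of health deficits present divided by the
number of items measured (41 items by default), a value in $[0, 1]$.
Categories follow the standard deficit-accumulation cuts: FI $< 0.10$ is
health, $0.10 \le$ FI $< 0.25$ pre-frailty, FI $\ge 0.25$ frailty. Both
boundary values are assigned to the *upper* class (0.10 is pre-frailty,
0.25 is frailty), matching the bracket conventions of the epidemiological
literature this package follows. A subject pre-frail at baseline who is
frail at follow-up has *progressed*; one who is healthy at follow-up has
*regressed*.

Missing items can be handled two ways: by default the FI denominator shrinks
to the measured items; alternatively `impute_deficits()` runs a
chained-equation scheme — each incomplete binary item is regressed
(logistic) on the mean of the remaining items, coefficients are perturbed by
a draw from their asymptotic distribution, and missing cells are redrawn as
Bernoulli over several sweeps. Five imputations are pooled by averaging the
per-imputation FIs. The single-summary predictor (mean of other items) keeps
the scheme stable with 41 collinear binary items; it is a deliberate
simplification of a full one-model-per-item chained system, adequate here
because the items are generated exchangeably.

hs-CRP tertiles use fixed cuts at 0.90 and 2.00 mg/L (boundaries inclusive
to the middle band), with a data-driven mode for other samples.

# Observational models

`or_from_counts()` is the closed form: cross-product odds ratio with the
Woolf interval, $\mathrm{SE}^2 = \sum 1/\text{cell}$. An unadjusted
logistic regression on a single 3-level exposure factor reproduces these
numbers exactly, which the test suite exploits as an oracle pair.
Zero cells fail loudly and offer the Haldane–Anscombe 0.5 correction as an
explicit flag rather than applying it silently.

`run_model_series()` fits the conventional three models: Model 1
unadjusted; Model 2 adjusted for age and sex; Model 3 additionally for BMI,
marital state, smoking, systolic and diastolic blood pressure, drinking,
sleep duration, hypertension, hyperlipidemia, diabetes and cardiovascular
disease. Inference is Wald throughout (CIs agree with the Woolf form in the
single-factor case; profile-likelihood intervals would not). Trend tests
re-enter the tertile as one ordinal score, 0/1/2 by default; scores are a
parameter because tertile medians are an equally defensible coding.
Subgroup analysis refits the model per stratum (dropping the stratifier
from the adjustment set by default, switchable) and tests effect
modification with a likelihood-ratio test on the tertile-by-stratifier
product terms.

Non-linearity uses a restricted cubic spline (natural spline, truncated
power basis) with 4 knots at the 0.05/0.35/0.65/0.95 quantiles — a common
default; the knot vector is a parameter. The odds-ratio curve is normalized
to OR $= 1$ at 1.46 mg/L, and the non-linearity p-value is a
likelihood-ratio test of the nonlinear spline terms against the linear
model.

# Synthetic cohort

`generate_cohort()` draws per-subject baseline deficit propensities from a
Beta distribution (default Beta(2, 14), mean 0.125), giving a realistic
health/pre-frailty mix with a small frail tail; baseline deficit counts are
Binomial(41, propensity). hs-CRP is lognormal with
$\mu = 0.378, \sigma = 0.985$, chosen so the mean is $\approx 2.4$ mg/L and
the sample tertile boundaries fall near the fixed cuts 0.90/2.00.

The wave-2 state (health / pre-frailty / frailty) comes from a
proportional-odds model whose linear predictor contains the baseline
category, the CRP-tertile score (low 0, middle 0.5, high 1) scaled by the
configured `crp_effect_logodds`, and optional covariate effects; cutpoints
are fixed so that a pre-frail subject at the reference tertile progresses
with probability $\approx 0.10$ and regresses with $\approx 0.31$, the
order of magnitude seen in population cohorts of this design. The wave-2
deficit count is then drawn from a Binomial(41, $q$) *truncated to the
count range of the drawn category*, so the FI recomputed from items always
agrees with the drawn state. Under this construction the conditional
high-vs-low odds ratio for any state boundary equals
$\exp(\texttt{crp\_effect\_logodds})$ exactly within a baseline stratum;
marginally (mixing baseline categories, as an incident-frailty analysis
does) the usual non-collapsibility of the odds ratio attenuates it
slightly, which is real behavior, not a generator artifact.

What the generator does *not* emulate: item-level heterogeneity (items are
exchangeable), informative missingness, measurement error in hs-CRP, and
time-varying covariates. Passing tests therefore demonstrate correctness of
the estimators under a clean data-generating process, not robustness to
those real-data complications.

# Synthetic GWAS pairs

`generate_sumstats_pair()` simulates per-SNP z-scores under the standard
polygenic summary-statistic model
$z = \sqrt{N} R \beta + \varepsilon,\ \varepsilon \sim N(0, R)$, per LD
block, where $R$ is block-exchangeable with per-block correlation. This
gives exactly the LD-score regression moments
$E[\chi^2_j] = 1 + N h^2 \ell_j / M$ and
$E[z_{1j} z_{2j}] = \sqrt{N_1 N_2}\,\rho_g \ell_j / M +
\rho\,n_\text{overlap}/\sqrt{N_1 N_2}$,
with $\ell_j = \sum_k r^2_{jk}$ the LD score. Block sizes and correlations
cycle deterministically around their configured centers so that $\ell_j$
varies (a constant LD score would make the regression unidentifiable).

True effects: with `causal_beta = 0`, per-SNP effect pairs are bivariate
normal with correlation `rg`; with a nonzero causal effect,
$\beta_2 = \theta \beta_1$ plus optional horizontal pleiotropy —
`balanced` adds zero-mean direct effects, `directional` adds effects
aligned with the exposure-increasing allele, the scenario that biases IVW
and that median/mode estimators defend against. Sample overlap correlates
the noise of the two traits with coefficient
$\rho\,n_\text{overlap}/\sqrt{N_1 N_2}$, the term the pleiotropy scan's
z-correlation step must detect. Defaults use the sample sizes and
effect scales of large published CRP and frailty-index GWAS
($N_1 = 204{,}402$, $N_2 = 175{,}226$, $h^2 = 0.0442 / 0.1094$,
$r_g = -0.39$) with a sparse 1% causal fraction, which produces
genome-wide-significant loci at realistic strength; LD-score regression
analyses use the polygenic limit (`prop_causal = 1`), the architecture the
method models.

Alleles are random A/C/G/T pairs with a configurable palindromic (A/T,
C/G) fraction whose frequencies sit near 0.5; a quarter of outcome rows
are stored allele-swapped (consistently sign-flipped) and a subset
strand-complemented, so harmonization has real work to do.

# LD-score regression

`ldsc_h2()` regresses $\chi^2_j$ on $\ell_j$ with a free intercept;
slope $\times M/N$ is the observed-scale SNP heritability, and the
intercept absorbs confounding inflation. Weights are $1/\max(\ell_j, 1)$
with a second step that also divides by the squared fitted mean (the
heteroskedasticity of $\chi^2$). `ldsc_rg()` regresses $z_{1j} z_{2j}$ on
$\ell_j$; slope $\times M/\sqrt{N_1 N_2}$ is the genetic covariance, the
free intercept absorbs sample overlap, and
$r_g = \rho_g / \sqrt{h^2_1 h^2_2}$ with both heritabilities re-estimated
on the same SNPs. All uncertainty comes from a delete-one-block jackknife
over contiguous SNP blocks, with the full ratio pipeline re-run inside
every delete-block so the $r_g$ standard error reflects the uncertainty of
the heritabilities too. $|r_g| > 1$ warns rather than errors (it happens by
noise near the boundary). A Bonferroni helper implements the family
threshold $0.05/14 = 3.57\times10^{-3}$ used when this screen accompanies
a 14-test panel.

Numerical notes: delete blocks should be long relative to the LD
correlation length; at 50k SNPs the default 200 blocks (250 SNPs each,
several LD blocks long) gives jackknife SEs within a few percent of the
cross-seed spread. On very short panels (around 10k SNPs) the jackknife
can understate the spread by ~20%; the tests document this regime
explicitly. Heritability is observed-scale only, treating the frailty
index as the quantitative trait it is; no liability conversion is offered.

# Pleiotropy scan

The scan tests, per SNP, the composite null "at most one trait is
associated" using the product $z_1 z_2$. Steps, in order:

1. **Prefilter**: SNPs with $z^2 > 80$ on either trait are removed — such
   SNPs are dominated by single-trait signal and would distort the
   genome-wide variance estimates. The boundary is exclusive ($z^2 = 79.9$
   survives).
2. **Z correlation**: the $2\times2$ correlation of $(z_1, z_2)$ is
   estimated on SNPs null-ish for both traits ($|z| < 1.96$), where it
   reflects sample overlap rather than shared signal. Truncation to the
   null box attenuates the correlation relative to the untruncated value —
   the tests compare against a truncated-normal oracle. When the
   off-diagonal exceeds 0.05, the pair is decorrelated by the symmetric
   inverse square root of the matrix before testing (both the
   decorrelation and variance-only paths exist; decorrelation is the
   default because "accounting for correlation" without it leaves the
   product's null distribution wrong).
3. **Variances**: $\mathrm{Var}(z)$ per trait is the empirical variance
   after the prefilter — the filter exists precisely to keep this estimate
   from being dragged by extreme loci.
4. **P-value**: with $F(x)$ the two-sided tail of the product of two
   standard normals — density $K_0(|t|)/\pi$, integrated by adaptive
   quadrature split at the logarithmic singularity at zero, with the
   exponentially scaled Bessel function beyond $|x|+1$ for conditioning —
   the p-value is
   $F(z_1 z_2/\sqrt{v_1}) + F(z_1 z_2/\sqrt{v_2}) - F(z_1 z_2)$.
   When $v_1 = v_2 = 1$ this collapses algebraically to $F(z_1 z_2)$. The
   combination is an asymptotic approximation and can exceed 1 for small
   products when the variances exceed 1; it is clamped to $(0, 1]$.
5. **Loci**: SNPs below $5\times10^{-8}$ are greedily clumped by ascending
   p-value, absorbing neighbors with $r^2 \ge 0.2$; clump leads within
   500 kb on one chromosome merge into a locus, and each locus reports its
   smallest-p lead SNP.

# Two-sample Mendelian randomization

Instrument selection keeps genome-wide-significant exposure SNPs
($P < 5\times10^{-8}$) and prunes by greedy clumping with the instrument
convention: a SNP survives only if its $r^2$ with every retained index SNP
is *below* 0.01 within a 5000 kb window. Harmonization aligns outcome
effects to the exposure's effect allele (sign-flipping swapped pairs,
resolving strand complements) and drops palindromic SNPs with effect-allele
frequency in $[0.42, 0.58]$ — "intermediate frequency" is not a sharp
term, so the window is a logged, configurable choice. The order is
select → clump → harmonize, mirroring how instrument counts shrink in
published analyses.

Estimators, all authored here on the per-SNP Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SEs:

* **IVW**, fixed or multiplicative random effects (SE inflated by
  $\max(1, \sqrt{Q/(k-1)})$) — the primary estimator.
* **MR-Egger**: weighted regression with free intercept after orienting
  exposure effects positive; the intercept and its test quantify
  directional pleiotropy; $t_{k-2}$ inference with the residual scale
  floored at 1.
* **Weighted median**: weight-interpolated 50th percentile, parametric
  bootstrap SE (1000 draws, seeded).
* **Simple/weighted mode**: mode of a kernel density of the ratios,
  modified Silverman bandwidth times a tunable $\phi$ (default 1),
  bootstrap SEs.
* **Cochran's Q** with $\chi^2_{k-1}$ p-value, and a **leave-one-out**
  table flagging removals that change the sign or move the estimate by
  more than one pooled SE.
* **MR-PRESSO**: leave-one-out weighted residual sum of squares, its
  parametric-bootstrap null, per-SNP outlier p-values (raw bootstrap
  proportions, so the Bonferroni cut $0.05/k$ stays reachable),
  outlier-corrected IVW, and a distortion test comparing the
  outlier-removal shift with random same-size removals.
* **Maximum likelihood**: the per-SNP true exposure effects are profiled
  out, leaving a 1-D minimization of
  $\sum_j (\beta_{Yj} - \theta\beta_{Xj})^2/(s_{Yj}^2 + \theta^2 s_{Xj}^2)$
  plus the log-determinant term — consistent under exposure-side
  measurement error where the plain ratio mean is not.
* **Penalized IVW**: weights multiplied by $\min(1, 20 p_j)$ with $p_j$
  the upper $\chi^2_1$ tail of the SNP's Q contribution.
* **MR-RAPS**: profile-score equations with a method-of-moments
  overdispersion parameter and a Huber $\rho$ (k = 1.345) by default.

When the Egger intercept is significant while IVW remains primary, the
suite attaches a warning instead of switching estimators — the tension is
surfaced, not resolved silently.

# Pipeline and reproducibility

`run_pipeline(run_config(...))` chains the stages in analysis order
(cohort → observational arms → LDSC → pleiotropy scan → MR), derives every
stage seed from one master seed, logs dropped-record counts, traps stage
failures (recorded in the report, with a warning) rather than aborting the
run, and optionally writes per-stage CSV/TSV/JSON outputs plus a
consolidated JSON report. Fixed seed means byte-identical outputs.

`scripts/acceptance.R` re-runs the headline computations from scratch —
the published-count odds ratios, the generator recovery of a 1.66
progression OR (20 cohorts of 50k subjects), pleiotropy-test calibration
at $10^5$ composite-null pairs, LD-score recovery at one 50k-SNP panel,
and the MR pipeline with ~170–200 instruments plus a 300-replicate IVW
coverage check — and writes them to JSON. Problem sizes are chosen so the
full script completes in a couple of minutes while keeping Monte-Carlo
error well inside the tolerances of interest.

# Known limitations

* The exchangeable-block LD world has no long-range LD, no MAF-dependent
  architecture and no population stratification; LDSC intercepts hover at
  1 by construction except under sample overlap.
* Observed-scale heritability only; no partitioned heritability.
* The imputation model is a single-predictor chained scheme, not a full
  MICE system.
* Adjusted (Model 2/3) odds ratios on synthetic data are internally
  consistent but are not expected to match any published cohort's values —
  those depend on the real covariate structure.
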