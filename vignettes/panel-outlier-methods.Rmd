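---
title: "Normalization and outlier-calling methods for targeted MODY expression panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization and outlier-calling methods for targeted MODY expression panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MODYexpress)
```

## The analysis problem

Hybridization-counting panels (nCounter-style) report molecule counts for a
few dozen probes per sample: endogenous targets, spiked positive controls
at a shared titration, empty negative controls, and candidate housekeeping
genes. In a suspected-MODY cohort the scientific question is whether any
patient shows extreme expression of a MODY-associated gene relative to
healthy controls. That question only makes sense after three corrections —
background, per-lane hybridization efficiency, and RNA input amount — and
only for genes that are actually expressed in the sampled tissue (whole
blood, where most pancreatic MODY genes are silent).

## The pipeline model

Let $c_{gs}$ be the raw count of probe $g$ in sample $s$.

**Background.** The negative controls of sample $s$ estimate nonspecific
binding; the threshold is $T_s = \bar{c}^{neg}_s + k \cdot SD^{neg}_s$
(sample SD, $n-1$; default $k = 2$). Counts are never
background-subtracted. Subtraction would produce zero and negative values
that break the geometric means used downstream; the threshold instead
drives a *detectability mask*: an endogenous gene is analyzable when
$c_{gs} > T_s$ (strictly) in at least `detect_min_fraction` of all samples
(default 0.5). Before any log-ratio computation, the values of
housekeeping and detectable endogenous genes that fall below the (equally
scaled) threshold are floored at it.

**Positive-control factors.** With $G_s$ the geometric mean of sample
$s$'s positive probes, every count of sample $s$ is multiplied by
$f_s = \frac{1}{G_s}\cdot\frac{1}{n}\sum_t G_t$. The arithmetic mean of
geometric means is the platform vendor's convention; it makes the factors
average to one on homogeneous cohorts and cancels exactly when all samples
are scaled by a common constant.

**geNorm content normalization.** Reference genes should track RNA input,
not biology. For candidates $j, k$ the pairwise variation is
$V_{jk} = SD_s\!\left(\log_2 \frac{x_{js}}{x_{ks}}\right)$ and the
stability of $j$ is $M_j = \frac{1}{n-1}\sum_{k \ne j} V_{jk}$: a gene
exactly proportional to another has $V = 0$ with it, and genes with
sample-specific regulation inflate every ratio they enter. The least
stable gene (highest $M$) is removed and $M$ recomputed until two remain;
ties in $M$ break lexicographically by gene name so the exclusion order is
deterministic. The number of reference genes is chosen by the
pairwise-variation curve: $V(n, n+1) = SD_s(\log_2 NF_n / NF_{n+1})$ with
$NF_n$ the per-sample geometric mean of the $n$ most stable genes; the
smallest $n \ge 2$ with $V < 0.15$ is selected (0.15 is the algorithm's
canonical recommendation, exposed as `genorm_v_cutoff`), falling back to
all candidates when the curve never drops below the cutoff. The final
un-rankable pair is ordered lexicographically. Content factors are then
computed from the selected genes exactly as the positive factors are from
the positive probes.

**Outlier calls.** For each patient $p$ and detectable gene $g$,
$z_{gp} = (x_{gp} - \mu_g)/\sigma_g$ with $\mu_g, \sigma_g$ the mean and
sample SD of the *controls'* normalized counts. Calls are inclusive:
$z \ge 2$ is `high`, $z \le -2$ is `low`. The z is computed on normalized
counts directly, not on logs — that is the formula as used in this assay
family — and a log-scale variant exists behind `zscore_log_scale` but is
off by default.

**Group statistics.** Patients vs. controls per detectable gene use a
normality-gated test: Shapiro–Wilk on each group at
`stats_alpha_normality` (0.05); both pass → unpaired two-sided Student
t-test (pooled variance, the default of the legacy analysis software this
mirrors; Welch via `stats_var_equal = FALSE`); otherwise a two-sided
Mann–Whitney U (exact for small untied samples, normal approximation with
tie correction otherwise). Constant vectors cannot be Shapiro-tested and
are routed to the nonparametric branch. Correlations with fasting
glucose, HbA1c and C-peptide use Pearson when both variables pass the same
gate, Spearman otherwise, over pairwise-complete observations (fewer than
4 pairs: skipped with a recorded reason). No multiple-testing correction
is applied anywhere, matching the exploratory, per-gene reporting style of
the assay's typical use; this inflates the family-wise error and is a
deliberate fidelity choice, not a recommendation.

## Clinical layer

WHO BMI classes use half-open intervals (normal [18.5, 25), overweight
[25, 30), obese ≥ 30, kg/m²). Glycemic control in treated patients is
dichotomized at the 7 % HbA1c treatment target; the *inclusive* boundary
(poor iff HbA1c ≥ 7.0) is adopted because it is the complement of the
"target < 7 %" criterion, and it is the only reading under which the
shipped 19-patient table reproduces its own summary fraction (12/19 =
63.2 %). Reference ranges: glucose 74–105 mg/dL and C-peptide
0.81–2.85 ng/mL as closed intervals, HbA1c < 5.7 % upper-bound-only.
Missing values are first class: excluded from means and SDs, and every
categorical fraction carries its denominator.

For onset-age stratification, patients with onset exactly 25 years fall in
the *young-onset* stratum (≤ 25 vs. > 25). The data this design mirrors
contain onset-25 patients, and the inclusive-young reading matches the
canonical "presents at or before 25" MODY criterion. The BMI-stratified
contrast is obese vs. normal weight; overweight patients are tallied but
not contrasted.

## The synthetic-data generator

`simulateCohort()` draws, under one seed (8 controls, 19 patients by
default):

* lane efficiencies $e_s = 2^{N(0, 0.3^2)}$ — the per-sample technical
  scale the positive factors must recover;
* negative probes $\sim$ Poisson(10), a realistic empty-probe background;
* 6 positive probes on a shared 4-fold titration (top 25 600 counts)
  scaled by $e_s$ with 5 % log-normal technical noise;
* expressed genes $e_s \cdot b_g \cdot 2^{N(0, \log_2(1.2)^2)}$ (20 %
  biological CV) with baselines $b_g$ on a log-spaced grid
  (100–3000 counts endogenous, 200–8000 housekeeping); three housekeeping
  candidates (EEF1G, G6PD, HPRT1) carry extra 0.5-log₂ per-sample jitter
  so geNorm has something to reject, mirroring a panel in which 5 of 8
  candidates end up as references;
* 12 of the 19 endogenous genes planted at background only (Poisson(10)),
  reproducing the blood-detectability structure in which only APPL1, BLK,
  GLIS3, HADH, IER3IP1, PLAGL1 and UCP2 are analyzable;
* optional planted outlier cells (mean × $2^{fc}$) and a planted stratum
  shift for recovery tests; clinical records with onset ages straddling
  25 and BMI spanning the WHO classes.

Counts are rounded to integers; all draws happen inside a private RNG
scope so the caller's random stream is untouched, and a given
configuration is bit-reproducible.

What the generator does *not* emulate: probe-specific hybridization
affinities, count overdispersion beyond log-normal × Poisson, cartridge
batch effects, RNA-degradation gradients, or any real biological
covariance between genes. Passing recovery tests therefore demonstrates
the pipeline's correctness under its own model assumptions — not that the
assay's biological conclusions transfer to real cohorts.

## Numerical choices and degenerate inputs

* SDs are sample SDs ($n-1$) throughout.
* Negative probes with zero variance yield threshold = mean, with a
  warning; all-zero negatives give threshold 0 and "detectable" then means
  "any nonzero count".
* A gene exactly at its threshold is *not* detectable (strict `>`).
* Zero positive-control or reference-gene counts are hard errors (their
  logs are undefined), named with the offending sample or gene.
* A control gene with zero SD is a hard error for z-scoring, naming the
  gene.
* Self-standardization is exact: controls scored against their own
  reference give per-gene mean 0 and SD 1 to ~1e-12 relative tolerance,
  and the test suite asserts it.

## Known limitations

The dominant statistical limitation is the control-arm size. With µ and σ
estimated from $n$ controls, the z of an independent patient cell is
distributed as $t_{n-1}\cdot\sqrt{1 + 1/n}$ under the null; at $n = 8$,
$P(|z| \ge 2) \approx 0.10$, not the nominal ~0.05 of a known-parameter
z. The recovery suite measures exactly this: planted-outlier sensitivity
≈ 0.97–0.99 at $|\log_2 FC| \ge 1.5$, but a per-cell false-call rate of
≈ 0.09–0.10 — roughly double the 0.05 engineering target asserted in the
acceptance suite, which therefore fails by design rather than be
weakened. Under the null, a 7-gene panel then flags
$1 - 0.9^7 \approx 52\,\%$ of patients by chance alone — context worth
keeping in mind when interpreting per-patient call fractions from cohorts
with single-digit control arms. Larger control cohorts, or calls based on
$t$-quantiles rather than a fixed ±2, would control this rate; the
package keeps the fixed ±2 convention because it is the assay family's
established practice.

Problem sizes in the shipped test and acceptance suites are chosen to
exercise the study-scale design thoroughly while staying desk-scale: the
geNorm oracle comparison runs 200 random matrices up to 6 genes × 8
samples, detectability recovery 100 seeded cohorts, outlier recovery 40
cohorts with 5 planted cells each, and the gated-test type-I simulation
2000 replicates at 8 vs. 19.
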