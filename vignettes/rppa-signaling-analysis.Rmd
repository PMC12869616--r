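---
title: "Moderated differential signaling analysis for RPPA perturbation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated differential signaling analysis for RPPA perturbation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppashift)
```

## The problem this package addresses

Reverse-phase protein arrays (RPPA) quantify a few hundred proteins and
phosphoproteins from cell lysates in parallel. A common experimental design
asks how a *perturbation* (here, one-hour exposure of brain endothelial cells
to soluble amyloid-beta) modulates a *stimulus response* (acute insulin
stimulation measured at phospho-sites such as Akt Ser473). The design that
motivates this package has seven treatment groups — untreated, vehicle,
insulin, two amyloid-beta isoforms alone, and each isoform plus insulin —
with three replicates each, processed in four array runs (batches): the
untreated/insulin pair, each isoform pair, and vehicle alone. Because each
group sits in exactly one batch, every insulin-response comparison is
within-batch by construction, while cross-batch comparisons must be treated
with care.

`rppashift` implements the complete analysis for this kind of study:

1. data handling with loading-factor QC and context-aware probe filtering;
2. per-contrast PCA replicate-coherence diagnostics;
3. a precision-weighted, empirical-Bayes moderated linear-model engine with
   second-order "shift" contrasts;
4. bounded composite scores combining effect size and FDR evidence;
5. invariant-probe inter-batch shift diagnostics;
6. a rule-based classifier of how the perturbation modulates the stimulus
   response; and
7. a synthetic-data generator with known truth that makes the whole pipeline
   testable without any external data.

## Data model and preprocessing

Expression values are log2 relative protein levels as interpolated by an RPPA
core facility from dilution series (the dilution-series fitting itself is out
of scope; values arrive probe-by-sample). Linear-scale input is converted on
read. Samples whose slide-wide loading correction factor CF2 falls outside
the open interval (0.25, 2.5) are flagged — never removed — as
protein-loading outliers.

Probes annotated as biologically irrelevant to the tissue context are
excluded before analysis, except probes whose context tags match the active
analysis context (for example, pericyte-relevant probes are retained when the
pericyte/astrocyte compartment is analysed). The pipeline default is to
filter first and then median-center each sample over the analysis probe set,
because sample medians over the full and the filtered panel differ slightly;
a `center_first` switch reproduces the opposite ordering. Probes with
missing values lose those samples per probe, with degrees of freedom tracked
per probe.

## Replicate-coherence QC

For every two-group contrast, PCA is run on the contrast's samples
(probe-wise centering, no variance scaling, deterministic sign convention
making the largest-magnitude loading positive). Coherence is summarised by

* silhouette widths of the two groups in the space of the components
  explaining at least 95% of the variance (the classic
  `(b - a) / max(a, b)` form; 0/0 is defined as 0), and
* the Mahalanobis distance between the two group centroids in two dimensions
  under the pooled within-class covariance (ridge-regularised only when
  singular).

A contrast is flagged low-coherence when the mean silhouette is below 0.25 or
any sample has a negative width. There is no field consensus on a numeric cutoff for this
flag; 0.25 is this package's default and is deliberately conservative — the
flag never removes samples, it only triggers per-sample precision weighting
in the affected contrast (or the user can force weighting per contrast). The
cutoff is exposed as `coherence_cutoff` in `pipeline_config()`.

## The moderated linear-model engine

Each probe is fit by weighted least squares with cell-means coding (one
coefficient per treatment group, no intercept), giving group means, a
residual variance `s2` on `d = n - g` degrees of freedom, and the average
log2 level `A`.

**Precision weights.** Sample-level quality differences are modelled as
`Var(residual of sample j) = sigma2_probe / w_j`. The weights are estimated by
iterating between per-probe weighted fits and leverage-corrected moment
updates of the sample factors, damped geometrically for stability, normalised
to geometric mean 1, and clamped to [0.05, 20]. Convergence is declared at
1e-3 on the log scale, which is far below the statistical uncertainty of the
weights at these sample sizes; with three replicates per group the
within-group direction of the likelihood is nearly flat, so a tighter
tolerance would only chase noise. Weights are estimated per affected
contrast, on that contrast's samples, not globally.

**Empirical-Bayes moderation.** Residual variances are shrunk under the
scaled-F model `s2 ~ s0^2(A) * F(d, d0)`. On the log scale,
`e = log(s2) - digamma(d/2) + log(d/2)` is an unbiased estimate of
`log(s0^2) - digamma(d0/2) + log(d0/2)` with variance
`trigamma(d/2) + trigamma(d0/2)`, so the hyperparameters follow from moment
matching with a numerical trigamma inverse (Newton iteration, tolerance
1e-8). With `trend = TRUE` the prior location is a lowess curve of `e` on
`A` (span 0.4), accommodating RPPA's intensity-dependent variance; with
`robust = TRUE` the log-variance residuals are winsorised at the (0.05,
0.95) quantiles before moment matching, and probes beyond the upper
winsorisation limit receive a per-probe prior df reduced as
`d0 / (1 + exceedance^2 / var)` (floored at 0.5) so genuinely hypervariable
probes are not over-shrunk. This robust step is a deliberate simplification
of the full robust empirical-Bayes machinery: it preserves the two
properties that matter downstream (outlier-resistant hyperparameters,
reduced shrinkage for outlier probes) with closed-form arithmetic. The
posterior variance is the usual convex combination
`(d0 * s0^2 + d * s2) / (d0 + d)`; if every variance is identical the prior
df is infinite, the posterior collapses onto the prior, and total df is
capped at 1e6 for t quantiles.

**Contrasts.** Any coefficient vector over the fitted groups is supported,
including the second-order shift contrast
`S = (perturbed+stimulus - perturbed) - (stimulus - untreated)` that measures
how the perturbation changes the stimulus response. Standard errors use the
moderated variance, p-values are two-sided on `d + d0` degrees of freedom,
Benjamini-Hochberg correction is applied per contrast, and confidence
intervals use moderated standard errors. Batch is deliberately *not* a model
covariate: group is confounded with batch by design, and every primary
contrast is within-batch or differenced across batches; batch health is
monitored separately (below).

Unit tests cross-check this engine against `limma` (hyperparameters,
posterior variances, moderated t on shared data, and `arrayWeights`
direction), and against closed-form classical t-tests in the `d0 = 0` limit.

## Composite scores

Effect size and evidence are mapped through raised-cosine ramps
`0.5 * (1 - cos(pi * (x - a)/(b - a)))` (0 at or below `a`, 1 at or above
`b`): |LFC| between `a = log2(1.1) ≈ 0.138` and `b = log2(1.5) ≈ 0.585`, and
`-log10(FDR)` between 1 (FDR 0.10) and 3 (FDR 0.001). The signed score is
100 times the geometric mean of the two components, carrying the sign of the
fold change. The geometric mean penalises imbalance, and either component at
zero annihilates the score — an FDR of exactly 0.10 scores zero regardless
of fold change (the ramp start is a closed zero). The exact half-cosine form
is this package's choice within the raised-cosine family; the knot pairs are
the package defaults and are fully configurable.

## Invariant probes and inter-batch shifts

An *invariant probe* is a total-protein probe whose within-batch two-group
95% confidence interval lies entirely within ±0.1 log2 units (inclusive at
the endpoints — strictness is unspecified in the source convention, and the
closed interval is the natural reading) in all three two-group batches, and
which is not on a user-supplied perturbation-sensitivity exclusion list (the
curated list is a required input for real data; the default is empty). This
criterion is intentionally stringent: with three replicates the moderated CI
half-width alone is of order two standard errors, so only quiet, precisely
measured probes qualify, and the set is expected to be a small minority of
the panel.

For each ordered group pair in different batches, per-probe differences of
group means over the invariant set are summarised by an exact Wilcoxon
signed-rank p-value (full conditional null distribution with midranks for
ties up to n = 25, computed by generating-function convolution; normal
approximation with continuity and tie correction above; zeros dropped by
default, with the signed-rank-zero variant behind a flag), the median log2
difference, and the unscaled median absolute deviation (descriptive, hence no
1.4826 consistency factor). A pair is *notable* when p < 0.20 and the
absolute median is at least 0.01. No correction is applied — the module
diagnoses batch effects, it does not remove them.

## Response classification

For every probe with a significant base stimulus response `I`, the contrast
quartet (`I`, `Ia`, `L`, `S`) is pushed through an explicit priority-ordered
rule table: a non-significant shift gives `no_effect`; a shift opposing `I`
gives `reversal` when the response under perturbation is itself significant
and opposite in direction, otherwise `attenuation` when the response shrank,
upgraded to `robust_attenuation` when both `L` and `S` pass a robust tier
(|fold change| beyond 1.5 with FDR below 0.001); a shift in the same
direction gives `augmentation`; anything else is `ambiguous`. Attenuation
calls are co-annotated `saturation_possible` when the perturbation alone
already moved the probe in the stimulus direction in both baseline contrasts
and the final levels do not differ — in that situation true attenuation
cannot be distinguished from a response ceiling. There is no canonical
decision tree for this taxonomy in the field, so this table is the package's
own explicit formalisation; it is deliberately total (every probe matches
exactly one rule, and the rationale string names it) and symmetric under
global sign flips, and its thresholds are ordinary function arguments, so an
alternative tree can be substituted. The robust tier defaults to FDR < 0.001
with fold change beyond 1.5 on both L and S. Probes
without a base insulin response are routed to `classify_basal()`, which
calls a basal perturbation effect only when both baseline contrasts agree in
direction and are both significant.

## The synthetic-data generator

`generate_dataset()` draws
`value = baseline + group_effect + batch_offset + noise` with Gaussian noise
on the log2 scale (the standard RPPA assumption), probe variances from a
scaled-inverse-chi-square prior around an intensity-dependent trend, and
per-sample quality factors dividing the noise variance. Defaults mirror the
study design the package targets and were fixed as the package's study
conditions: 268 probes (62 phospho), seven groups with three replicates in
the four-batch layout, a base insulin effect of 1.0 log2 units, attenuation
factor 0.3, typical residual sd about 0.15 at mid-abundance with a gently
decreasing trend (d0 = 4), invariant anchor probes at sd 0.05, and a −0.15
log2 offset on the vehicle-only run, emulating the systematic displacement
that a solitary vehicle run can acquire in this batch layout. A contamination flag mixes in
3×-sd measurements to exercise robust moderation. A single integer seed
fully determines the output, and the caller's RNG state is restored.

Modulation scenarios (attenuated, reversed, saturated) act on one isoform
arm and leave the other intact, so one dataset exercises both a modulated
and an unmodulated call for the same probe.

What the generator does *not* emulate: spatial slide artifacts, antibody
cross-reactivity, dilution-series nonlinearity, or probe-specific batch
responses (batch offsets are constant across probes within a run, apart from
a doubled-sensitivity probe class). Two consequences matter for
interpretation. First, a constant per-batch offset is removed exactly by
sample-wise median centering, so batch-shift recovery is demonstrated on the
pre-centering matrix; in real data batch effects are probe-specific and
survive centering, which is precisely why the invariant-probe diagnostic
exists. Second, passing tests on this generator shows the statistics are
implemented correctly under the stated model, not that the model captures
every pathology of real arrays.

## Numerical choices and problem sizes

Tolerances and conventions collected in one place: trigamma inversion to
1e-8; lowess span 0.4 with variances floored at 1e-10 before logs; weight
iteration damped, clamped to [0.05, 20], converged at 1e-3 in log units;
silhouette 0/0 defined as 0 and singleton groups given width 0; Mahalanobis
ridge `1e-8 * trace/2` only when singular; exact signed-rank enumeration up
to n = 25; score ties broken by probe id; fold changes of exactly 0 count as
neither up nor down; infinite prior df capped at 1e6 total df.

The shipped test suite validates calibration on simulations sized to run in
minutes on a laptop: pooled type-I error and CI coverage on twenty 500-probe
null datasets (10,000 probe draws), hyperparameter recovery at 200 probes,
batch-offset recovery at 800 probes, and classifier recovery at 200 scenario
probes plus the full default pipeline. These sizes are the package's
verification choices; all of them scale up by changing one argument.

## Known limitations

* The robust moderation step is a simplification (winsorised moment matching
  with heuristic per-probe prior-df reduction), not the full
  robust empirical-Bayes estimator of the limma literature; tests pin its qualitative behaviour.
* The classifier's rule table is a formalisation of a qualitative taxonomy
  (see above) and is exposed as ordinary function arguments rather than a
  frozen constant, so alternative rule sets can be substituted.
* With three replicates per group, the invariant-probe criterion admits few
  probes by design; inter-batch medians over very small invariant sets are
  fragile, and the code warns below five probes.
* The pipeline assumes the seven-group/four-batch layout for its headline
  contrast set; the underlying modules are design-agnostic.

## A worked example

```{r example, eval = FALSE}
library(rppashift)

d <- generate_dataset(sim_config(seed = 7))
report <- run_pipeline(d$expr, d$samples, d$annotation)
report
report$counts
head(report$call_grid)
write_report_bundle(report, "rppashift-report")
```
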