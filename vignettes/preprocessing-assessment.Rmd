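---
title: "Assessing background correction and transformation for spotted microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing background correction and transformation for spotted microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spotglow)
```

## The problem

A one-color spotted microarray yields, for every spot, a foreground
intensity $F$ (mean pixel intensity over the spotted region) and a local
background intensity $B$ (mean pixel intensity of the surrounding region).
$F$ mixes the specific hybridization signal with non-specific noise —
non-specific binding, wash deposits, slide autofluorescence, scanner
optics.  Two early preprocessing choices shape everything downstream in a
two-class comparison: how the background is removed and how the corrected
intensities are transformed.  The choices trade off two failure modes:

* **fold-change compression** — the platform's |log2 fold-change| falls
  short of the truth (as measured by a low-noise reference assay such as
  TaqMan qPCR), concentrated at low intensities;
* **variance inflation at low intensity** — on the log2 scale the replicate
  SD explodes as the corrected intensity approaches zero, degrading
  p-values.

`spotglow` implements four background corrections, the log2 and glog
transformations, the downstream inference chain, and the machinery to
quantify both failure modes against a gold standard — plus a hybrid
transformation that takes fold-changes from the log2 pipeline and p-values
from the glog pipeline of the same correction.

## Background corrections

* **standard** — $F - B$; negative values whenever $F < B$, which become
  missing after log2.
* **none** — $F$ unchanged; positive, but leaves an additive offset that
  compresses fold-changes.
* **edwards** — $F - B$ where that difference exceeds a small threshold
  $\delta > 0$; below it, the smooth monotone positive function
  $\delta \exp\!\big(1 - (B + \delta)/F\big)$.  The branches agree at
  $F - B = \delta$, and the output is strictly positive for any $F > 0$,
  so the log2 pipeline has no missing values.  The default $\delta$ is the
  smallest strictly positive $F - B$ on each array, i.e. as close to plain
  subtraction as positivity allows; spots far below their background are
  then mapped to extremely small positive values, and the resulting log2
  values are extreme — supplying a larger `delta` trades that tail for
  bias.
* **normexp** — models the standard-corrected intensity as
  $X = N + S$ with background noise
  $N \sim \mathcal{N}(\mu, \sigma^2)$ and signal
  $S \sim \mathrm{Exp}(\text{mean } \alpha)$, fitted per array by maximum
  likelihood, and replaces each observation by the posterior mean
  $E[S \mid X = x] = \mu_{sf} + \sigma\,
  \phi(\mu_{sf}/\sigma)/\Phi(\mu_{sf}/\sigma)$ with
  $\mu_{sf} = x - \mu - \sigma^2/\alpha$: strictly positive and monotone.

Numerical choices for normexp: the likelihood is optimized over
$(\mu, \log\sigma, \log\alpha)$ on median-centred, SD-scaled data (the
problem is then scale-free), by Nelder–Mead from a method-of-moments start
(third central moment for $\alpha$, residual variance for $\sigma$) with
deterministic scale-jittered restarts, because the likelihood can be flat
in $\sigma$.  The tail ratio $\phi/\Phi$ in the correction is evaluated
through `log`-scale density and CDF, so the far left tail is stable and
the output never underflows to zero.

## Transformations

The generalized log on the log2 scale is

$$\mathrm{glog}(x;\alpha,\lambda) \;=\; \log_2(e)\,
  \ln\!\Big(x - \alpha + \sqrt{(x-\alpha)^2 + \lambda}\Big),$$

defined and strictly increasing for every finite $x$, including the
negative corrected intensities that break log2.  With $\alpha = 0,
\lambda = 1$ it is $\log_2(e)\,\mathrm{arcsinh}(x)$.  At intensities far
above $\sqrt{\lambda}$ its asymptote is $\log_2(x - \alpha) + 1$; the
additive constant ($\log_2 2$, from $z + \sqrt{z^2+\lambda} \to 2z$)
cancels in every fold-change and is removed by median normalization, so
glog and log2 are equivalent at high intensity in every quantity the
pipeline reports.  For $x - \alpha \ll -\sqrt{\lambda}$ the direct formula
cancels catastrophically; the implementation switches to the conjugate
form $\lambda / (\sqrt{z^2+\lambda} - z)$.

$(\alpha, \lambda)$ are estimated by transform-both-sides maximum
likelihood: replicate measurements within each gene-by-condition group are
modelled as homoscedastic normal after transformation, giving the profile
criterion $\sum \ln J(x) - (N/2)\ln \hat\sigma^2_w$ with Jacobian
$J(x) = 1/\sqrt{(x-\alpha)^2+\lambda}$ and $\hat\sigma^2_w$ the pooled
within-group variance.  A coarse log-spaced $\lambda$ grid (anchored to
the variance of the data, so the estimator is scale-equivariant) crossed
with $\alpha \in [0, \text{5th percentile}]$ is refined by simplex
descent.  Under a two-component error model with multiplicative SD
$\sigma_\eta$ and additive SD $\sigma_\varepsilon$ the variance-stabilizing
value is $\lambda^\ast \approx (\sigma_\varepsilon/\sigma_\eta)^2$, which
the estimator recovers within a small factor on simulated data.  Within
`run_pipeline()` the parameters are estimated on the corrected matrix of
the pipeline's own background correction, so that $\alpha$ absorbs that
correction's residual additive offset — this is why no separate
"normexp + offset" variant is needed.  Degenerate inputs (zero
within-group variance up to floating-point rounding) are rejected rather
than fitted.

## Inference chain

Each pipeline runs correction → transformation → global-median
normalization (per array, subtract the array median and add back the
median of medians; idempotent, leaves within-array differences untouched)
→ replicate-spot averaging (mean of available spots; missing only when all
spots are missing) → per-gene two-group fits → empirical-Bayes moderation.
Fold-changes are condition B minus condition A on the log2 scale.

Moderation shrinks each gene's residual variance toward a prior
$(d_0, s_0^2)$ estimated by matching the first two moments of
$\ln s_g^2$ to the scaled-F prior predictive (digamma/trigamma moment
equations; Newton inversion of the trigamma function).  The posterior
variance is $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the
moderated $t$ has $d_0 + d_g$ degrees of freedom.  $d_0 = 0$ reduces
exactly to the classical pooled t-test; the implementation agrees with an
independent moderated-statistics implementation to floating-point
precision on common inputs (asserted in the tests).

The **hybrid** transformation (`run_pipeline(..., transform = "hybrid")`)
runs both transforms under one correction and combines them:
`logfc` (and the reference intensity) from log2, `t_stat` and `p` from
glog — low compression where it matters, stabilized variance where it
matters.

## Evaluation machinery

All curves share one x-axis: the per-gene reference intensity, the minimum
over conditions of the mean log2 standard-corrected intensity, regardless
of the method being evaluated, so methods are comparable point for point.

* **Compression**: $|\text{logfc}_\text{gold}| - |\text{logfc}|$ per gene
  (positive = attenuation), smoothed by lowess against reference
  intensity; sites are pooled before smoothing.
* **Replicate SD curves**: SD across replicate arrays per gene and
  condition versus the reference mean, per method.
* **Concordance**: Pearson $r$ for linearity; intraclass correlation
  (one-way random effects, single measure;
  $(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+\mathrm{MSW})$) for
  agreement — a uniform halving of fold-changes leaves $r = 1$ but lowers
  the ICC, which is exactly how intensity-dependent compression shows up.
  The variant choice matters: a two-way or consistency ICC would forgive
  scale disagreement.  P-values are compared on the probit scale
  (`qnorm`, clipped to $[10^{-300}, 1 - 10^{-16}]$); small p-values map to
  large negative quantiles, and any monotone relabelling would leave the
  coefficient magnitudes unchanged.
* **Volcano classification**: a gene is called when
  $|\text{logfc}| > 1$ and $p < 10^{-6}$, both strict; the p threshold is
  deliberately severe in lieu of formal multiple-testing adjustment.
  Confusion tables report sensitivity, specificity and accuracy, with
  undefined ratios flagged as `NA` rather than zero.
* lowess defaults: span 0.3, 3 robustifying iterations — robust at the
  gene counts simulated here; both are arguments everywhere.

## The additivity test

If background noise adds to the foreground, then across the replicate
spots of one gene on one array (which share the hybridization signal) the
OLS slope of $F$ on $B$ should be near 1.  `run_additivity_test()`
computes one slope per gene per array, excludes degenerate triplets
(constant $B$), and summarizes with a trimmed mean: 5% trimmed in total,
2.5% per tail — "trim 5%" is ambiguous and the fraction is an argument.
The 95% interval uses the standard error of the trimmed mean from the
winsorized variance; a seeded bootstrap (2000 resamples) is available as a
sensitivity check since the two can differ in skewed slope distributions.
A spatial grid of $B$ by print position plus a grid-neighbour correlation
statistic checks the premise that the local background is driven by
position, not by the spot's own foreground.

## What the generator emulates

`sim_config()` / `simulate_dataset()` generate, per spot,

$$F = \beta\,B + \mu_{g,c}\, e^{\eta} + \varepsilon, \qquad
  \eta \sim \mathcal{N}(0, \sigma_\eta^2),\;
  \varepsilon \sim \mathcal{N}(0, \sigma_\varepsilon^2),$$

with $B$ read off a smooth spatial background field (three seeded cosine
modes per axis, rescaled to the requested SD, default 40 AFU, plus
per-spot noise, default 20 AFU, around a 150 AFU mean), background slope
$\beta$ (default 1: exactly additive), truncation at $F \ge 0$ by
resampling $\varepsilon$ up to 100 times then clipping, and the observed
background equal to the true one.  Defaults describe a low-density
triplicate-spotted cDNA array: 1000 genes, 5 arrays per condition per
site, two sites sharing the truth with independent layouts and fields,
baseline expression $2^{\mathcal{N}(7, 1.8^2)}$ AFU, 30% of genes
differentially expressed with |log2 FC| uniform on (0.5, 6),
$\sigma_\eta = 0.25$, $\sigma_\varepsilon = 50$ AFU.  Under these settings
roughly 10% of spots have $F < B$, so standard subtraction yields negative
corrected intensities and the log2 pipeline produces missing values, as on
real arrays.  The matched gold standard simulates 4 low-noise (SD 0.2
log2 units) replicates per condition and analyses them with the same
linear-model-plus-moderation machinery as the arrays, the way a qPCR
reference panel is processed alongside a microarray study; plain t-test
p-values are available via `moderate = FALSE`, but a bounded-df t
reference scale would differ from any variance-stabilized platform purely
through tail weight.

What the generator does **not** emulate: dye effects (one-color only),
scanner saturation at high PMT voltage, print-tip or batch effects,
gene-specific variance heterogeneity beyond the intensity-driven kind, and
cross-hybridization.  Passing tests therefore demonstrate that the methods
behave as the two-component additive-background model predicts — not that
any particular real platform satisfies that model.

## Problem sizes and determinism

The shipped checks run the full eight-method grid on one site of the
default simulation (1000 genes, 5 + 5 arrays, triplicate spots), recover
the background slope on 294 genes × 20 arrays (5880 slopes), and fit
normexp on $10^5$ draws — sizes at which every qualitative contrast is
stable across seeds while a full run stays in the tens of seconds.  All
randomness flows from a single integer seed through fixed per-stage
offsets, so identical configurations reproduce byte-identical outputs; the
package's analysis functions themselves contain no randomness apart from
the optional bootstrap interval, which takes its own seed.

## Known limitations

* The Edwards threshold rule is a convention; the original smooth-function
  form is specified only qualitatively in the literature, and any function
  meeting the continuity/monotonicity/positivity contract would do.
* Normexp is fitted per array; a global fit across arrays is not offered.
* Only global-median normalization is implemented (no loess between
  arrays, no merged transformation-normalization à la VSN).
* The ICC variant and the per-tail trim interpretation are documented
  choices, not the only defensible ones; both are configurable.
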