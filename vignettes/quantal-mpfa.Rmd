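---
title: "Quantal analysis of evoked EPSCs with synquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of evoked EPSCs with synquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

## The model

synquant analyses unitary excitatory postsynaptic currents (EPSCs) evoked in
a postsynaptic cell by single presynaptic action potentials, recorded in
paired whole-cell configuration. The generative assumption is Katz's
binomial release-site model: a connection consists of $N$ independent
functional release sites, each of which releases at most one vesicle per
action potential with probability $P_r$, and each released vesicle
contributes a quantal charge $q$ (fC) to the postsynaptic response. Under
this model the per-trial EPSC charge has

$$\mu = N P_r q, \qquad
  \sigma^2 = N P_r (1 - P_r)\, q^2, \qquad
  P(\text{failure}) = (1 - P_r)^N .$$

Eliminating $P_r$ gives the variance–mean parabola
$\sigma^2 = q\,\bar I - \bar I^2 / N$. Multiple-probability fluctuation
analysis (MPFA) exploits this: the same connection is recorded under three
to five extracellular Ca^2+^/Mg^2+^ conditions, which move $P_r$ along the
parabola; a weighted fit of $\sigma^2 = A \bar I - B \bar I^2$ across the
per-condition (mean, variance) points then yields $q = A$, $N_{frs} = 1/B$
and per-condition $P_r = \bar I / (N_{frs}\, q)$. At least a three-point
spread in $P_r$ (in practice a severalfold change in mean charge from the
lowest to the highest Ca^2+^) is required for the curvature — and hence
$N$ — to be identifiable.

$N_{frs}$ is reported as a positive real number, never rounded: it is an
estimator of a count, and cohort-level quantities derived from it (sites
per active zone, occupancy) are ratios of means.

## Pairwise variance and point weights

Trial-to-trial variance is estimated with the consecutive-difference
("pairwise") estimator

$$s^2_{pw} = \frac{\sum_{i=1}^{n-1} (x_{i+1} - x_i)^2}{2(n-1)},$$

which is unbiased for iid data but, unlike the ordinary sample variance,
insensitive to slow drift: for a pure linear ramp $x_i = a + b i$ it equals
$b^2/2$ regardless of $n$, while the ordinary variance grows as
$b^2 n^2/12$. The price is efficiency: on iid Gaussian epochs the sampling
variance of $s^2_{pw}$ is
$\sigma^4\,[8(n-1) + 4(n-2)]/[4(n-1)^2] \approx 3\sigma^4/n$, about 1.5
times that of $s^2$. The test suite verifies both properties by simulation.

Fit weights are the reciprocal of the Gaussian-approximation variance of a
sample variance, $\mathrm{Var}(s^2) = 2\sigma^4/(n-1)$, evaluated at the
parabola's *predicted* variances and iterated to convergence
(`fitParabola(reweight = TRUE)`, relative tolerance $10^{-6}$, at most 20
iterations). Constant factors — including the pairwise estimator's 3/2
efficiency penalty — cancel in relative weights, which is why the simple
formula suffices. Exact refinements involving higher moments change the
weights only marginally at the epoch sizes considered here ($n \approx 75$),
as the parameter-recovery study below quantifies.

Numerical guards: predicted variances are floored at $10^{-6}$ of the
largest observed variance before inversion so a degenerate (zero-variance)
point cannot produce an infinite weight; if the reweighted system becomes
singular the last stable fit is kept. If all supplied weights are
non-finite (all-degenerate input) the fit falls back to equal weights with
a warning. A fit whose curvature is non-positive — or negligible, with
$B\,\bar I_{max} \le 10^{-8} A$ — is reported as "no curvature": $q$ is
taken from the initial weighted slope, and $N_{frs}$ is NA rather than a
meaningless huge number.

## Epoch stability

Long MPFA recordings are screened for rundown with a regression of EPSC
charge against time within each epoch. The acceptance rule is
$|\text{slope}| < 0.05$ with charge normalized to the epoch mean and time
to the epoch duration, i.e. less than 5 % systematic drift across the
epoch; the normalization makes the criterion scale-free, and the
inequality is strict (a drift of exactly 5 % fails, with a small
floating-point guard so the boundary is decided deterministically).

One practical consequence matters for simulation studies: at low $P_r$ the
trial-charge coefficient of variation approaches
$\sqrt{(1-P_r)/(N P_r)} \gg 1$, so the sampling SD of the fitted normalized
slope ($\approx CV / (0.29\sqrt{n})$) is several times the 0.05 bound even
for perfectly stationary epochs. The criterion is therefore a *drift
guard* for recorded data, not a statistical test; `varianceMeanPoints()`
lets the caller keep flagged epochs (`requireStability = FALSE`, each kept
epoch logged with a warning), and all simulation studies in this package
run with that override.

## The synthetic-data generator

`simulateTrialCharges()` is the generative twin of the model above, with
three variability terms layered on the Bernoulli release sum:

* `cvIntra` (default 0.3 where quantal noise is wanted) — independent
  multiplicative noise per released vesicle per trial, drawn
  $\mathcal N(1, cv)$. Moments are exact ($\mathrm{E}=q$,
  $\mathrm{Var}=q^2 cv^2$); at $cv = 0.3$ a draw is negative with
  probability $\approx 4\times10^{-4}$, which is tolerated rather than
  truncated so the closed-form moments used as test oracles stay exact.
  Intra-site variance inflates the fitted $q$ by exactly $(1 + cv^2)$ in
  expectation — the variance–mean slope at the origin is $q(1+cv^2)$ —
  while leaving $N_{frs}$ unbiased; the estimator-bias study checks the
  predicted 1.09 inflation at $cv = 0.3$.
* `cvInter` (default 0) — per-site quanta drawn once per experiment and
  shared across epochs. This is a simulator-only feature: the single-$q$
  binomial moments (and MPFA itself) do not model unequal site quanta, so
  `theoreticalMoments()` deliberately excludes it. The relative sizes of
  intra- and inter-site quantal variance at these synapses are unknown;
  the defaults are placeholders, not claims.
* `noiseSd` — additive Gaussian baseline charge noise, and
  `driftPerEpoch` — linear multiplicative scaling of the quantal content
  reaching $(1 + d)$ at the epoch end, included so the stability criterion
  and the drift-robustness of the pairwise variance can be exercised.

The default study design mirrors the experimental one: four calcium
conditions (0.5/1.5/2/4 mM) with $P_r = \{0.1, 0.33, 0.5, 0.8\}$, 75
trials per epoch at 5 s inter-stimulus intervals, and (for the human-like
reference connection) $N = 20$, $q = 40$ fC. Seeding is hierarchical: one
master seed per experiment; per-epoch seeds derived by fixed integer
arithmetic so each epoch is independently reproducible.

Rendered traces use a negative-going alpha function
$I(t) = -A\,(t'/\tau)\,e^{1 - t'/\tau}$ with $A = \text{charge}/(\tau e)$,
so the requested charge equals $\int |I|\,dt$ exactly. The waveform is a
rendering surrogate — only its kinetic summaries are meaningful — since
real EPSC shapes are never specified beyond latency, 10–90 % rise, 37 %
decay and charge.

What the generator does **not** emulate: series-resistance changes and
their compensation, receptor saturation/desensitization (handled
pharmacologically in the recordings this models), correlated or
non-Gaussian baseline noise, stimulation artifacts, multi-peaked or
asynchronous release, and spontaneous events. Passing recovery tests
therefore show correctness of the estimators under the stated model, not
robustness to every pathology of real recordings.

## EPSC detection conventions

Detection follows the standard threshold scheme: baseline and noise SD are
estimated from the pre-stimulus window (baseline = window mean; at least
50 samples required), and the first post-stimulus deflection beyond
$k \times SD$ (with $k \in [2,4]$, default 3) is a candidate event. The
event is accepted only if threshold is reached within 2 ms of the stimulus
(onset time limit) and the peak within 3 ms of the threshold crossing
(peak time limit); otherwise the trial is a failure and carries no
kinetics. Onset is defined by back-projecting the 10–90 % rise slope line
to baseline — the onset concept is named but not defined in the detection
settings this reproduces, so the definition is isolated in one place and
can be swapped. All level crossings (10 %, 90 %, 37 %) are linearly
interpolated between samples; the 37 % decay is read directly off the
trace rather than from an exponential fit, since "decay (37 %)" names a
level, not a model. Charge is the trapezoidal integral of the
baseline-subtracted current magnitude from onset until the current returns
within one noise SD of baseline after the peak, capped at 50 ms; 1 pA·ms
is reported as 1 fC. Latency is referenced to the caller-supplied stimulus
time.

## Ultrastructure rules

Vesicle classes are defined on the scalar membrane-gap distance (outer
vesicle leaflet to inner plasma-membrane leaflet): docked = direct
contact, operationalized as $\le 0.5$ nm to absorb measurement
quantization; pre-docked $\le 5$ nm without contact; pool $\le 100$ nm;
outside beyond. All bounds are closed on the upper end, so boundary values
deterministically fall in the inner class, and the four classes partition
every distance. Docked + pre-docked form the membrane-proximal pool.
Whether a published "within 100 nm" measures from vesicle centre or
membrane is left to the data producer — distances enter as pre-measured
scalars. `generateActiveZone()` draws distances uniformly from each
class-defining interval (pre-docked from (0.5, 5] nm so the
generator/classifier round trip is exact), `boutonVolumeSphere()`
implements the spherical approximation
$V = \tfrac{4}{3\sqrt{\pi}}\,\text{area}^{3/2}$ from the largest
cross-section, and `azSummary()` delegates the docked-count-vs-area rank
correlation to `stats::cor(method = "spearman")`.

## Derived cross-species metrics

`derivedReport()` combines cohort means: release sites per AZ = mean
$N_{frs}$ / mean $N_{lm}$ (valid because each bouton contains a single
AZ), AZ area per release site, and docking-site occupancy = mean docked
vesicles per AZ divided by sites per AZ. All ratios are computed from
unrounded means; presentation rounding (one decimal, or appropriate
significant figures) is applied only when printing, which is how the
published one-decimal figures arise. Occupancy is an estimate ratio, not a
probability: values above 1 are reported with a note, never clamped. The
rat-to-human age conversion is the linear map
$\text{years} = 12 + (\text{day} - 38)/3.3$, anchored at sexual maturity.

```{r derived}
hu <- readCohortSummary(system.file("extdata", "cohort_summary_human.json",
                                    package = "synquant"))
rt <- readCohortSummary(system.file("extdata", "cohort_summary_rat.json",
                                    package = "synquant"))
derivedReport(hu, reference = rt)
derivedReport(rt, reference = rt)
```

## A full synthetic round trip

```{r roundtrip}
conds <- data.frame(label = c("0.5Ca", "1.5Ca", "2Ca", "4Ca"),
                    ca_mM = c(0.5, 1.5, 2, 4),
                    p_r = c(0.1, 0.33, 0.5, 0.8))
exp <- makeExperiment(QuantalParameters(nSites = 20, q = 40), conds,
                      nTrialsPerEpoch = 75, seed = 1)
fit <- suppressWarnings(mpfa(exp, requireStability = FALSE))
fit
```

## Problem sizes and known limitations

The packaged simulation studies use 100 experiments of 4 × 75 trials for
parameter recovery and 200 experiments of 4 × 300 trials for the
estimator-bias study — sizes at which the recovery medians are stable to a
few percent while the whole suite runs in seconds. Known limitations:
$N_{frs}$ from a 3–5-point parabola is noisy for any single connection
(the recovery criteria are therefore on medians across experiments, as the
cohort comparisons are on means); the Gaussian variance-of-variance weight
is an approximation, adequate at these epoch sizes but not exact; the
stability criterion is a drift guard, not a test, and must be overridden
for high-variance simulated epochs; and the alpha-function surrogate
cannot validate detection against real waveform diversity.
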