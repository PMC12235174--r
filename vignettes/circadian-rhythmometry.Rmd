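---
title: "Circadian rhythmometry of bioluminescence reporter assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian rhythmometry of bioluminescence reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circalum)
```

## The measurement and the analysis problem

Luciferase transcriptional reporters turn promoter activity into light. In
a typical *C. elegans* plate assay, populations of ~50 adult nematodes sit
in the wells of a 96-well plate inside a luminometer; each well is
integrated for a few seconds every 30 minutes, for three days under a dual
entraining cycle (12:12 light/dark combined with a cold/warm cycle, ZT0 =
lights-on and cold onset) and then three days under constant darkness and
temperature (free run, "DD/WW"). Recording conventionally starts at ZT12.

The raw trace of a well is not a clean oscillation. It rides on a large
baseline, climbs over the first day while luciferase accumulates, decays
over days as substrate is consumed and the population ages, and carries
shot-to-shot noise. The scientific questions are nevertheless simple:

* does a well oscillate, and with what period, amplitude and peak time
  (acrophase)?
* do the acrophases of many wells cluster, i.e. is the population
  synchronized to the zeitgeber?
* do two strains differ in their endogenous (free-running) period?
* does an independent qPCR time course of a transcript cycle?

`circalum` implements this chain: trace preprocessing, Lomb-Scargle
period estimation, cosinor fitting and rhythmicity classification,
circular statistics of acrophases, group comparisons, and qPCR analysis
(2^-ddCt quantification plus a JTK_CYCLE rhythm test) — together with a
synthetic-plate generator so that every stage can be verified against
known ground truth.

## The synthetic plate generator

`generateTrace()` simulates one well as

$$y(t) = e(t)\,\big[M + A\cos\theta(t)\big] + \varepsilon_t, \qquad
  e(t) = \big(1 - e^{-3t/T}\big)\, e^{-\lambda t},$$

a structure chosen as the simplest one that the preprocessing chain is
designed to invert: a baseline plus an enveloped cosine plus additive
Gaussian noise. The envelope combines a saturating ramp over the
accumulation transient $T$ (the ramp reaches 95% of its plateau at $T$)
with exponential damping at rate $\lambda$; both baseline and oscillation
share it, as they do in real recordings where the reporter chemistry
scales the whole signal. The oscillation runs at the entrained period
until release and at the free-running period $\tau$ afterwards, with a
phase-continuous transition (a `phaseOffsetAtRelease` parameter exists to
emulate acrophase shifts at release, default 0). A Bernoulli draw decides
whether a well is rhythmic; arrhythmic wells get $A = 0$ but the same
envelope and noise stream.

Defaults are the recorded study conditions where these are stated — 30 min
sampling, 3 entrained + 3 free-running days, recording start ZT12,
entrained peak at ZT18 (night/warm phase), a 24 h accumulation transient —
and otherwise values a plate-assay practitioner would call realistic,
fixed once:

| parameter | default | rationale |
|---|---|---|
| `mesor` | 1000 counts | typical net plate signal scale |
| `amplitude` | 400 counts | robust but not overwhelming oscillation |
| `dampingRate` | 0.01 / h | signal halves in ~3 days, visible decay by day 6 |
| `noiseSd` | 150 counts | per-bin noise giving fit $R^2 \sim 0.6$–$0.9$ on rhythmic wells |
| `fractionRhythmic` | 0.5 | plate assays of this kind score roughly half of wells rhythmic |

What the generator deliberately does **not** emulate: luciferase reaction
kinetics, temperature compensation, masking (direct stimulus effects on
the reporter), inter-well optical crosstalk, or non-Gaussian outliers from
condensation and bubbles. Tests passing on synthetic plates therefore
demonstrate the correctness of the estimators under the assumed signal
model, not robustness to every artifact of real plates.

Per-well seeds are derived deterministically from the plate seed
(`(seed * 10007 + wellIndex * 7919) mod (2^31 - 1)`), so wells are
independent but a plate is reproducible from a single integer.

`generateCtTable()` plants a known relative-expression profile in a
replicate Ct table under the perfect-doubling model (target Ct shifted by
$-\log_2$ of expression), sampled every 4 h from ZT1 over one entrained
and two free-running days — the design of a bulk-RNA qPCR time course.

## Preprocessing

`runPreprocess()` applies, in order:

1. **background subtraction** — a scalar plate blank;
2. **transient trimming** — the first 12–24 h (default 24) are removed,
   because early signal reflects luciferase accumulation, not promoter
   rhythm; times stay on the absolute hours-from-start axis so the ZT
   mapping survives;
3. **detrending** — subtraction of a centered moving average over 24 h: a
   full-period average annihilates a 24 h oscillation's mean, so the
   baseline is removed while the rhythm passes essentially intact;
4. **smoothing** — a centered 2 h moving average;
5. **normalization** — division by the maximum over the first 24 h after
   trimming, making traces comparable across wells (that window's maximum
   becomes exactly 1).

Numerical choices worth stating. Windows are defined on the *time* axis
(all samples within half a window of $t$), symmetric and inclusive of both
endpoints, so recordings with gaps — the plate regularly leaves the
luminometer to see the zeitgeber — are handled without special cases, and
a moving average reproduces any straight line exactly in its interior. At
the edges the average runs over the available part of the window, which
distorts the detrended signal within half a window of the recording's
ends; the pipeline therefore excludes those samples from period fitting
(`edgeExclusion`, default half the detrend window — measured on noiseless
synthetic plates, this one choice removes a period bias of up to ~0.6 h
for long-period traces). The normalization order follows the wording
"detrended, smoothed and normalized" as written; a dead well (no positive
signal in the normalization window) is an error that the plate-level
pipeline logs and skips.

## Period, acrophase and rhythmicity

**Lomb-Scargle.** `lombScargle()` computes the classical
variance-normalized Scargle periodogram with the per-frequency time
offset, on a frequency grid from 1/37 to 1/18 cycles per hour with step
$1/(30 \times \mathrm{span})$ — an 18–37 h search window with
oversampling 30, both bounds included. The estimate is invariant under
affine transforms of the values and under time translation, and on evenly
sampled data it coincides with the classical DFT periodogram (a test
asserts equality to 1e-8 against an independently coded DFT oracle).

**Cosinor.** `cosinorFit()` minimizes
$\sum_j\{y_j - [M + A\cos(2\pi(t_j-\phi)/\tau)]\}^2$. For fixed $\tau$
the problem is linear after the sine/cosine expansion and is solved in
closed form. For free $\tau$ the period is *profiled*: the closed-form SSE
is evaluated on the periodogram's own grid and the best grid point is
refined by a bounded one-dimensional search. This sidesteps the
initialization fragility of generic nonlinear least squares — the
objective in $\tau$ has many local minima, and a Gauss–Newton iteration
started at a wrong period happily converges to a harmonic — while
minimizing the identical objective (a test shows closed form and an
iterative minimizer agree in SSE to 1e-8). Amplitude is reported
non-negative with the acrophase folded accordingly; acrophases map through
the recording's ZT offset and are reported modulo 24.

**Classification.** Under entrainment, a trace with a ~24 h period and
$R^2 \ge 0.5$ is *Synchronized*; under free run, a period anywhere in the
circadian 18–37 h window with $R^2 \ge 0.5$ is *Circadian*; anything else
is *Arrhythmic*. All bounds are inclusive. The "~24 h" rule carries no
published width; `tol24` defaults to 1 h — sampling, grid resolution and
noise make exactly 24.00 h unattainable — and is configuration-exposed.
Because classification gates on the cosinor $R^2$, no Lomb-Scargle
false-alarm calibration is attempted.

**Peak phases.** For Rayleigh plots the phase of interest is the observed
bioluminescent peak, not the fitted acrophase: `findPeakPhases()` returns,
per 24 h cycle, the clock time of the smoothed trace's maximum, and for
the free-run summary only the first post-release peak. Both peak phase
and cosinor acrophase are reported per well.

## Circular statistics

Acrophases live on a 24 h circle, so `circularSummary()` treats each
phase as a unit vector: the resultant length $R \in [0,1]$ measures
clustering (1 = identical phases, 0 = perfect cancellation) and the mean
vector's direction is the mean phase. Uniformity is tested with the
Rayleigh test using Zar's closed-form approximation
$p = \exp\{\sqrt{1+4n+4(n^2-R_n^2)} - (1+2n)\}$, $R_n = nR$, whose size
at $n = 14$ is verified by simulation to sit inside $[0.04, 0.06]$ at
$\alpha = 0.05$. The phase standard error uses Fisher's circular
dispersion $\hat\delta = (1-\hat\rho_2)/(2\hat\rho_1^2)$,
$\mathrm{SE} = \sqrt{\hat\delta/n}$, converted to hours; for tight
clusters this agrees with the familiar linear SEM, which is how published
"mean ± SEM" phases are most naturally read. A summary with $R < 0.3$ is
flagged *dispersed*: its mean phase is reported but should not be
over-interpreted — free-running acrophase distributions with $R$ near 0.1
do occur in weakly entrained designs.

## qPCR: 2^-ddCt and JTK_CYCLE

`ddct()` averages replicate Ct values per timepoint and gene, forms
$\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{reference}$ against an
invariant housekeeping gene, references a calibrator timepoint (default:
the earliest, typically ZT1), and returns fold changes $2^{-\Delta\Delta
Ct}$ — exactly 1 at the calibrator. When target and reference reactions
pair by sample, a per-replicate SEM is attached.

`jtkCycle()` is a from-scratch implementation of the JTK_CYCLE scheme:
the series is rank-correlated (Kendall's tau-b) against cosine reference
waveforms over a grid of candidate periods (default {20, 24, 28} h for
4 h sampling) and phase lags on the sampling grid; the family of
per-(period, lag) p-values is Bonferroni-corrected and the minimum is
reported. The p-value of the Kendall score $S$ comes from its *exact*
null distribution, built by a q-multinomial recurrence conditioned on the
reference template's tie structure — templates sampled every 4 h over
several days repeat values across cycles, and ignoring those ties would
misstate the null. The exact null is used up to $n = 50$ (it is cheap:
the distribution has $O(n^2)$ support); beyond that a normal
approximation with tie and continuity corrections takes over. Ties in the
*data* make the exact lookup conservative; a constant series carries no
rank information and is reported with $p = 1$ outright. Being rank-based,
the test is invariant under monotone transforms of expression.

Replicates are averaged to one value per timepoint before ranking (the
JTK convention). Entrained and free-running days are analyzed jointly by
default, matching how a combined qPCR time course is usually tested;
`dailyPatternSummary()` adds a purely descriptive day/night block
comparison.

## Group comparisons and the pipeline

`comparePeriods()` compares per-well period estimates between strains
(unpaired; Welch's t is the headline statistic, with the pooled-variance
test also emitted) or between conditions within wells (paired), each with
a Shapiro-Wilk normality check on the relevant quantity. Sidak-style
multiplicity handling only matters for >2 groups and is out of scope for
the two-strain design; two-group runs report raw p-values.

`runFullPipeline()` chains everything per well, skips failing wells with
a logged reason (every well ends in exactly one of results, dead-well log,
or error log), summarizes acrophase circular statistics per strain and
condition over rhythmic wells, tallies percent rhythmic, and writes CSV
tables plus a JSON manifest embedding all parameters and the plate seed.
Given identical inputs the output is byte-identical — there is no hidden
randomness anywhere downstream of the generator.

```{r pipeline-example, eval = FALSE}
plate <- generatePlate(
  list(GenotypeSpec("control", periodFreerun = 24.2),
       GenotypeSpec("mutant", periodFreerun = 27.1)),
  nWells = 30, seed = 1)
res <- runFullPipeline(plate)
res$comparisons$freerunBetweenStrains
```

## Verification strategy and problem sizes

Every estimator is tested against an independent oracle rather than
against itself: the periodogram against a DFT periodogram, the cosinor
against an exhaustive (period, acrophase) grid search and an iterative
minimizer, Kendall's tau against pair enumeration and the classical
implementation in `stats`, the exact S-null against the classical exact
Kendall test in the untied case, the preprocessing chain against
brute-force double-loop moving averages, and t statistics against the
textbook formulas. Calibration claims are checked by seeded Monte Carlo
at the sizes the claims are made for: the Rayleigh size with 10,000
uniform samples of $n = 14$; JTK's type-I rate on 1,000 null Ct tables
and its power on 200 tables with a planted 24 h, 2-fold rhythm at 0.25
cycles of Ct noise; and end-to-end period recovery on 100 replicate
plates of 30 control (τ = 24.2 h) + 30 mutant (τ = 27.1 h) wells, the
two-strain design at its published scale. These sizes keep the whole
suite and the reproduction script each within a few minutes on one CPU
while leaving Monte Carlo error well below the tested margins.

## Known limitations

* The moving-average detrend attenuates non-24 h rhythms by the
  Dirichlet-kernel gain of the window; period estimates are unaffected
  (the filter is zero-phase), but fitted amplitudes after preprocessing
  are relative, not absolute.
* The "initial maximum" normalization is sensitive to noise spikes inside
  the normalization window; no outlier rejection is attempted.
* The Synchronized/Circadian rules inherit the sharpness of their
  thresholds: a well with $R^2 = 0.49$ is Arrhythmic by definition, and
  percent-rhythmic tallies move accordingly.
* JTK's Bonferroni correction over the period x lag family is
  conservative, the more so the denser the candidate grid.
* Population-mean analysis (fitting the mean trace of a well group) is
  available by averaging wells upstream, but uncertainty then reflects
  the mean trace, not well-to-well variability.
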