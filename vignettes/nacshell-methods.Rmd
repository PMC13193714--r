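---
title: "Models and methods behind nacshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nacshell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacshell)
```

nacshell implements the computational side of a study of functional
gradients along the rostro-caudal axis of the medial nucleus accumbens
shell (medNAcSh): event-locked fiber-photometry analysis of D1-SPN
population calcium signals, scoring of the behavioral assays the
recordings accompany (unpredicted reward consumption, optogenetic
free-licking blocks, real-time place preference/avoidance), marker
co-expression quantification in single-cell count data and classified
FISH cells, and the inferential statistics used throughout (paired
t-tests, two-way mixed repeated-measures ANOVA, Sidak post-hoc
contrasts). Because raw in-vivo recordings for such studies are rarely
deposited, the package ships generative simulators for every input class;
all downstream stages are validated against the simulators' known ground
truth.

## The photometry signal model

A session records two co-registered channels at 1017.3 Hz: the
calcium-dependent signal (465 nm excitation, `F`) and the isosbestic
reference (405 nm, `F_iso`), at which the indicator's fluorescence is
calcium-independent. The simulator generates

* `F(t) = B_s(t) (1 + dff(t)/100) + m(t) + e_s(t)`
* `F_iso(t) = B_i(t) + c m(t) + e_i(t)`

where `B_s`, `B_i` are single-exponential photobleaching decays, `m` is a
shared slow motion artifact, `e` is white measurement noise, and `dff` is
the true normalized calcium signal carrying event-locked transients. The
design choices:

* **Motion as an Ornstein–Uhlenbeck process** (default SD 0.02 a.u.
  against a 2 a.u. signal level, time constant 10 s): fiber bending and
  headstage micro-motion produce slow, mean-reverting, shared drift —
  exactly the artifact class the isosbestic regression targets. The
  discretization is the exact AR(1) recursion, so statistics are
  rate-independent.
* **Single-exponential bleaching per channel.** Fast early bleaching is
  handled by the pipeline's 3-min trim; what remains is slow, so the
  default time constant is 3600 s for both channels. Both wavelengths
  bleach the same fluorophore, so equal *typical* rates are the right
  cohort-level default; per-animal differences in either direction are
  introduced by the cohort simulator (log-normal jitter, SD 0.2 on the
  log, on each channel's constant independently). This matters: a *fixed*
  rate mismatch between channels would leave a residual within-window
  trend of constant sign in every animal after the isosbestic fit —
  a systematic artifact real cohorts do not share — whereas per-animal
  variation yields zero-mean between-animal variability that a paired
  test absorbs correctly.
* **Isosbestic coupling `c = 0.75`**, the 405/465 brightness ratio:
  mechanical artifacts scale with the amount of light collected, so the
  artifact's gain into each channel tracks that channel's fluorescence
  level. With this default the regression slope that removes motion also
  removes the (equal-rate component of) bleaching.
* **Event transients** are difference-of-exponentials kernels
  `k(t) = exp(-t/decay) - exp(-t/rise)` (defaults rise 0.5 s, decay 2 s)
  normalized to unit analytic peak, so a configured amplitude of −3%
  means the true `dff` reaches exactly −3% at the kernel peak. Pauses are
  negative, excitations positive; validation enforces the sign.

## The preprocessing pipeline

Stage order is fixed: 10× block-mean downsample (1017.3 → 101.73 Hz),
zero-phase 1 Hz low-pass, 3-min start trim, then per-event window
extraction, isosbestic fit, and ΔF/F0 conversion.

* **Block means rather than decimation** give the 10× count reduction and
  act as anti-aliasing ahead of the filter. The nominal "100 Hz" working
  rate is carried exactly as 101.73 Hz; all window indices derive from
  the true rate.
* **The low-pass filter** is a 2nd-order Butterworth applied forward and
  backward (4th-order zero-phase overall). Initial conditions are set to
  the first sample's steady state and the input is odd-reflection padded,
  so a constant trace passes through bit-exactly and edge transients are
  suppressed. The realization is a contract tested through its frequency
  response: unit DC gain, <1% loss at 0.1 Hz, ≥20 dB attenuation at five
  times the cutoff. Both channels are filtered identically (symmetric
  treatment); a `channels` argument exposes signal-only filtering.
* **Trimming** removes samples before 180 s but preserves absolute time:
  events keep their clock and events inside the trimmed span are flagged
  excluded rather than silently dropped.
* **The isosbestic fit** is an ordinary least-squares regression of the
  signal channel on the isosbestic channel, computed independently per
  event window (default −10 to +20 s, configurable to +30 s), giving
  `F0 = a F_iso + b`. ΔF/F0 is `(F − F0)/F0 × 100`; a non-positive `F0`
  is a hard error identifying the offending samples, never a silent clip.
* **Baseline correction** subtracts each trial's mean ΔF/F0 over −10 to
  −1 s, making the per-trial baseline mean exactly zero.

Epoch quantification uses a baseline epoch of −6 to −1 s and an event
epoch of 0 to 5 s, both closed at the ends (at a 1 Hz bandwidth the
boundary choice is immaterial, but it must be fixed for reproducibility).
Area under the curve is trapezoidal — exact for affine traces, second-
order accurate otherwise — and peak extrema are the sample extrema within
the epoch. Metrics are computed on each animal's trial-averaged trace,
matching the convention in which the t-test's `n` equals the number of
animals; a `per = "trial"` option exposes the alternative. Reward-task
heatmaps keep one row per animal, aversive-task heatmaps one row per
trial; pause responses are summarized by epoch minima, excitations by
maxima, both overridable.

## Behavioral scoring

* **Reward task**: 30 trials of 10 s reward access at uniform random ITIs
  (30–50 s in the testing stage). A trial succeeds iff at least one lick
  falls inside the closed window `[onset, onset + 10]`; the first such
  lick is the photometry alignment event. Reported percentages are
  rounded half-up to integers (16.2/30 → 54%, 17.67/30 → 59%,
  18.5/30 → 62%). Training criteria: 10 successes (tethering stage), 12
  (testing stage); the free-licking task advances when the relative
  difference of the last two sessions' lick counts is below 30% — the
  "variability" wording is interpreted as `|L1 − L2| / mean(L1, L2)`, and
  documented as such.
* **Optogenetic blocks** are half-open `[start, end)`, partitioning the
  session without double counting. Epoch-type means average per-block
  rates (identical to pooling for the equal-duration published designs,
  and the sensible generalization otherwise); consumption inhibition is
  the strict inequality `mean_nonopto − mean_opto > 0`.
* **Place preference** attributes each inter-sample interval to the
  chamber of its first sample and each movement step to the chamber where
  the step starts, so the two chambers' time fractions always sum to
  100%. The stimulated side on days 2–3 is the side preferred on day 1;
  an exact 50/50 tie goes to chamber A with a warning (a case the
  protocol never produces).
* **Metabolic records**: Weir energy expenditure `3.9 VO2 + 1.1 VCO2`
  (kcal, volumes in L) and respiratory quotient `VCO2/VO2`.

The behavioral simulators use homogeneous Poisson lick trains (rate 2 Hz
during access; laser blocks multiply the rate by a suppression factor),
which make block means analytically predictable. Engaged reward trials
(probability `p_engage`, default 0.6 — the published cohorts collect
roughly half to two thirds of rewards) are guaranteed at least one lick;
the task protocols do not state lick statistics, so these are simulator
defaults, not claims about the source data. Place-preference dynamics are
a two-state continuous-time chain with per-chamber exit rates, positions
sampled uniformly at 10 Hz inside the current 30 × 30 cm chamber — enough
structure for occupancy and distance contracts, with no pretense of
modeling trajectories.

## Expression quantification

Count matrices are filtered in a single pass, the convention of standard
single-cell loaders: genes detected (count ≥ 1) in ≥ 3 cells and cells
with ≥ 1250 detected genes, both evaluated on the input matrix. (The
filter is consequently idempotent only when removed genes and cells
co-occur; this mirrors the reference implementation rather than a
fixed-point definition.) Positivity is the single-copy rule on raw
counts — normalization preserves zeros, so no normalization is needed for
any reported proportion. Co-expression is `100 |A⁺ ∩ B⁺| / |denominator|`
with both orientations exposed. FISH percentages average section → animal
→ group so animals weigh equally; optical density is ROI minus background
(anterior commissure) per hemisphere, hemispheres averaged, negative
values preserved.

The count simulator draws marker positivity as Bernoulli variables with
exact pairwise joints along an acyclic pair graph (conditional sampling
from a root), which covers the study's hub structure — one probe gene
jointly configured with both receptor markers. Positive cells receive
`1 + Poisson` counts so the single-copy rule recovers the latent truth
exactly.

## Statistics

The paired t-test is the textbook form on unit differences (`n − 1`
denominator, two-tailed t tail mass). The two-way mixed ANOVA is the
classical complete-data decomposition: the between-subjects factor is
tested against subjects-within-groups MS, the within factor and
interaction against the within-subjects error MS, with no sphericity
correction (with two within levels sphericity is vacuous anyway). Group
sizes may differ; with one between and one within factor the design
remains orthogonal, so the sums of squares are unambiguous. Post-hoc
contrasts of two within levels inside each group use the shared
within-error MS and its df — for 34 animals in 3 groups with 2 levels,
t(31) in every group — and Sidak adjustment `1 − (1 − p)^m` with `m` the
number of groups. Tail probabilities come from R's `pt`/`pf` (regularized
incomplete beta underneath), spot-checked against tabulated quantiles at
1e−10.

A three-day place-preference design analyzed elsewhere with fractional
degrees of freedom (e.g. F(1.822, 71.05)) implies a sphericity correction
that the uncorrected analysis here will not reproduce; the package
deliberately produces the uncorrected table and leaves the discrepancy
documented rather than imitating a correction the methods text disclaims.

## Numerical and degenerate-input policy

Validation errors name the offending field. Degenerate fits (constant
isosbestic window), non-positive baselines, infinite t (zero-variance
nonzero-mean differences), incomplete ANOVA designs, empty post-filter
matrices, unassignable chamber samples and missing hemispheres all raise
informative errors or flagged values rather than silent coercions.
Half-up rounding is used for reported integer percentages. Seeds are
threaded explicitly: every simulator is a pure function of its config
including the seed, and cohort runners derive per-animal seeds from the
cohort seed, keeping everything below the 32-bit integer range.

## What the simulations do and do not show

Calibration studies run the full pipeline at the study's sizes: 500
no-transient cohorts (8 animals × 10 events) for the type-I error of the
epoch-minima contrast; 50 cohorts with a −3% pause for amplitude recovery
(the 1 Hz filter slightly attenuates a 0.5 s-rise transient, so recovered
minima sit a few percent shy of the injected amplitude — well inside the
±20% recovery band) and detection power; signal-free sessions with strong
shared artifact for the ≥5× RMS improvement of isosbestic over
window-mean baselines; and 100-seed classifier runs at suppression 0.5
(inhibition called in >95% of seeds) and 1.0 (null calibration, ~50%).
The simulators emulate the *structure* of real sessions — shared
artifacts, bleaching, Poisson licking, two-chamber dynamics, sparse
counts with controlled co-expression — but not hemodynamic contamination,
indicator nonlinearity, bout-structured licking, or spatially smooth
trajectories; passing tests certify the analysis code under the stated
generative model, not those additional features of real data. Problem
sizes in the test suite (e.g. 50,000 cells for law-of-large-numbers
checks, 10,000 replicates for t-test calibration) were chosen as the
smallest sizes at which the asserted tolerances are comfortably
statistically identifiable.
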