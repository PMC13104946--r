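---
title: "Models and methods behind foragesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foragesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragesim)
```

# The task environment

`foragesim` models a continuous foraging task: a subject moves freely among
three reward patches, each running an independent concurrent
variable-interval schedule. After every press at patch *j* a waiting
interval λ is sampled; reward becomes available once λ elapses and then
waits to be harvested by the next press. A press before completion is
unrewarded and — crucially — resets the patch: a fresh λ is sampled and the
clock restarts.

Two interval laws define the two task variants:

* **Exponential** (`schedule_spec("exponential", m)`): density
  μ e^(−μλ), μ = 1/m. The hazard is the constant μ, so elapsed time carries
  no information about impending availability, and by the memoryless
  property a premature reset leaves the distribution of the remaining wait
  unchanged (`time_to_availability_after_reset()` demonstrates this
  distributional identity by simulation). Premature presses are therefore
  nearly free.
* **Gamma** (`schedule_spec("gamma", m)`): shape a = 10 fixed, rate
  b = a/m. The hazard rises from zero, concentrating availability near the
  mean, so premature presses discard accumulated progress and are costly.

Mean intervals default to 7, 14, and 21 s for the fast, med, and slow
patches — in both variants, so that the variants differ in temporal
structure rather than average richness. Time is continuous, in seconds,
with 64-bit timestamps; the simulator is event-driven, with cue values
queryable at arbitrary times.

## Cue semantics

The stimulus encodes a scalar X(t) ∈ [0, 1] per patch, with different
semantics per variant:

* exponential: X = 1 − e^(−μ(t − t_i)), the cumulative probability that
  reward has become available since the last press at t_i. This is a
  statistic of the patch's long-run parameters, not of the active interval.
* gamma: X = min((t − t_i)/λ_i, 1), normalized progression through the
  currently sampled interval λ_i — interval-specific information. The
  source formulation can also be read as dividing elapsed time by the gap
  between consecutive press times; we take the denominator to be the active
  sampled interval, the only reading under which the cue is a progression
  signal that saturates exactly when reward becomes available.

Both cues are nondecreasing between presses, which the test suite checks as
a property.

# The dynamic texture stimulus

The cue is displayed as the spatial mean color of a dynamic, scale-invariant
texture, so that viewing distance conveys no extra information. The texture
lives in the Fourier domain on an N × N grid (default N = 128) with
amplitude law S_A(u, v) = (u² + v²)^(−1/2), zero at DC, and per-frequency
AR(1) dynamics

S_f(u, v, t) = ω S_f(u, v, t−1) + sqrt(1 − ω²) · (R₁ + iR₂) S_A(u, v),

with R₁, R₂ standard normal and persistence ω(u, v) = exp(−α S_A(u, v)),
α = 0.1 by default. Because the innovation is scaled by sqrt(1 − ω²), the
process is stationary from the first frame with marginal variance S_A² in
both quadrature components — a property the tests verify directly, along
with the lag-k autocorrelation ω^k.

Numerical choices worth recording:

* **Hermitian symmetrization.** After every update the half-plane with
  lower linear index is kept and its conjugate is copied to the mirrored
  frequencies (self-conjugate Nyquist/DC entries forced real). Averaging
  conjugate pairs instead would also enforce symmetry but halves the
  marginal variance, destroying the stationary-variance identity above;
  copying preserves it exactly.
* **ω direction.** As written, ω = exp(−α S_A) makes low spatial
  frequencies (largest S_A) decorrelate fastest. Whether that direction is
  intended is ambiguous; `spectrum_field(omega_form = "inverse")` provides
  exp(−α/S_A) as a switch rather than silently guessing.
* **Cue injection.** The cue term κ e^{iθ} is added to the DC coefficient
  only. Adding it to all coefficients would place a spatial impulse at one
  pixel; injecting at DC is the only reading compatible with a *mean-color*
  code.
* **Phase range.** θ = θ_min + (θ_max − θ_min)X with defaults ±2π/3, chosen
  to traverse the blue→red arc of the CIE Luv hue circle as the cue rises.
  The color lookup table (`make_phase_lut()`) uses 256 half-open phase bins
  (a phase exactly on an edge falls in the lower bin, with an epsilon guard
  against floating-point wrap error) at fixed lightness L = 70 and chroma
  60 in Luv, converted to 8-bit sRGB via `grDevices::convertColor`.

Effective reliability is quantified by decoding: the circular mean of the
per-pixel phases estimates θ, and its mean resultant length measures
coherence. Decoding error falls monotonically in κ — the operational sense
in which κ *is* cue reliability — and the tests establish this with texture
realizations shared across κ levels (pairing removes between-seed variance
from the comparison).

```{r stimulus-demo}
f <- spectrum_field(64, alpha = 0.1)
f <- step_spectrum(f)
frame <- render_frame(f, kappa = 4, theta = phase_from_cue(0.7))
unlist(decode_phase(frame))
```

# Synthetic foragers

The synthetic-data module exists to produce event logs with the statistical
structure the analysis pipeline assumes — quality-graded allocation,
bimodal inter-push intervals, quality-ordered transitions, and
reliability-dependent precision. Agents never observe λ_i or availability
directly; they see only noisy cue values and reward outcomes.

The **cue-threshold agent** is the workhorse. Every `poll_dt` = 0.25 s it
reads each patch's cue with two noise components, both scaled by 1/√κ so
the concentration parameter plays its stimulus role without rendering
frames inside the loop (an observation model equivalent in spirit to
decoding rendered frames, which remains available through the stimulus
module):

* fast per-poll Gaussian noise (`cue_noise_sd` = 0.25), and
* a per-session, per-patch calibration bias (`cue_bias_sd` = 0.25), drawn
  once per block.

The slow component matters: per-poll noise averages out over the ~10²–10³
decisions of a 15-minute block, so with fast noise alone allocation orders
the patches perfectly at any reliability. A persistent miscalibration of
the color-to-probability mapping is what lets an unreliable cue misorder
patches at the block level, which is the phenomenon the reliability
analyses measure.

The noisy reading becomes a *perceived probability that a press now would
be rewarded*: the cue itself under exponential semantics, and the posterior
mass of completion Φ((Â − 1)/σ) under gamma semantics, where reward
requires the progression cue to have reached 1. A patch is *ready* when
this perceived probability exceeds `cue_threshold` (default 0.3). The agent
presses its current patch as soon as it is ready. When a different patch
becomes ready first, it makes a one-shot stay-or-go decision: it estimates
the remaining wait at the current patch from the cue — m·log[(1−X)/(1−thr)]
for the exponential cue, (1−A)·m for the gamma cue, with m the patch's mean
interval (the agent is assumed to have learned the patch means) — and goes
with probability plogis((wait − travel_time)/wait_scale), paying
`travel_time` = 3 s; otherwise it commits to waiting out its patch.

This single rule, driven entirely by the two variants' cue semantics,
reproduces the qualitative reorganization between variants: under the
exponential cue the current patch re-becomes pressworthy within a few
seconds, so staying usually wins (high, quality-ordered self-transitions
and short IPIs); under the gamma cue a just-pressed patch promises a wait
on the order of the full interval, so the agent leaves for whichever patch
completes first — self-transitions collapse, switches concentrate on the
fast patch, and IPIs stretch to the interval scale.

The **rate-matching agent** presses at Poisson times (`base_push_rate` =
0.2 /s) and chooses patches by softmax (temperature 0.25) over
exponentially weighted reward-rate estimates (learning rate 0.2, neutral
initialization 0.5); it collapses to uniform choice when the temperature
diverges or learning is frozen. The **random agent** is the rate-matched
null model made flesh: Poisson times, uniform labels — and therefore must
(and does) normalize to 1 under the null-model analysis, which calibrates
the pipeline.

All agents optionally emit a rapid same-patch follow-up press after a press
(`repress_prob`, mean latency 0.4 s), emulating the short-interval
exploitation mode; it defaults off, and the bimodality tests enable it
explicitly. Parameters of all agents are calibration knobs chosen to put
the logs in a realistic regime, not estimates of any subject's parameters.

# The analysis pipeline

All analyses consume a `session_log` — strictly increasing press times with
patch labels and reward flags.

* **Push fractions and matching.** `quality_rank_spearman()` pools one
  (fraction, quality-rank) pair per patch per block, quality ranked
  slow = 1 to fast = 3, and uses the two-sided asymptotic approximation.
  Per-block correlations on 3 points get an exact permutation p-value over
  the 6 rank orderings (`per_block_spearman()`); note the smallest
  attainable two-sided p is then 1/3, so per-block "significance" at
  conventional levels is impossible by construction — a caveat the
  documentation states rather than resolving by a different, unstated test.
* **IPIs.** Per-patch inter-push intervals are differences between
  consecutive pushes *at that patch*, regardless of intervening pushes
  elsewhere (the reading under which within-patch bimodality is
  well-defined); a global pooled version is available via `patch = NULL`.
  Bimodality is assessed by two-component separation on log intervals
  (`ipi_bimodality()`).
* **Transitions.** Counted over consecutive push pairs; rows normalized;
  the directed-switching summary is P(→fast | not fast) = transitions
  (med or slow)→fast over all transitions out of med and slow.
* **Visits, stay, return.** A visit is a maximal same-patch run; stay time
  is t_last − t_first within a visit (single-push visits retained with
  stay 0, excludable via `drop_single`); return time is the gap between
  leaving a patch and the first push upon return.
* **Null model.** Surrogates match the real log's event count, with
  exponential inter-push intervals at the empirical mean rate
  (n−1)/(t_n − t_1) and uniform labels; total duration is whatever the
  sampled intervals imply. Defaults to 1000 replicates. Normalization is
  the plain ratio real/null; ratios are exactly invariant to rescaling all
  timestamps.
* **Continuous push rate.** The printed inter-press-interval definition is
  treated as the consecutive difference t(i+1) − t(i) (its stated use as an
  inverse rate requires positive consecutive spacing). The piecewise
  constant series 1/Δt_i is rescaled by the session's time-averaged rate —
  the rescaling statistic is not pinned down by the source, and the time
  average makes a perfectly periodic session identically 1 — then smoothed
  with a centered 60-s moving average (shrinking windows at the edges).
  Duplicate timestamps would give infinite rates; they are clipped to the
  smallest positive spacing with a warning.
* **Time courses.** Windowed push fractions use a 60-s window sliding in
  10-s steps on a session-relative grid; windows with no pushes are masked.
  The time-resolved Spearman correlation is computed per block at each
  window (3 observations, so values in {−1, −0.5, 0, 0.5, 1}) and averaged
  across blocks with SEM; no baseline subtraction is applied to the
  windowed fractions.

```{r pipeline-demo}
logs <- run_blocks(5, 2024, agent_spec("cue_threshold"),
                   variant = "gamma", kappa = 8, duration = 600)
quality_rank_spearman(logs)[c("rho", "p", "n")]
```

# What the generator emulates — and what it does not

The synthetic conditions are those of the task design: three patches at
7/14/21 s means, ~15-minute (900 s) blocks, both variants' cue semantics,
and graded reliability. On these conditions the agents reproduce the
*directional* phenomena: quality-ordered fractions, medians, and
self-transitions; bimodal pooled IPIs; higher pooled correlation under
higher κ; and the gamma-variant reorganization (longer IPIs, suppressed
self-transitions, switches directed at the fast patch).

Passing tests on these logs therefore validates the pipeline's mechanics
and the direction of its contrasts, not any quantitative claim about real
subjects: the agents have no spatial trajectories, no within-session
learning of patch identities (allocation is stationary within a block up to
noise), no individual differences, and no normative policy (no
marginal-value-theorem or POMDP solution). Headline magnitudes from animal
experiments are not reproduction targets at desk scale.

# Problem sizes and numerical tolerances

Monte-Carlo checks use sizes chosen to make their tolerances principled:
10⁵ draws for moment recovery (3 standard errors), 5×10⁴ per arm for the
reset-invariance KS test (p > 0.01), 100 blocks × 1000 null replicates for
null calibration (ratios within [0.9, 1.1]), 100 paired texture seeds for
the reliability ordering, 10⁴ AR(1) steps for stationary variance (4 SE)
and autocorrelation (absolute tolerance 0.04), and 50 blocks per condition
for the variant/reliability contrasts. The spectral slope is fitted on
radially averaged log amplitude over integer radii up to N/2 − 1 and is
required to sit within 0.15 of −1.

# Known limitations

* The per-block significance construction on 3 observations is inherently
  limited (see above); pooled statistics carry the inferential weight.
* The cue-threshold agent assumes known patch means for its wait estimate;
  an acquisition phase is not modeled.
* `omega_form = "amplitude"` (the printed law) makes coarse spatial
  structure flicker fastest; use `"inverse"` if slower coarse dynamics are
  desired.
* The null model matches event count and rate but not session duration
  exactly; for very sparse logs the surrogate span varies noticeably across
  replicates.
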