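# foragesim

Simulation and analysis of continuous three-patch foraging under
variable-interval reward schedules.

`foragesim` is aimed at behavioral neuroscientists and computational
ethologists studying how foragers allocate effort among competing reward
sites when reward timing is stochastic and the sensory evidence about it is
unreliable. It provides, with no animal data required:

* the generative environment of a continuous foraging task — three patches
  ("fast", "med", "slow") whose reward-availability intervals are drawn
  from either exponential or gamma laws;
* the dynamic scale-invariant (1/f) visual stimulus that signals
  availability through a phase-encoded mean color, with reliability set by
  a concentration parameter κ;
* synthetic forager agents that turn those ingredients into realistic
  push-event logs; and
* the analysis pipeline that turns event logs into matching statistics,
  transition dynamics, null-model-normalized engagement times, and
  time-resolved allocation courses.

## The model

Each patch *j* runs a concurrent variable-interval schedule. After every
press, a waiting interval λ is sampled; reward becomes available once λ has
elapsed and waits to be harvested by the next press. Two interval laws are
supported:

* **Exponential**: f(λ) = μ_j e^(−μ_j λ), mean 1/μ_j. The hazard h(t) = μ_j
  is constant (memoryless), so a premature press — which resets the patch
  and resamples λ — carries essentially no temporal cost.
* **Gamma**: shape a = 10, rate b_j = a / mean_j, giving an increasing
  hazard and a high cost for premature presses.

Default mean intervals are 7 / 14 / 21 s for the fast / med / slow patches
in both variants.

The cue signal X(t) ∈ [0, 1] differs by variant: the exponential cue is the
cumulative availability probability 1 − e^(−μ_j (t − t_i)) since the last
press at t_i; the gamma cue is progression through the active interval,
min((t − t_i)/λ_i, 1). X is mapped affinely to a phase angle θ and injected
into the DC coefficient of a 1/f spatiotemporal texture,

    C(x, y, t) = IFFT[ S_f(u, v, t) + κ e^{iθ(t)} ],

whose coefficients evolve as independent AR(1) processes with amplitude law
S_A(u, v) = (u² + v²)^(−1/2) and Hermitian symmetry (real frames). The
spatial mean color then encodes θ with reliability controlled by κ, which
the package quantifies with a circular-mean phase decoder.

The analysis side computes push fractions and their Spearman correlation
with quality rank (slow = 1, med = 2, fast = 3), per-patch inter-push
intervals, transition matrices with P(→fast | not fast), visit segmentation
into stay and return times normalized by a rate-matched null model
(exponential inter-push intervals at the empirical mean rate, uniform patch
labels), continuous push rate, and sliding-window time courses.

## Worked example

Simulate one 15-minute gamma-variant block with a reliable cue and analyze
it:

```r
library(foragesim)

log <- run_session(session_config("gamma", kappa = 8, duration = 900, seed = 7),
                   agent_spec("cue_threshold"))
round(push_fraction(log), 3)
#>  fast   med  slow
#> 0.646 0.204 0.150

transition_matrix(log)
#> <transition_matrix> P(next | current):
#>       to
#> from    fast   med  slow
#>   fast 0.598 0.212 0.189
#>   med  0.810 0.048 0.143
#>   slow 0.613 0.387 0.000
#> P(-> fast | not fast) = 0.726

set.seed(7)
block_metrics(log, null_reps = 1000)
#> <block_metrics> block b1, 206 pushes
#> push fraction:  fast 0.646, med 0.204, slow 0.150
#> IPI median (s): fast 5.88, med 17.75, slow 28.00
#> normalized stay:  3.09, 0.27, 0.00  | normalized return:  0.57, 1.25, 1.65
```

The agent allocates pushes in quality order (0.65 / 0.20 / 0.15), directs
switches overwhelmingly toward the fast patch (P(→fast | not fast) = 0.73),
and spaces its presses on the scale of the gamma intervals (median IPIs
5.9 / 17.8 / 28.0 s). Normalized stay/return times show engagement
concentrated at the fast patch far beyond what overall push rate predicts
(stay ratio 3.1 at fast vs 0.0 at slow).

Multi-condition experiments (variants × κ levels, with pooled statistics
and time courses written to disk) run through `run_experiment()`; dynamic
stimulus frames render through `spectrum_field()` / `render_frame()` and
export via `write_frame_png()`.

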