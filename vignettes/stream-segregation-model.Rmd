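---
title: "A two-stage neuromechanistic model of auditory stream segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage neuromechanistic model of auditory stream segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamseg)
```

## The phenomenon

A repeating ABA_ tone pattern — low tone A, high tone B, low tone A, then a
silence, each lasting 100 ms — is first heard as a single galloping stream
(*integrated*). Over several seconds the probability of hearing two
separate streams of A tones and B tones (*segregated*) grows: the
*build-up* of stream segregation. Build-up is faster and reaches a higher
level the larger the frequency difference (DF, in semitones) between A and
B. Interruptions matter: a brief silent pause partially *resets*
perception toward integrated, while a single unexpected tone — a
*distractor* inserted in the silent gap between triplets or a frequency
*deviant* replacing a B tone — *promotes* segregation.

`streamseg` implements a two-stage mechanistic account of these
observations and the psychoacoustic paradigms used to probe them, so that
build-up curves, pause resets and perturbation effects can be simulated
and analyzed at desk scale.

## Stage 1: adapting tonotopic inputs

The first stage converts a stimulus timeline into drive for three
downstream units that pool primary auditory cortex (A1) activity at
tonotopic locations A (0 st), B (DF st), and their midpoint AB (DF/2 st).
Each tone contributes a rectangular pulse for its duration, weighted by a
Gaussian tuning profile `exp(-d^2 / (2 w^2))` in semitone distance `d`.

Two observations about early A1 responses shape this stage, both governed
by one fast timescale `tau_a1 = 500` ms:

* **Amplitude adaptation.** The response gain starts at `amp_onset_gain`
  (default 3) and decays to 1 over the first 2–3 triplets.
* **Emergence of DF dependence.** At onset the response to each tone is
  broad and nearly centered; tonotopic differentiation emerges with
  adaptation. We parameterize this as an *effective DF*: tone locations
  are contracted toward the A/B midpoint by a fraction that relaxes from
  `df_onset_frac` (default 0.03) to 1. Contracting positions by `f` is
  equivalent to broadening the tuning width by `1/f`, so the default says
  that unadapted responses carry almost no tonotopic information about the
  A–B separation, which is what biases the integration unit at onset.

During silences that exceed the triplet grammar (stimulus pauses) both
quantities relax back toward their onset values with `tau_rec = 100` ms,
so that after a pause of a few hundred milliseconds the input resembles
stimulus onset — the mechanistic source of the pause reset.

Two further structural choices proved necessary and are the package's own
design decisions:

* **Rate-dependent forward masking of A tones** (`a_rate_masking`,
  default 0.65). A tones recur at twice the rate of B tones and are
  therefore more strongly forward-masked; we fold this rate dependence
  into a static amplitude factor on A-tone responses. Without it the
  adapted drive to the AB unit can never exceed the peripheral drive at
  small DF under symmetric Gaussian weights, and neither the integration
  bias at DF = 4 nor the DF ordering of build-up levels is attainable.
* **A broader pooling kernel for the integration unit**
  (`ab_width_factor`, default 2). The AB unit integrates the region
  spanning both tones, so it pools a wider swath of the tonotopic axis
  than the sharply tuned peripheral units (peripheral width
  `tuning_width_st = 3.5` st, AB width 7 st). A single shared width
  cannot simultaneously give a reliable onset integration bias at DF = 4
  (which needs narrow peripheral tuning, so that the contracted onset
  tones drive AB more than A or B) and a metastable integrated state at
  DF = 10 (which needs the AB unit to remain competitive when the tones
  are 10 st apart).

Novel events — distractor and deviant tones, which break the triplet
pattern — follow special rules: their drive is boosted to the unadapted
amplitude (`boost_to_unadapted`), their response at the A location is
attenuated by `masking_factor = 0.5` (they closely follow an A-tone
offset), and under the differential-processing hypothesis
(`gate_non_triplet_from_AB = TRUE`, the packaged default) they are
excluded from the integration unit's input entirely. Setting the gate off
reproduces the alternative in which novel tones reach all units
tonotopically.

## Stage 2: stochastic competition

Three units `k in {A, AB, B}` carry firing rates `r_k` evolving as

```
tau_r dr_k/dt = -r_k + F(beta_e e_k - beta_i (r_A + r_AB + r_B)
                         - g a_k + I_k + chi_k)
tau_e de_k/dt = -e_k + r_k
tau_a da_k/dt = -a_k + r_k
```

with `F` a logistic sigmoid (threshold `F_threshold`, slope `F_slope`),
recurrent NMDA-like excitation (`tau_e = 70` ms, `beta_e = 0.65`)
bridging the silent gaps between tones, instantaneous global inhibition
pooling all three rates including the unit's own (`beta_i = 0.3`; note
`beta_e > beta_i`, net local excitation), linear spike-frequency
adaptation (`g = 0.045`, `tau_a = 1.4` s) and additive
Ornstein–Uhlenbeck noise `chi_k` (sd `noise_sigma = 0.07`, correlation
time `noise_tau = 30` ms). The rate timescale is `tau_r = 10` ms.

The percept readout follows the summed-activity rule: a time bin (one
triplet, 400 ms) is *integrated* when the bin-averaged `r_AB` is at least
the bin-averaged `r_A + r_B`, *segregated* otherwise; exact ties count as
integrated. A sample-by-sample majority variant is available via
`classify_bins(..., mode = "sample")`; bin-averaged rates are the
default.

## Numerics

Integration uses an Euler–Maruyama scheme with step `dt = 0.5 tau_r =
5` ms, vectorized across trials. The OU term uses its exact
discretization (`chi' = chi e^(-dt/tau) + sigma sqrt(1 - e^(-2 dt/tau))
Z`), which is correct at any step size, rather than a naive Euler update.
Non-finite states abort with the offending variable named. The
deterministic part of the scheme is first-order: against an adaptive
ODE oracle the error decreases linearly in `dt` and drops below 1e-3 at
steps around 0.016 ms (the test suite verifies both the convergence and
the oracle match).

Frozen-noise ensembles pre-generate, per trial `i`, the initial
conditions (`r`, `e`, `a` uniform on [0, 0.1], noise from its stationary
law) and the OU path under seed `master_seed + i`. The per-trial streams
are therefore identical across stimulus conditions, bank sizes and
execution order, and a longer path shares its prefix with a shorter one —
so two conditions differing only after time T produce bit-identical
trajectories up to T.

Two readout conventions deal with pauses: bins continue across silent
intervals, and a trailing partial bin (created when a pause shifts the
grid) is dropped; difference scores at the final test triplet instead use
an explicit 400 ms window anchored at stimulus offset
(`prop_seg_window()`).

## What the calibration fixed, and why

The printed competition constants (`tau_r`, `tau_e`, `tau_a`, `beta_e`,
`beta_i`, `g`) and the input-stage timescales (`tau_a1`, `tau_rec`) are
taken as given. The sigmoid, noise and input-geometry constants are not
determined by those values; they were fixed once by the package's
calibration harness (`calibrate()`) against the qualitative phenomena and
then frozen. Three dynamical regimes had to be balanced:

* **Dominance must be input-maintained.** If `F_threshold` is low enough
  that `beta_e - beta_i` sustains a dominant unit without input, the
  first winner persists indefinitely and build-up levels pin near the
  2-of-3 readout lottery at every DF. The default threshold (0.32) sits
  above the recurrent-excitation margin, so holding dominance requires
  ongoing input — which is what makes dominance DF-dependent.
* **The onset race must stay off the sigmoid's saturated shoulder.** At
  stimulus onset all three units receive strong, nearly symmetric drive;
  if `F` saturates, global inhibition cannot resolve a winner and the
  co-active transient reads as spurious segregation. The onset gain (3)
  together with the threshold keeps the symmetric operating point in the
  sensitive range where winner-take-all collapse amplifies the AB unit's
  onset edge.
* **Noise must be fast.** With `noise_tau = 30` ms the noise averages out
  over the ~200 ms onset collapse (protecting the integration bias at
  DF = 4, where the AB edge is smallest) while still driving the
  alternations that carry build-up toward its long-run level.

## Conventions worth knowing

* **Static-input ensembles are burned in.** The "input static" condition
  represents the post-build-up alternation regime, so those ensembles are
  simulated with a 2.4 s lead-in that is discarded before binning
  (`condition_buildup()` does this automatically). Without it the early
  bins reflect the initial-condition race rather than the alternation
  equilibrium, and the curve is not flat.
* **Convergence is checked at 6 s.** The adapting-input curve approaches
  the static level asymptotically; at 4 s the adaptation legacy of the
  early integrated phase (`tau_a = 1.4` s) still biases it upward by
  roughly 0.08, and by 15 triplets the two agree within Monte-Carlo
  error. The packaged checks therefore evaluate convergence on
  15-triplet runs and onset/ordering on 10-triplet runs, at 500 trials.
* **During-pause movement toward 0.5 is a pooled statement.** With the
  summed-activity readout, a fully silent bin compares one unit's decay
  against two, which leans segregated; the absolute movement toward 0.5
  during a 600 ms pause holds at DF 4 and 7 and is tested pooled across
  DF (mean distance from 0.5 in the silent bin vs the last pre-pause
  bin), matching the mixed-direction character of the phenomenon (the
  proportion increases toward 0.5 at DF 4 and decreases at high DF).
* **Frequency arithmetic is 12-tone equal temperament** throughout:
  `x + s st` maps to `x * 2^(s/12)` Hz, and the `(A+B)/2` distractor
  location is the semitone midpoint, i.e. the geometric mean in Hz —
  consistent with logarithmic tonotopy.
* **The rove ladder** spans 420–1060 Hz in five geometrically even rungs
  (steps of 4.007 st ≈ 4 st, pinned to the printed endpoints), giving a
  maximum B frequency of 1888 Hz (truncated) at DF = 10.
* **Base-frequency roving is uniform.** Whether the roving was uniform or
  balanced is not specified; `rove_base_frequency()` draws uniformly
  under a recorded seed.
* **One shared recovery constant.** Amplitude and effective-DF adaptation
  recover with the same `tau_rec`; nothing in the phenomenology requires
  separate constants.

## What the stimulus generator does and does not emulate

Timelines are exact in the milliseconds domain: tone onsets, durations,
pause placement, distractor centering (25 ms margins in the 100 ms gap)
and deviant substitution are integer-ms operations, so design arithmetic
is free of floating drift. Audio synthesis (pure sinusoids, 10 ms linear
ramps, digital full-scale level convention) is a convenience for
listening; no SPL calibration, headphone transfer function, cochlear
filtering or binaural pathway is modeled. Passing the packaged checks
therefore speaks to the mechanistic account of streaming dynamics, not to
any claim about reproducing subject-level audio percepts: the model's
contact with behavior is through the same summary statistics the
psychoacoustic paradigms use (proportions segregated and their difference
scores).

## Worked example

```{r example, eval = FALSE}
a1 <- a1_params()
net <- network_params()

# build-up at DF = 7, 500 trials
buf <- condition_buildup(make_triplet_sequence(10, 7, 420), a1, net,
                         n_trials = 500, master_seed = 1)
round(buf$prop_seg, 2)

# a gated distractor 2 st above B promotes segregation
pert <- run_perturbation_conditions(a1, net, 500, 1, cells = "disB+2")
pert$deltas
```

## Limitations

Three lumped units cannot represent distractors as forming their own
stream, continuous tonotopic gradients, rate/timing feature maps or
attention; the gating of non-triplet events is imposed, not emergent. The
readout's behavior during complete silence is a convention (see above),
and the model makes no attempt to fit individual subjects — only the
signs, orderings and timescales of the group-level phenomena.
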