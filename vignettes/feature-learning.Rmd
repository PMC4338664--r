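---
title: "Unsupervised spatiotemporal feature learning from event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised spatiotemporal feature learning from event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Event cameras (silicon retinas) do not produce frames. Each pixel emits an
*address event* `(t, x, y, p)` whenever its log-luminance has changed by a
contrast threshold since its last event — ON (`p = +1`) for increases, OFF
for decreases — with microsecond timing. Features for this data must be
*spatiotemporal*: a detector should recognise not a static patch but a
dynamic pattern, e.g. "an oriented edge translating at this speed", and
should be learnable without labels.

`evsn` implements a competitive predictive architecture for exactly this:

1. **Preprocessing** — events are pooled into square cells and filtered with
   a causal exponential kernel, giving a per-receptive-field analog vector
   `A(t)` (one trace per cell) sampled every millisecond and normalized to
   `[0, 1]`.
2. **Predictor bank** — `N` echo-state networks (ESNs), each a fixed random
   reservoir with a trainable linear readout, receive `A(t_n)` and output a
   prediction of the *next* sample, `Âᵏ(t_n + dt)`. Only readouts learn, by
   recursive least squares (RLS), online.
3. **Selection** — each predictor reports a similarity
   `Sᵖₖ = Σᵢ|Aᵢ·Âᵢ| / (Σᵢ|Aᵢ| · Σᵢ|Âᵢ|)` between its previous prediction and
   the observed input. A sigmoid with an adaptive midpoint converts `Sᵖₖ`
   into an input current for non-leaky integrate-and-fire neurons wired as a
   winner-take-all (WTA): over each 1 ms tick, only the most strongly driven
   channel spikes. **Only the winner's readout is trained on that tick**, so
   predictors specialise.
4. **Predictability minimization (PM)** — one estimator network per channel
   tries to name the winner *from the other channels' similarities only*.
   When estimator `k` succeeds while `k` itself is the winner, `k`'s win
   carried no private information; the channel is inhibited for `T_inh`,
   handing the input to a competitor. This drives the bank toward
   non-redundant detectors.

An activity gate silences the whole selection layer (and all learning)
whenever the mean of the analog vector is at or below a threshold, so the
system is quiet without stimulation.

```{r quick-look}
library(evsn)
cfg <- arch_config(n_esn = 8, seed = 1)
sched <- rbind(bar_schedule(reps = 3, phase = "learn"),
               bar_schedule(reps = 3, phase = "test"))
report <- run_experiment(cfg, sched)
glance(report)
modal_winners(report)
autoplot(report)
```

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `contrast_threshold` | 0.14 | log-luminance | ≈ ln(1.15): one event per ~15% relative contrast change |
| `noise_rate` | 0.1 | events/px/s | stationary Poisson background, fair polarity |
| `cell_size` | 5 (3 tiled) | px | spatial pooling; 128×128 px → 25×25 cells |
| `rf_half_extent` | 8 | cells | 17×17-cell field → input dimension `m = 289` |
| `tau` | 0.01 | s | exponential kernel memory |
| `dt_s` | 0.001 | s | processing tick |
| `n_neurons` | 15 | — | reservoir size |
| `spectral_radius` | 0.7 | — | echo-state contraction (< 1) |
| `w_in/w_back/w_out` ranges | 0.4 / 0.02 / 0.01 | — | symmetric uniform init |
| `forgetting`, `delta` | 0.999, 0.01 | — | readout RLS memory and prior `P₀ = I/δ` |
| `g_min`, `g_max` | 5000, 15000 | Hz | IF current range: with `theta = 1`, rates span 5–15 kHz |
| `lambda` | 5e-5 | — | sigmoid selectivity |
| `kp`, controller period | 0.1, 0.5 ms | — | proportional tracking of the winner's similarity by the offset `x0` |
| `t_inh_s` | 0.01 | s | PM inhibition length |
| `gate_threshold` | 0.01 | — | minimum mean analog activity |
| `pm_forgetting` | 1 | — | estimator RLS memory (see below) |

Two defaults deserve their own justification.

**Estimator memory (`pm_forgetting = 1`).** The PM rule asks whether a win
is *predictable from the peers*. An estimator with a short memory (the
readouts' 0.999, ≈1 s) can predict any persistent winner from recency alone
— it just keeps emitting the recent target — so every stable specialist
would be permanently inhibited and the competition degenerates into a
round-robin rotation with no stable detector map. With infinite-memory
least squares the estimator must fit one global map from peer similarities
to winner identity over the whole history, so only genuinely redundant
channels are suppressed. This is the package's design choice; the estimators
are otherwise trained exactly like the readouts.

**Winner tie resolution.** With `lambda = 5e-5`, a similarity more than a
few tens of `lambda` above the offset saturates to `g_max` *exactly* at
double precision, so competing currents tie even though the underlying
similarities differ. Because the encoder is strictly increasing, the argmax
over currents is mathematically the argmax over similarities;
`select_winner()` therefore ranks equal currents by similarity and uses the
lowest index only for exact similarity ties. Without this, floating-point
saturation would hand nearly every decision to channel 1.

## The synthetic sensor

The generator emulates a 128×128 change-based sensor:

* **Moving bars** (`stimulus_bar()`): a 3-px stripe with 1-px soft edges and
  contrast `10·ΔI` translating along its normal at constant speed
  (default 200 px/s), sweeping the field cyclically like patterns on a
  treadmill. Because the per-pixel log-luminance pulse is piecewise linear
  in time, the threshold-crossing times are solved in closed form — this is
  the limit of frame-based rendering as the frame interval goes to zero, and
  a test verifies agreement with the generic 0.1 ms frame pipeline
  (`luminance_to_events()`). Each edge yields ~10 events per pixel crossing.
* **Jittered bitmaps** (`stimulus_bitmap()`): a static pattern (digit glyphs
  1–9 ship as PBM masters) displaced by a uniform integer random walk,
  emulating microsaccades; the initial appearance sets the per-pixel
  reference level, so an unjittered pattern is invisible, as it is to a real
  change-based sensor.
* **Noise**: stationary Poisson per pixel with fair polarity. Real sensors
  additionally show hot pixels, refractory effects, latency jitter and
  luminance-dependent rates — none of which are modelled, so passing tests
  here demonstrate the learning dynamics, not robustness to every sensor
  artefact.

Free stimulus parameters (bar speed 200 px/s, noise 0.1 Hz/px, 0.6 s pauses)
were fixed once at values typical for treadmill-style recordings and are
exposed in the configuration rather than tuned.

## Numerical choices

* Timestamps are integer microseconds; coordinates 0-based, half-open
  `[0, width)`. Tick `k` owns events in `((k−1)·dt, k·dt]`.
* The incremental filter update `a ← a·e^(−Δt/τ) + Σ e^(−(t−tᵢ)/τ)` is
  algebraically identical to re-summing the kernel over the event history;
  the test suite holds them to 1e−12.
* Normalization divides by the running maximum component seen so far in the
  field, floored at 1 so silence is not amplified. Before any stimulus has
  set that scale, dense coincident noise can transiently open the gate —
  a documented edge case of this normalization.
* IF integration restarts at each 1 ms decision window. At 5–15 kHz the
  global reset fires many times per window, so carrying accumulators across
  windows would change nothing; within a window the race has the closed-form
  solution "argmax current spikes every `theta/I`".
* The winner's RLS update pairs the reservoir state that issued the pending
  prediction with the subsequently observed sample (a priori error, shared
  inverse-correlation matrix across output dimensions). If `P` degenerates
  it is reinitialized with a warning.
* The PM inhibition rule requires *both* estimator agreement and
  `winner = k`. (Read literally, the source rule also inhibits non-winning
  channels whose estimators agree; inhibiting a non-winner has no immediate
  effect, so the stricter conjunctive rule is implemented.)
* Estimators step and inhibit only on gated ticks, and never train during
  test phases; learning of every readout is frozen while `phase = "test"`.
* `error_quiescence()` attributes the first 100 ms of each blank gap to the
  preceding stimulus (the kernel and prediction tails decay on that scale)
  before measuring gap errors.

## Problem sizes

The shipped experiments are scaled for a desktop run: 1 s presentations,
0.6 s pauses, 3 repetitions per orientation, 15-neuron reservoirs. A full
9-orientation training run is ≈43 s of simulated sensor time (≈43,000
ticks) and takes well under a minute with the compiled engine; the
recruitment study (20 ESNs × 5 seeds) runs in a few minutes. The compiled
tick loop (`src/engine.cpp`) is a line-for-line port of the plain-R
reference path, and the suite asserts their equivalence to 1e−10.

## Known limitations

* **Capacity-driven sweep splitting.** A linear readout of a 15-neuron
  reservoir spans at most a rank-15 family of output patterns, while a full
  sweep of a 17×17-cell field traverses many more distinguishable analog
  patterns. Competition therefore often assigns *segments* of one sweep to
  2–3 predictors instead of one specialist per orientation. The
  orientation→modal-winner map is nevertheless stable across repeated frozen
  test presentations; but counts of "recruited" networks at these scaled
  durations run above the minimum one-per-feature, and a single feature
  presented alone is shared rather than captured by one network.
* **Rest-state output of the logistic reservoir.** With the logistic state
  nonlinearity the no-input reservoir converges to a non-zero fixed point,
  and a readout trained only on gated (active) data maps that state to an
  output of order 1. Prediction errors in blank gaps therefore sit near the
  stimulated-period median rather than near zero; only a zero-centred
  nonlinearity (e.g. tanh) would make the rest output vanish structurally.
* Polarity is carried through the data model but deliberately unused by the
  preprocessing, and receptive fields are fixed, non-overlapping and
  unlearned.
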