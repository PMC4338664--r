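# evsn — unsupervised spatiotemporal feature learning for event-based vision

Event cameras (silicon retinas, DVS-style sensors) emit asynchronous address
events `(t, x, y, p)` — microsecond-stamped ON/OFF marks wherever a pixel's
log-luminance moves by a contrast threshold — instead of frames. Classical
visual features (Gabor patches, interest points) assume still images and say
nothing about the temporal structure that is this data's whole point. `evsn`
is for researchers in neuromorphic engineering and computational
neuroscience who want *dynamic* feature detectors learned directly, and
without labels, from such event streams — and a fully synthetic sensor
front end so everything runs without hardware.

## The architecture

Events are pooled into cells and filtered with a causal exponential kernel
`G(t, tᵢ) = e^{−(t−tᵢ)/τ} H(t−tᵢ)`, giving an analog vector **A**(t) per
receptive field, sampled each millisecond and normalized to [0, 1]. A bank
of `N` echo-state networks predicts the next sample:

    sᵏ(tₙ) = f( Wᵏ_r sᵏ(tₙ₋₁) + Wᵏ_in A(tₙ) + Wᵏ_back outᵏ(tₙ₋₁) )
    outᵏ(tₙ) = Wᵏ_out sᵏ(tₙ)  =  Âᵏ(tₙ + dt)

with `f` the logistic function, reservoirs rescaled to spectral radius 0.7,
and only `Wᵏ_out` trained (recursive least squares, online). Each predictor
reports a similarity

    Sᵖₖ = Σᵢ |Aᵢ · Âᵏᵢ| / ( Σᵢ|Aᵢ| · Σᵢ|Âᵏᵢ| )  ∈ [0, 1],

which a sigmoid with an adaptive midpoint (proportional controller, 0.5 ms
period) converts into currents for non-leaky integrate-and-fire neurons in a
winner-take-all circuit spiking at 5–15 kHz. Per tick, **only the winning
ESN is trained**, so predictors specialise on distinct dynamic patterns. A
predictability-minimization layer — one estimator network per channel, each
seeing only its *peers'* similarities — temporarily inhibits channels whose
wins are predictable from the others, pushing the bank toward non-redundant
detectors. An activity gate keeps the circuit (and learning) silent when
input activity is low.

## Worked example

Eight predictors, nine bar orientations (0°–160°), three learning
presentations each, then three frozen test presentations:

```r
library(evsn)
cfg <- arch_config(n_esn = 8, seed = 1)
sched <- rbind(bar_schedule(reps = 3, phase = "learn"),
               bar_schedule(reps = 3, phase = "test"))
report <- run_experiment(cfg, sched)
glance(report)
#> # A tibble: 1 × 6
#>   n_ticks  n_rf gated_frac training_samples n_esn n_recruited
#> 1   86400     1      0.333            14439     8           8
```

86,400 one-millisecond ticks were simulated; the activity gate was open a
third of the time (bars sweep in and out of the receptive field, and blank
pauses separate presentations); 14,439 gated learning ticks each trained
exactly one readout. The learned detector map, read from the frozen test
phase:

```r
modal_winners(report) |> dplyr::filter(phase == "test", rep == 1)
#>    label  phase  rep modal_winner n_gated
#>  1 bar0   test     1            8     614
#>  2 bar100 test     1            3     483
#>  3 bar120 test     1            4     531
#>  4 bar140 test     1            8     543
#>  ...
```

Each orientation has a modal winner; with 8 networks and 9 orientations one
network (here ESN 8) must cover two. The same map repeats on test
repetitions 2 and 3 — the detectors are stable once learning is frozen.
`recruitment_report(report)` shows all 8 networks carried 10–16% of the
training load, `autoplot(report)` draws the winner timeline against the
stimulus ground truth, and `plot_errors(report)` the per-ESN prediction
error traces. For the tiled, multi-receptive-field detector see
`tile_receptive_fields()` / `run_tiled()`, and for complex shapes
`digit_schedule()` (jittered digit bitmaps).

A command-line front end (`inst/scripts/evsn`) wraps simulation, training
and reporting for shell use.

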