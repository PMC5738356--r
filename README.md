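# spikeforce

Supervised training of chaotic spiking neural networks by online
recursive least squares (FORCE learning), as an R package.

Populations of spiking neurons can be taught to *generate* arbitrary
dynamics: a reservoir of integrate-and-fire neurons is wired with a
strong sparse random matrix `G ω⁰` that puts it into chaotic spiking,
and a linear readout `x̂(t) = φᵀ r(t)` of the filtered spike trains is
learned online so that it reproduces a teaching signal `x(t)`.  The
readout is fed back into the network as a current `Q η x̂(t)`, so the
full weight matrix is

    ω = G ω⁰ + Q η φᵀ

— a fixed chaotic backbone plus a learned rank-m feedback.  The decoders
φ are updated every few milliseconds of simulated time by recursive
least squares,

    P ← P − (P r rᵀ P) / (1 + rᵀ P r),   φ ← φ − (P r) eᵀ,

with `e = x̂ − x` and `P(0) = I/λ`; the recursion is exactly batch ridge
regression, and the feedback loop clamps the output error from the first
updates while the reservoir's chaos is tamed into the target dynamics.
After training the decoders are frozen and the network runs
autonomously.

The package provides theta (quadratic integrate-and-fire phase), LIF and
Izhikevich reservoirs plus a smooth rate-unit baseline; generators for
the standard teaching signals (sinusoids, sawtooth, Van der Pol, Lorenz
trajectories, note-pulse songs, high-dimensional temporal signals and a
synthetic pixel-movie stand-in); post-training manipulations
(excitation/inhibition rescaling, HDTS compression/reversal/attenuation,
neuron lesioning); and quantitative read-outs (firing statistics, replay
classification, eigenspectra, spike-deletion chaos diagnostics, and the
network-size convergence experiment).  It is aimed at computational
neuroscientists who want a scriptable, tested implementation of
FORCE-trained spiking reservoirs at desk scale.

## A worked example

Train 2000 LIF neurons to sing a 5 Hz sinusoid (the standard oscillator
benchmark), then let the network free-run:

```r
library(spikeforce)

fit <- force_train(sup_sinusoid(5), model = "lif",
                   N = 2000, G = 0.04, Q = 10, p = 0.1,
                   rls_lambda = 0.0025,
                   schedule = train_schedule(0, 4, 5, dt_ms = 0.5,
                                             dt_rls_ms = 2.5),
                   seed = 1)
fit
#> FORCE-trained lif network
#>   N = 2000, p = 0.1, G = 0.04, Q = 10, supervisor: 5 Hz sinusoid (m = 1)
#>   schedule: 0 s init / 4 s train / 5 s test (dt = 0.5 ms, RLS every 2.5 ms)
#>   test-phase L2 error: 0.8353 (log: -0.18)
#>   test-phase mean firing rate: 20.5 Hz
```

During training the decoded output is clamped onto the target (training
residual ≈ 0.16); in the 5 s test phase the network keeps oscillating at
5 Hz on its own, at a mean rate of ≈ 20 Hz — the free-running phase
drifts slowly relative to the absolute clock, which is why the raw
test-phase L2 is larger than the training residual while the waveform
itself stays clean.  `plot(fit)` shows the decoded trace against the
target, a spike raster and the decoder-norm history; `coef(fit)` returns
the decoders, `predict(fit, t_s = 5)` continues the frozen network, and
`simulate(fit, nsim = 3)` draws perturbed replicates.

Preset experiments reproduce the standard desk-scale results end to end:

```r
run_preset("fig1_rate", seed = 1)        # 1000 rate units, 5 Hz sinusoid
run_preset("fig2_theta_sine", seed = 1)  # 2000 theta neurons, ~25 Hz
run_preset("fig3_ode_to_joy_scaled", seed = 1)  # note-sequence replay
run_preset("hdts_replay_synthetic", seed = 1)   # movie replay via HDTS
```

and post-training perturbations act on frozen fits:

```r
mov <- run_preset("hdts_replay_synthetic", seed = 1)
summary(mov)$test_correlation                     # ~0.99 unperturbed
predict(mov, perturbation = perturbation_spec(compression = 4))
predict(lesion_neurons(mov, 0.3), t_s = 4)
```

## Package layout

* `R/neurons.R`, `R/synapses.R` — unit models, filters, weight builders
* `R/rls.R`, `R/train.R`, `R/fit-methods.R` — the learning rule,
  `force_train()` and the `force_fit` methods
* `R/supervisors.R` — teaching-signal generators
* `R/metrics.R`, `R/experiments.R` — read-outs and the chaos/convergence
  experiments
* `R/perturbations.R` — post-training manipulations
* `R/presets.R`, `R/io.R` — preset experiments and plain-text run
  artefacts
* `src/force_engine.cpp` — the fixed-step integration loop
* `vignettes/force-spiking-networks.Rmd` — models, conventions and
  design choices in detail
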