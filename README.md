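# effspike

Simulation and analysis of **efficient predictive-coding spiking
networks**: populations of leaky integrate-and-fire neurons derived from
greedy minimization of a signal-coding error plus costs on spiking, the
model family in which spontaneous cortical Up/Down states appear as the
signature of a network correcting its own representation.

## Who this is for

Computational neuroscientists studying the relation between coding
efficiency and network dynamics: how synaptic delays and membrane noise
turn a precise balanced network into one with synchronized spontaneous
bursts, and how costs on spiking (biophysically: firing thresholds and
spike-triggered adaptation) tune it back to an efficient asynchronous
regime.

## The model

A network of `N` neurons with decoding weights `w_i ∈ R^J` represents a
signal `x(t)` (the exponential filtration, rate `λ`, of an input `s(t)`)
through the linear read-out `x̂_j = Σ_i w_ij r_i`, with `r_i` the
exponentially filtered spike train. Spikes are emitted only when they
reduce the objective

    E(t) = ‖x(t) − x̂(t)‖² + ν Σ_i r_i + μ Σ_i r_i²

which makes the membrane potential equal the projected coding error,
`V_i = w_iᵀ(x − x̂) − μ r_i`, with dynamics

    V̇_i = −λ V_i + Σ_j w_ij s_j − Σ_k φ_ik o_k − μ o_i + σ η_i,
    spike when V_i > ‖w_i‖²/2 + μ/2 + ν/2,

where `φ = w wᵀ` is the lateral/recurrent coupling matrix. The linear
cost `ν` raises all thresholds; the quadratic cost `μ` also deepens the
after-spike reset. With transmission delays and noise, low costs produce
synchronized spontaneous Up states; the package quantifies them (MUA,
shuffle-corrected spike-triggered MUA, Up-state intervals and durations,
CV2, synchrony) and sweeps the `(ν, μ)` plane for the regime minimizing
`Total error = α⟨error⟩ + β⟨cost⟩`.

## Worked example: spontaneous Up states in the quiescent network

```r
library(effspike)

spec <- build_random_network(100, 3, rng_seed = 11)   # N = 100, J = 3
cfg  <- sim_config(dt = 1e-4, duration = 20, leak_rate = 4, delay = 1e-3,
                   noise_sd = 0.25, rng_seed = 7, coupling_mode = "delayed")
quiet <- input_signal(matrix(0, 3, 20 / 1e-4), dt = 1e-4)  # no drive

res  <- simulate_network(spec, quiet, cost_params(nu = 0, mu = 5), cfg)
res
#> <sim_result> 100 neurons, 20 s at dt = 1e-04 s; 41212 spikes ( 2060.6 spk/s population )

segs <- detect_up_states(res$spikes)
segs
#> <upstate_segments> 17 Up state(s) in 20 s (criterion: 20 % active within 1 ms )

interburst_statistics(segs)$mean_ibi          # 1.189  (s between bursts)
duration_statistics(segs)$mean_duration       # 0.0106 (s per burst)
compute_cv2(res$spikes)$mean                  # 0.52   (irregular firing)
```

Although the network receives no input, membrane noise triggers spikes
whose coding errors the recurrent connectivity then corrects, producing
17 synchronized population bursts in 20 s separated by ~1.2 s of near
silence; single-neuron firing stays irregular (CV2 ≈ 0.5). Rerunning
with `noise_sd = 0` gives 0 spikes — the quiescent network is silent
without noise — and raising `nu` makes the Up states rarer until they
vanish. In the active state (e.g. `smoothed_white_noise(3, 20, 1e-4,
amplitude = 40)` as input) the same network tracks the signal, and
`cost_sweep()` maps coding error, spike cost and Up-state frequency over
the cost plane:

```r
gen  <- function(seed) smoothed_white_noise(3, 2, 1e-4, 2, 40, rng_seed = seed)
surf <- cost_sweep(spec, gen, sim_config(dt = 1e-4, duration = 2,
                                         noise_sd = 0.25),
                   nu_grid = c(0, 1, 2, 4, 8), mu_grid = c(0, 1, 2, 4, 8),
                   n_repeats = 3, rng_seed = 1)
surf$optimum   # cost setting minimizing Total error (alpha = beta = 1)
```

A command-line wrapper with `simulate`, `sweep`, `stats` and `demo`
subcommands is installed at
`system.file("cli", "effspike.R", package = "effspike")`.

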