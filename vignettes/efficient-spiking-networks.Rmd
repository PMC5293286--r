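---
title: "Efficient predictive-coding spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient predictive-coding spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effspike)
```

## The model

A population of $N$ leaky integrate-and-fire neurons jointly represents a
$J$-dimensional signal $x(t)$, the exponential filtration (rate $\lambda$)
of a feed-forward input $s(t)$. Each neuron $i$ carries a decoding weight
vector $w_i \in \mathbb{R}^J$; the read-out is
$\hat{x}_j(t) = \sum_i w_{ij}\, r_i(t)$, where $r_i$ is the spike train of
neuron $i$ filtered with the same exponential kernel. The network is not a
hand-designed circuit: it is derived by asking that each spike greedily
minimize the objective

$$E(t) = \lVert x(t) - \hat{x}(t) \rVert^2
       + \nu \sum_i r_i(t) + \mu \sum_i r_i(t)^2 ,$$

a squared coding error plus a linear cost $\nu$ on total firing and a
quadratic cost $\mu$ on squared rates. Carrying out the minimization turns
the membrane potential into the projection of the instantaneous coding
error onto the neuron's weight,
$V_i = w_i^\top (x - \hat{x}) - \mu r_i$, governed by

$$\dot V_i = -\lambda V_i + \sum_j w_{ij} s_j(t)
            - \sum_k \phi_{ik}\, o_k(t) - \mu\, o_i(t) + \sigma \eta_i(t),$$

with $\phi = $ the Gram matrix of the weights (lateral and recurrent
couplings, `connectivity_matrix()`), $o_k$ the spike trains, and
$\sigma\eta_i$ independent white membrane noise. A spike is fired when

$$V_i > \tfrac{1}{2}\lVert w_i \rVert^2 + \tfrac{\mu}{2} + \tfrac{\nu}{2}.$$

The costs therefore have a direct biophysical reading: $\nu$ raises all
thresholds uniformly (homeostatic excitability), and $\mu$ additionally
deepens the spike-triggered reset (adaptation). Note one typographic
wrinkle in the source material: the firing rule is printed in two forms,
with and without the factor $\tfrac12$ on $\lVert w_i\rVert^2$; the
derivation from the greedy minimization unambiguously supports the
$\tfrac12$ form, which is what `firing_thresholds()` implements.

With instantaneous synapses and no noise, the derivation guarantees that
every spike lowers $E$ and that the projected error stays bounded by the
thresholds — the network tracks with single-spike precision and the costs
are best left at zero. Biological networks have neither property: with a
synaptic transmission delay, a spike cannot inhibit the spiker's peers
before they too cross threshold, so neurons of similar selectivity fire
together and neurons of opposite selectivity answer them one delay later
(the "ping-pong"). With membrane noise, spurious spikes create errors that
the network then corrects. Both mechanisms generate *Up states*: transient,
internally generated bursts of synchronized population firing, present even
without any external drive. Their read-out, however, oscillates around
zero — the bursts recruit opposite-selectivity neurons in alternation, so
they interfere only minimally with the represented signal.

## Integration scheme and numerical choices

* **Membrane integration** is forward Euler at `dt` (default 0.1 ms), with
  Euler–Maruyama noise increments $\sigma\sqrt{dt}\,z$. `noise_sd` is
  quoted in the millisecond-based units conventional for this model (a
  value of 0.25 means an increment of $0.25\sqrt{dt_{\rm ms}}$); it is
  converted to the per-second grid at the configuration boundary.
* **Signals, rates and read-outs** use the *exact* exponential-Euler
  update $y_{t+1} = e^{-\lambda dt} y_t + u_t$ (`leaky_filter()`,
  `decode_estimate()`), which is unconditionally stable. Because the
  membrane uses plain Euler while the error terms use the exact filter,
  the identity $V_i = w_i^\top(x-\hat{x}) - \mu r_i$ holds only up to a
  discretization residual; `membrane_consistency_residual()` measures it,
  and it shrinks at first order in `dt` (this is a deliberate diagnostic:
  had both sides used the identical recursion the residual would be zero
  by construction and would certify nothing).
* **Delay semantics.** In the delayed mode (default) every suprathreshold
  neuron fires within the step and its *lateral* couplings take effect
  `delay` seconds later (default 1 ms all-to-all, 2 ms topographic). The
  neuron's own reset (autapse and the $\mu$ hyperpolarization) is applied
  immediately: the reset is the neuron's own mechanism, whereas
  synchronization arises because lateral inhibition is late. The source
  material does not state whether the self-terms are delayed, so the
  alternative is available as `self_delay = TRUE`.
* **Instantaneous mode** resolves within-step spikes sequentially,
  largest threshold violation first, ties broken uniformly at random,
  with immediate recurrent updates. This is the regime in which the
  greedy-descent and bounded-error guarantees hold, and the test suite
  checks both there. With membrane noise, zero costs and (near-)opposite
  weight pairs this mode can cycle — the noise decouples $V$ from the
  true error, and mutually excitatory pairs can re-trigger each other
  indefinitely within one step — so the core guards the within-step spike
  count and fails loudly rather than looping.
* **Spike failure** (`p_spike` < 1) draws one Bernoulli per suprathreshold
  neuron per step; on failure no reset is applied, so the membrane stays
  near threshold and firing is *deferred*, not removed. Consequently a
  lower `p_spike` thins synchronous recruitment but need not reduce the
  total spike count of a long run.
* **Reproducibility.** All randomness — weights, inputs, membrane noise,
  tie-breaks, failures — flows through R's RNG from user-supplied seeds.
  Membrane-noise draws are consumed for every neuron at every step, so two
  runs with the same seed and different costs see the same frozen noise
  (with `p_spike = 1`).

## The minimal two-neuron episodes

Two analytically tractable episodes anchor the test suite. With weights
$(a, -b)$, zero costs and negligible leak, one forced spike of the large
neuron ($a = 10b$) drives the estimate a distance $10b$ from the origin,
and the small neuron corrects it with exactly ten spikes. With
antisymmetric weights $(a, -a)$ and linear cost $\nu$, a forced spike of a
neuron sitting at its no-cost threshold $a^2/2$ is answered by one
corrective spike of its partner (requires $\nu < a^2$); the returning
excitatory coupling re-triggers the first neuron — sustaining the
ping-pong — unless $\nu$ exceeds twice the leak-induced decay
$2a^2\varepsilon$, $\varepsilon = 1 - e^{-\lambda\,\text{delay}}$. In the
simulated episode the round trip lasts two delays, so the exact switch
point is $a^2(1 - e^{-2\lambda\,\text{delay}})$, which tends to
$2a^2\varepsilon$ for small $\lambda\,\text{delay}$; the tests place
$\nu$ well inside and well outside the window rather than at its edge.

## Spike-train statistics

* **MUA** (`compute_mua()`): population sum of spike trains convolved with
  $e^{-\lambda_D t}$, $\lambda_D = 50$ Hz.
* **S-MUA** (`compute_smua()`): the multi-unit activity observed in a
  ±100 ms window around each spike, corrected by the same quantity with
  spikes and MUA taken from incongruent trials (circular shift of the
  trial index), averaged over neurons and normalized by the total spike
  count. Because MUA is shared by all neurons of a trial, the
  neuron-by-neuron definition collapses algebraically to a
  cross-correlation of the population spike-count train with the MUA; the
  implementation computes that identical form on a 1 ms lag grid.
  One property deserves emphasis: since the MUA kernel is causal, the
  spike-triggered average is the (symmetric) spike-count autocorrelation
  convolved with the kernel, so its argmax is displaced from zero by up
  to one kernel time constant ($1/\lambda_D = 20$ ms) toward positive
  lags — in burst-synchronized regimes it lands a few milliseconds after
  zero, an offset invisible at coarser lag resolutions. The tests
  therefore assert zero-lag locking at the kernel scale (argmax within
  $1/\lambda_D$ of zero, zero-lag value dominating the window edges)
  rather than a literal argmax of zero.
* **Up states** (`detect_up_states()`): a step is "up" when at least 20%
  of the neurons fired within the trailing window (default: one synaptic
  delay, the timescale on which synchronized recruitment happens). The
  20% criterion is operational; results are qualitatively robust to it.
  Raising the fraction shrinks the set of qualifying steps — total Up time
  is monotone and stricter segments nest inside looser ones — but the
  segment *count* can transiently rise when a long segment splits, which
  is why the tests assert set-shrinkage rather than count monotonicity.
* **Interval statistics**: inter-burst intervals are fitted with a Gamma
  distribution (maximum likelihood via `MASS::fitdistr`, moment-matched
  start, at least 10 intervals); durations are summarized with an
  Epanechnikov-kernel density (`stats::density`, plug-in bandwidth,
  overridable), as the duration distribution is generally multimodal.
* **CV2** (`compute_cv2()`): $2|ISI_{j+1}-ISI_j|/(ISI_{j+1}+ISI_j)$
  averaged over consecutive interval pairs and over neurons with at least
  three spikes; ~1 for Poisson firing, 0 for clockwork firing, invariant
  to time rescaling.

## Efficiency analysis and its study conditions

Efficiency is measured by
$\langle error\rangle$ — the time- and dimension-averaged absolute
residual $|x_j - \hat{x}_j|$, rescaled by the across-neuron mean weight
norm — and $\langle cost\rangle$ — the average population firing rate in
spikes/s — combined as
$\text{Total error} = \alpha\langle error\rangle + \beta\langle
cost\rangle$ with $\alpha = \beta = 1$ by default. `cost_sweep()`
evaluates the three measures over a $(\nu, \mu)$ grid with common random
numbers across cells (the same repeat uses the same input and noise seeds
everywhere) and locates the minimizing cell, reporting the few best cells
alongside since the valley of good settings is shallow.

The original study's network and input parameters are not printed in its
main text, so this package fixes its own study conditions once and uses
them throughout tests and the acceptance analysis:

* all-to-all network of $N = 100$ neurons (scaled down from 400 to keep
  the default test run in seconds; $N$ is a constructor argument), $J=3$
  signal dimensions, standard-normal weights;
* $\lambda = 4$ Hz membrane/decoder leak; `dt` = 0.1 ms; 1 ms delay;
* membrane noise $\sigma = 0.25$ (ms-based units) for the Up-state
  regimes — its stationary membrane excursion ($\approx 2.8$) is about
  twice the zero-cost threshold, so the quiescent network produces
  Up states at low costs and falls asynchronous as $\nu$ grows;
* active-state drive: smoothed white noise, $\lambda_{\rm input} = 2$ Hz,
  amplitude 40, giving a target signal of standard deviation $\approx 3$
  per dimension — about twice the mean weight norm, so failing to track
  it is markedly worse than tracking it;
* sweep grid $\nu, \mu \in \{0, 1, 2, 4, 8\}$, 3 repeats of 2 s per cell,
  with a 20 s trial at the located optimum for spike-train statistics.

One structural feature of the measure is worth stating plainly. A single
spike adds $1/T$ to $\langle cost\rangle$ but can reduce
$\langle error\rangle$ by at most
$\lVert w_i\rVert / (\lambda J T \langle\lVert w\rVert\rangle) \approx
1/(\lambda J T)$, because its effect on the read-out decays at
$\lambda$. With $\lambda J = 12$ under these conditions, the equally
weighted total therefore always rewards fewer spikes once the
pathological synchronized firing has been eliminated: on any finite grid
the Total-error minimum sits at the high-cost end of the swept range,
away from the zero-cost edges where the delayed network ping-pongs at
five orders of magnitude higher cost. The qualitative findings are
unaffected — the $\langle error\rangle$ alone has a genuine interior
minimum in $\nu$ (tracking degrades once thresholds exceed the drive),
Total error is far more sensitive to $\mu$ than to $\nu$, Up-state
frequency decreases with $\nu$ and is zero at the located optimum, and
firing there is near-Poisson (CV2 $\approx 1$). A regime in which the
total-error optimum is interior in the strict sense would require
$\lambda J \lesssim 1$, i.e. a decoder time constant of seconds.

## What the synthetic conditions do and do not show

All inputs are generated in code: there is no external data. The
smoothed-noise drive emulates a stationary, Gaussian, temporally
correlated stimulus with independent dimensions; the circular bump drive
emulates a single object moving on a ring. Real sensory drive is neither
stationary nor Gaussian, real networks have heterogeneous delays and
plastic weights, and slow (e.g. NMDA-like) currents are outside the model
(fast currents only). Passing tests therefore certify the internal
consistency of the derivation (greedy descent, bounded error, membrane ≡
projected error), the exact minimal-model episodes, and the qualitative
regime structure under the stated conditions — not quantitative agreement
with any biological recording.

## Known limitations

* The within-step sequential resolution of instantaneous mode is
  quadratic in the number of simultaneous crossings; it is intended for
  the small analytical networks, not for large synchronized ones.
* Chaotic regimes are exactly reproducible for a fixed seed but not
  stable under parameter perturbations: raising $\nu$ on a frozen noise
  realization reduces the spike count in the cost-regularized regime, but
  in strongly synchronized regimes trajectory divergence can produce
  small non-monotonicities.
* Storing membrane traces (`record_v = TRUE`) allocates an $N \times T$
  array; use short trials when recording.
* `spike_matrix()`/`firing_rates()` materialize dense arrays and are
  meant for diagnostic-scale runs.
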