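# Shared fixtures: minimal two-neuron models, small noisy networks and
# synthetic rasters. Everything is generated in code under fixed seeds.

DT <- 1e-4

two_neuron_spec <- function(w1, w2) {
  spec <- build_random_network(2, 1, rng_seed = 1)
  set_weights(spec, matrix(c(w1, w2)))
}

zero_input <- function(n_dims, duration, dt = DT) {
  input_signal(matrix(0, n_dims, round(duration / dt)), dt)
}

# a spike raster built directly from times/ids (for the statistics tests)
synthetic_raster <- function(time_s, neuron_id, n_neurons, duration,
                             dt = 1e-3) {
  spike_raster(time_s, neuron_id, n_neurons, dt,
               n_steps = round(duration / dt))
}

# independent homogeneous Poisson rasters on a common grid
poisson_raster <- function(n_neurons, rate_hz, duration, dt = 1e-3,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  times <- c(); ids <- c()
  for (i in seq_len(n_neurons)) {
    n <- rpois(1, rate_hz * duration)
    if (n > 0) {
      tt <- sort(runif(n, 0, duration))
      tt <- (floor(tt / dt)) * dt  # snap to the grid
      times <- c(times, tt); ids <- c(ids, rep(i, n))
    }
  }
  spike_raster(times, ids, n_neurons, dt, n_steps)
}

# study-condition network + config used by the regime-level tests:
# scaled-down all-to-all network in the delayed, noisy setting
study_network <- function(n = 100, seed = 11) build_random_network(n, 3, seed)

study_config <- function(duration, noise_sd = 0.25, rng_seed = 1,
                         p_spike = 1) {
  sim_config(dt = DT, duration = duration, leak_rate = 4, delay = 1e-3,
             noise_sd = noise_sd, p_spike = p_spike, rng_seed = rng_seed,
             coupling_mode = "delayed")
}

study_input <- function(duration, seed, amplitude = 40) {
  smoothed_white_noise(3, duration, DT, smoothing_rate = 2,
                       amplitude = amplitude, rng_seed = seed)
}
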