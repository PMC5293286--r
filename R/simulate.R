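#' Simulation configuration
#'
#' Times are in seconds and rates in Hz throughout. The membrane noise
#' standard deviation `noise_sd` is quoted in the millisecond-based units
#' used for reporting noise levels (an Euler--Maruyama increment of
#' `noise_sd * sqrt(dt_ms)` per step); it is converted internally to the
#' per-second grid (`noise_sd * sqrt(1000)`).
#'
#' @param dt integration step in seconds (default 0.1 ms).
#' @param duration trial length in seconds; may be left `NULL` to take the
#'   length of the input signal.
#' @param leak_rate membrane/decoder leak rate `lambda` in Hz.
#' @param delay synaptic transmission delay in seconds; must be an integer
#'   multiple of `dt`. Must be `>= dt` in delayed mode and `0` in
#'   instantaneous mode.
#' @param noise_sd membrane white-noise standard deviation (ms-based
#'   units, e.g. `0.25`); `0` disables noise.
#' @param p_spike probability in `[0, 1]` that a suprathreshold neuron
#'   actually emits a spike in a step (spike-generation failure); on
#'   failure no reset is applied, so the membrane stays near threshold.
#' @param rng_seed optional integer seed applied just before integration.
#' @param coupling_mode `"delayed"` (all suprathreshold neurons fire
#'   within the same step; lateral couplings act after `delay`) or
#'   `"instantaneous"` (spikes within a step resolved one at a time,
#'   largest threshold violation first, ties broken at random, with
#'   immediate recurrent update).
#' @param self_delay if `TRUE` the neuron's own reset (autapse and the
#'   `mu` adaptation) is also delayed; by default it is immediate, since
#'   the reset is the neuron's own mechanism while synchronization comes
#'   from the *lateral* couplings being delayed.
#' @param initial_v initial membrane potential(s), recycled to `N`.
#' @param bias optional per-neuron constant input current (recycled),
#'   useful for holding neurons at a controlled operating point in the
#'   minimal-model analyses.
#' @param record_v if `TRUE` the full `N x T` membrane-potential array is
#'   stored in the result (memory permitting; intended for small runs).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-4, duration = NULL, leak_rate = 4,
                       delay = 1e-3, noise_sd = 0, p_spike = 1,
                       rng_seed = NULL,
                       coupling_mode = c("delayed", "instantaneous"),
                       self_delay = FALSE, initial_v = 0, bias = 0,
                       record_v = FALSE) {
  coupling_mode <- match.arg(coupling_mode)
  check_positive_scalar(dt, "dt")
  if (!is.null(duration)) check_positive_scalar(duration, "duration")
  check_positive_scalar(leak_rate, "leak_rate")
  check_nonneg_scalar(delay, "delay")
  check_nonneg_scalar(noise_sd, "noise_sd")
  if (!is.numeric(p_spike) || length(p_spike) != 1L || p_spike < 0 || p_spike > 1)
    stop_arg("`p_spike` must lie in [0, 1]")
  delay_steps <- as.integer(round(delay / dt))
  if (abs(delay - delay_steps * dt) > 1e-9 * max(dt, delay))
    stop_arg("`delay` must be an integer multiple of `dt`")
  if (coupling_mode == "instantaneous" && delay_steps != 0L)
    stop_arg("instantaneous coupling requires `delay = 0`")
  if (coupling_mode == "delayed" && delay_steps < 1L)
    stop_arg("delayed coupling requires `delay >= dt`")
  structure(list(dt = dt, duration = duration, leak_rate = leak_rate,
                 delay = delay, delay_steps = delay_steps,
                 noise_sd = noise_sd, p_spike = p_spike,
                 rng_seed = rng_seed, coupling_mode = coupling_mode,
                 self_delay = isTRUE(self_delay),
                 initial_v = initial_v, bias = bias,
                 record_v = isTRUE(record_v)),
            class = "sim_config")
}

#' Spike raster container
#'
#' A data frame of spikes (`time_s`, `neuron_id` with 1-based ids; times
#' at the left edge of the emitting step) carrying the grid metadata
#' needed by the statistics functions.
#'
#' @param time_s spike times in seconds.
#' @param neuron_id 1-based neuron ids.
#' @param n_neurons number of neurons in the network.
#' @param dt grid step in seconds.
#' @param n_steps number of grid steps in the trial.
#' @return A data frame of class `spike_raster` with attributes
#'   `n_neurons`, `dt`, `n_steps`, `duration`.
#' @export
spike_raster <- function(time_s, neuron_id, n_neurons, dt, n_steps) {
  df <- data.frame(time_s = as.numeric(time_s),
                   neuron_id = as.integer(neuron_id))
  df <- df[order(df$time_s, df$neuron_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_neurons = as.integer(n_neurons), dt = dt,
            n_steps = as.integer(n_steps), duration = n_steps * dt,
            class = c("spike_raster", "data.frame"))
}

raster_steps <- function(raster) {
  as.integer(round(raster$time_s / attr(raster, "dt"))) + 1L
}

#' Simulate the predictive-coding spiking network
#'
#' Integrates the membrane equation `dV/dt = -lambda*V + w %*% s(t)
#' - phi %*% o(t - delay) - mu*o(t) + sigma*eta(t)` by forward Euler on
#' the input's grid and applies the firing rule `V_i > Thres_i` (see
#' [firing_thresholds()]). The target signal and the decoded estimate are
#' computed with the exact exponential filter ([leaky_filter()],
#' [decode_estimate()]); the Euler-integrated membrane potential agrees
#' with the projected coding error `w (x - xhat) - mu*r` up to `O(dt)`
#' (see [membrane_consistency_residual()]).
#'
#' @param spec a `network_spec`.
#' @param input an `input_signal` whose dimensionality matches
#'   `spec$n_signals` and whose grid matches `config`.
#' @param costs a [cost_params()] object.
#' @param config a [sim_config()] object.
#' @param forced_spikes optional data frame with columns `time_s` and
#'   `neuron_id`: spikes imposed at the given steps regardless of the
#'   threshold (used to perturb the quiescent network in the minimal-model
#'   analyses).
#' @return An object of class `sim_result` with fields `spikes` (a
#'   [spike_raster()]), `estimate` (`J x T` decoded signal), `target`
#'   (`J x T`), `V` (`N x T` if `record_v`, else `NULL`), and the `spec`,
#'   `costs`, `config`, `input` used.
#' @export
#' @examples
#' spec <- network_spec(matrix(1))  # single neuron, w = 1
#' inp <- input_signal(matrix(2, 1, 4000), dt = 1e-4)
#' cfg <- sim_config(dt = 1e-4, delay = 0, coupling_mode = "instantaneous",
#'                   record_v = TRUE)
#' res <- simulate_network(spec, inp, cost_params(), cfg)
#' nrow(res$spikes)  # spikes fired while tracking the step input
simulate_network <- function(spec, input, costs = cost_params(),
                             config = sim_config(), forced_spikes = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(input, "input_signal"),
            inherits(costs, "cost_params"), inherits(config, "sim_config"))
  if (nrow(input$s) != spec$n_signals)
    stop_arg("input has ", nrow(input$s), " dimension(s) but the network ",
             "expects ", spec$n_signals)
  if (abs(input$dt - config$dt) > 1e-12)
    stop_arg("input grid (dt = ", input$dt, ") does not match the ",
             "configuration (dt = ", config$dt, ")")
  n_steps <- ncol(input$s)
  if (!is.null(config$duration) &&
      abs(config$duration - n_steps * config$dt) > config$dt / 2)
    stop_arg("input duration does not match `config$duration`")

  N <- spec$n_neurons
  thres <- firing_thresholds(spec, costs)
  sigma <- config$noise_sd * sqrt(1000)  # ms-based units -> per-second grid
  v0 <- rep_len(config$initial_v, N)
  bias <- rep_len(config$bias, N)

  if (is.null(forced_spikes)) {
    fstep <- integer(0); fneuron <- integer(0)
  } else {
    fstep <- as.integer(round(forced_spikes$time_s / config$dt)) + 1L
    fneuron <- as.integer(forced_spikes$neuron_id)
    if (any(fneuron < 1L | fneuron > N)) stop_arg("forced neuron id out of range")
    if (any(fstep < 1L | fstep > n_steps)) stop_arg("forced spike time out of range")
  }

  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  core <- .sim_core(spec$w, spec$phi, thres, input$s,
                    config$dt, config$leak_rate, costs$mu, sigma,
                    config$p_spike, config$delay_steps,
                    config$coupling_mode == "instantaneous",
                    config$self_delay, v0, bias, fstep, fneuron,
                    config$record_v)

  raster <- spike_raster((core$step - 1) * config$dt, core$neuron,
                         n_neurons = N, dt = config$dt, n_steps = n_steps)
  structure(list(
    spikes = raster,
    estimate = decode_estimate(raster, spec, config$leak_rate, config$dt,
                               n_steps = n_steps),
    target = leaky_filter(input$s, config$leak_rate, config$dt),
    V = if (config$record_v) core$V else NULL,
    spec = spec, costs = costs, config = config, input = input,
    n_steps = n_steps, duration = n_steps * config$dt),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$spec$n_neurons, "neurons,",
      x$duration, "s at dt =", x$config$dt, "s;",
      nrow(x$spikes), "spikes (",
      round(nrow(x$spikes) / x$duration, 1), "spk/s population )\n")
  invisible(x)
}

#' Decode the signal estimate from a spike raster
#'
#' The estimate is the weighted sum of instantaneous firing rates,
#' `xhat_j(t) = sum_i w[i, j] * r_i(t)`, where each rate is the leaky
#' filtration of the spike train (a spike makes `r_i` jump by 1, decaying
#' at `leak_rate` thereafter). Decoding is linear: the decode of a union
#' of rasters is the sum of the decodes.
#'
#' @param raster a [spike_raster()] (or a `sim_result`).
#' @param spec the `network_spec` whose weights decode the spikes.
#' @param leak_rate decoder leak rate in Hz.
#' @param dt grid step in seconds.
#' @param n_steps number of grid steps (defaults to the raster's).
#' @return A `J x T` matrix.
#' @export
decode_estimate <- function(raster, spec, leak_rate = 4, dt = NULL,
                            n_steps = NULL) {
  if (inherits(raster, "sim_result")) {
    spec <- raster$spec; dt <- raster$config$dt
    leak_rate <- raster$config$leak_rate; n_steps <- raster$n_steps
    raster <- raster$spikes
  }
  stopifnot(inherits(spec, "network_spec"))
  dt <- dt %||% attr(raster, "dt")
  n_steps <- n_steps %||% attr(raster, "n_steps")
  J <- spec$n_signals
  innov <- matrix(0, nrow = n_steps, ncol = J)
  if (nrow(raster) > 0) {
    steps <- as.integer(round(raster$time_s / dt)) + 1L
    agg <- rowsum(spec$w[raster$neuron_id, , drop = FALSE], group = steps)
    innov[as.integer(rownames(agg)), ] <- agg
  }
  a <- exp(-leak_rate * dt)
  out <- matrix(0, nrow = J, ncol = n_steps)
  for (j in seq_len(J))
    out[j, ] <- as.numeric(stats::filter(innov[, j], a, method = "recursive"))
  out
}

#' Binary spike-count matrix of a raster
#'
#' @param raster a [spike_raster()].
#' @param n_steps number of grid steps (defaults to the raster's).
#' @return An `N x T` integer matrix of per-step spike counts.
#' @export
spike_matrix <- function(raster, n_steps = NULL) {
  n_steps <- n_steps %||% attr(raster, "n_steps")
  N <- attr(raster, "n_neurons")
  o <- matrix(0L, nrow = N, ncol = n_steps)
  if (nrow(raster) > 0) {
    idx <- cbind(raster$neuron_id, raster_steps(raster))
    # incremental assignment handles repeated spikes within a step
    for (k in seq_len(nrow(raster)))
      o[idx[k, 1], idx[k, 2]] <- o[idx[k, 1], idx[k, 2]] + 1L
  }
  o
}

#' Instantaneous firing rates of a raster
#'
#' Leaky filtration of each neuron's spike train: a spike makes the rate
#' jump by 1, decaying exponentially at `leak_rate`.
#'
#' @inheritParams spike_matrix
#' @param leak_rate leak rate in Hz.
#' @param dt grid step (defaults to the raster's).
#' @return An `N x T` matrix.
#' @export
firing_rates <- function(raster, leak_rate = 4, dt = NULL, n_steps = NULL) {
  dt <- dt %||% attr(raster, "dt")
  o <- spike_matrix(raster, n_steps)
  a <- exp(-leak_rate * dt)
  for (i in seq_len(nrow(o))) {
    # skip silent neurons: their rate stays 0
    if (any(o[i, ] != 0))
      o[i, ] <- as.numeric(stats::filter(o[i, ], a, method = "recursive"))
  }
  storage.mode(o) <- "double"
  o
}

#' Consistency of the integrated membrane potential with the coding error
#'
#' In the model the membrane potential is the projection of the global
#' coding error on the neuron's weight, `V_i = w_i . (x - xhat) - mu*r_i`.
#' This function measures the worst-case discrepancy between the
#' Euler-integrated potentials of a noiseless simulation and that directly
#' evaluated expression. For the no-delay (instantaneous) configuration
#' the residual is `O(dt)` and shrinks linearly with the step size.
#'
#' @param result a `sim_result` produced with `record_v = TRUE` and
#'   `noise_sd = 0`.
#' @param costs cost parameters (defaults to those of the run).
#' @return Scalar `max_{i,t} |V_i(t) - (w_i . (x - xhat) - mu*r_i)|`, with
#'   the per-step maxima attached as attribute `"per_step"`.
#' @export
membrane_consistency_residual <- function(result, costs = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$V))
    stop_arg("simulation was run without `record_v = TRUE`")
  if (result$config$noise_sd > 0)
    stop_arg("the residual is only meaningful for a noiseless run ",
             "(noise_sd = 0): with membrane noise V is not expected to ",
             "equal the projected coding error")
  costs <- costs %||% result$costs
  r <- firing_rates(result$spikes, result$config$leak_rate,
                    result$config$dt, result$n_steps)
  W <- result$spec$w %*% (result$target - result$estimate) - costs$mu * r
  d <- abs(result$V - W)
  res <- max(d, 0)
  attr(res, "per_step") <- apply(d, 2, max)
  res
}
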