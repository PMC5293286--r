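#' Input signal container
#'
#' Holds a `J x T` array of input samples on a uniform time grid. Step `t`
#' covers the interval `[(t-1)*dt, t*dt)`.
#'
#' @param s numeric `J x T` matrix (one row per input dimension).
#' @param dt time step in seconds.
#' @param kind free-form tag describing how the signal was generated.
#' @return An object of class `input_signal` with fields `s`, `dt`,
#'   `duration`.
#' @export
input_signal <- function(s, dt, kind = "custom") {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  dimnames(s) <- NULL
  storage.mode(s) <- "double"
  check_positive_scalar(dt, "dt")
  if (!all(is.finite(s))) stop_arg("input samples must be finite")
  structure(list(s = s, dt = dt, duration = ncol(s) * dt, kind = kind),
            class = "input_signal")
}

#' @export
print.input_signal <- function(x, ...) {
  cat("<input_signal>", x$kind, ":", nrow(x$s), "dimension(s),",
      ncol(x$s), "steps of", x$dt, "s (", x$duration, "s )\n")
  invisible(x)
}

#' Leaky (exponential) filtering of a time series
#'
#' Integrates `dy/dt = -rate * y + input` on the grid with the exact
#' exponential update `y[t] = y[t-1] * exp(-rate * dt) + input[t] * dt`,
#' which is unconditionally stable and linear in the input. This is the
#' filter that turns an input into the target signal, a spike train into
#' an instantaneous firing rate, and weighted spikes into the decoded
#' estimate.
#'
#' @param series numeric vector or `K x T` matrix (one row per channel).
#' @param rate leak rate `lambda` in Hz (`> 0`).
#' @param dt time step in seconds.
#' @param initial initial value(s) `y(0)`, recycled across channels.
#' @return Filtered series with the same shape as `series`.
#' @export
#' @examples
#' y <- leaky_filter(rep(2, 5000), rate = 4, dt = 1e-3)
#' tail(y, 1)  # ~ 2 / 4, the steady state of the leaky integrator
leaky_filter <- function(series, rate, dt, initial = 0) {
  check_positive_scalar(rate, "rate")
  check_positive_scalar(dt, "dt")
  vec <- !is.matrix(series)
  x <- if (vec) matrix(series, nrow = 1) else series
  init <- rep_len(initial, nrow(x))
  a <- exp(-rate * dt)
  out <- x
  for (k in seq_len(nrow(x)))
    out[k, ] <- as.numeric(stats::filter(x[k, ] * dt, a,
                                         method = "recursive",
                                         init = init[k]))
  if (vec) drop(out) else out
}

#' Smoothed white-noise input
#'
#' Each dimension is discretized white noise (i.i.d. Gaussian per step,
#' scaled by `amplitude / sqrt(dt)` so that the statistics of the smoothed
#' signal do not depend on the step size) convolved with the exponential
#' filter `exp(-smoothing_rate * t)`. Dimensions are mutually independent.
#' The stationary standard deviation of each smoothed dimension is
#' approximately `amplitude / sqrt(2 * smoothing_rate)`.
#'
#' @param n_dims number of independent input dimensions.
#' @param duration trial length in seconds.
#' @param dt time step in seconds.
#' @param smoothing_rate exponential smoothing rate `lambda_input` in Hz.
#' @param amplitude white-noise amplitude; `0` gives an all-zero signal.
#' @param rng_seed optional integer seed.
#' @return An `input_signal` of kind `"smoothed_noise"`.
#' @export
smoothed_white_noise <- function(n_dims, duration, dt,
                                 smoothing_rate = 2, amplitude = 1,
                                 rng_seed = NULL) {
  check_positive_scalar(duration, "duration")
  check_positive_scalar(dt, "dt")
  check_positive_scalar(smoothing_rate, "smoothing_rate")
  check_nonneg_scalar(amplitude, "amplitude")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_steps <- max(1L, round(duration / dt))
  z <- matrix(rnorm(n_dims * n_steps), nrow = n_dims) * amplitude / sqrt(dt)
  out <- input_signal(leaky_filter(z, smoothing_rate, dt), dt,
                      kind = "smoothed_noise")
  attr(out, "smoothing_rate") <- smoothing_rate
  attr(out, "amplitude") <- amplitude
  out
}

#' Circular Gaussian-bump drive for the topographic network
#'
#' The stimulus is a bump on the ring: pixel `j` at angle `theta_j`
#' receives `s_j(t) = A * exp(B * (cos(theta_j - c(t)) - 1))`, where the
#' bump center `c(t)` is a smoothed-white-noise trajectory (exponential
#' filter at `trajectory_rate`, rescaled to stationary standard deviation
#' `trajectory_sd` radians).
#'
#' @param params a [topographic_params()] object (`A`, `B`, and the pixel
#'   count `n_on` are used).
#' @param duration trial length in seconds.
#' @param dt time step in seconds.
#' @param trajectory_rate smoothing rate of the bump-center trajectory, Hz.
#' @param trajectory_sd stationary standard deviation of `c(t)`, radians.
#' @param rng_seed optional integer seed.
#' @return An `input_signal` of kind `"circular_bump"`; the trajectory
#'   `c(t)` is attached as attribute `"trajectory"`.
#' @export
circular_bump_drive <- function(params, duration, dt,
                                trajectory_rate = 2, trajectory_sd = pi / 2,
                                rng_seed = NULL) {
  stopifnot(inherits(params, "topographic_params"))
  check_positive_scalar(duration, "duration")
  check_positive_scalar(dt, "dt")
  check_positive_scalar(trajectory_rate, "trajectory_rate")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_steps <- max(1L, round(duration / dt))
  raw <- leaky_filter(rnorm(n_steps) / sqrt(dt), trajectory_rate, dt)
  a <- exp(-trajectory_rate * dt)
  sd0 <- sqrt(dt / (1 - a^2))  # stationary sd of the unit-amplitude filter
  cc <- raw * trajectory_sd / sd0
  theta <- 2 * pi * (0:(params$n_on - 1L)) / params$n_on
  s <- params$A * exp(params$B * (cos(outer(theta, cc, "-")) - 1))
  out <- input_signal(s, dt, kind = "circular_bump")
  attr(out, "trajectory") <- cc
  out
}

#' Target signal of an input
#'
#' The target is the input convolved with the decoder's exponential filter
#' `exp(-leak_rate * t)`: the quantity the network's read-out is trying to
#' track. A zero input gives a zero target at all times.
#'
#' @param input an `input_signal`.
#' @param leak_rate decoder/membrane leak rate `lambda` in Hz.
#' @return An object of class `target_signal` with fields `x` (`J x T`)
#'   and `dt`.
#' @export
target_signal <- function(input, leak_rate = 4) {
  stopifnot(inherits(input, "input_signal"))
  structure(list(x = leaky_filter(input$s, leak_rate, input$dt),
                 dt = input$dt),
            class = "target_signal")
}

#' Write a multichannel time series as CSV
#'
#' Column 1 is time in seconds (left edge of each step), then one column
#' per dimension.
#'
#' @param x an `input_signal`, `target_signal`, or `K x T` matrix.
#' @param path output file path.
#' @param dt time step; taken from `x` when available.
#' @param prefix column-name prefix for the dimensions.
#' @return The path, invisibly.
#' @export
write_signal_csv <- function(x, path, dt = NULL, prefix = "dim") {
  if (inherits(x, "input_signal")) { dt <- x$dt; x <- x$s }
  if (inherits(x, "target_signal")) { dt <- x$dt; x <- x$x }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (is.null(dt)) stop_arg("`dt` is required for a bare matrix")
  df <- data.frame(time_s = (seq_len(ncol(x)) - 1) * dt, t(x))
  names(df)[-1] <- paste0(prefix, seq_len(nrow(x)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series CSV written by [write_signal_csv()]
#'
#' @param path file path.
#' @return An `input_signal` (dimensions in rows).
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path)
  if (names(df)[1] != "time_s") stop_arg("expected a `time_s` first column")
  dt <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  input_signal(t(as.matrix(df[, -1, drop = FALSE])), dt, kind = "from_csv")
}
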