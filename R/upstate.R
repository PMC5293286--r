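# Spike-train statistics: MUA, shuffle-corrected S-MUA, Up-state
# detection, inter-burst / duration summaries, CV2 and synchrony.

#' Multi-unit activity
#'
#' Convolves every neuron's spike train with the exponential kernel
#' `exp(-decay_rate * t)` and sums across neurons. The default
#' `decay_rate` of 50 Hz is short enough to capture fast fluctuations of
#' the population rate.
#'
#' @param raster a [spike_raster()].
#' @param n_neurons,dt grid metadata (default: taken from the raster).
#' @param decay_rate kernel decay rate `lambda_D` in Hz.
#' @return An object of class `mua_trace` with fields `values` (length
#'   `T`, non-negative), `dt`, `decay_rate`.
#' @export
compute_mua <- function(raster, n_neurons = NULL, dt = NULL,
                        decay_rate = 50) {
  dt <- dt %||% attr(raster, "dt")
  n_steps <- attr(raster, "n_steps")
  counts <- tabulate(raster_steps(raster), nbins = n_steps)
  a <- exp(-decay_rate * dt)
  values <- as.numeric(stats::filter(counts, a, method = "recursive"))
  structure(list(values = values, dt = dt, decay_rate = decay_rate),
            class = "mua_trace")
}

#' Shuffle-corrected spike-triggered multi-unit activity
#'
#' For each spike, the multi-unit activity is observed in a window of
#' `window` seconds before and after the spike (lag 0 = the MUA at the
#' spike time). To correct for chance coincidences, the same quantity is
#' computed with each trial's spikes paired against the MUA of an
#' *incongruent* trial (circular shift of the trial index), and
#' subtracted. The corrected profile is averaged over neurons and
#' normalized by the total number of spikes. Because the MUA is shared by
#' all neurons within a trial, the sum over neurons collapses exactly to a
#' cross-correlation of the population spike-count train with the MUA;
#' that algebraically identical form is computed here.
#'
#' A synchronized network yields a profile peaking at zero lag; for
#' independent neurons the corrected profile fluctuates around zero.
#'
#' @param trials list of at least two [spike_raster()]s on identical
#'   grids (the shuffle needs an incongruent pairing).
#' @param dt grid step (default: taken from the rasters).
#' @param window half-width of the lag window in seconds.
#' @param lag_step lag resolution in seconds (both series are binned to
#'   this resolution; it should be well below `1/decay_rate`).
#' @param decay_rate MUA kernel decay rate in Hz.
#' @return An object of class `smua_profile` with fields `lags` (symmetric
#'   about 0), `values`, `n_trials`, `peak_lag` (argmax, ties resolved to
#'   the smallest absolute lag).
#' @export
compute_smua <- function(trials, dt = NULL, window = 0.1,
                         lag_step = 1e-3, decay_rate = 50) {
  if (!is.list(trials) || length(trials) < 2L)
    stop_arg("the shuffle correction requires at least two trials: ",
             "S-MUA pairs each trial's spikes with the multi-unit ",
             "activity of an incongruent trial")
  dt <- dt %||% attr(trials[[1]], "dt")
  n_steps <- attr(trials[[1]], "n_steps")
  n_neurons <- attr(trials[[1]], "n_neurons")
  for (tr in trials)
    if (!identical(attr(tr, "n_steps"), n_steps))
      stop_arg("all trials must share the same grid")
  bin <- max(1L, as.integer(round(lag_step / dt)))
  n_bins <- n_steps %/% bin
  L <- as.integer(round(window / (bin * dt)))
  lags_idx <- (-L):L

  bin_series <- function(v, reduce) {
    v <- v[seq_len(n_bins * bin)]
    m <- matrix(v, nrow = bin)
    reduce(m)
  }
  K <- length(trials)
  O <- vector("list", K); M <- vector("list", K)
  total_spikes <- 0
  for (k in seq_len(K)) {
    counts <- tabulate(raster_steps(trials[[k]]), nbins = n_steps)
    mua <- compute_mua(trials[[k]], dt = dt, decay_rate = decay_rate)$values
    O[[k]] <- bin_series(counts, colSums)
    M[[k]] <- bin_series(mua, colMeans)
    total_spikes <- total_spikes + nrow(trials[[k]])
  }
  xcorr <- function(o, m) {
    vapply(lags_idx, function(l) {
      if (l >= 0) sum(o[seq_len(n_bins - l)] * m[seq_len(n_bins - l) + l])
      else        sum(o[seq_len(n_bins + l) - l] * m[seq_len(n_bins + l)])
    }, numeric(1))
  }
  raw <- shuf <- numeric(length(lags_idx))
  for (k in seq_len(K)) {
    raw <- raw + xcorr(O[[k]], M[[k]])
    shuf <- shuf + xcorr(O[[k]], M[[k %% K + 1L]])
  }
  values <- (raw - shuf) / (n_neurons * max(total_spikes, 1))
  lags <- lags_idx * bin * dt
  ord <- order(-values, abs(lags))
  structure(list(lags = lags, values = values, n_trials = K,
                 peak_lag = lags[ord[1]]),
            class = "smua_profile")
}

# Per-step count of distinct neurons with >= 1 spike inside the trailing
# window of `win_steps` steps. Computed in O(total spikes) by merging each
# neuron's spike-extended intervals and accumulating a difference array.
active_neuron_count <- function(raster, n_neurons, dt, window,
                                n_steps = NULL) {
  n_steps <- n_steps %||% attr(raster, "n_steps")
  win <- max(1L, as.integer(round(window / dt)))
  if (nrow(raster) == 0) return(integer(n_steps))
  steps <- raster_steps(raster)
  ids <- raster$neuron_id
  ord <- order(ids, steps)
  ids <- ids[ord]; steps <- steps[ord]
  # a spike at step s makes its neuron "active" on [s, s + win - 1]
  new_int <- c(TRUE, ids[-1] != ids[-length(ids)] |
                 diff(steps) > win)
  grp <- cumsum(new_int)
  starts <- steps[new_int]
  ends <- pmin(steps[c(new_int[-1], TRUE)] + win - 1L, n_steps)
  d <- integer(n_steps + 1L)
  tab_s <- tabulate(starts, nbins = n_steps + 1L)
  tab_e <- tabulate(ends + 1L, nbins = n_steps + 1L)
  cumsum(tab_s - tab_e)[seq_len(n_steps)]
}

#' Detect Up states in a spike raster
#'
#' A step belongs to an Up state when at least `fraction` of the neurons
#' were simultaneously active, i.e. fired at least one spike inside the
#' trailing window of length `window` (default: one synaptic delay, 1 ms,
#' the timescale over which many neurons fire together during an Up
#' state). Contiguous qualifying steps merge into segments. The 20%
#' default criterion is a hand-set operational threshold; results are
#' qualitatively robust to its precise value.
#'
#' @param raster a [spike_raster()].
#' @param n_neurons,dt grid metadata (default: taken from the raster).
#' @param fraction criterion fraction in `(0, 1]`.
#' @param window "simultaneity" window in seconds.
#' @return An object of class `upstate_segments` with a data frame
#'   `segments` (`start_s`, `end_s`; disjoint, ordered, `end > start`),
#'   plus `criterion_fraction`, `window`, `n_neurons`, `duration`.
#' @export
detect_up_states <- function(raster, n_neurons = NULL, dt = NULL,
                             fraction = 0.2, window = 1e-3) {
  n_neurons <- n_neurons %||% attr(raster, "n_neurons")
  dt <- dt %||% attr(raster, "dt")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_arg("`fraction` must lie in (0, 1]")
  n_steps <- attr(raster, "n_steps")
  count <- active_neuron_count(raster, n_neurons, dt, window, n_steps)
  up <- count >= fraction * n_neurons
  r <- rle(up)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values
  seg <- data.frame(start_s = (starts_idx[keep] - 1L) * dt,
                    end_s = ends_idx[keep] * dt)
  structure(list(segments = seg, criterion_fraction = fraction,
                 window = window, n_neurons = n_neurons,
                 duration = n_steps * dt),
            class = "upstate_segments")
}

#' @export
print.upstate_segments <- function(x, ...) {
  cat("<upstate_segments>", nrow(x$segments), "Up state(s) in",
      x$duration, "s (criterion:", x$criterion_fraction * 100,
      "% active within", x$window * 1e3, "ms )\n")
  invisible(x)
}

#' Inter-burst-interval statistics of Up states
#'
#' The inter-burst interval (IBI) is the silent time between the end of
#' one Up state and the start of the next. With at least `min_fit`
#' intervals the IBI distribution is fitted with a Gamma distribution by
#' maximum likelihood (moment-matched start).
#'
#' @param segments an [detect_up_states()] result.
#' @param min_fit minimum number of intervals required for the Gamma fit.
#' @return A list with `ibis` (possibly empty), `mean_ibi`, `n`, `gamma`
#'   (list with `shape`, `rate`, `scale`, or `NULL`), and `fit_status`.
#' @export
interburst_statistics <- function(segments, min_fit = 10) {
  stopifnot(inherits(segments, "upstate_segments"))
  seg <- segments$segments
  if (nrow(seg) < 2) {
    return(list(ibis = numeric(0), mean_ibi = NA_real_, n = 0L,
                gamma = NULL,
                fit_status = "need at least 2 Up states for intervals"))
  }
  ibis <- seg$start_s[-1] - seg$end_s[-nrow(seg)]
  out <- list(ibis = ibis, mean_ibi = mean(ibis), n = length(ibis),
              gamma = NULL, fit_status = "not fitted")
  if (length(ibis) >= min_fit && all(ibis > 0)) {
    m <- mean(ibis); v <- var(ibis)
    fit <- tryCatch(
      MASS::fitdistr(ibis, "gamma",
                     start = list(shape = m^2 / v, rate = m / v),
                     lower = c(1e-8, 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- fit$estimate
      out$gamma <- list(shape = unname(est["shape"]),
                        rate = unname(est["rate"]),
                        scale = 1 / unname(est["rate"]))
      out$fit_status <- "ok"
    } else out$fit_status <- "gamma fit failed"
  } else if (length(ibis) < min_fit) {
    out$fit_status <- paste0("fewer than ", min_fit,
                             " intervals; fit refused")
  }
  out
}

#' Duration statistics of Up states
#'
#' Durations are summarized with a non-parametric Epanechnikov-kernel
#' density estimate (bandwidth by the usual plug-in rule unless
#' overridden), since the duration distribution is generally not well
#' described by a unimodal parametric family.
#'
#' @param segments an [detect_up_states()] result.
#' @param bandwidth optional kernel bandwidth (seconds).
#' @param n_grid number of grid points for the density.
#' @return A list with `durations`, `mean_duration`, `n`, and `density`
#'   (list `x`, `y`, `bw`, or `NULL` when fewer than 2 durations).
#' @export
duration_statistics <- function(segments, bandwidth = NULL, n_grid = 512) {
  stopifnot(inherits(segments, "upstate_segments"))
  seg <- segments$segments
  if (nrow(seg) == 0)
    return(list(durations = numeric(0), mean_duration = NA_real_, n = 0L,
                density = NULL))
  durations <- seg$end_s - seg$start_s
  dens <- NULL
  if (length(durations) >= 2) {
    d <- density(durations, bw = bandwidth %||% "nrd0",
                 kernel = "epanechnikov", n = n_grid)
    dens <- list(x = d$x, y = d$y, bw = d$bw)
  }
  list(durations = durations, mean_duration = mean(durations),
       n = length(durations), density = dens)
}

#' Local coefficient of variation of inter-spike intervals (CV2)
#'
#' For each neuron with at least 3 spikes, CV2 is the mean over
#' consecutive interval pairs of `2 * |ISI[j+1] - ISI[j]| /
#' (ISI[j+1] + ISI[j])`. A Poisson train gives values near 1, a perfectly
#' regular train gives 0, and the statistic is invariant to uniform time
#' rescaling. Neurons with fewer than 3 spikes are excluded from the
#' population mean.
#'
#' @param raster a [spike_raster()].
#' @param per_neuron if `TRUE`, return the per-neuron values as well.
#' @return A list with `mean`, `per_neuron` (named vector or `NULL`),
#'   `n_eligible`, and `status` (`"ok"` or `"undefined"` when no neuron
#'   has enough spikes).
#' @export
compute_cv2 <- function(raster, per_neuron = TRUE) {
  by_neuron <- split(raster$time_s, raster$neuron_id)
  vals <- vapply(by_neuron, function(tt) {
    if (length(tt) < 3) return(NA_real_)
    isi <- diff(sort(tt))
    pair_sum <- isi[-1] + isi[-length(isi)]
    cv2 <- 2 * abs(diff(isi)) / pair_sum
    mean(cv2[pair_sum > 0])
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    return(list(mean = NA_real_, per_neuron = NULL, n_eligible = 0L,
                status = "undefined: no neuron with >= 3 spikes"))
  list(mean = mean(vals),
       per_neuron = if (per_neuron) vals else NULL,
       n_eligible = length(vals), status = "ok")
}

#' Synchrony fraction
#'
#' Per step, the percentage of neurons that fired at least one spike
#' inside the trailing window; 50% means half of the network is spiking
#' in every window. The summary is the mean over steps in which any
#' neuron was active.
#'
#' @param raster a [spike_raster()].
#' @param n_neurons,dt grid metadata (default: taken from the raster).
#' @param window trailing window in seconds (`>= dt`).
#' @return A list with `values` (percentage per step), `summary` (mean
#'   percentage over active steps; `NA` with `status = "undefined"` for an
#'   empty raster), `window`.
#' @export
synchrony_fraction <- function(raster, n_neurons = NULL, dt = NULL,
                               window = 1e-3) {
  n_neurons <- n_neurons %||% attr(raster, "n_neurons")
  dt <- dt %||% attr(raster, "dt")
  if (window < dt) stop_arg("`window` must be at least one grid step")
  count <- active_neuron_count(raster, n_neurons, dt, window)
  values <- 100 * count / n_neurons
  active <- count > 0
  if (!any(active))
    return(list(values = values, summary = NA_real_,
                status = "undefined: empty raster", window = window))
  list(values = values, summary = mean(values[active]),
       status = "ok", window = window)
}
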