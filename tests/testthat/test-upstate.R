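test_that("MUA is the summed exponential filtration of the raster", {
  r <- synthetic_raster(0.05, 1, 3, 0.2, dt = 1e-3)
  m <- compute_mua(r, decay_rate = 50)
  st <- 51
  expect_true(all(m$values[1:(st - 1)] == 0))
  expect_equal(m$values[st], 1)
  expect_equal(m$values[st + 40], exp(-50 * 40 * 1e-3), tolerance = 1e-10)
  # two coincident spikes double the trace (linearity)
  r2 <- synthetic_raster(c(0.05, 0.05), c(1, 2), 3, 0.2, dt = 1e-3)
  expect_equal(compute_mua(r2, decay_rate = 50)$values, 2 * m$values)
  # empty raster
  r0 <- synthetic_raster(numeric(0), integer(0), 3, 0.2, dt = 1e-3)
  expect_true(all(compute_mua(r0)$values == 0))
})

test_that("S-MUA needs two trials and cancels for identical pairings", {
  r <- poisson_raster(10, 5, 10, seed = 1)
  expect_error(compute_smua(list(r)), "two trials")
  # identical trials: raw and shuffle pairings coincide -> exactly zero
  prof <- compute_smua(list(r, r))
  expect_true(all(prof$values == 0))
})

test_that("S-MUA vanishes for independent Poisson populations", {
  trials <- lapply(1:8, function(k) poisson_raster(40, 8, 30, seed = 40 + k))
  prof <- compute_smua(trials)
  # scale reference: the uncorrected spike-triggered MUA level per spike
  # and neuron is ~ rate_total / decay = 40*8/50 = 6.4 spikes of MUA,
  # i.e. ~0.16 per neuron; the corrected profile must sit well below it
  expect_lt(max(abs(prof$values)), 0.03)
})

test_that("synchronous population bursts lock the S-MUA to zero lag", {
  # bursts at trial-specific random times; all neurons fire within 2 ms
  set.seed(99)
  mk <- function() {
    bursts <- sort(runif(40, 0, 60))
    tt <- c(); id <- c()
    for (b in bursts) {
      who <- sample(30, 25)
      tt <- c(tt, b + runif(25, 0, 2e-3)); id <- c(id, who)
    }
    synthetic_raster(tt, id, 30, 60, dt = 1e-3)
  }
  prof <- compute_smua(list(mk(), mk(), mk()))
  i0 <- which(prof$lags == 0)
  expect_lte(abs(prof$peak_lag), 0.002)
  # concentration: zero-lag value dwarfs the window edges
  edge <- mean(abs(prof$values[abs(prof$lags) >= 0.05]))
  expect_gt(prof$values[i0], 10 * edge)
})

test_that("Up-state detection applies the simultaneous-fraction criterion", {
  # 30% of neurons co-active within one window -> one segment
  r <- synthetic_raster(rep(0.100, 30), 1:30, 100, 1, dt = 1e-3)
  segs <- detect_up_states(r, window = 5e-3)
  expect_equal(nrow(segs$segments), 1)
  expect_equal(segs$segments$start_s, 0.100)
  expect_equal(segs$segments$end_s, 0.105)  # window-extended activity
  expect_equal(segs$criterion_fraction, 0.2)  # the default criterion
  # at most 10% co-active -> no segment
  r2 <- synthetic_raster(rep(0.1, 10), 1:10, 100, 1, dt = 1e-3)
  expect_equal(nrow(detect_up_states(r2, window = 5e-3)$segments), 0)
})

test_that("raising the criterion fraction never lengthens or adds segments", {
  res <- simulate_network(study_network(50), zero_input(3, 3),
                          cost_params(0, 5), study_config(3, rng_seed = 3))
  # the qualifying-step set shrinks as the criterion rises: total Up time
  # is non-increasing and every stricter segment nests inside a looser one
  # (segment counts alone can rise transiently when a segment splits)
  fracs <- c(0.1, 0.2, 0.4, 0.6)
  segs_by_f <- lapply(fracs, function(f)
    detect_up_states(res$spikes, fraction = f)$segments)
  up_time <- vapply(segs_by_f, function(s) sum(s$end_s - s$start_s),
                    numeric(1))
  expect_true(all(diff(up_time) <= 0))
  for (k in seq_along(fracs)[-1]) {
    hi <- segs_by_f[[k]]; lo <- segs_by_f[[k - 1]]
    if (nrow(hi) > 0) {
      nested <- vapply(seq_len(nrow(hi)), function(i)
        any(lo$start_s <= hi$start_s[i] + 1e-9 &
              lo$end_s >= hi$end_s[i] - 1e-9), logical(1))
      expect_true(all(nested))
    }
  }
  # and Up plus Down time never exceeds the trial
  segs <- detect_up_states(res$spikes)
  ib <- interburst_statistics(segs)
  du <- duration_statistics(segs)
  expect_lte(sum(ib$ibis) + sum(du$durations), 3 + 1e-9)
})

test_that("inter-burst intervals follow from segment arithmetic", {
  seg <- structure(list(
    segments = data.frame(start_s = c(0.5, 1.0, 1.5, 2.0),
                          end_s = c(0.55, 1.05, 1.55, 2.05)),
    criterion_fraction = 0.2, window = 1e-3, n_neurons = 10,
    duration = 3), class = "upstate_segments")
  ib <- interburst_statistics(seg)
  expect_equal(ib$ibis, rep(0.45, 3))
  expect_equal(ib$mean_ibi, 0.45)
  expect_match(ib$fit_status, "fewer than")
  one <- seg; one$segments <- one$segments[1, ]
  expect_equal(interburst_statistics(one)$ibis, numeric(0))
})

test_that("the gamma fit recovers planted interval parameters within 5%", {
  set.seed(12)
  ib <- rgamma(10000, shape = 2, scale = 1)
  n <- length(ib) + 1
  starts <- cumsum(ib + 0.05)
  seg <- structure(list(
    segments = data.frame(start_s = c(0, starts),
                          end_s = c(0, starts) + 0.05),
    criterion_fraction = 0.2, window = 1e-3, n_neurons = 10,
    duration = max(starts) + 1), class = "upstate_segments")
  fit <- interburst_statistics(seg)
  expect_equal(fit$fit_status, "ok")
  expect_lt(abs(fit$gamma$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$gamma$scale - 1), 0.05)
})

test_that("duration summaries integrate to one and recover planted modes", {
  seg1 <- structure(list(
    segments = data.frame(start_s = 0.2, end_s = 0.25),
    criterion_fraction = 0.2, window = 1e-3, n_neurons = 10,
    duration = 1), class = "upstate_segments")
  d1 <- duration_statistics(seg1)
  expect_equal(d1$durations, 0.05)
  expect_null(d1$density)
  # bimodal synthetic durations
  set.seed(5)
  durs <- c(rnorm(400, 0.05, 0.005), rnorm(400, 0.2, 0.01))
  starts <- cumsum(durs + 0.5) - durs
  seg2 <- structure(list(
    segments = data.frame(start_s = starts, end_s = starts + durs),
    criterion_fraction = 0.2, window = 1e-3, n_neurons = 10,
    duration = max(starts + durs) + 1), class = "upstate_segments")
  d2 <- duration_statistics(seg2)
  area <- sum(d2$density$y) * diff(d2$density$x[1:2])
  expect_equal(area, 1, tolerance = 0.02)
  # the two planted modes are recovered within a bandwidth
  y <- d2$density$y; x <- d2$density$x
  peaks <- x[which(diff(sign(diff(y))) == -2) + 1]
  peaks <- peaks[y[match(peaks, x)] > max(y) / 4]
  expect_equal(length(peaks), 2)
  expect_lt(abs(peaks[1] - 0.05), 2 * d2$density$bw + 0.005)
  expect_lt(abs(peaks[2] - 0.20), 2 * d2$density$bw + 0.01)
})

test_that("CV2 matches its defining arithmetic and limiting cases", {
  # consecutive intervals (1, 3): single pair value 2*2/4 = 1
  r <- synthetic_raster(c(0, 1, 4), rep(1, 3), 1, 5, dt = 1e-3)
  expect_equal(compute_cv2(r)$mean, 1)
  # perfectly regular train
  reg <- synthetic_raster(seq(0, 9.9, by = 0.1), rep(1, 100), 1, 10,
                          dt = 1e-3)
  expect_equal(compute_cv2(reg)$mean, 0)
  # Poisson trains: population mean CV2 ~ 1
  pois <- poisson_raster(60, 20, 60, seed = 4)
  expect_lt(abs(compute_cv2(pois)$mean - 1), 0.08)
  # invariance under uniform time rescaling
  r5 <- synthetic_raster(5 * c(0, 1, 4), rep(1, 3), 1, 25, dt = 1e-3)
  expect_equal(compute_cv2(r5)$mean, compute_cv2(r)$mean)
  # no eligible neuron
  r0 <- synthetic_raster(c(0.1, 0.2), c(1, 2), 2, 1, dt = 1e-3)
  expect_match(compute_cv2(r0)$status, "undefined")
})

test_that("synchrony percentage counts window-active neurons", {
  # all neurons fire every step -> 100%
  n_steps <- 50
  tt <- rep((0:(n_steps - 1)) * 1e-3, each = 4)
  id <- rep(1:4, n_steps)
  r <- synthetic_raster(tt, id, 4, 0.05, dt = 1e-3)
  sy <- synchrony_fraction(r, window = 1e-3)
  expect_equal(sy$summary, 100)
  # exactly half the neurons firing every step -> 50%
  r2 <- synthetic_raster(tt[id <= 2], id[id <= 2], 4, 0.05, dt = 1e-3)
  expect_equal(synchrony_fraction(r2, window = 1e-3)$summary, 50)
  # empty raster -> undefined summary
  r0 <- synthetic_raster(numeric(0), integer(0), 4, 0.05, dt = 1e-3)
  expect_match(synchrony_fraction(r0)$status, "undefined")
})
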