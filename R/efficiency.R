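# Coding-error / spike-cost efficiency measures and the (nu, mu) sweep.

#' Mean coding error of a simulation trial
#'
#' Time-averaged absolute distance between the target signal and the
#' decoded estimate, averaged over signal dimensions and rescaled by the
#' across-neuron mean Euclidean norm of the decoding weights (so the
#' measure does not depend on the overall scale of `w`; doubling all
#' weights with a fixed residual halves the reported error).
#'
#' @param result a `sim_result`.
#' @param spec the network (default: the one stored in `result`).
#' @return Non-negative scalar, dimensionless.
#' @export
coding_error <- function(result, spec = NULL) {
  stopifnot(inherits(result, "sim_result"))
  spec <- spec %||% result$spec
  mean_norm <- mean(sqrt(rowSums(spec$w^2)))
  if (mean_norm <= 0) stop_arg("mean weight norm is zero; error undefined")
  mean(abs(result$target - result$estimate)) / mean_norm
}

#' Mean spike cost of a simulation trial
#'
#' Total spike count divided by the trial length: the average population
#' firing rate in spikes per second.
#'
#' @param result a `sim_result`.
#' @return Non-negative scalar (Hz, population).
#' @export
spike_cost <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  nrow(result$spikes) / result$duration
}

#' Total error: weighted sum of coding error and spike cost
#'
#' `alpha * <error> + beta * <cost>`. Equal weighting (`alpha = beta = 1`,
#' the default) is the natural choice: a single spike then contributes one
#' unit to the cost and, through the weight normalization of the error,
#' about one unit to the error it can remove.
#'
#' @param mean_error mean coding error (or a `sim_result`, from which
#'   both components are computed).
#' @param mean_cost mean spike cost (ignored when a `sim_result` is
#'   given).
#' @param alpha,beta non-negative weights, not both zero.
#' @return An object of class `efficiency_report` with fields
#'   `mean_error`, `mean_cost`, `alpha`, `beta`, `total_error`.
#' @export
total_error <- function(mean_error, mean_cost = NULL, alpha = 1, beta = 1) {
  if (inherits(mean_error, "sim_result")) {
    res <- mean_error
    mean_error <- coding_error(res)
    mean_cost <- spike_cost(res)
  }
  check_nonneg_scalar(alpha, "alpha")
  check_nonneg_scalar(beta, "beta")
  if (alpha == 0 && beta == 0)
    stop_arg("at least one of `alpha`, `beta` must be positive")
  check_nonneg_scalar(mean_error, "mean_error")
  check_nonneg_scalar(mean_cost, "mean_cost")
  structure(list(mean_error = mean_error, mean_cost = mean_cost,
                 alpha = alpha, beta = beta,
                 total_error = alpha * mean_error + beta * mean_cost),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat("<efficiency_report> <error> =", signif(x$mean_error, 4),
      " <cost> =", signif(x$mean_cost, 4), "spk/s  Total =",
      signif(x$total_error, 4),
      sprintf("(alpha = %g, beta = %g)\n", x$alpha, x$beta))
  invisible(x)
}

#' Sweep the cost plane and locate the optimal working regime
#'
#' For every cell of the `(nu, mu)` grid, the network is simulated
#' `n_repeats` times with fresh input and noise realizations (the same
#' repeat uses the same seeds in every cell, so cells are compared under
#' common random numbers), and the mean coding error, mean spike cost,
#' total error and (optionally) Up-state frequency are averaged per cell.
#' The optimum is the cell minimizing the total error; because the total
#' error typically has a shallow valley of near-equivalent settings, the
#' few best cells are reported alongside the optimum.
#'
#' @param spec a `network_spec`.
#' @param input_generator either a fixed `input_signal` or a function
#'   `function(seed)` returning one (fresh realization per repeat).
#' @param config a [sim_config()]; its `rng_seed` is overridden per run.
#' @param nu_grid,mu_grid numeric vectors of linear / quadratic costs.
#' @param n_repeats independent repeats per cell (`>= 1`).
#' @param rng_seed master seed from which all per-repeat seeds derive.
#' @param alpha,beta total-error weights.
#' @param track_upstates if `TRUE`, attach Up-state frequency (segments
#'   per second, quiescent-style detection with package defaults) per
#'   cell.
#' @param upstate_fraction,upstate_window Up-state criterion parameters.
#' @return An object of class `efficiency_surface` with `nu_grid`,
#'   `mu_grid`, matrices `error`, `cost`, `total`, `upstate_freq` (rows =
#'   `nu`, columns = `mu`), the `optimum` (`nu`, `mu`, `total`), a
#'   `top_cells` data frame, `n_repeats`, `rng_seed`.
#' @export
cost_sweep <- function(spec, input_generator, config,
                       nu_grid, mu_grid, n_repeats = 3, rng_seed = 1,
                       alpha = 1, beta = 1, track_upstates = TRUE,
                       upstate_fraction = 0.2, upstate_window = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "sim_config"))
  if (length(nu_grid) == 0 || length(mu_grid) == 0)
    stop_arg("cost grids must be non-empty")
  if (n_repeats < 1) stop_arg("`n_repeats` must be >= 1")
  upstate_window <- upstate_window %||% max(config$delay, config$dt)

  # common random numbers: repeat r uses the same seeds in every cell
  input_seed <- function(r) (rng_seed + 7919L * r) %% 2147483629L
  sim_seed <- function(r) (rng_seed + 7919L * r + 104729L) %% 2147483629L
  inputs <- lapply(seq_len(n_repeats), function(r) {
    if (is.function(input_generator)) input_generator(input_seed(r))
    else input_generator
  })

  dims <- c(length(nu_grid), length(mu_grid))
  err <- cst <- tot <- upf <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_along(nu_grid)) {
    for (j in seq_along(mu_grid)) {
      costs <- cost_params(nu = nu_grid[i], mu = mu_grid[j])
      e <- k <- u <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        cfg <- config
        cfg$rng_seed <- sim_seed(r)
        res <- tryCatch(
          simulate_network(spec, inputs[[r]], costs, cfg),
          error = function(ex)
            stop_arg("simulation failed at cell (nu = ", nu_grid[i],
                     ", mu = ", mu_grid[j], "), repeat ", r, ": ",
                     conditionMessage(ex)))
        e[r] <- coding_error(res)
        k[r] <- spike_cost(res)
        if (track_upstates) {
          segs <- detect_up_states(res$spikes, fraction = upstate_fraction,
                                   window = upstate_window)
          u[r] <- nrow(segs$segments) / res$duration
        }
      }
      err[i, j] <- mean(e); cst[i, j] <- mean(k)
      tot[i, j] <- alpha * err[i, j] + beta * cst[i, j]
      if (track_upstates) upf[i, j] <- mean(u)
    }
  }
  opt_idx <- arrayInd(which.min(tot), dims)
  ord <- order(tot)
  top <- head(ord, 5L)
  top_idx <- arrayInd(top, dims)
  structure(list(
    nu_grid = nu_grid, mu_grid = mu_grid,
    error = err, cost = cst, total = tot,
    upstate_freq = if (track_upstates) upf else NULL,
    optimum = list(nu = nu_grid[opt_idx[1]], mu = mu_grid[opt_idx[2]],
                   total = tot[opt_idx]),
    top_cells = data.frame(nu = nu_grid[top_idx[, 1]],
                           mu = mu_grid[top_idx[, 2]],
                           total = tot[top]),
    alpha = alpha, beta = beta,
    n_repeats = n_repeats, rng_seed = rng_seed),
    class = "efficiency_surface")
}

#' @export
print.efficiency_surface <- function(x, ...) {
  cat("<efficiency_surface>", length(x$nu_grid), "x", length(x$mu_grid),
      "cells,", x$n_repeats, "repeat(s); optimum at (nu =", x$optimum$nu,
      ", mu =", x$optimum$mu, ") Total =", signif(x$optimum$total, 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.efficiency_surface <- function(x, ...) {
  grid <- expand.grid(nu = x$nu_grid, mu = x$mu_grid,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(grid,
             error = as.vector(x$error),
             cost = as.vector(x$cost),
             total = as.vector(x$total),
             upstate_freq = if (is.null(x$upstate_freq)) NA_real_
                            else as.vector(x$upstate_freq),
             n_repeats = x$n_repeats)
}

#' Write an efficiency surface as long-format CSV (plus JSON summary)
#'
#' @param surface an `efficiency_surface`.
#' @param csv_path output CSV path
#'   (`nu,mu,error,cost,total,upstate_freq,n_repeats`).
#' @param json_path optional path for the optimum + configuration echo.
#' @return `csv_path`, invisibly.
#' @export
write_surface_csv <- function(surface, csv_path, json_path = NULL) {
  stopifnot(inherits(surface, "efficiency_surface"))
  write.csv(as.data.frame(surface), csv_path, row.names = FALSE,
            quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(optimum = surface$optimum,
                              top_cells = surface$top_cells,
                              alpha = surface$alpha, beta = surface$beta,
                              n_repeats = surface$n_repeats,
                              rng_seed = surface$rng_seed),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
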