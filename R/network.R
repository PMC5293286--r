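#' Cost parameters for spiking
#'
#' The linear cost `nu` penalizes the total firing rate of the population;
#' it raises every neuron's firing threshold by `nu/2`. The quadratic cost
#' `mu` penalizes squared rates; it raises thresholds by `mu/2` and adds a
#' spike-triggered hyperpolarization of size `mu` to the neuron that just
#' fired. Both are in units of weight squared (the natural scale of the
#' recurrent couplings).
#'
#' @param nu linear cost, `>= 0`.
#' @param mu quadratic cost, `>= 0`.
#' @return An object of class `cost_params`.
#' @export
#' @examples
#' cost_params(nu = 2, mu = 4)
cost_params <- function(nu = 0, mu = 0) {
  check_nonneg_scalar(nu, "nu")
  check_nonneg_scalar(mu, "mu")
  structure(list(nu = nu, mu = mu), class = "cost_params")
}

#' @export
print.cost_params <- function(x, ...) {
  cat("<cost_params> nu =", x$nu, " mu =", x$mu, "\n")
  invisible(x)
}

#' Parameters of the topographic (ring) network and its bump input
#'
#' `A` and `B` set the peak amplitude and concentration of the circular
#' Gaussian input bump; `C` and `D` set the peak amplitude and
#' concentration of the blob-shaped ON/OFF decoding weights. `n_on` and
#' `n_off` are the ON and OFF subpopulation sizes and must be equal: each
#' ON neuron shares its ring position with one OFF neuron.
#'
#' @param A input peak amplitude (`> 0`).
#' @param B input tuning concentration (`> 0`).
#' @param C weight peak amplitude (`> 0`).
#' @param D weight tuning concentration (`> 0`).
#' @param n_on,n_off ON / OFF subpopulation sizes (equal, `>= 1`).
#' @return An object of class `topographic_params`.
#' @export
topographic_params <- function(A = 1, B = 3, C = 0.2, D = 3,
                               n_on = 200, n_off = n_on) {
  check_positive_scalar(A, "A"); check_positive_scalar(B, "B")
  check_positive_scalar(C, "C"); check_positive_scalar(D, "D")
  if (n_on < 1 || n_off < 1 || n_on != round(n_on) || n_off != round(n_off))
    stop_arg("`n_on` and `n_off` must be positive integers")
  if (n_on != n_off)
    stop_arg("`n_on` and `n_off` must be equal: ON and OFF neurons pair up ",
             "at the same ring positions")
  structure(list(A = A, B = B, C = C, D = D,
                 n_on = as.integer(n_on), n_off = as.integer(n_off)),
            class = "topographic_params")
}

#' Construct a network specification from a weight matrix
#'
#' Low-level constructor. Weights are stored one row per neuron (`N x J`),
#' so the recurrent coupling matrix is the Gram matrix `phi = w %*% t(w)`,
#' whose entry `(i, k)` is the inner product of the decoding weights of
#' neurons `i` and `k`. A spike of neuron `k` subtracts column `k` of
#' `phi` from the membrane potentials, which is lateral inhibition between
#' same-selectivity neurons, lateral excitation between opposite-selectivity
#' neurons, and a self-reset of `-phi[k, k]` for the spiking neuron.
#'
#' @param w numeric `N x J` matrix of decoding weights.
#' @param kind `"random_alltoall"` or `"topographic"`.
#' @param positions optional per-neuron ring angle in `[0, 2*pi)`.
#' @param polarity optional per-neuron `"ON"`/`"OFF"` tag.
#' @return An object of class `network_spec` with fields `n_neurons`,
#'   `n_signals`, `w`, `phi`, `kind`, `positions`, `polarity`.
#' @export
network_spec <- function(w, kind = c("random_alltoall", "topographic"),
                         positions = NULL, polarity = NULL) {
  kind <- match.arg(kind)
  w <- as.matrix(w)
  storage.mode(w) <- "double"
  if (!all(is.finite(w))) stop_arg("weights must be finite")
  structure(list(n_neurons = nrow(w), n_signals = ncol(w),
                 w = w, phi = w %*% t(w), kind = kind,
                 positions = positions, polarity = polarity),
            class = "network_spec")
}

#' Replace the weights of a network specification
#'
#' Recomputes the coupling matrix from the new weights. Used to turn a
#' generated specification into one of the analytically tractable minimal
#' models (for example two neurons with weights `a` and `-b`).
#'
#' @param spec a `network_spec`.
#' @param w new `N x J` weight matrix (same dimensions).
#' @return The updated `network_spec`.
#' @export
set_weights <- function(spec, w) {
  stopifnot(inherits(spec, "network_spec"))
  w <- as.matrix(w)
  if (!identical(dim(w), dim(spec$w)))
    stop_arg("replacement weights must be ", spec$n_neurons, " x ",
             spec$n_signals)
  spec$w <- w
  storage.mode(spec$w) <- "double"
  spec$phi <- spec$w %*% t(spec$w)
  spec
}

#' Build an all-to-all network with random Gaussian weights
#'
#' Decoding weights are drawn i.i.d. from a standard normal distribution;
#' every pair of neurons is coupled through the Gram matrix of the weights.
#' The same seed always yields the identical network.
#'
#' @param n_neurons number of neurons `N >= 1`.
#' @param n_signals number of input/signal dimensions `J >= 1`.
#' @param rng_seed integer seed for the weight draw.
#' @return A `network_spec` of kind `"random_alltoall"`.
#' @export
#' @examples
#' spec <- build_random_network(400, 3, rng_seed = 1)
#' dim(spec$w)
build_random_network <- function(n_neurons, n_signals, rng_seed = 1) {
  if (!is.numeric(n_neurons) || length(n_neurons) != 1L || n_neurons < 1 ||
      n_neurons != round(n_neurons))
    stop_arg("`n_neurons` must be a positive integer")
  if (!is.numeric(n_signals) || length(n_signals) != 1L || n_signals < 1 ||
      n_signals != round(n_signals))
    stop_arg("`n_signals` must be a positive integer")
  set.seed(rng_seed)
  w <- matrix(rnorm(n_neurons * n_signals), nrow = n_neurons)
  network_spec(w, kind = "random_alltoall")
}

#' Build a spatially organized ring network of ON and OFF neurons
#'
#' Neurons sit at equally spaced positions on a ring of `n_on` sites, one
#' ON and one OFF neuron per site. The decoding weight of the ON neuron at
#' site `i` onto pixel `j` is `C * exp(D * (cos(2*pi*(j - i)/n) - 1))`, a
#' circular Gaussian blob peaking at its own site; OFF weights are the
#' negation. Integer site indices are used in the cosine so the profile is
#' single-period on the ring. Couplings `-phi` are then local: inhibitory
#' between nearby same-polarity neurons, excitatory between nearby
#' opposite-polarity neurons, and negligible between distant neurons.
#'
#' @param params a [topographic_params()] object.
#' @return A `network_spec` of kind `"topographic"` with `positions` (ring
#'   angles, shared between the ON/OFF pair at each site) and `polarity`.
#' @export
build_topographic_network <- function(params = topographic_params()) {
  stopifnot(inherits(params, "topographic_params"))
  n <- params$n_on
  idx <- 0:(n - 1L)
  ring <- params$C * exp(params$D * (cos(2 * pi * outer(idx, idx, "-") / n) - 1))
  w <- rbind(ring, -ring)  # rows: n ON neurons then n OFF neurons
  theta <- 2 * pi * idx / n
  network_spec(w, kind = "topographic",
               positions = c(theta, theta),
               polarity = rep(c("ON", "OFF"), each = n))
}

#' Recurrent coupling matrix of a network
#'
#' Returns the Gram matrix `phi = w %*% t(w)` (entry `(i, k)` the inner
#' product of the two neurons' decoding weights). The recurrent current is
#' `-phi %*% o`: the matrix of lateral and recurrent (autapse) connections.
#'
#' @param spec a `network_spec`.
#' @return A symmetric `N x N` matrix.
#' @export
connectivity_matrix <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  if (is.null(spec$w)) stop_arg("network has no weights")
  spec$phi
}

#' Firing thresholds
#'
#' `Thres_i = sum_j(w[i, j]^2)/2 + mu/2 + nu/2`: half the squared weight
#' norm of the neuron, plus half of each cost. Raising either cost raises
#' every threshold at rate 1/2, making the network more tolerant to small
#' coding errors.
#'
#' @param spec a `network_spec`.
#' @param costs a [cost_params()] object.
#' @return Numeric vector of length `N`.
#' @export
#' @examples
#' sp <- network_spec(matrix(c(3, 4), nrow = 1))
#' firing_thresholds(sp, cost_params(nu = 2, mu = 4))  # 12.5 + 1 + 2
firing_thresholds <- function(spec, costs = cost_params()) {
  stopifnot(inherits(spec, "network_spec"), inherits(costs, "cost_params"))
  rowSums(spec$w^2) / 2 + costs$mu / 2 + costs$nu / 2
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$kind, ":", x$n_neurons, "neurons,",
      x$n_signals, "signal dimension(s)\n")
  if (!is.null(x$polarity))
    cat("  ON:", sum(x$polarity == "ON"), " OFF:", sum(x$polarity == "OFF"), "\n")
  invisible(x)
}

#' Serialize a network specification to JSON
#'
#' @param spec a `network_spec`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
network_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  obj <- list(kind = spec$kind,
              n_neurons = spec$n_neurons,
              n_signals = spec$n_signals,
              w = spec$w,
              positions = spec$positions,
              polarity = spec$polarity)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a network specification from JSON
#'
#' @param path file path or JSON string produced by [network_to_json()].
#' @return A `network_spec` (the coupling matrix is recomputed from `w`).
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  w <- matrix(unlist(obj$w), nrow = obj$n_neurons, ncol = obj$n_signals)
  network_spec(w, kind = obj$kind,
               positions = if (!is.null(obj$positions)) as.numeric(obj$positions),
               polarity = if (!is.null(obj$polarity)) as.character(obj$polarity))
}
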