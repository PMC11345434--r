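#' Simulation settings for the oscillator network
#'
#' @param dt integration step in seconds (default 1 ms, matching 1 kHz
#'   sampling).
#' @param n_steps total integration steps (including burn-in).
#' @param burn_in initial steps discarded from the output (default 2 s worth).
#' @param seed RNG seed; if `NULL` the current RNG state is used.
#' @param initial_state optional length-`2N` state vector ordered
#'   `(x_1..x_N, y_1..y_N)`; defaults to independent `N(0, 0.1^2)` draws.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, n_steps, burn_in = round(2 / dt),
                       seed = NULL, initial_state = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  n_steps <- as.integer(n_steps)
  burn_in <- as.integer(burn_in)
  if (burn_in < 0 || burn_in >= n_steps)
    stop("require 0 <= burn_in < n_steps", call. = FALSE)
  structure(list(dt = dt, n_steps = n_steps, burn_in = burn_in, seed = seed,
                 initial_state = initial_state),
            class = "sim_config")
}

check_conforming <- function(params, C) {
  if (nrow(C) != params$n)
    stop("coupling matrix is ", nrow(C), "x", ncol(C),
         " but `params` has n = ", params$n, " nodes (field: values)",
         call. = FALSE)
}

#' Deterministic drift of the coupled Stuart-Landau network
#'
#' Evaluates the noiseless right-hand side of the network equations at a state
#' `(x_1..x_N, y_1..y_N)`:
#' `dx_i = (a_i - x_i^2 - y_i^2) x_i - omega_i y_i + G * sum_j C_ij (x_j - x_i)`
#' and analogously for `y_i` with `+omega_i x_i` and coupling in `y`.
#'
#' @param params an [oscillator_params()] object.
#' @param C coupling matrix (receiver-row/sender-column), see
#'   [coupling_matrix()].
#' @param state numeric vector of length `2N`, ordered x-block then y-block.
#' @return Numeric vector of length `2N`: `(dx/dt, dy/dt)`.
#' @export
hopf_drift <- function(params, C, state) {
  check_conforming(params, C)
  n <- params$n
  if (length(state) != 2L * n)
    stop("`state` must have length 2N = ", 2L * n, " (field: state)",
         call. = FALSE)
  x <- state[seq_len(n)]
  y <- state[n + seq_len(n)]
  r2 <- x^2 + y^2
  rs <- rowSums(C)
  dx <- (params$a - r2) * x - params$omega * y +
    params$G * (as.vector(C %*% x) - rs * x)
  dy <- (params$a - r2) * y + params$omega * x +
    params$G * (as.vector(C %*% y) - rs * y)
  unname(c(dx, dy))
}

#' Simulate the stochastic coupled Hopf network
#'
#' Integrates the network with a stochastic Heun scheme: the drift is advanced
#' by an explicit predictor-corrector step (plain Euler systematically
#' inflates the limit-cycle radius by `omega^2 dt / 2`), and at every step
#' each scalar component of both the x and y equations receives an
#' independent Gaussian increment `beta * sqrt(dt) * N(0, 1)`. The y
#' variables are internal to the dynamics; only the x read-out is returned,
#' with the burn-in discarded. Identical `(params, C, config)` (including
#' seed) give a bit-identical series.
#'
#' @inheritParams hopf_drift
#' @param config a [sim_config()] object.
#' @return A [region_ts()] with `n_steps - burn_in` samples.
#' @examples
#' p <- oscillator_params(a = 0.25, f = 1, beta = 0, G = 0, n = 1)
#' ts <- simulate_hopf(p, coupling_matrix(matrix(0, 1, 1)),
#'                     sim_config(n_steps = 10000, seed = 1))
#' @export
simulate_hopf <- function(params, C, config) {
  check_conforming(params, C)
  n <- params$n
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- config$initial_state
  if (is.null(st)) st <- rnorm(2L * n, 0, 0.1)
  if (length(st) != 2L * n)
    stop("`initial_state` must have length 2N = ", 2L * n, call. = FALSE)
  noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  x <- simulate_hopf_cpp(params$a, params$omega, params$G, unclass(C),
                         params$beta, config$dt, config$n_steps,
                         config$burn_in, st[seq_len(n)], st[n + seq_len(n)],
                         noise_seed)
  region_ts(x, dt = config$dt, region_ids = params$region_ids)
}
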