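#' Jacobian of the network linearised at the origin
#'
#' Linearising the coupled Stuart-Landau equations at the origin (the
#' subcritical working point `a_i < 0`) gives the block Jacobian
#' `A = [[K, -Omega], [Omega, K]]` with `K = diag(a_i - G * rowsum_i(C)) + G*C`
#' and `Omega = diag(omega_i)`: the diffusive coupling contributes `+G*C_ij`
#' off the diagonal and `-G * sum_j C_ij` on the diagonal of both the x and y
#' blocks. The additive noise enters with covariance `Q = beta^2 * I`.
#'
#' @inheritParams hopf_drift
#' @return An object of class `linearized_system`: list with `jacobian`
#'   (`2N x 2N`, state order `x_1..x_N, y_1..y_N`), `noise_q` (the scalar
#'   `beta^2` on the diagonal of `Q`), `region_ids`, `n`.
#' @export
build_jacobian <- function(params, C) {
  check_conforming(params, C)
  n <- params$n
  K <- params$G * unclass(C)
  diag(K) <- params$a - params$G * rowSums(C)
  Om <- diag(params$omega, n)
  A <- rbind(cbind(K, -Om), cbind(Om, K))
  structure(list(jacobian = A, noise_q = params$beta^2,
                 region_ids = params$region_ids, n = n),
            class = "linearized_system")
}

#' @export
print.linearized_system <- function(x, ...) {
  cat("<linearized_system> ", x$n, " nodes (", nrow(x$jacobian),
      "x", ncol(x$jacobian), " Jacobian), noise q = ", x$noise_q, "\n",
      sep = "")
  invisible(x)
}

# internal: stability check shared by the analytic operations
check_stable <- function(max_re) {
  if (max_re > -1e-6)
    stop("model not in stable linear regime; require a_i < 0 net of coupling ",
         "(max Re eigenvalue = ", signif(max_re, 4), ")", call. = FALSE)
}

#' Stationary covariance of the linearised network
#'
#' Solves the Lyapunov equation `A Sigma + Sigma A^T + Q = 0` for the
#' stationary covariance of the linear stochastic system `dX = A X dt +
#' beta dW`. Requires all eigenvalues of `A` to have negative real part
#' (margin `-1e-6`).
#'
#' @param sys a [build_jacobian()] result.
#' @return Symmetric positive semidefinite `2N x 2N` matrix.
#' @export
stationary_covariance <- function(sys) {
  stopifnot(inherits(sys, "linearized_system"))
  sol <- lyap_solve_cpp(sys$jacobian, sys$noise_q)
  check_stable(sol$max_re)
  sol$sigma
}

#' Lagged covariance of the linearised network
#'
#' For a stable linear stochastic system, `Cov(tau) = expm(A * tau) * Sigma`,
#' whose x-block entry `(i, j)` is `cov(x_i(t + tau), x_j(t))`. At `tau = 0`
#' this returns `Sigma` exactly.
#'
#' @param sys a [build_jacobian()] result.
#' @param sigma the stationary covariance from [stationary_covariance()].
#' @param tau lag in seconds (`>= 0`).
#' @return `2N x 2N` matrix.
#' @export
lagged_covariance <- function(sys, sigma, tau) {
  stopifnot(inherits(sys, "linearized_system"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a nonnegative scalar (seconds)", call. = FALSE)
  if (tau == 0) return(sigma)
  check_stable(max(Re(eigen(sys$jacobian, only.values = TRUE)$values)))
  expmat_cpp(sys$jacobian * tau) %*% sigma
}

#' Model FC and FS in closed form
#'
#' The analytic route of the generative model: the stationary covariance from
#' the Lyapunov equation gives the model FC (x-block normalised to
#' correlations), and the matrix-exponential lagged covariance gives the model
#' FS at lag `tau`, normalised by the same static standard deviations —
#' mirroring the empirical estimators, so that fitted couplings are comparable
#' across the analytic and simulation modes.
#'
#' @inheritParams hopf_drift
#' @param tau lag in seconds.
#' @return A [moment_pair()] (with `dt = NA`: analytic moments have no
#'   sampling interval).
#' @export
model_moments <- function(params, C, tau) {
  sys <- build_jacobian(params, C)
  n <- sys$n
  sol <- lyap_solve_cpp(sys$jacobian, sys$noise_q)
  check_stable(sol$max_re)
  sxx <- sol$sigma[seq_len(n), seq_len(n), drop = FALSE]
  sds <- sqrt(diag(sxx))
  denom <- tcrossprod(sds)
  fc <- sxx / denom
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  cv <- expmat_cpp(sys$jacobian * tau) %*% sol$sigma
  fs <- cv[seq_len(n), seq_len(n), drop = FALSE] / denom
  fc <- pmin(pmax(fc, -1), 1)
  fs <- pmin(pmax(fs, -1), 1)
  dimnames(fc) <- dimnames(fs) <- list(params$region_ids, params$region_ids)
  moment_pair(fc = fc, fs = fs, tau = tau)
}
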