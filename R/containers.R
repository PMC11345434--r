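#' Oscillator parameters for the coupled Hopf network
#'
#' Bundles the node-level parameters of the Stuart-Landau network: the
#' bifurcation parameter `a` (nodes sit on a stable limit cycle of radius
#' `sqrt(a)` for `a > 0` and on a noisy stable fixed point for `a < 0`), the
#' intrinsic frequencies, the global coupling gain `G` that scales the total
#' input each node receives, and the standard deviation `beta` of the additive
#' Gaussian noise.
#'
#' Exactly one of `f` (intrinsic frequency in Hz) or `omega` (angular velocity
#' in rad/s) must be supplied; the other is derived as `omega = 2*pi*f`.
#'
#' @param a numeric vector of bifurcation parameters (1/s), one per node.
#'   Scalars are recycled to `n` when `n` is given.
#' @param f intrinsic frequencies in Hz (alternative to `omega`).
#' @param omega angular velocities in rad/s (alternative to `f`).
#' @param G global coupling weight (dimensionless, scalar, `>= 0`).
#' @param beta additive noise standard deviation (signal units, `>= 0`).
#' @param region_ids optional character vector of node labels; defaults to
#'   `"n01", "n02", ...`.
#' @param n number of nodes, required only when all vector arguments are
#'   scalars.
#' @return An object of class `oscillator_params`: a list with elements
#'   `a`, `f`, `omega`, `G`, `beta`, `region_ids`, `n`.
#' @examples
#' p <- oscillator_params(a = -0.02, f = 1, n = 3)
#' p$omega / (2 * pi)
#' @export
oscillator_params <- function(a, f = NULL, omega = NULL, G = 1, beta = 0.02,
                              region_ids = NULL, n = NULL) {
  if (is.null(f) && is.null(omega))
    stop("supply one of `f` (Hz) or `omega` (rad/s)", call. = FALSE)
  if (!is.null(f) && !is.null(omega) &&
      any(abs(f - omega / (2 * pi)) > 1e-12))
    stop("`f` and `omega` disagree: require f = omega/(2*pi)", call. = FALSE)
  if (is.null(omega)) omega <- 2 * pi * f
  if (is.null(f)) f <- omega / (2 * pi)
  if (is.null(n)) n <- max(length(a), length(f), length(region_ids))
  a <- rep_len(as.numeric(a), n)
  f <- rep_len(as.numeric(f), n)
  omega <- rep_len(as.numeric(omega), n)
  if (is.null(region_ids)) region_ids <- sprintf("n%02d", seq_len(n))
  if (length(region_ids) != n)
    stop("`region_ids` must have length ", n, call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(omega)))
    stop("`a` and `omega`/`f` must be finite", call. = FALSE)
  if (!is.finite(G) || G < 0) stop("`G` must be finite and >= 0", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("`beta` must be finite and >= 0", call. = FALSE)
  structure(
    list(a = a, f = f, omega = omega, G = G, beta = beta,
         region_ids = as.character(region_ids), n = n),
    class = "oscillator_params"
  )
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params> ", x$n, " nodes\n", sep = "")
  cat("  a: ", paste(signif(unique(x$a), 3), collapse = ", "),
      " | f (Hz): [", signif(min(x$f), 3), ", ", signif(max(x$f), 3),
      "] | G = ", x$G, " | beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Validated asymmetric coupling matrix
#'
#' Constructs/validates an effective-connectivity matrix `C`. The orientation
#' convention used throughout the package is receiver-row / sender-column:
#' `C[i, j]` is the weight of the input node `i` receives from node `j`
#' (the link `j -> i`). Entries must be nonnegative and finite, the diagonal
#' zero.
#'
#' @param values square numeric matrix.
#' @param region_ids optional node labels; defaults to existing dimnames or
#'   `"n01", ...`. Stored as dimnames.
#' @return The validated numeric matrix with region ids as dimnames.
#' @examples
#' C <- coupling_matrix(rbind(c(0, 0), c(0.3, 0)))
#' C["n02", "n01"]  # input to node 2 from node 1
#' @export
coupling_matrix <- function(values, region_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop("coupling matrix must be square, got ",
         nrow(values), "x", ncol(values), call. = FALSE)
  if (!all(is.finite(values)))
    stop("coupling matrix contains non-finite entries", call. = FALSE)
  if (any(values < 0))
    stop("coupling matrix entries must be nonnegative", call. = FALSE)
  if (any(diag(values) != 0))
    stop("coupling matrix diagonal must be zero", call. = FALSE)
  n <- nrow(values)
  if (is.null(region_ids)) {
    region_ids <- rownames(values)
    if (is.null(region_ids)) region_ids <- sprintf("n%02d", seq_len(n))
  }
  if (length(region_ids) != n)
    stop("`region_ids` must have length ", n, call. = FALSE)
  dimnames(values) <- list(as.character(region_ids), as.character(region_ids))
  values
}

#' Parcellated region-by-time series
#'
#' A light container for a `T x N` matrix of per-region samples with its
#' sampling interval. Columns are regions, rows are time points.
#'
#' @param values numeric `T x N` matrix (`T >= 2`, finite entries).
#' @param dt sampling interval in seconds.
#' @param region_ids optional region labels (default: column names or
#'   `"n01", ...`).
#' @return An object of class `region_ts` with elements `values`, `dt`,
#'   `region_ids`.
#' @export
region_ts <- function(values, dt, region_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("time series contains non-finite values", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive scalar (seconds)", call. = FALSE)
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- sprintf("n%02d", seq_len(ncol(values)))
  }
  if (length(region_ids) != ncol(values))
    stop("`region_ids` length must match the number of columns", call. = FALSE)
  colnames(values) <- as.character(region_ids)
  structure(list(values = values, dt = dt,
                 region_ids = as.character(region_ids)),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat("<region_ts> ", nrow(x$values), " samples x ", ncol(x$values),
      " regions, dt = ", x$dt, " s (", round(nrow(x$values) * x$dt, 3),
      " s)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.region_ts <- function(x, ...) x$values

#' Pair of moment matrices (FC and lagged FS)
#'
#' Holds the zero-lag Pearson functional connectivity `fc` and the lagged
#' normalised covariance `fs` at lag `tau`. `fs[i, j]` is the correlation of
#' region `i` shifted later by `tau` with region `j` unshifted, i.e. row =
#' receiver, column = sender, matching the coupling-matrix orientation.
#'
#' @param fc symmetric `N x N` Pearson correlation matrix, unit diagonal.
#' @param fs `N x N` lagged normalised covariance matrix (generally
#'   asymmetric), entries in `[-1, 1]`.
#' @param tau lag in seconds.
#' @param dt sampling interval in seconds (`NA` for analytic model moments).
#' @param n_samples number of samples the moments were estimated from (`NA`
#'   for analytic moments).
#' @return An object of class `moment_pair`.
#' @export
moment_pair <- function(fc, fs, tau, dt = NA_real_, n_samples = NA_real_) {
  if (!is.matrix(fc) || !is.matrix(fs) || !all(dim(fc) == dim(fs)))
    stop("`fc` and `fs` must be matrices of identical shape", call. = FALSE)
  if (nrow(fc) != ncol(fc)) stop("moment matrices must be square", call. = FALSE)
  if (max(abs(fc - t(fc))) > 1e-8)
    stop("`fc` must be symmetric", call. = FALSE)
  if (max(abs(diag(fc) - 1)) > 1e-8)
    stop("`fc` must have unit diagonal", call. = FALSE)
  if (min(fc) < -1 - 1e-8 || max(fc) > 1 + 1e-8 ||
      min(fs) < -1 - 1e-8 || max(fs) > 1 + 1e-8)
    stop("moment entries must lie in [-1, 1]", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a nonnegative scalar (seconds)", call. = FALSE)
  if (!is.na(dt) && abs(tau / dt - round(tau / dt)) > 0.5 + 1e-9)
    stop("`tau` must be an integer multiple of `dt`", call. = FALSE)
  structure(list(fc = fc, fs = fs, tau = tau, dt = dt, n_samples = n_samples),
            class = "moment_pair")
}

#' @export
print.moment_pair <- function(x, ...) {
  cat("<moment_pair> ", nrow(x$fc), " regions, tau = ", x$tau, " s",
      if (!is.na(x$n_samples)) paste0(", n_samples = ", x$n_samples),
      "\n", sep = "")
  invisible(x)
}

# internal: off-diagonal entries as a vector
offdiag <- function(m) m[row(m) != col(m)]
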