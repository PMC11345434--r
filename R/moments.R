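#' Empirical functional connectivity (Pearson FC)
#'
#' Pearson correlation between every pair of regions' time series. Constant
#' columns (degenerate variance) get zero off-diagonal correlation with a
#' warning.
#'
#' @param ts a [region_ts()] (or plain `T x N` matrix).
#' @return Symmetric `N x N` correlation matrix with unit diagonal.
#' @export
compute_fc <- function(ts) {
  x <- if (inherits(ts, "region_ts")) ts$values else ts
  if (nrow(x) < 3) stop("need T >= 3 samples", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / (nrow(x) - 1)
  sds <- sqrt(diag(S))
  const <- sds == 0
  if (any(const)) {
    warning("constant column(s) ", paste(which(const), collapse = ", "),
            ": correlations set to 0", call. = FALSE)
    sds[const] <- Inf
  }
  fc <- S / tcrossprod(sds)
  fc <- pmin(pmax((fc + t(fc)) / 2, -1), 1)
  diag(fc) <- 1
  dimnames(fc) <- list(colnames(x), colnames(x))
  fc
}

#' Lagged normalised covariance (FS)
#'
#' Correlation between region `i` shifted later by `tau` and region `j`
#' unshifted, computed over the overlapping window of length `T - L`
#' (`L = tau/dt`, no wrap-around): `fs[i, j] = corr(x_i(t + tau), x_j(t))`.
#' Row = receiver/later, column = sender/earlier, matching the coupling-matrix
#' orientation, so a directed link `j -> i` raises `fs[i, j]` above
#' `fs[j, i]`. Columns are demeaned over the full series and the covariance is
#' normalised by the static (lag-0) standard deviations, so `fs` reduces to
#' the FC at `tau = 0` and stays in `[-1, 1]`.
#'
#' @param ts a [region_ts()].
#' @param tau lag in seconds; must be a positive integer multiple of the
#'   sampling interval (within `dt/2`).
#' @return `N x N` matrix, generally asymmetric.
#' @export
compute_lagged_fs <- function(ts, tau) {
  stopifnot(inherits(ts, "region_ts"))
  x <- ts$values
  dt <- ts$dt
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a positive scalar lag in seconds", call. = FALSE)
  L <- round(tau / dt)
  if (abs(tau - L * dt) >= dt / 2 * (1 - 1e-9))
    stop("`tau` = ", tau, " s is not an integer multiple of dt = ", dt,
         " s (ambiguous lag)", call. = FALSE)
  if (L < 1) stop("lag rounds to 0 samples; `tau` must be >= dt", call. = FALSE)
  n <- nrow(x)
  if (n <= L + 2) stop("need T > L + 2 samples for lag L = ", L, call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colSums(xc^2) / (n - 1))
  if (any(sds == 0)) {
    warning("constant column(s): lagged covariance set to 0", call. = FALSE)
    sds[sds == 0] <- Inf
  }
  late <- xc[(L + 1):n, , drop = FALSE]
  early <- xc[1:(n - L), , drop = FALSE]
  cv <- crossprod(late, early) / (n - L - 1)
  fs <- cv / tcrossprod(sds)
  fs <- pmin(pmax(fs, -1), 1)
  dimnames(fs) <- list(colnames(x), colnames(x))
  fs
}

#' Empirical FC and lagged FS as a moment pair
#'
#' Convenience wrapper bundling [compute_fc()] and [compute_lagged_fs()] into
#' a [moment_pair()].
#'
#' @inheritParams compute_lagged_fs
#' @return A [moment_pair()].
#' @export
empirical_moments <- function(ts, tau) {
  stopifnot(inherits(ts, "region_ts"))
  x <- ts$values
  n <- nrow(x)
  L <- round(tau / ts$dt)
  if (n < 3) stop("need T >= 3 samples", call. = FALSE)
  if (abs(tau - L * ts$dt) >= ts$dt / 2 * (1 - 1e-9) || L < 1)
    stop("`tau` = ", tau, " s is not a positive integer multiple of dt = ",
         ts$dt, " s", call. = FALSE)
  if (n <= L + 2) stop("need T > L + 2 samples for lag L = ", L, call. = FALSE)
  # both crossproducts in one centered pass (BLAS)
  cp <- moment_crossprods_cpp(x, L)
  S <- cp$s / (n - 1)
  sds <- sqrt(diag(S))
  if (any(sds == 0)) {
    warning("constant column(s): correlations set to 0", call. = FALSE)
    sds[sds == 0] <- Inf
  }
  denom <- tcrossprod(sds)
  fc <- pmin(pmax((S + t(S)) / 2 / denom, -1), 1)
  diag(fc) <- 1
  fs <- pmin(pmax(cp$cl / (n - L - 1) / denom, -1), 1)
  dimnames(fc) <- dimnames(fs) <- list(colnames(x), colnames(x))
  moment_pair(fc = fc, fs = fs, tau = tau, dt = ts$dt, n_samples = n)
}

# internal: Welch averaged periodogram (Hann window, 50% overlap).
welch_psd <- function(x, dt, seg_seconds = 4, overlap = 0.5) {
  x <- x - mean(x)
  n <- length(x)
  nseg <- min(n, round(seg_seconds / dt))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  nf <- floor(nseg / 2) + 1L
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- abs(fft(seg))^2
    psd <- psd + p[seq_len(nf)]
  }
  psd <- psd / (length(starts) * sum(w^2) / dt / nseg)
  list(freq = (seq_len(nf) - 1) / (nseg * dt), psd = psd)
}

#' Intrinsic frequencies from a cohort of series
#'
#' Per participant and region, the frequency of maximum power spectral density
#' within the requested band (Welch averaged periodogram, 4-s Hann segments
#' with 50% overlap; the peak search is restricted to the band, which is the
#' zero-phase equivalent of narrowband filtering before peak picking);
#' returned as the cross-participant mean per region. These are the narrowband
#' peak frequencies used as the oscillators' intrinsic `f_i`.
#'
#' @param cohort list of [region_ts()] objects sharing region ids and `dt`.
#' @param band numeric length-2 `(f_lo, f_hi)` in Hz, inside `(0, Nyquist)`.
#' @return Named numeric vector of per-region frequencies (Hz).
#' @export
estimate_intrinsic_frequencies <- function(cohort, band = c(0.5, 2)) {
  if (inherits(cohort, "region_ts")) cohort <- list(cohort)
  if (length(cohort) < 1) stop("need at least one participant", call. = FALSE)
  ids <- cohort[[1]]$region_ids
  dt <- cohort[[1]]$dt
  for (ts in cohort) {
    if (!identical(ts$region_ids, ids))
      stop("participants must share region ids", call. = FALSE)
    if (ts$dt != dt) stop("participants must share dt", call. = FALSE)
  }
  nyq <- 1 / (2 * dt)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] > nyq)
    stop("`band` must satisfy 0 < f_lo < f_hi <= Nyquist (", nyq, " Hz)",
         call. = FALSE)
  peaks <- sapply(cohort, function(ts) {
    apply(ts$values, 2, function(col) {
      sp <- welch_psd(col, dt)
      sel <- sp$freq >= band[1] & sp$freq <= band[2]
      if (!any(sel)) stop("band contains no spectral bins; series too short",
                          call. = FALSE)
      sp$freq[sel][which.max(sp$psd[sel])]
    })
  })
  peaks <- matrix(peaks, nrow = length(ids))
  stats::setNames(rowMeans(peaks), ids)
}

#' Average moment pairs across participants
#'
#' Elementwise mean of the FC and FS matrices; `n_samples` accumulates.
#' All inputs must share shape, `tau` and `dt`.
#'
#' @param pairs list of [moment_pair()] objects.
#' @return A [moment_pair()].
#' @export
average_moments <- function(pairs) {
  if (inherits(pairs, "moment_pair")) pairs <- list(pairs)
  if (length(pairs) < 1) stop("need at least one moment pair", call. = FALSE)
  ref <- pairs[[1]]
  for (p in pairs) {
    if (!identical(dim(p$fc), dim(ref$fc)))
      stop("moment pairs have mismatched shapes", call. = FALSE)
    if (p$tau != ref$tau) stop("moment pairs have mismatched tau", call. = FALSE)
    if (!identical(is.na(p$dt), is.na(ref$dt)) ||
        (!is.na(p$dt) && p$dt != ref$dt))
      stop("moment pairs have mismatched dt", call. = FALSE)
  }
  fc <- Reduce(`+`, lapply(pairs, `[[`, "fc")) / length(pairs)
  fs <- Reduce(`+`, lapply(pairs, `[[`, "fs")) / length(pairs)
  moment_pair(fc = fc, fs = fs, tau = ref$tau, dt = ref$dt,
              n_samples = sum(vapply(pairs, `[[`, numeric(1), "n_samples")))
}

#' Split-half reliability of per-participant coupling matrices
#'
#' Randomly splits the cohort into two halves, averages the coupling matrices
#' within each half, and returns the Pearson correlation of the off-diagonal
#' entries between the two half-cohort means.
#'
#' @param ec_list list of per-participant coupling matrices (>= 4).
#' @param seed RNG seed for the split.
#' @return Pearson r (scalar), with the split and seed attached as attributes
#'   `"halves"` and `"seed"`.
#' @export
split_half_reliability <- function(ec_list, seed = NULL) {
  n <- length(ec_list)
  if (n < 4) stop("need at least 4 participants for a split-half check",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  h1 <- idx[seq_len(floor(n / 2))]
  h2 <- idx[(floor(n / 2) + 1):n]
  m1 <- Reduce(`+`, ec_list[h1]) / length(h1)
  m2 <- Reduce(`+`, ec_list[h2]) / length(h2)
  r <- cor(offdiag(m1), offdiag(m2))
  attr(r, "halves") <- list(h1 = h1, h2 = h2)
  attr(r, "seed") <- seed
  r
}
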