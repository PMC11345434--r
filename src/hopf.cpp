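#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fast deterministic normal generator (mt19937_64 + explicit Box-Muller, so
// the stream does not depend on the standard library's normal_distribution
// implementation). Seeded from R's RNG by the caller, which keeps the
// set.seed() -> trajectory contract while generating noise several times
// faster than round trips through R's RNG.
struct FastNormal {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit FastNormal(uint64_t seed) : eng(seed) {}
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = ((eng() >> 11) + 1.0) * (1.0 / 9007199254740993.0); // (0,1]
    double u2 = (eng() >> 11) * (1.0 / 9007199254740992.0);         // [0,1)
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double th = 6.283185307179586476925287 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// Stochastic Heun integration of the coupled Stuart-Landau network.
//
// State is (x_i, y_i) per node; only x is read out. The drift is advanced
// with a Heun predictor-corrector (plain explicit Euler inflates the limit
// cycle radius by omega^2 dt / 2, a 4% bias at 1 Hz and dt = 1 ms); the
// additive noise beta * sqrt(dt) * N(0,1) enters once per step and scalar
// component, drawn from R's RNG so set.seed() on the R side fixes the
// trajectory exactly.
// [[Rcpp::export]]
arma::mat simulate_hopf_cpp(const arma::vec& a, const arma::vec& omega,
                            double G, const arma::mat& C, double beta,
                            double dt, int n_steps, int burn_in,
                            const arma::vec& x0, const arma::vec& y0,
                            double noise_seed) {
  const arma::uword N = a.n_elem;
  arma::vec x = x0, y = y0;
  // total coupling input weight per receiver (diffusive coupling diagonal)
  const arma::vec row_in = G * arma::sum(C, 1);
  arma::mat out(n_steps - burn_in, N);
  const double sdt = beta * std::sqrt(dt);
  const bool noisy = sdt > 0.0;
  FastNormal rng(static_cast<uint64_t>(noise_seed));
  arma::vec wx(N, arma::fill::zeros), wy(N, arma::fill::zeros);
  arma::vec dx1(N), dy1(N), dx2(N), dy2(N), xp(N), yp(N);
  const arma::mat Ct = C.t();             // row i of C contiguous
  const double* Cm = Ct.memptr();
  auto drift = [&](const double* xs, const double* ys,
                   double* dx, double* dy) {
    for (arma::uword i = 0; i < N; ++i) {
      double cx = 0.0, cy = 0.0;
      const double* Ci = Cm + i * N;
      for (arma::uword j = 0; j < N; ++j) {
        const double w = Ci[j];           // C(i, j)
        cx += w * xs[j];
        cy += w * ys[j];
      }
      const double r2 = xs[i] * xs[i] + ys[i] * ys[i];
      dx[i] = (a(i) - r2) * xs[i] - omega(i) * ys[i] + G * cx - row_in(i) * xs[i];
      dy[i] = (a(i) - r2) * ys[i] + omega(i) * xs[i] + G * cy - row_in(i) * ys[i];
    }
  };
  bool guard = true;
  for (int t = 0; t < n_steps; ++t) {
    if (noisy)
      for (arma::uword i = 0; i < N; ++i) {
        wx(i) = sdt * rng();
        wy(i) = sdt * rng();
      }
    drift(x.memptr(), y.memptr(), dx1.memptr(), dy1.memptr());
    for (arma::uword i = 0; i < N; ++i) {
      xp(i) = x(i) + dx1(i) * dt + wx(i);
      yp(i) = y(i) + dy1(i) * dt + wy(i);
    }
    drift(xp.memptr(), yp.memptr(), dx2.memptr(), dy2.memptr());
    guard = true;
    for (arma::uword i = 0; i < N; ++i) {
      x(i) += 0.5 * (dx1(i) + dx2(i)) * dt + wx(i);
      y(i) += 0.5 * (dy1(i) + dy2(i)) * dt + wy(i);
      guard = guard && std::isfinite(x(i)) && std::isfinite(y(i)) &&
              std::abs(x(i)) <= 1e6 && std::abs(y(i)) <= 1e6;
    }
    if (!guard)
      stop("numerical blow-up during integration (|state| > 1e6): reduce dt or use a working point a_i < 0");
    if (t >= burn_in) out.row(t - burn_in) = x.t();
  }
  return out;
}

// Stationary covariance of dX = A X dt + sqrt(q) dW (Q = q * I), solving the
// Lyapunov equation A Sigma + Sigma A^T + Q = 0 in the eigenbasis of A:
// with A = V L W (W = V^-1), Sigma_tilde = W Sigma W^T satisfies
// Sigma_tilde_kl = -(W Q W^T)_kl / (lambda_k + lambda_l).
// Returns Sigma and the largest real part of the spectrum so the caller can
// enforce the stability margin before trusting the solution.
// [[Rcpp::export]]
List lyap_solve_cpp(const arma::mat& A, double q) {
  arma::cx_vec eval;
  arma::cx_mat evec;
  if (!arma::eig_gen(eval, evec, A))
    stop("eigendecomposition of the Jacobian failed");
  const double max_re = arma::real(eval).max();
  arma::cx_mat W;
  if (!arma::inv(W, evec))
    stop("Jacobian eigenvector matrix is singular (defective system)");
  arma::cx_mat Qt = q * (W * W.st());
  const arma::uword n = A.n_rows;
  arma::cx_mat St(n, n);
  for (arma::uword k = 0; k < n; ++k)
    for (arma::uword l = 0; l < n; ++l) {
      const std::complex<double> s = eval(k) + eval(l);
      St(k, l) = (std::abs(s) > 1e-14) ? -Qt(k, l) / s
                                       : std::complex<double>(0.0, 0.0);
    }
  arma::cx_mat Sigma_c = evec * St * evec.st();
  arma::mat Sigma = arma::real(Sigma_c);
  Sigma = 0.5 * (Sigma + Sigma.t());
  return List::create(_["sigma"] = Sigma, _["max_re"] = max_re);
}

// Matrix exponential (used for the lagged covariance exp(A*tau) * Sigma).
// [[Rcpp::export]]
arma::mat expmat_cpp(const arma::mat& M) {
  return arma::expmat(M);
}

// Model moments and (optionally) the analytic Jacobian of the off-diagonal
// (FC, FS) entries with respect to the off-diagonal coupling entries.
//
// Everything is computed in the eigenbasis of the Jacobian A = V L W
// (W = V^-1). A perturbation dC_ij enters A as +G at (i,j) and -G at (i,i)
// in both the x and y blocks, so B = W dA V is rank-2 and each sensitivity
// needs only O(n^2) work plus the O(n^3) back-transforms:
//   Lyapunov:  dSigma_tilde_kl = -(B St + (B St)^T)_kl / (l_k + l_l)
//   exponential (divided differences): (W dP V)_kl = B_kl * phi(l_k, l_l),
//   phi(x, y) = (e^{x tau} - e^{y tau})/(x - y),  tau e^{x tau} on the diagonal.
// The normalisation chain (correlations use the model's own standard
// deviations) is included, so the Jacobian is exact for the reported moments.
// [[Rcpp::export]]
List gec_moments_cpp(const arma::vec& a, const arma::vec& omega, double G,
                     double beta, const arma::mat& C, double tau,
                     bool want_jacobian) {
  const arma::uword N = a.n_elem;
  const arma::uword n = 2 * N;
  // A = [[K, -Om], [Om, K]]
  arma::mat K = G * C;
  K.diag() = a - G * arma::sum(C, 1);
  arma::mat A(n, n, arma::fill::zeros);
  A.submat(0, 0, N - 1, N - 1) = K;
  A.submat(N, N, n - 1, n - 1) = K;
  A.submat(0, N, N - 1, n - 1) = -arma::diagmat(omega);
  A.submat(N, 0, n - 1, N - 1) = arma::diagmat(omega);

  arma::cx_vec lam;
  arma::cx_mat V;
  if (!arma::eig_gen(lam, V, A)) stop("eigendecomposition failed");
  const double max_re = arma::real(lam).max();
  List out = List::create(_["max_re"] = max_re);
  if (max_re > -1e-6) return out;  // caller enforces the stability margin
  arma::cx_mat W;
  if (!arma::inv(W, V)) stop("defective Jacobian eigenbasis");

  // stationary covariance in the eigenbasis
  arma::cx_mat Qt = (beta * beta) * (W * W.st());
  arma::cx_mat St(n, n);
  for (arma::uword k = 0; k < n; ++k)
    for (arma::uword l = 0; l < n; ++l)
      St(k, l) = -Qt(k, l) / (lam(k) + lam(l));
  arma::cx_mat Sig_c = V * St * V.st();
  arma::mat Sigma = arma::real(Sig_c);
  Sigma = 0.5 * (Sigma + Sigma.t());

  // matrix exponential and lagged covariance
  arma::cx_vec elam = arma::exp(lam * tau);
  arma::cx_mat P_c = V * arma::diagmat(elam) * W;
  arma::mat P = arma::real(P_c);
  arma::mat Cov = P * Sigma;

  arma::mat sxx = Sigma.submat(0, 0, N - 1, N - 1);
  arma::mat cxx = Cov.submat(0, 0, N - 1, N - 1);
  arma::vec s = arma::sqrt(sxx.diag());
  arma::mat denom = s * s.t();
  arma::mat fc = sxx / denom;
  fc = 0.5 * (fc + fc.t());
  fc.diag().ones();
  arma::mat fs = cxx / denom;
  out["fc"] = fc;
  out["fs"] = fs;
  if (!want_jacobian) return out;

  // divided differences of exp(z * tau)
  arma::cx_mat Phi(n, n);
  for (arma::uword k = 0; k < n; ++k)
    for (arma::uword l = 0; l < n; ++l) {
      const std::complex<double> d = lam(k) - lam(l);
      Phi(k, l) = (std::abs(d) > 1e-10) ? (elam(k) - elam(l)) / d
                                        : tau * elam(k);
    }

  const arma::uword p = N * (N - 1);      // off-diagonal C entries
  arma::mat J(2 * p, p, arma::fill::zeros);
  arma::cx_mat Vst = V.st();
  arma::uword col = 0;
  for (arma::uword j = 0; j < N; ++j) {
    for (arma::uword i = 0; i < N; ++i) {
      if (i == j) continue;
      // B = W dA V, rank-2 (x block and y block rows of node i)
      arma::cx_vec w1 = W.col(i), w2 = W.col(N + i);
      arma::cx_rowvec u1 = V.row(j) - V.row(i);
      arma::cx_rowvec u2 = V.row(N + j) - V.row(N + i);
      arma::cx_mat B = G * (w1 * u1 + w2 * u2);
      // Lyapunov sensitivity
      arma::cx_mat BSt = G * (w1 * (u1 * St) + w2 * (u2 * St));
      arma::cx_mat Rt = BSt + BSt.st();
      arma::cx_mat dSt(n, n);
      for (arma::uword k = 0; k < n; ++k)
        for (arma::uword l = 0; l < n; ++l)
          dSt(k, l) = -Rt(k, l) / (lam(k) + lam(l));
      arma::mat dSig = arma::real(V * dSt * Vst);
      dSig = 0.5 * (dSig + dSig.t());
      // exponential sensitivity and lagged-covariance sensitivity
      arma::mat dP = arma::real(V * (B % Phi) * W);
      arma::mat dCov = dP * Sigma + P * dSig;
      arma::mat dsxx = dSig.submat(0, 0, N - 1, N - 1);
      arma::mat dcxx = dCov.submat(0, 0, N - 1, N - 1);
      // normalisation chain: d(corr) through the model variances
      arma::vec dvar_rel = dsxx.diag() / sxx.diag();  // dSigma_aa / Sigma_aa
      arma::uword row = 0;
      for (arma::uword jj = 0; jj < N; ++jj)
        for (arma::uword ii = 0; ii < N; ++ii) {
          if (ii == jj) continue;
          const double scale = 0.5 * (dvar_rel(ii) + dvar_rel(jj));
          // residual r = emp - model, so dr/dC = -dmodel/dC
          J(row, col) = -(dsxx(ii, jj) / denom(ii, jj) - fc(ii, jj) * scale);
          J(p + row, col) = -(dcxx(ii, jj) / denom(ii, jj) - fs(ii, jj) * scale);
          ++row;
        }
      ++col;
    }
  }
  out["jacobian"] = J;
  return out;
}

// Centered crossproducts for the empirical moments: S = xc' xc and the
// L-lagged crossproduct xc[(L+1):T, ]' xc[1:(T-L), ], computed with BLAS on
// views so the fitting loop's per-iteration moments need no R-level copies.
// [[Rcpp::export]]
List moment_crossprods_cpp(const arma::mat& x, int L) {
  const arma::uword T = x.n_rows;
  arma::mat xc = x;
  xc.each_row() -= arma::mean(x, 0);
  arma::mat S = xc.t() * xc;
  arma::mat CL = xc.rows(L, T - 1).t() * xc.rows(0, T - 1 - L);
  return List::create(_["s"] = S, _["cl"] = CL);
}
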