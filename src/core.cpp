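// Iterative phase-retrieval cores. All randomness (initial phases) is
// generated on the R side; these routines are fully deterministic.
// Arrays arrive in unshifted FFT ordering (zero frequency at element 0,0);
// the R wrappers do the re-ordering once.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::cx_mat;
using arma::mat;
using arma::umat;

namespace {

// Magnitude projection: on valid pixels replace |F| by the measurement,
// keep the calculated phase; invalid pixels pass through unchanged.
// Also accumulates the R-factor numerator sum(||F| - m|) over valid pixels.
cx_mat project_magnitude(const cx_mat& F, const mat& mag, const umat& valid,
                         double& rnum) {
  cx_mat out(F.n_rows, F.n_cols);
  const double tiny = 1e-300;
  for (arma::uword i = 0; i < F.n_elem; ++i) {
    if (valid[i]) {
      double a = std::abs(F[i]);
      rnum += std::abs(a - mag[i]);
      out[i] = (a > tiny) ? F[i] * (mag[i] / a)
                          : std::complex<double>(mag[i], 0.0);
    } else {
      out[i] = F[i];
    }
  }
  return out;
}

} // namespace

// In situ CDI sweep: simultaneous reconstruction of a time series with the
// time-invariant static region passed along frames as a weighted blend.
// mags:  list of magnitude matrices (one per frame)
// valid: validity mask shared by all frames
// P:     illumination function
// MS/MD: static / dynamic supports (disjoint)
// S0/D0: per-frame initial static / dynamic estimates
// share_static = false disables the cross-frame constraint (independent
// per-frame retrieval, for the control experiment).
// avg_window: the returned objects are the running mean of the iterates of
// the last avg_window sweeps (1 = final iterate only), suppressing the
// iteration-to-iteration noise fitting of the magnitude projection.
// [[Rcpp::export]]
Rcpp::List insitu_core(Rcpp::List mags, const arma::umat& valid,
                       const arma::cx_mat& P, const arma::umat& MS,
                       const arma::umat& MD, Rcpp::List S0, Rcpp::List D0,
                       double gamma, double eps_frac, int n_iter,
                       bool share_static, bool alpha_squared,
                       int avg_window, bool density_range) {
  const int T = mags.size();
  std::vector<mat> M(T);
  std::vector<cx_mat> S(T), D(T);
  for (int t = 0; t < T; ++t) {
    M[t] = Rcpp::as<mat>(mags[t]);
    S[t] = Rcpp::as<cx_mat>(S0[t]);
    D[t] = Rcpp::as<cx_mat>(D0[t]);
  }
  const mat absP = arma::abs(P);
  const double alpha_max = absP.max();
  if (alpha_max <= 0) Rcpp::stop("illumination function is identically zero");
  const double alpha = alpha_squared ? alpha_max * alpha_max : alpha_max;
  const double eps = eps_frac * alpha_max * alpha_max;
  // probe-weighted object-update factor, precomputed once
  const cx_mat W = (absP % arma::conj(P)) / (alpha * (absP % absP + eps));
  const mat MSd = arma::conv_to<mat>::from(MS);
  const mat MDd = arma::conv_to<mat>::from(MD);

  double rden = 0.0;
  for (int t = 0; t < T; ++t) {
    for (arma::uword i = 0; i < valid.n_elem; ++i)
      if (valid[i]) rden += M[t][i];
  }
  if (rden <= 0) Rcpp::stop("all-zero measured magnitudes");

  arma::vec r_trace(n_iter);
  cx_mat S_run = S[0];
  if (avg_window < 1) avg_window = 1;
  if (avg_window > n_iter) avg_window = n_iter;
  const int avg_start = n_iter - avg_window;
  std::vector<cx_mat> Oacc(T);
  for (int t = 0; t < T; ++t) Oacc[t].zeros(P.n_rows, P.n_cols);

  for (int j = 0; j < n_iter; ++j) {
    double rnum = 0.0;
    for (int t = 0; t < T; ++t) {
      cx_mat Sp = share_static ? cx_mat(gamma * S_run + (1.0 - gamma) * S[t])
                               : S[t];
      cx_mat O = Sp + D[t];
      cx_mat psi = O % P;
      cx_mat F = arma::fft2(psi);
      cx_mat Fp = project_magnitude(F, M[t], valid, rnum);
      cx_mat psip = arma::ifft2(Fp);
      cx_mat Op = O + W % (psip - psi);
      if (density_range) {
        // projected electron density: Re >= 0 (refractive decrement) and
        // Im <= 0 (absorption) for every bundled material
        for (arma::uword i = 0; i < Op.n_elem; ++i) {
          double re = Op[i].real(), im = Op[i].imag();
          if (re < 0.0 || im > 0.0)
            Op[i] = std::complex<double>(re < 0.0 ? 0.0 : re,
                                         im > 0.0 ? 0.0 : im);
        }
      }
      S[t] = Op % MSd;
      D[t] = Op % MDd;
      S_run = S[t];
      if (j >= avg_start) Oacc[t] += S[t] + D[t];
    }
    r_trace[j] = rnum / rden;
    if (j % 32 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List Sout(T), Dout(T), Oout(T);
  for (int t = 0; t < T; ++t) {
    Sout[t] = S[t];
    Dout[t] = D[t];
    Oout[t] = cx_mat(Oacc[t] / double(avg_window));
  }
  return Rcpp::List::create(Rcpp::Named("objects") = Oout,
                            Rcpp::Named("statics") = Sout,
                            Rcpp::Named("dynamics") = Dout,
                            Rcpp::Named("r_trace") = r_trace);
}

// Oversampling-smoothness (OSS) single-frame phase retrieval: HIO update
// inside the support, with the off-support density low-pass filtered by a
// Gaussian W(k) = exp(-k^2/(2 alpha^2)) whose width steps down over the
// schedule. Optionally a known static region is re-imposed each iteration.
// psi0: initial real-space iterate. Returns the lowest-R iterate.
// range_mode: real-space constraint applied inside the support each
// iteration — 0 none, 1 real non-negative object (Re >= 0, Im = 0),
// 2 projected-density range (Re >= 0, Im <= 0).
// [[Rcpp::export]]
Rcpp::List oss_core(const arma::mat& mag, const arma::umat& valid,
                    const arma::umat& support, const arma::cx_mat& psi0,
                    double beta, int n_iter, int n_filters,
                    bool has_static, const arma::cx_mat& static_vals,
                    const arma::umat& static_mask, int range_mode) {
  const arma::uword n = mag.n_rows;
  cx_mat psi = psi0;

  // squared radial frequency in pixels, unshifted ordering
  mat r2(n, n);
  for (arma::uword i = 0; i < n; ++i) {
    double fi = (i <= n / 2) ? double(i) : double(i) - double(n);
    for (arma::uword j = 0; j < n; ++j) {
      double fj = (j <= n / 2) ? double(j) : double(j) - double(n);
      r2(i, j) = fi * fi + fj * fj;
    }
  }

  double rden = 0.0;
  for (arma::uword i = 0; i < valid.n_elem; ++i)
    if (valid[i]) rden += mag[i];
  if (rden <= 0) Rcpp::stop("all-zero measured magnitudes");

  const mat supd = arma::conv_to<mat>::from(support);
  arma::vec alphas = arma::linspace(double(n), double(n) / 10.0,
                                    std::max(n_filters, 1));
  const int stage_len = std::max(1, (n_iter + n_filters - 1) / n_filters);

  arma::vec r_trace(n_iter);
  arma::vec e_trace(n_iter); // off-support energy of the iterate
  // per-stage best iterate (by the running R of the full iterate) seeds the
  // next stage; the returned result is the best supported object across
  // stage boundaries, scored by its own Fourier R-factor.
  double stage_best_r = arma::datum::inf;
  cx_mat stage_best_psi = psi, stage_best_obj = psi;
  double global_best_r = arma::datum::inf;
  cx_mat global_best_obj = psi;
  int stage = -1;
  mat Wf;

  auto object_r = [&](const cx_mat& obj) {
    cx_mat Fo = arma::fft2(obj);
    double rnum = 0.0;
    for (arma::uword i = 0; i < Fo.n_elem; ++i)
      if (valid[i]) rnum += std::abs(std::abs(Fo[i]) - mag[i]);
    return rnum / rden;
  };
  auto close_stage = [&]() {
    double ro = object_r(stage_best_obj);
    if (ro < global_best_r) {
      global_best_r = ro;
      global_best_obj = stage_best_obj;
    }
  };

  for (int j = 0; j < n_iter; ++j) {
    int st = std::min(j / stage_len, n_filters - 1);
    if (st != stage) {
      stage = st;
      double a = alphas[stage];
      Wf = arma::exp(-0.5 * r2 / (a * a));
      if (j > 0) {
        close_stage();
        psi = stage_best_psi;   // restart from the stage's best iterate
        stage_best_r = arma::datum::inf;
      }
    }
    cx_mat F = arma::fft2(psi);
    double rnum = 0.0;
    cx_mat Fp = project_magnitude(F, mag, valid, rnum);
    double rj = rnum / rden;
    r_trace[j] = rj;
    cx_mat psip = arma::ifft2(Fp);
    cx_mat inside = psip;
    if (range_mode == 1) {
      for (arma::uword i = 0; i < inside.n_elem; ++i)
        inside[i] = std::complex<double>(std::max(inside[i].real(), 0.0), 0.0);
    } else if (range_mode == 2) {
      for (arma::uword i = 0; i < inside.n_elem; ++i) {
        double re = inside[i].real(), im = inside[i].imag();
        if (re < 0.0 || im > 0.0)
          inside[i] = std::complex<double>(re < 0.0 ? 0.0 : re,
                                           im > 0.0 ? 0.0 : im);
      }
    }
    // HIO: keep the (range-projected) field on the support, damp off-support
    cx_mat nxt = supd % inside + (1.0 - supd) % (psi - beta * psip);
    // OSS: low-pass the off-support density
    cx_mat filt = arma::ifft2(Wf % arma::fft2(nxt));
    nxt = supd % nxt + (1.0 - supd) % filt;
    if (has_static) {
      for (arma::uword i = 0; i < static_mask.n_elem; ++i)
        if (static_mask[i]) nxt[i] = static_vals[i];
    }
    if (rj < stage_best_r) {
      stage_best_r = rj;
      stage_best_psi = psi;  // the iterate the R-factor was measured on
      stage_best_obj = supd % inside;
    }
    double e_out = 0.0;
    for (arma::uword i = 0; i < support.n_elem; ++i)
      if (!support[i]) e_out += std::norm(nxt[i]);
    e_trace[j] = e_out;
    psi = nxt;
    if (j % 16 == 0) Rcpp::checkUserInterrupt();
  }

  close_stage();
  return Rcpp::List::create(Rcpp::Named("object") = global_best_obj,
                            Rcpp::Named("r_factor") = global_best_r,
                            Rcpp::Named("r_trace") = r_trace,
                            Rcpp::Named("energy_outside") = e_trace);
}
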