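// Numerical core: centered unitary 2-D DFT (FFTW), periodic Daubechies-4
// wavelet transform, monotone FISTA for the L1-wavelet objective, and a
// separable Gaussian blur with replicate edges.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Centered unitary FFT
// ---------------------------------------------------------------------------

// circular shift: out(i,j) = in((i+s) mod n, (j+s) mod n), block copies
static arma::cx_mat circ_shift(const arma::cx_mat& x, int s) {
  int n = x.n_rows;
  arma::cx_mat out(n, n);
  for (int j = 0; j < n; ++j) {
    int js = (j + s) % n;
    const std::complex<double>* src = x.colptr(js);
    std::complex<double>* dst = out.colptr(j);
    std::copy(src + s, src + n, dst);          // rows s..n-1 -> 0..n-1-s
    std::copy(src, src + s, dst + (n - s));    // rows 0..s-1 -> n-s..n-1
  }
  return out;
}

// cached alignment-agnostic plans per (n, sign)
static fftw_plan get_plan(int n, int sign) {
  static std::map<std::pair<int, int>, fftw_plan> cache;
  auto key = std::make_pair(n, sign);
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  arma::cx_mat a(n, n), b(n, n);
  fftw_plan p = fftw_plan_dft_2d(
      n, n, reinterpret_cast<fftw_complex*>(a.memptr()),
      reinterpret_cast<fftw_complex*>(b.memptr()), sign,
      (n >= 256 ? FFTW_MEASURE : FFTW_ESTIMATE) | FFTW_UNALIGNED);
  cache[key] = p;
  return p;
}

static arma::cx_mat fft2_raw(const arma::cx_mat& x, int sign) {
  int n = x.n_rows;
  arma::cx_mat out(n, n);
  // square + separable DFT: row/col-major distinction immaterial
  fftw_plan p = get_plan(n, sign);
  fftw_execute_dft(p,
      const_cast<fftw_complex*>(reinterpret_cast<const fftw_complex*>(x.memptr())),
      reinterpret_cast<fftw_complex*>(out.memptr()));
  return out;
}

static arma::cx_mat fft2c_(const arma::cx_mat& x) {
  int n = x.n_rows;
  int s_pre = (n + 1) / 2;  // ifftshift
  int s_post = n / 2;       // fftshift
  arma::cx_mat k = fft2_raw(circ_shift(x, s_pre), FFTW_FORWARD);
  return circ_shift(k, s_post) / static_cast<double>(n);
}

static arma::cx_mat ifft2c_(const arma::cx_mat& k) {
  int n = k.n_rows;
  int s_pre = (n + 1) / 2;
  int s_post = n / 2;
  arma::cx_mat x = fft2_raw(circ_shift(k, s_pre), FFTW_BACKWARD);
  return circ_shift(x, s_post) / static_cast<double>(n);
}

// [[Rcpp::export]]
arma::cx_mat cpp_fft2c(const arma::cx_mat& x) {
  if (x.n_rows != x.n_cols) stop("input must be square");
  return fft2c_(x);
}

// [[Rcpp::export]]
arma::cx_mat cpp_ifft2c(const arma::cx_mat& k) {
  if (k.n_rows != k.n_cols) stop("input must be square");
  return ifft2c_(k);
}

// ---------------------------------------------------------------------------
// Daubechies-4 (four-tap) orthonormal wavelet, periodic boundary.
// Templated on the value type so complex images transform directly.
// ---------------------------------------------------------------------------

static const double SQ3 = 1.7320508075688772935;
static const double DEN = 5.6568542494923801952;  // 4*sqrt(2)
static const double H[4] = {(1 + SQ3) / DEN, (3 + SQ3) / DEN,
                            (3 - SQ3) / DEN, (1 - SQ3) / DEN};
static const double G[4] = {H[3], -H[2], H[1], -H[0]};

// one analysis level in place on x[0..m-1]; wrap handled outside the hot loop
template <typename T>
static void dwt1_step(T* x, int m, T* tmp) {
  int h = m / 2;
  for (int k = 0; k + 1 < h; ++k) {  // 2k+3 <= m-1: no wrap
    const T* v = x + 2 * k;
    tmp[k]     = H[0] * v[0] + H[1] * v[1] + H[2] * v[2] + H[3] * v[3];
    tmp[h + k] = G[0] * v[0] + G[1] * v[1] + G[2] * v[2] + G[3] * v[3];
  }
  if (h >= 1) {
    int k = h - 1;
    T v0 = x[2 * k], v1 = x[(2 * k + 1) % m], v2 = x[(2 * k + 2) % m],
      v3 = x[(2 * k + 3) % m];
    tmp[k]     = H[0] * v0 + H[1] * v1 + H[2] * v2 + H[3] * v3;
    tmp[h + k] = G[0] * v0 + G[1] * v1 + G[2] * v2 + G[3] * v3;
  }
  std::copy(tmp, tmp + m, x);
}

template <typename T>
static void idwt1_step(T* x, int m, T* tmp) {
  int h = m / 2;
  std::fill(tmp, tmp + m, T(0));
  for (int k = 0; k + 1 < h; ++k) {
    T a = x[k], d = x[h + k];
    T* o = tmp + 2 * k;
    o[0] += H[0] * a + G[0] * d;
    o[1] += H[1] * a + G[1] * d;
    o[2] += H[2] * a + G[2] * d;
    o[3] += H[3] * a + G[3] * d;
  }
  if (h >= 1) {
    int k = h - 1;
    T a = x[k], d = x[h + k];
    for (int t = 0; t < 4; ++t)
      tmp[(2 * k + t) % m] += H[t] * a + G[t] * d;
  }
  std::copy(tmp, tmp + m, x);
}

// row transform expressed column-wise: output column k combines input
// columns 2k..2k+3 (mod m), so all accesses stay contiguous
template <typename T>
static void dwt2_level(arma::Mat<T>& w, int m, std::vector<T>& buf,
                       std::vector<T>& tmp, arma::Mat<T>& scratch) {
  for (int j = 0; j < m; ++j) {  // columns
    T* col = w.colptr(j);
    std::copy(col, col + m, buf.data());
    dwt1_step(buf.data(), m, tmp.data());
    std::copy(buf.data(), buf.data() + m, col);
  }
  int h = m / 2;
  for (int k = 0; k < h; ++k) {  // rows
    const T* c0 = w.colptr((2 * k) % m);
    const T* c1 = w.colptr((2 * k + 1) % m);
    const T* c2 = w.colptr((2 * k + 2) % m);
    const T* c3 = w.colptr((2 * k + 3) % m);
    T* a = scratch.colptr(k);
    T* d = scratch.colptr(h + k);
    for (int i = 0; i < m; ++i) {
      a[i] = H[0] * c0[i] + H[1] * c1[i] + H[2] * c2[i] + H[3] * c3[i];
      d[i] = G[0] * c0[i] + G[1] * c1[i] + G[2] * c2[i] + G[3] * c3[i];
    }
  }
  for (int j = 0; j < m; ++j)
    std::copy(scratch.colptr(j), scratch.colptr(j) + m, w.colptr(j));
}

template <typename T>
static void idwt2_level(arma::Mat<T>& w, int m, std::vector<T>& buf,
                        std::vector<T>& tmp, arma::Mat<T>& scratch) {
  // rows (inverse): input columns (a_k, d_k) scatter into output columns
  int h = m / 2;
  for (int j = 0; j < m; ++j)
    std::fill(scratch.colptr(j), scratch.colptr(j) + m, T(0));
  for (int k = 0; k < h; ++k) {
    const T* a = w.colptr(k);
    const T* d = w.colptr(h + k);
    for (int t = 0; t < 4; ++t) {
      T* o = scratch.colptr((2 * k + t) % m);
      double ht = H[t], gt = G[t];
      for (int i = 0; i < m; ++i) o[i] += ht * a[i] + gt * d[i];
    }
  }
  for (int j = 0; j < m; ++j)
    std::copy(scratch.colptr(j), scratch.colptr(j) + m, w.colptr(j));
  for (int j = 0; j < m; ++j) {  // columns
    T* col = w.colptr(j);
    std::copy(col, col + m, buf.data());
    idwt1_step(buf.data(), m, tmp.data());
    std::copy(buf.data(), buf.data() + m, col);
  }
}

template <typename T>
static arma::Mat<T> dwt2_t(const arma::Mat<T>& x, int levels) {
  int n = x.n_rows;
  arma::Mat<T> w = x;
  std::vector<T> buf(n), tmp(n);
  arma::Mat<T> scratch(n, n);
  int m = n;
  for (int l = 0; l < levels; ++l) {
    dwt2_level(w, m, buf, tmp, scratch);
    m /= 2;
  }
  return w;
}

template <typename T>
static arma::Mat<T> idwt2_t(const arma::Mat<T>& w, int levels) {
  int n = w.n_rows;
  arma::Mat<T> x = w;
  std::vector<T> buf(n), tmp(n);
  arma::Mat<T> scratch(n, n);
  int m = n >> (levels - 1);
  for (int l = 0; l < levels; ++l) {
    idwt2_level(x, m, buf, tmp, scratch);
    m *= 2;
  }
  return x;
}

// [[Rcpp::export]]
arma::mat cpp_dwt2(const arma::mat& x, int levels) {
  int n = x.n_rows;
  if ((int)x.n_cols != n) stop("input must be square");
  if (n % (1 << levels) != 0) stop("size must be divisible by 2^levels");
  return dwt2_t(x, levels);
}

// [[Rcpp::export]]
arma::mat cpp_idwt2(const arma::mat& w, int levels) {
  if (w.n_rows != w.n_cols) stop("input must be square");
  return idwt2_t(w, levels);
}

// ---------------------------------------------------------------------------
// Monotone FISTA for 0.5*||M(Fx - y)||^2 + lam*||Psi x||_1
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cs_fista(const arma::cx_mat& y, const arma::mat& mask, double lam,
                  int max_iters, double tol, int levels) {
  int n = y.n_rows;
  if ((int)y.n_cols != n || (int)mask.n_rows != n || (int)mask.n_cols != n)
    stop("shape mismatch");
  if (n % (1 << levels) != 0) stop("size must be divisible by 2^levels");

  // When n is divisible by 2^(levels+1), run the whole iteration in
  // unshifted (natural FFT order) coordinates: the N/2 circular image shift
  // commutes with the periodic DWT as a signed permutation of coefficients,
  // which the L1 norm and soft-thresholding are invariant to, so iterates
  // and objectives are identical while all fftshifts drop out of the loop.
  bool shiftfree = (n % (1 << (levels + 1))) == 0;
  int s_pre = (n + 1) / 2, s_post = n / 2;
  double nd = static_cast<double>(n);

  auto Fwd = [&](const arma::cx_mat& a) {
    return shiftfree ? arma::cx_mat(fft2_raw(a, FFTW_FORWARD) / nd)
                     : fft2c_(a);
  };
  auto Inv = [&](const arma::cx_mat& a) {
    return shiftfree ? arma::cx_mat(fft2_raw(a, FFTW_BACKWARD) / nd)
                     : ifft2c_(a);
  };

  arma::mat mask_i = mask;
  arma::cx_mat y_i = y;
  if (shiftfree) {
    y_i = circ_shift(y, s_pre);
    arma::cx_mat mc(mask, arma::mat(n, n, arma::fill::zeros));
    mask_i = arma::real(circ_shift(mc, s_pre));
  }
  arma::uvec idx = arma::find(mask_i > 0.5);
  arma::cx_vec ys = y_i.elem(idx);
  arma::cx_mat ym(n, n, arma::fill::zeros);
  ym.elem(idx) = ys;
  arma::cx_mat x = Inv(ym);      // zero-filled start
  arma::cx_mat x_old = x;
  arma::cx_vec Fxs = ys;         // (F x0)[idx] = measured values exactly
  arma::cx_vec Fxs_old = Fxs;

  auto data_of = [&](const arma::cx_vec& Fs) {
    double s = 0.0;
    for (arma::uword i = 0; i < Fs.n_elem; ++i) {
      std::complex<double> r = Fs[i] - ys[i];
      s += std::norm(r);
    }
    return 0.5 * s;
  };
  // complex soft threshold in place; returns the post-threshold L1 norm
  auto soft_l1 = [&](arma::cx_mat& w) {
    double l1 = 0.0;
    std::complex<double>* p = w.memptr();
    size_t nn = w.n_elem;
    for (size_t i = 0; i < nn; ++i) {
      double a = std::abs(p[i]);
      if (a <= lam) {
        p[i] = 0.0;
      } else {
        p[i] *= 1.0 - lam / a;
        l1 += a - lam;
      }
    }
    return l1;
  };

  double obj = data_of(Fxs) +
               lam * arma::accu(arma::abs(dwt2_t<std::complex<double>>(x, levels)));
  std::vector<double> trace;
  trace.reserve(max_iters);
  double t = 1.0;
  int iters = 0;
  arma::cx_mat resid(n, n);

  for (int k = 0; k < max_iters; ++k) {
    ++iters;
    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    double beta = (t - 1.0) / t_new;

    // gradient at the extrapolated point z = x + beta (x - x_old), using
    // linearity of F: (F z)[idx] = (1+beta) Fxs - beta Fxs_old
    resid.zeros();
    for (arma::uword i = 0; i < idx.n_elem; ++i)
      resid[idx[i]] = (1.0 + beta) * Fxs[i] - beta * Fxs_old[i] - ys[i];
    arma::cx_mat g = Inv(resid);
    // v = z - g, fused
    arma::cx_mat v(n, n);
    {
      const std::complex<double>* px = x.memptr();
      const std::complex<double>* po = x_old.memptr();
      const std::complex<double>* pg = g.memptr();
      std::complex<double>* pv = v.memptr();
      size_t nn = v.n_elem;
      for (size_t i = 0; i < nn; ++i)
        pv[i] = (1.0 + beta) * px[i] - beta * po[i] - pg[i];
    }
    arma::cx_mat w = dwt2_t<std::complex<double>>(v, levels);
    double l1_new = soft_l1(w);
    arma::cx_mat x_new = idwt2_t<std::complex<double>>(w, levels);
    arma::cx_vec Fxs_new = Fwd(x_new).eval().elem(idx);
    double obj_new = data_of(Fxs_new) + lam * l1_new;

    double num = 0.0, den = 0.0;
    {
      const std::complex<double>* pa = x_new.memptr();
      const std::complex<double>* pb = x.memptr();
      for (size_t i = 0; i < x.n_elem; ++i) {
        num += std::norm(pa[i] - pb[i]);
        den += std::norm(pb[i]);
      }
    }
    double relchg = std::sqrt(num) / std::max(std::sqrt(den), 1e-300);

    if (obj_new <= obj) {  // monotone acceptance; reject => momentum restart
      x_old = std::move(x);
      x = std::move(x_new);
      Fxs_old = std::move(Fxs);
      Fxs = std::move(Fxs_new);
      obj = obj_new;
    } else {
      x_old = x;
      Fxs_old = Fxs;
    }
    t = t_new;
    trace.push_back(obj);
    if (!std::isfinite(obj)) stop("non-finite objective in FISTA");
    if (relchg < tol) break;
  }

  if (shiftfree) x = circ_shift(x, s_post);
  return List::create(_["image"] = x, _["trace"] = trace, _["iters"] = iters,
                      _["objective"] = obj);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, replicate ("nearest") edges
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_gauss_blur(const arma::mat& x, double sigma, int radius) {
  if (sigma < 0) stop("sigma must be non-negative");
  if (sigma == 0 || radius < 1) return x;
  int n1 = x.n_rows, n2 = x.n_cols;
  std::vector<double> kern(2 * radius + 1);
  double s = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    double v = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    kern[t + radius] = v;
    s += v;
  }
  for (auto& v : kern) v /= s;

  arma::mat tmp(n1, n2), out(n1, n2);
  for (int j = 0; j < n2; ++j) {  // along rows, replicate at edges
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0;
        if (ii >= n1) ii = n1 - 1;
        acc += kern[t + radius] * x(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0;
        if (jj >= n2) jj = n2 - 1;
        acc += kern[t + radius] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}
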