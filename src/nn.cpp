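// Unrolled MoDL-style reconstruction network: 3x3 convolutions via im2col +
// BLAS gemm, ResNet denoiser (conv-ReLU-conv-scale residual blocks, global
// skip), closed-form single-coil data consistency, and manual reverse-mode
// gradients for scan-specific (zero-shot) self-supervised training.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <fftw3.h>

using namespace Rcpp;

// from core.cpp
arma::cx_mat cpp_fft2c(const arma::cx_mat& x);
arma::cx_mat cpp_ifft2c(const arma::cx_mat& k);

// ---------------------------------------------------------------------------
// im2col for 3x3 "same" convolution with zero padding.
// Images live as (n*n) x C matrices, pixels flattened column-major.
// ---------------------------------------------------------------------------

static arma::mat im2col3(const arma::mat& X, int n) {
  int C = X.n_cols;
  arma::mat P(n * n, 9 * C, arma::fill::zeros);
  int o = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      // P[(i,j), o*C + c] = X[(i+di, j+dj), c] (zero outside)
      int i0 = std::max(0, -di), i1 = std::min(n, n - di);  // valid i range
      int j0 = std::max(0, -dj), j1 = std::min(n, n - dj);
      for (int c = 0; c < C; ++c) {
        const double* src = X.colptr(c);
        double* dst = P.colptr(o * C + c);
        for (int j = j0; j < j1; ++j) {
          const double* s = src + (j + dj) * n + (i0 + di);
          double* d = dst + j * n + i0;
          std::copy(s, s + (i1 - i0), d);
        }
      }
      ++o;
    }
  }
  return P;
}

// adjoint of im2col3 applied to dP (n*n x 9C) -> dX (n*n x C)
static arma::mat col2im3(const arma::mat& dP, int n, int C) {
  arma::mat dX(n * n, C, arma::fill::zeros);
  int o = 0;
  for (int dj = -1; dj <= 1; ++dj) {
    for (int di = -1; di <= 1; ++di) {
      int i0 = std::max(0, -di), i1 = std::min(n, n - di);
      int j0 = std::max(0, -dj), j1 = std::min(n, n - dj);
      for (int c = 0; c < C; ++c) {
        const double* src = dP.colptr(o * C + c);
        double* dst = dX.colptr(c);
        for (int j = j0; j < j1; ++j) {
          const double* s = src + j * n + i0;
          double* d = dst + (j + dj) * n + (i0 + di);
          for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
        }
      }
      ++o;
    }
  }
  return dX;
}

static arma::mat conv3(const arma::mat& X, int n, const arma::mat& W,
                       const arma::rowvec& b) {
  arma::mat out = im2col3(X, n) * W;
  out.each_row() += b;
  return out;
}

// ---------------------------------------------------------------------------
// Parameter plumbing
// ---------------------------------------------------------------------------

struct NetParams {
  arma::mat W_in;
  arma::rowvec b_in;
  std::vector<arma::mat> W1, W2;
  std::vector<arma::rowvec> b1, b2;
  arma::mat W_out;
  arma::rowvec b_out;
  double mu;
  int blocks;
};

static NetParams unpack_params(const List& p, int blocks) {
  NetParams np;
  np.blocks = blocks;
  np.W_in = as<arma::mat>(p["W_in"]);
  np.b_in = as<arma::rowvec>(p["b_in"]);
  List W1 = p["W1"], b1 = p["b1"], W2 = p["W2"], b2 = p["b2"];
  for (int b = 0; b < blocks; ++b) {
    np.W1.push_back(as<arma::mat>(W1[b]));
    np.b1.push_back(as<arma::rowvec>(b1[b]));
    np.W2.push_back(as<arma::mat>(W2[b]));
    np.b2.push_back(as<arma::rowvec>(b2[b]));
  }
  np.W_out = as<arma::mat>(p["W_out"]);
  np.b_out = as<arma::rowvec>(p["b_out"]);
  np.mu = as<double>(p["mu"]);
  return np;
}

struct NetGrads {
  arma::mat W_in;
  arma::rowvec b_in;
  std::vector<arma::mat> W1, W2;
  std::vector<arma::rowvec> b1, b2;
  arma::mat W_out;
  arma::rowvec b_out;
  double mu;
  void init(const NetParams& np) {
    W_in = arma::zeros(arma::size(np.W_in));
    b_in = arma::zeros<arma::rowvec>(np.b_in.n_elem);
    for (int b = 0; b < np.blocks; ++b) {
      W1.push_back(arma::zeros(arma::size(np.W1[b])));
      b1.push_back(arma::zeros<arma::rowvec>(np.b1[b].n_elem));
      W2.push_back(arma::zeros(arma::size(np.W2[b])));
      b2.push_back(arma::zeros<arma::rowvec>(np.b2[b].n_elem));
    }
    W_out = arma::zeros(arma::size(np.W_out));
    b_out = arma::zeros<arma::rowvec>(np.b_out.n_elem);
    mu = 0.0;
  }
};

// complex n x n <-> (n*n) x 2 channel matrix
static arma::mat cx_to_ch(const arma::cx_mat& x) {
  int n = x.n_rows;
  arma::mat out(n * n, 2);
  out.col(0) = arma::vectorise(arma::real(x));
  out.col(1) = arma::vectorise(arma::imag(x));
  return out;
}

static arma::cx_mat ch_to_cx(const arma::mat& m, int n) {
  return arma::cx_mat(arma::reshape(m.col(0), n, n),
                      arma::reshape(m.col(1), n, n));
}

// ---------------------------------------------------------------------------
// Denoiser forward/backward
// ---------------------------------------------------------------------------

struct DenoiserCache {
  arma::mat x2;               // denoiser input
  std::vector<arma::mat> h;   // inputs to each block (h[0] after conv_in), size B+1
  std::vector<arma::mat> r;   // post-ReLU activations per block
};

static arma::mat denoiser_forward(const arma::mat& x2, int n,
                                  const NetParams& np, double alpha,
                                  DenoiserCache* cache) {
  arma::mat h = conv3(x2, n, np.W_in, np.b_in);
  if (cache) {
    cache->x2 = x2;
    cache->h.clear();
    cache->r.clear();
    cache->h.push_back(h);
  }
  for (int b = 0; b < np.blocks; ++b) {
    arma::mat c1 = conv3(h, n, np.W1[b], np.b1[b]);
    arma::mat r = arma::clamp(c1, 0.0, arma::datum::inf);
    arma::mat c2 = conv3(r, n, np.W2[b], np.b2[b]);
    h += alpha * c2;
    if (cache) {
      cache->r.push_back(r);
      cache->h.push_back(h);
    }
  }
  return x2 + conv3(h, n, np.W_out, np.b_out);
}

// returns gradient w.r.t. x2; accumulates parameter grads
static arma::mat denoiser_backward(const arma::mat& g_out, int n,
                                   const NetParams& np, double alpha,
                                   const DenoiserCache& cache, NetGrads& gr) {
  int B = np.blocks;
  // out = x2 + conv(h_B, W_out)
  gr.W_out += im2col3(cache.h[B], n).t() * g_out;
  gr.b_out += arma::sum(g_out, 0);
  arma::mat g_h = col2im3(g_out * np.W_out.t(), n, np.W_out.n_rows / 9);
  for (int b = B - 1; b >= 0; --b) {
    // h_{b+1} = h_b + alpha * conv2(relu(conv1(h_b)))
    arma::mat g_c2 = alpha * g_h;
    gr.W2[b] += im2col3(cache.r[b], n).t() * g_c2;
    gr.b2[b] += arma::sum(g_c2, 0);
    arma::mat g_r = col2im3(g_c2 * np.W2[b].t(), n, np.W2[b].n_rows / 9);
    arma::mat g_c1 = g_r % arma::conv_to<arma::mat>::from(cache.r[b] > 0);
    gr.W1[b] += im2col3(cache.h[b], n).t() * g_c1;
    gr.b1[b] += arma::sum(g_c1, 0);
    g_h += col2im3(g_c1 * np.W1[b].t(), n, np.W1[b].n_rows / 9);
  }
  gr.W_in += im2col3(cache.x2, n).t() * g_h;
  gr.b_in += arma::sum(g_h, 0);
  return g_out + col2im3(g_h * np.W_in.t(), n, np.W_in.n_rows / 9);
}

// ---------------------------------------------------------------------------
// Unrolled forward (+ optional caches), mixed-norm loss, full backward
// ---------------------------------------------------------------------------

static arma::cx_mat dc_closed_form(const arma::cx_mat& z, const arma::cx_mat& y,
                                   const arma::umat& dc_mask, double mu,
                                   arma::cx_mat* k_store) {
  arma::cx_mat K = cpp_fft2c(z);
  if (k_store) *k_store = K;
  arma::cx_mat Kout = K;
  arma::uvec idx = arma::find(dc_mask);
  Kout.elem(idx) = (y.elem(idx) + mu * K.elem(idx)) / (1.0 + mu);
  return cpp_ifft2c(Kout);
}

struct UnrollCaches {
  std::vector<DenoiserCache> den;
  std::vector<arma::cx_mat> kz;  // k-space of each denoiser output
};

static arma::cx_mat unrolled_forward_(const arma::cx_mat& y,
                                      const arma::umat& input_mask,
                                      const arma::umat& dc_mask,
                                      const NetParams& np, int unrolls,
                                      double alpha, UnrollCaches* caches) {
  int n = y.n_rows;
  arma::cx_mat ym(n, n, arma::fill::zeros);
  arma::uvec iin = arma::find(input_mask);
  ym.elem(iin) = y.elem(iin);
  arma::cx_mat x = cpp_ifft2c(ym);  // zero-filled network input
  for (int u = 0; u < unrolls; ++u) {
    DenoiserCache* dc = nullptr;
    if (caches) {
      caches->den.emplace_back();
      dc = &caches->den.back();
    }
    arma::mat z2 = denoiser_forward(cx_to_ch(x), n, np, alpha, dc);
    arma::cx_mat z = ch_to_cx(z2, n);
    arma::cx_mat K;
    x = dc_closed_form(z, y, dc_mask, np.mu, caches ? &K : nullptr);
    if (caches) caches->kz.push_back(K);
  }
  return x;
}

// [[Rcpp::export]]
arma::cx_mat cpp_zs_forward(const List& params, const arma::cx_mat& y,
                            const arma::umat& input_mask,
                            const arma::umat& dc_mask, int unrolls, int blocks,
                            double alpha) {
  NetParams np = unpack_params(params, blocks);
  return unrolled_forward_(y, input_mask, dc_mask, np, unrolls, alpha, nullptr);
}

// mixed L1/L2 loss on complex vectors: |u-v|_1/|u|_1 + |u-v|_2/|u|_2
static double mixed_loss_(const arma::cx_vec& u, const arma::cx_vec& v,
                          arma::cx_vec* g_v) {
  arma::cx_vec d = u - v;
  arma::vec ad = arma::abs(d);
  double n1u = arma::accu(arma::abs(u));
  double n2u = arma::norm(u, 2);
  double n1d = arma::accu(ad);
  double n2d = arma::norm(d, 2);
  double L = n1d / n1u + n2d / n2u;
  if (g_v) {
    arma::vec safe1 = ad;
    safe1.transform([](double a) { return a > 1e-300 ? a : 1.0; });
    arma::cx_vec g = -d / arma::conv_to<arma::cx_vec>::from(safe1) / n1u;
    if (n2d > 1e-300) g += -d / (n2d * n2u);
    *g_v = g;
  }
  return L;
}

// [[Rcpp::export]]
List cpp_zs_loss_grad(const List& params, const arma::cx_mat& y,
                      const arma::umat& input_mask, const arma::umat& dc_mask,
                      const arma::umat& loss_mask, int unrolls, int blocks,
                      double alpha, bool want_grad) {
  int n = y.n_rows;
  NetParams np = unpack_params(params, blocks);
  UnrollCaches caches;
  arma::cx_mat x = unrolled_forward_(y, input_mask, dc_mask, np, unrolls, alpha,
                                     want_grad ? &caches : nullptr);
  arma::cx_mat Kx = cpp_fft2c(x);
  arma::uvec ils = arma::find(loss_mask);
  arma::cx_vec u = y.elem(ils), v = Kx.elem(ils);
  arma::cx_vec g_v;
  double L = mixed_loss_(u, v, want_grad ? &g_v : nullptr);

  if (!want_grad)
    return List::create(_["loss"] = L, _["image"] = x);

  NetGrads gr;
  gr.init(np);
  // d L / d x through v = (F x)[loss set]
  arma::cx_mat G(n, n, arma::fill::zeros);
  G.elem(ils) = g_v;
  arma::cx_mat g_x = cpp_ifft2c(G);  // adjoint of unitary centered DFT

  arma::uvec idc = arma::find(dc_mask);
  double denom = 1.0 + np.mu;
  for (int u_i = unrolls - 1; u_i >= 0; --u_i) {
    // x = ifft2c(Kout), Kout = (Y + mu K)/(1+mu) on dc set, K elsewhere
    arma::cx_mat gK = cpp_fft2c(g_x);
    // mu gradient: dKout/dmu = (K - Y)/(1+mu)^2 on dc set
    arma::cx_vec dmu =
        (caches.kz[u_i].elem(idc) - y.elem(idc)) / (denom * denom);
    gr.mu += arma::accu(arma::real(arma::conj(gK.elem(idc)) % dmu));
    gK.elem(idc) *= (np.mu / denom);
    arma::cx_mat g_z = cpp_ifft2c(gK);
    arma::mat g_x_prev =
        denoiser_backward(cx_to_ch(g_z), n, np, alpha, caches.den[u_i], gr);
    g_x = ch_to_cx(g_x_prev, n);
  }

  List W1(blocks), b1(blocks), W2(blocks), b2(blocks);
  for (int b = 0; b < blocks; ++b) {
    W1[b] = gr.W1[b];
    b1[b] = gr.b1[b];
    W2[b] = gr.W2[b];
    b2[b] = gr.b2[b];
  }
  List grads = List::create(
      _["W_in"] = gr.W_in, _["b_in"] = gr.b_in, _["W1"] = W1, _["b1"] = b1,
      _["W2"] = W2, _["b2"] = b2, _["W_out"] = gr.W_out, _["b_out"] = gr.b_out,
      _["mu"] = gr.mu);
  return List::create(_["loss"] = L, _["image"] = x, _["grads"] = grads);
}

// [[Rcpp::export]]
List cpp_mixed_loss(const arma::cx_vec& u, const arma::cx_vec& v) {
  double L = mixed_loss_(u, v, nullptr);
  return List::create(_["loss"] = L);
}
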