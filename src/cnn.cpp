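// 3D convolutional regression network: conv(same) -> ReLU -> max-pool(same,
// stride 1) -> fully connected (ReLU) -> linear output. Trained with SGD +
// momentum on MSE plus L2 weight decay. Single precision internally; the
// stride-1 same-padded convolution is realized as a dense matrix built from
// the filter weights so that forward and backward passes are plain GEMMs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Geometry {
  int C, L, K;          // input dims: channel, lag, feature
  int kc, kl, kf;       // filter dims
  int S;                // spatial size C*L*K
  int NK;               // kernel size kc*kl*kf
  // conv_map[pos * NK + k] = flat input index or -1 (outside padding)
  std::vector<int> conv_map;
  // pool neighbours (same padding, stride 1, window covering +0/+1 per dim)
  std::vector<std::vector<int>> pool_nb;

  Geometry(IntegerVector dims, IntegerVector filt, IntegerVector pool) {
    C = dims[0]; L = dims[1]; K = dims[2];
    kc = filt[0]; kl = filt[1]; kf = filt[2];
    S = C * L * K;
    NK = kc * kl * kf;
    const int pc = (kc - 1) / 2, pl = (kl - 1) / 2, pf = (kf - 1) / 2;
    conv_map.assign(static_cast<size_t>(S) * NK, -1);
    for (int f = 0; f < K; ++f)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < C; ++c) {
          const int pos = c + C * (l + L * f);
          for (int zf = 0; zf < kf; ++zf)
            for (int zl = 0; zl < kl; ++zl)
              for (int zc = 0; zc < kc; ++zc) {
                const int jc = c + zc - pc, jl = l + zl - pl, jf = f + zf - pf;
                if (jc < 0 || jc >= C || jl < 0 || jl >= L || jf < 0 || jf >= K)
                  continue;
                const int k = zc + kc * (zl + kl * zf);
                conv_map[static_cast<size_t>(pos) * NK + k] =
                    jc + C * (jl + L * jf);
              }
        }
    const int wc = pool[0], wl = pool[1], wf = pool[2];
    pool_nb.resize(S);
    for (int f = 0; f < K; ++f)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < C; ++c) {
          const int pos = c + C * (l + L * f);
          for (int zf = 0; zf < wf; ++zf)
            for (int zl = 0; zl < wl; ++zl)
              for (int zc = 0; zc < wc; ++zc) {
                const int jc = c + zc, jl = l + zl, jf = f + zf;
                if (jc >= C || jl >= L || jf >= K) continue;
                pool_nb[pos].push_back(jc + C * (jl + L * jf));
              }
        }
  }
};

// Scatter filter weights into the dense conv operator A ((F*S) x S).
void build_A(const arma::fmat& Wc, const Geometry& g, arma::fmat& A) {
  const int F = Wc.n_rows;
  A.zeros(static_cast<size_t>(F) * g.S, g.S);
  for (int f = 0; f < F; ++f)
    for (int pos = 0; pos < g.S; ++pos) {
      const size_t row = static_cast<size_t>(f) * g.S + pos;
      const int* mp = &g.conv_map[static_cast<size_t>(pos) * g.NK];
      for (int k = 0; k < g.NK; ++k)
        if (mp[k] >= 0) A(row, mp[k]) += Wc(f, k);
    }
}

struct Params {
  arma::fmat Wc;   // F x NK
  arma::fvec bc;   // F
  arma::fmat W1;   // H x (F*S)
  arma::fvec b1;   // H
  arma::frowvec W2;  // 1 x H
  float b2;
};

Params params_from_list(const List& w) {
  Params p;
  p.Wc = arma::conv_to<arma::fmat>::from(
      as<arma::mat>(w["Wc"]));
  p.bc = arma::conv_to<arma::fvec>::from(as<arma::vec>(w["bc"]));
  p.W1 = arma::conv_to<arma::fmat>::from(as<arma::mat>(w["W1"]));
  p.b1 = arma::conv_to<arma::fvec>::from(as<arma::vec>(w["b1"]));
  p.W2 = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(w["W2"]));
  p.b2 = static_cast<float>(as<double>(w["b2"]));
  return p;
}

List params_to_list(const Params& p) {
  return List::create(
      _["Wc"] = arma::conv_to<arma::mat>::from(p.Wc),
      _["bc"] = arma::conv_to<arma::vec>::from(p.bc),
      _["W1"] = arma::conv_to<arma::mat>::from(p.W1),
      _["b1"] = arma::conv_to<arma::vec>::from(p.b1),
      _["W2"] = arma::conv_to<arma::rowvec>::from(p.W2),
      _["b2"] = static_cast<double>(p.b2));
}

// Forward pass for a batch; optionally keeps intermediates for backprop.
struct Cache {
  arma::fmat conv;   // (F*S) x B, post-ReLU
  arma::fmat pooled; // (F*S) x B
  arma::umat argmx;  // (F*S) x B, index into conv rows within same filter
  arma::fmat h1;     // H x B, post-ReLU
};

arma::frowvec forward(const Params& p, const arma::fmat& A,
                      const Geometry& g, const arma::fmat& Xb,
                      Cache* cache) {
  const int F = p.Wc.n_rows;
  const int B = Xb.n_cols;
  arma::fmat conv = A * Xb;                     // (F*S) x B
  for (int f = 0; f < F; ++f)
    conv.rows(static_cast<size_t>(f) * g.S, static_cast<size_t>(f) * g.S + g.S - 1) += p.bc(f);
  conv.transform([](float v) { return v > 0.0f ? v : 0.0f; });  // ReLU
  arma::fmat pooled(conv.n_rows, B);
  arma::umat argmx;
  if (cache) argmx.set_size(conv.n_rows, B);
  for (int b = 0; b < B; ++b) {
    const float* cv = conv.colptr(b);
    float* pv = pooled.colptr(b);
    for (int f = 0; f < F; ++f) {
      const size_t off = static_cast<size_t>(f) * g.S;
      for (int pos = 0; pos < g.S; ++pos) {
        const std::vector<int>& nb = g.pool_nb[pos];
        float best = cv[off + nb[0]];
        int besti = nb[0];
        for (size_t q = 1; q < nb.size(); ++q) {
          const float v = cv[off + nb[q]];
          if (v > best) { best = v; besti = nb[q]; }
        }
        pv[off + pos] = best;
        if (cache) argmx(off + pos, b) = off + besti;
      }
    }
  }
  arma::fmat h1 = p.W1 * pooled;
  h1.each_col() += p.b1;
  h1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  arma::frowvec yhat = p.W2 * h1 + p.b2;
  if (cache) {
    cache->conv = std::move(conv);
    cache->pooled = std::move(pooled);
    cache->argmx = std::move(argmx);
    cache->h1 = std::move(h1);
  }
  return yhat;
}

double full_mse(const Params& p, const arma::fmat& A, const Geometry& g,
                const arma::fmat& X, const arma::frowvec& y, int chunk = 256) {
  double acc = 0.0;
  const int n = X.n_cols;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk) - 1;
    arma::frowvec yh = forward(p, A, g, X.cols(s, e), nullptr);
    arma::frowvec d = yh - y.cols(s, e);
    acc += arma::accu(arma::square(d));
  }
  return acc / n;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(NumericMatrix X_, NumericVector y_, IntegerVector dims,
                   IntegerVector filt, IntegerVector pool, List init,
                   IntegerMatrix order, int batch_size, double lr,
                   double momentum, double l2, bool track_loss) {
  const Geometry g(dims, filt, pool);
  arma::fmat X = arma::conv_to<arma::fmat>::from(
      as<arma::mat>(X_));                       // S x N
  arma::frowvec y = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(y_));
  Params p = params_from_list(init);
  const int epochs = order.nrow();
  const int n = X.n_cols;
  const float flr = static_cast<float>(lr);
  const float fmom = static_cast<float>(momentum);
  const float fl2 = static_cast<float>(l2);

  Params v;  // momentum buffers
  v.Wc.zeros(p.Wc.n_rows, p.Wc.n_cols);
  v.bc.zeros(p.bc.n_elem);
  v.W1.zeros(p.W1.n_rows, p.W1.n_cols);
  v.b1.zeros(p.b1.n_elem);
  v.W2.zeros(p.W2.n_elem);
  v.b2 = 0.0f;

  arma::fmat A;
  build_A(p.Wc, g, A);
  std::vector<double> losses;
  losses.push_back(full_mse(p, A, g, X, y));

  const int F = p.Wc.n_rows;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(n, s + batch_size) - 1;
      const int B = e - s + 1;
      arma::uvec idx(B);
      for (int i = 0; i < B; ++i) idx(i) = order(ep, s + i) - 1;
      arma::fmat Xb = X.cols(idx);
      arma::frowvec yb(B);
      for (int i = 0; i < B; ++i) yb(i) = y(idx(i));

      Cache cache;
      arma::frowvec yh = forward(p, A, g, Xb, &cache);
      arma::frowvec dy = (yh - yb) * (2.0f / B);

      // output layer
      arma::frowvec dW2 = dy * cache.h1.t();
      const float db2 = arma::accu(dy);
      arma::fmat dh1 = p.W2.t() * dy;           // H x B
      dh1 %= arma::conv_to<arma::fmat>::from(cache.h1 > 0.0f);

      arma::fmat dW1 = dh1 * cache.pooled.t();
      arma::fvec db1 = arma::sum(dh1, 1);
      arma::fmat dpool = p.W1.t() * dh1;        // (F*S) x B

      // route through max-pool, then ReLU mask
      arma::fmat dconv(dpool.n_rows, dpool.n_cols, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        float* dc = dconv.colptr(b);
        const float* dp = dpool.colptr(b);
        for (size_t r = 0; r < dpool.n_rows; ++r)
          dc[cache.argmx(r, b)] += dp[r];
      }
      dconv %= arma::conv_to<arma::fmat>::from(cache.conv > 0.0f);

      // conv gradients via the dense operator
      arma::fmat dA = dconv * Xb.t();           // (F*S) x S
      arma::fmat dWc(F, g.NK, arma::fill::zeros);
      for (int f = 0; f < F; ++f) {
        const size_t off = static_cast<size_t>(f) * g.S;
        for (int pos = 0; pos < g.S; ++pos) {
          const int* mp = &g.conv_map[static_cast<size_t>(pos) * g.NK];
          const float* row = nullptr;
          for (int k = 0; k < g.NK; ++k)
            if (mp[k] >= 0) dWc(f, k) += dA(off + pos, mp[k]);
          (void)row;
        }
      }
      arma::fvec dbc(F);
      for (int f = 0; f < F; ++f) {
        const size_t off = static_cast<size_t>(f) * g.S;
        dbc(f) = arma::accu(dconv.rows(off, off + g.S - 1));
      }

      // SGD with momentum + L2 weight decay (biases undecayed)
      v.Wc = fmom * v.Wc - flr * (dWc + fl2 * p.Wc);
      v.bc = fmom * v.bc - flr * dbc;
      v.W1 = fmom * v.W1 - flr * (dW1 + fl2 * p.W1);
      v.b1 = fmom * v.b1 - flr * db1;
      v.W2 = fmom * v.W2 - flr * (dW2 + fl2 * p.W2);
      v.b2 = fmom * v.b2 - flr * db2;
      p.Wc += v.Wc; p.bc += v.bc;
      p.W1 += v.W1; p.b1 += v.b1;
      p.W2 += v.W2; p.b2 += v.b2;
      build_A(p.Wc, g, A);
    }
    if (track_loss) losses.push_back(full_mse(p, A, g, X, y));
  }
  if (!track_loss) losses.push_back(full_mse(p, A, g, X, y));
  return List::create(_["weights"] = params_to_list(p),
                      _["loss"] = NumericVector(losses.begin(), losses.end()));
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericVector cnn_predict_cpp(NumericMatrix X_, IntegerVector dims,
                              IntegerVector filt, IntegerVector pool,
                              List weights) {
  const Geometry g(dims, filt, pool);
  arma::fmat X = arma::conv_to<arma::fmat>::from(as<arma::mat>(X_));
  Params p = params_from_list(weights);
  arma::fmat A;
  build_A(p.Wc, g, A);
  const int n = X.n_cols;
  NumericVector out(n);
  const int chunk = 256;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk) - 1;
    arma::frowvec yh = forward(p, A, g, X.cols(s, e), nullptr);
    for (int i = s; i <= e; ++i) out[i] = yh(i - s);
  }
  return out;
}
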