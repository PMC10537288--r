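// Single-precision bidirectional-LSTM kernels.
//
// The recurrent layers dominate training cost (a 180-step recurrence with
// hidden sizes up to 180), so the step loop lives here; everything it needs
// for backpropagation-through-time is cached on the C++ side and handed back
// to R as an external pointer to avoid copying large activations.
//
// Layout: the input is one scalar feature per time step, x (B x L).
// Gate order inside the 4H blocks: input, forget, cell, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct LstmCache {
  fmat x;      // B x L
  fcube gates; // B x 4H x L, post-activation
  fcube c;     // B x H x L
  fcube tc;    // B x H x L, tanh(c_t)
  fcube h;     // B x H x L
  int H;
};

static inline fmat sigmf(const fmat &z) { return 1.0f / (1.0f + exp(-z)); }

// [[Rcpp::export(name = ".lstm_forward")]]
List lstm_forward_cpp(const arma::mat &x_, const arma::vec &Wx_,
                      const arma::mat &Wh_, const arma::vec &b_) {
  fmat x = conv_to<fmat>::from(x_);
  frowvec Wx = conv_to<frowvec>::from(Wx_.t()); // 1 x 4H
  fmat Wh = conv_to<fmat>::from(Wh_);           // H x 4H
  frowvec b = conv_to<frowvec>::from(b_.t());
  const uword B = x.n_rows, L = x.n_cols, H = Wh.n_rows;

  LstmCache *cache = new LstmCache();
  cache->x = x;
  cache->gates.set_size(B, 4 * H, L);
  cache->c.set_size(B, H, L);
  cache->tc.set_size(B, H, L);
  cache->h.set_size(B, H, L);
  cache->H = (int)H;

  fmat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    fmat z = x.col(t) * Wx + h * Wh;
    z.each_row() += b;
    fmat i = sigmf(z.cols(0, H - 1));
    fmat f = sigmf(z.cols(H, 2 * H - 1));
    fmat g = tanh(z.cols(2 * H, 3 * H - 1));
    fmat o = sigmf(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    fmat tc = tanh(c);
    h = o % tc;
    cache->gates.slice(t) = join_rows(join_rows(i, f), join_rows(g, o));
    cache->c.slice(t) = c;
    cache->tc.slice(t) = tc;
    cache->h.slice(t) = h;
  }
  XPtr<LstmCache> ptr(cache, true);
  return List::create(Named("h_last") = conv_to<mat>::from(h),
                      Named("cache") = ptr);
}

// Backpropagation through time with gradient injected at the final hidden
// state only (all architectures here consume just the final state of each
// direction).
// [[Rcpp::export(name = ".lstm_backward")]]
List lstm_backward_cpp(SEXP cache_, const arma::vec &Wx_, const arma::mat &Wh_,
                       const arma::mat &dh_last_) {
  XPtr<LstmCache> cache(cache_);
  frowvec Wx = conv_to<frowvec>::from(Wx_.t());
  fmat Wh = conv_to<fmat>::from(Wh_);
  const uword B = cache->x.n_rows, L = cache->x.n_cols, H = (uword)cache->H;

  fmat dh = conv_to<fmat>::from(dh_last_);
  fmat dc(B, H, fill::zeros);
  frowvec dWx(4 * H, fill::zeros);
  fmat dWh(H, 4 * H, fill::zeros);
  frowvec db(4 * H, fill::zeros);
  fmat dx(B, L, fill::zeros);

  for (uword tt = L; tt-- > 0;) {
    const fmat &gates = cache->gates.slice(tt);
    fmat i = gates.cols(0, H - 1);
    fmat f = gates.cols(H, 2 * H - 1);
    fmat g = gates.cols(2 * H, 3 * H - 1);
    fmat o = gates.cols(3 * H, 4 * H - 1);
    const fmat &tc = cache->tc.slice(tt);
    fmat c_prev = (tt == 0) ? fmat(B, H, fill::zeros) : cache->c.slice(tt - 1);
    fmat h_prev = (tt == 0) ? fmat(B, H, fill::zeros) : cache->h.slice(tt - 1);

    fmat do_ = dh % tc;
    dc += dh % o % (1.0f - tc % tc);
    fmat di = dc % g;
    fmat df = dc % c_prev;
    fmat dg = dc % i;

    fmat dz(B, 4 * H);
    dz.cols(0, H - 1) = di % i % (1.0f - i);
    dz.cols(H, 2 * H - 1) = df % f % (1.0f - f);
    dz.cols(2 * H, 3 * H - 1) = dg % (1.0f - g % g);
    dz.cols(3 * H, 4 * H - 1) = do_ % o % (1.0f - o);

    dWx += cache->x.col(tt).t() * dz;
    dWh += h_prev.t() * dz;
    db += sum(dz, 0);
    dx.col(tt) = dz * Wx.t();
    dh = dz * Wh.t();
    dc = dc % f;
  }
  return List::create(Named("dWx") = conv_to<vec>::from(dWx.t()),
                      Named("dWh") = conv_to<mat>::from(dWh),
                      Named("db") = conv_to<vec>::from(db.t()),
                      Named("dx") = conv_to<mat>::from(dx));
}
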