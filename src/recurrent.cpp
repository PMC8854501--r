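// One-step-ahead recurrent regressors (simple RNN, GRU, LSTM) for short lag
// windows: forward pass, backpropagation through time, Adam.  Scalar input
// per time step, single recurrent layer, linear output head read from the
// last hidden state.  All randomness (weight init, batch shuffling) comes
// from an internal splitmix64 stream so training is bit-reproducible from
// the seed alone and never touches R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// splitmix64: tiny, platform-independent, good enough for init + shuffling
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed + 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

enum Kind { RNN = 0, GRU = 1, LSTM = 2 };

int n_gates(int kind) { return kind == RNN ? 1 : (kind == GRU ? 3 : 4); }

// parameter layout: for each gate g, [3g]=W (H x 1), [3g+1]=U (H x H),
// [3g+2]=b (H x 1); then out_w (H x 1), out_b (1 x 1).
// gate order — GRU: z, r, n; LSTM: i, f, o, g.
std::vector<mat> init_params(int kind, int hidden, XRng& rng) {
  const int G = n_gates(kind);
  const double a = 1.0 / std::sqrt((double)hidden);
  std::vector<mat> P;
  auto runif_mat = [&](int r, int c) {
    mat m(r, c);
    for (uword j = 0; j < m.n_elem; ++j) m(j) = (2.0 * rng.unif() - 1.0) * a;
    return m;
  };
  for (int g = 0; g < G; ++g) {
    P.push_back(runif_mat(hidden, 1));       // W
    P.push_back(runif_mat(hidden, hidden));  // U
    P.push_back(mat(hidden, 1, fill::zeros));
  }
  if (kind == LSTM) P[3 * 1 + 2].fill(1.0);  // forget-gate bias at 1
  P.push_back(runif_mat(hidden, 1));         // out_w
  P.push_back(mat(1, 1, fill::zeros));       // out_b
  return P;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {  // per-timestep activations for BPTT
  std::vector<mat> h;              // hidden after each step (T entries)
  std::vector<mat> z, r, hh;       // GRU
  std::vector<mat> i, f, o, g, c, ch;  // LSTM
};

// X: B x T (one window per row); returns yhat (1 x B)
rowvec forward(const std::vector<mat>& P, int kind, const mat& X, Cache* cc) {
  const int H = P[0].n_rows, B = X.n_rows, T = X.n_cols;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  auto pre = [&](int g, const rowvec& xt, const mat& hprev) {
    mat A = P[3 * g] * xt + P[3 * g + 1] * hprev;
    A.each_col() += vec(P[3 * g + 2]);
    return A;
  };
  for (int t = 0; t < T; ++t) {
    rowvec xt = X.col(t).t();
    if (kind == RNN) {
      h = tanh(pre(0, xt, h));
    } else if (kind == GRU) {
      mat z = sigm(pre(0, xt, h));
      mat r = sigm(pre(1, xt, h));
      mat A = P[3 * 2] * xt + P[3 * 2 + 1] * (r % h);
      A.each_col() += vec(P[3 * 2 + 2]);
      mat hh = tanh(A);
      mat hn = (1.0 - z) % h + z % hh;
      if (cc) { cc->z.push_back(z); cc->r.push_back(r); cc->hh.push_back(hh); }
      h = hn;
    } else {
      mat i = sigm(pre(0, xt, h));
      mat f = sigm(pre(1, xt, h));
      mat o = sigm(pre(2, xt, h));
      mat g = tanh(pre(3, xt, h));
      c = f % c + i % g;
      mat ch = tanh(c);
      if (cc) {
        cc->i.push_back(i); cc->f.push_back(f); cc->o.push_back(o);
        cc->g.push_back(g); cc->c.push_back(c); cc->ch.push_back(ch);
      }
      h = o % ch;
    }
    if (cc) cc->h.push_back(h);
  }
  // residual head: the network models the one-step CHANGE on top of the
  // last lag, so an untrained net starts at the persistence forecast and
  // extrapolation error is bounded by the increment scale
  rowvec yhat = X.col(T - 1).t() + P[3 * n_gates(kind)].t() * h;
  yhat += P[3 * n_gates(kind) + 1](0, 0);
  return yhat;
}

// accumulates gradients into Gd; returns batch MSE
double backward(const std::vector<mat>& P, int kind, const mat& X,
                const rowvec& y, std::vector<mat>& Gd) {
  Cache cc;
  rowvec yhat = forward(P, kind, X, &cc);
  const int H = P[0].n_rows, B = X.n_rows, T = X.n_cols;
  const int G = n_gates(kind);
  rowvec err = yhat - y;
  double loss = accu(err % err) / B;
  rowvec dy = 2.0 * err / B;

  Gd[3 * G] += cc.h[T - 1] * dy.t();
  Gd[3 * G + 1](0, 0) += accu(dy);
  mat dh = P[3 * G] * dy;
  mat dc(H, B, fill::zeros);

  auto hprev_at = [&](int t) {
    return t == 0 ? mat(H, B, fill::zeros) : cc.h[t - 1];
  };
  auto acc = [&](int g, const mat& da, const rowvec& xt, const mat& hsrc) {
    Gd[3 * g] += da * xt.t();
    Gd[3 * g + 1] += da * hsrc.t();
    Gd[3 * g + 2] += sum(da, 1);
  };
  for (int t = T - 1; t >= 0; --t) {
    rowvec xt = X.col(t).t();
    mat hprev = hprev_at(t);
    if (kind == RNN) {
      mat da = dh % (1.0 - cc.h[t] % cc.h[t]);
      acc(0, da, xt, hprev);
      dh = P[1].t() * da;
    } else if (kind == GRU) {
      const mat &z = cc.z[t], &r = cc.r[t], &hh = cc.hh[t];
      mat dz = dh % (hh - hprev);
      mat dhh = dh % z;
      mat dhp = dh % (1.0 - z);
      mat dan = dhh % (1.0 - hh % hh);
      acc(2, dan, xt, r % hprev);
      mat drh = P[3 * 2 + 1].t() * dan;
      mat dr = drh % hprev;
      dhp += drh % r;
      mat daz = dz % z % (1.0 - z);
      acc(0, daz, xt, hprev);
      dhp += P[1].t() * daz;
      mat dar = dr % r % (1.0 - r);
      acc(1, dar, xt, hprev);
      dhp += P[3 * 1 + 1].t() * dar;
      dh = dhp;
    } else {
      const mat &i = cc.i[t], &f = cc.f[t], &o = cc.o[t], &g = cc.g[t];
      const mat &ch = cc.ch[t];
      mat cprev = t == 0 ? mat(H, B, fill::zeros) : cc.c[t - 1];
      mat do_ = dh % ch;
      dc += dh % o % (1.0 - ch % ch);
      mat df = dc % cprev, di = dc % g, dg = dc % i;
      mat dcp = dc % f;
      mat dai = di % i % (1.0 - i);
      mat daf = df % f % (1.0 - f);
      mat dao = do_ % o % (1.0 - o);
      mat dag = dg % (1.0 - g % g);
      acc(0, dai, xt, hprev);
      acc(1, daf, xt, hprev);
      acc(2, dao, xt, hprev);
      acc(3, dag, xt, hprev);
      dh = P[1].t() * dai + P[3 * 1 + 1].t() * daf +
           P[3 * 2 + 1].t() * dao + P[3 * 3 + 1].t() * dag;
      dc = dcp;
    }
  }
  return loss;
}

std::vector<mat> list_to_params(Rcpp::List params) {
  std::vector<mat> P;
  for (int k = 0; k < params.size(); ++k)
    P.push_back(Rcpp::as<mat>(params[k]));
  return P;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_recurrent(const arma::mat& X, const arma::vec& y,
                               int kind, int hidden, int epochs, double lr,
                               int batch_size, double seed,
                               double weight_decay) {
  const int N = X.n_rows;
  XRng rng((uint64_t)seed);
  std::vector<mat> P = init_params(kind, hidden, rng);
  std::vector<mat> M, V;
  for (auto& p : P) { M.push_back(mat(size(p), fill::zeros));
                      V.push_back(mat(size(p), fill::zeros)); }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  const long total_steps = (long)epochs * ((N + batch_size - 1) / batch_size);
  // tail weight averaging (Polyak): the returned parameters are the mean
  // over the last quarter of optimization steps, which damps the noise of
  // minibatch fitting without touching the trajectory itself
  const long avg_from = total_steps - total_steps / 4;
  long avg_count = 0;
  std::vector<mat> Pavg;
  for (auto& p : P) Pavg.push_back(mat(size(p), fill::zeros));
  std::vector<int> idx(N);
  for (int k = 0; k < N; ++k) idx[k] = k;
  Rcpp::NumericVector trace(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int k = N - 1; k > 0; --k)  // Fisher–Yates
      std::swap(idx[k], idx[(int)(rng.unif() * (k + 1))]);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      int B = std::min(batch_size, N - start);
      mat Xb(B, X.n_cols);
      rowvec yb(B);
      for (int k = 0; k < B; ++k) {
        Xb.row(k) = X.row(idx[start + k]);
        yb(k) = y(idx[start + k]);
      }
      std::vector<mat> Gd;
      for (auto& p : P) Gd.push_back(mat(size(p), fill::zeros));
      double loss = backward(P, kind, Xb, yb, Gd);
      ep_loss += loss * B;
      ++step;
      // linear decay to 2% of the base step keeps late epochs refining the
      // fit instead of jittering around the optimum
      double lr_t = lr * std::max(0.02, 1.0 - (double)step / total_steps);
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (size_t k = 0; k < P.size(); ++k) {
        M[k] = b1 * M[k] + (1.0 - b1) * Gd[k];
        V[k] = b2 * V[k] + (1.0 - b2) * (Gd[k] % Gd[k]);
        // decoupled weight decay (AdamW): shrink weights directly
        P[k] -= lr_t * ((M[k] / c1) / (sqrt(V[k] / c2) + eps) +
                        weight_decay * P[k]);
      }
      if (step > avg_from) {
        ++avg_count;
        for (size_t k = 0; k < P.size(); ++k) Pavg[k] += P[k];
      }
    }
    trace[ep] = ep_loss / N;
  }

  if (avg_count > 0)
    for (size_t k = 0; k < P.size(); ++k) P[k] = Pavg[k] / (double)avg_count;

  Rcpp::List out(P.size());
  for (size_t k = 0; k < P.size(); ++k) out[k] = Rcpp::wrap(P[k]);
  return Rcpp::List::create(Rcpp::Named("params") = out,
                            Rcpp::Named("loss_trace") = trace);
}

// [[Rcpp::export]]
arma::vec cpp_predict_recurrent(Rcpp::List params, int kind,
                                const arma::mat& X) {
  std::vector<mat> P = list_to_params(params);
  rowvec yhat = forward(P, kind, X, nullptr);
  return yhat.t();
}

// [[Rcpp::export]]
double cpp_batch_loss(Rcpp::List params, int kind, const arma::mat& X,
                      const arma::vec& y, Rcpp::List grads_out) {
  // exposed for gradient verification in tests: fills grads_out (same
  // layout as params) with analytic gradients of the batch MSE
  std::vector<mat> P = list_to_params(params);
  std::vector<mat> Gd;
  for (auto& p : P) Gd.push_back(mat(size(p), fill::zeros));
  double loss = backward(P, kind, X, rowvec(y.t()), Gd);
  for (size_t k = 0; k < P.size(); ++k)
    grads_out[k] = Rcpp::wrap(Gd[k]);
  return loss;
}
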