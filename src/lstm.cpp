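// Unidirectional LSTM sequence-to-sequence binary classifier with a
// fully-connected softmax head, trained with Adam + BPTT.
//
// The network is small enough (hundreds of hidden units, two classes) that
// a dedicated dense implementation on top of BLAS is the right tool; batches
// of equal-length segments are processed as H x B matrices per time step.
//
// All randomness (weight init, batch shuffling) comes from a private
// mt19937 seeded from R, so training is deterministic given the seed in
// single-threaded BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::mat;
using arma::cube;

struct Net {
  mat W;        // 4H x (D+H), gate order i f g o
  arma::vec b;  // 4H
  mat Wo;       // 2 x H
  arma::vec bo; // 2
};

static Net init_net(int D, int H, std::mt19937& rng) {
  Net n;
  std::uniform_real_distribution<double> u(-1.0, 1.0);
  const double s_in = std::sqrt(6.0 / (D + H + 4.0 * H));
  n.W.set_size(4 * H, D + H);
  for (auto& v : n.W) v = u(rng) * s_in;
  n.b.zeros(4 * H);
  n.b.subvec(H, 2 * H - 1).fill(1.0); // forget-gate bias
  const double s_out = std::sqrt(6.0 / (H + 2.0));
  n.Wo.set_size(2, H);
  for (auto& v : n.Wo) v = u(rng) * s_out;
  n.bo.zeros(2);
  return n;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// forward pass over a batch; optionally keep activations for BPTT
struct FwdCache {
  cube gi, gf, gg, go, c, h; // H x B x T
};

static double forward_loss(const Net& net, const cube& X,
                           const arma::imat& Y, const arma::imat& M,
                           FwdCache* cache, mat* probs_out) {
  const int D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const int H = net.Wo.n_cols;
  (void)D;
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  if (cache) {
    cache->gi.set_size(H, B, T); cache->gf.set_size(H, B, T);
    cache->gg.set_size(H, B, T); cache->go.set_size(H, B, T);
    cache->c.set_size(H, B, T);  cache->h.set_size(H, B, T);
  }
  double loss = 0.0; long nobs = 0;
  for (int t = 0; t < T; ++t) {
    mat zin = arma::join_cols(X.slice(t), h);     // (D+H) x B
    mat z = net.W * zin;
    z.each_col() += net.b;
    mat gi = sigm(z.rows(0, H - 1));
    mat gf = sigm(z.rows(H, 2 * H - 1));
    mat gg = arma::tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigm(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    mat tc = arma::tanh(c);
    h = go % tc;
    if (cache) {
      cache->gi.slice(t) = gi; cache->gf.slice(t) = gf;
      cache->gg.slice(t) = gg; cache->go.slice(t) = go;
      cache->c.slice(t) = c;   cache->h.slice(t) = h;
    }
    mat logits = net.Wo * h;                       // 2 x B
    logits.each_col() += net.bo;
    mat mx = arma::max(logits, 0);
    mat ex = arma::exp(logits.each_row() - mx);
    mat p = ex.each_row() / arma::sum(ex, 0);
    if (probs_out && B == 1) probs_out->col(t) = p.col(0);
    for (int bcol = 0; bcol < B; ++bcol) {
      if (!M(bcol, t)) continue;
      loss += -std::log(std::max(p(Y(bcol, t), bcol), 1e-12));
      ++nobs;
    }
  }
  return nobs ? loss / nobs : 0.0;
}

struct Grads { mat W; arma::vec b; mat Wo; arma::vec bo; };

static double fwd_bwd(const Net& net, const cube& X, const arma::imat& Y,
                      const arma::imat& M, Grads& g) {
  const int D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const int H = net.Wo.n_cols;
  FwdCache cc;
  double loss = forward_loss(net, X, Y, M, &cc, nullptr);
  long nobs = 0;
  for (int t = 0; t < T; ++t)
    for (int bcol = 0; bcol < B; ++bcol) nobs += M(bcol, t) ? 1 : 0;
  if (!nobs) nobs = 1;

  g.W.zeros(4 * H, D + H); g.b.zeros(4 * H);
  g.Wo.zeros(2, H); g.bo.zeros(2);
  mat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    // recompute softmax grads
    mat logits = net.Wo * cc.h.slice(t);
    logits.each_col() += net.bo;
    mat mx = arma::max(logits, 0);
    mat ex = arma::exp(logits.each_row() - mx);
    mat p = ex.each_row() / arma::sum(ex, 0);
    mat dlogit = p;                                  // 2 x B
    for (int bcol = 0; bcol < B; ++bcol) {
      if (M(bcol, t)) dlogit(Y(bcol, t), bcol) -= 1.0;
      else dlogit.col(bcol).zeros();
    }
    dlogit /= (double)nobs;
    g.Wo += dlogit * cc.h.slice(t).t();
    g.bo += arma::sum(dlogit, 1);
    mat dh = net.Wo.t() * dlogit + dh_next;

    const mat& gi = cc.gi.slice(t); const mat& gf = cc.gf.slice(t);
    const mat& gg = cc.gg.slice(t); const mat& go = cc.go.slice(t);
    mat tc = arma::tanh(cc.c.slice(t));
    mat dc = dh % go % (1.0 - tc % tc) + dc_next;
    mat dgo = dh % tc % go % (1.0 - go);
    mat cprev = (t > 0) ? cc.c.slice(t - 1) : mat(H, B, arma::fill::zeros);
    mat dgf = dc % cprev % gf % (1.0 - gf);
    mat dgi = dc % gg % gi % (1.0 - gi);
    mat dgg = dc % gi % (1.0 - gg % gg);
    dc_next = dc % gf;

    mat dz = arma::join_cols(arma::join_cols(dgi, dgf),
                             arma::join_cols(dgg, dgo)); // 4H x B
    mat hprev = (t > 0) ? cc.h.slice(t - 1) : mat(H, B, arma::fill::zeros);
    mat zin = arma::join_cols(X.slice(t), hprev);
    g.W += dz * zin.t();
    g.b += arma::sum(dz, 1);
    mat dzin = net.W.t() * dz;                      // (D+H) x B
    dh_next = dzin.rows(D, D + H - 1);
  }
  return loss;
}

struct AdamState { mat mW, vW, mWo, vWo; arma::vec mb, vb, mbo, vbo; long t = 0; };

static void adam_step(Net& net, const Grads& g, AdamState& st, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.t += 1;
  const double bc1 = 1.0 - std::pow(b1, (double)st.t);
  const double bc2 = 1.0 - std::pow(b2, (double)st.t);
  auto upd = [&](mat& w, const mat& gw, mat& m, mat& v) {
    m = b1 * m + (1 - b1) * gw;
    v = b2 * v + (1 - b2) * (gw % gw);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  };
  auto updv = [&](arma::vec& w, const arma::vec& gw, arma::vec& m, arma::vec& v) {
    m = b1 * m + (1 - b1) * gw;
    v = b2 * v + (1 - b2) * (gw % gw);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  };
  upd(net.W, g.W, st.mW, st.vW);
  updv(net.b, g.b, st.mb, st.vb);
  upd(net.Wo, g.Wo, st.mWo, st.vWo);
  updv(net.bo, g.bo, st.mbo, st.vbo);
}

// seq_x: list of D x T matrices; seq_y: list of integer vectors (0/1, length
// T). Sequences must share D; lengths may differ (batches pad with masks).
// [[Rcpp::export]]
List cpp_lstm_train(List seq_x, List seq_y, IntegerVector train_idx,
                    IntegerVector val_idx, int hidden, int batch_size,
                    int max_epochs, double lr0, double lr_drop_factor,
                    int lr_drop_every, int patience, int seed,
                    bool verbose) {
  const int nseq = seq_x.size();
  if (nseq == 0) stop("empty sequence list");
  std::vector<mat> X(nseq);
  std::vector<arma::ivec> Y(nseq);
  int D = -1;
  for (int i = 0; i < nseq; ++i) {
    X[i] = as<mat>(seq_x[i]);
    Y[i] = as<arma::ivec>(seq_y[i]);
    if (D < 0) D = X[i].n_rows;
    if ((int)X[i].n_rows != D) stop("inconsistent feature dimension");
    if (X[i].n_cols != Y[i].n_elem) stop("label length mismatch");
  }
  std::mt19937 rng(seed);
  Net net = init_net(D, hidden, rng);
  AdamState st;
  st.mW.zeros(arma::size(net.W)); st.vW.zeros(arma::size(net.W));
  st.mb.zeros(net.b.n_elem); st.vb.zeros(net.b.n_elem);
  st.mWo.zeros(arma::size(net.Wo)); st.vWo.zeros(arma::size(net.Wo));
  st.mbo.zeros(net.bo.n_elem); st.vbo.zeros(net.bo.n_elem);

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  for (auto& v : tr) v -= 1;
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto& v : va) v -= 1;

  auto eval_set = [&](const std::vector<int>& idx) {
    double loss = 0; long n = 0;
    for (int i : idx) {
      const int T = X[i].n_cols;
      cube Xc(D, 1, T);
      for (int t = 0; t < T; ++t) Xc.slice(t).col(0) = X[i].col(t);
      arma::imat Yb(1, T), Mb(1, T, arma::fill::ones);
      for (int t = 0; t < T; ++t) Yb(0, t) = Y[i][t];
      loss += forward_loss(net, Xc, Yb, Mb, nullptr, nullptr) * T;
      n += T;
    }
    return n ? loss / n : 0.0;
  };

  Net best = net;
  double best_val = std::numeric_limits<double>::infinity();
  int exceed = 0, best_epoch = 0;
  NumericVector train_log, val_log;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    const double lr = lr0 * std::pow(lr_drop_factor,
                                     (epoch - 1) / std::max(1, lr_drop_every));
    std::vector<int> order = tr;
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int nb = 0;
    for (size_t start = 0; start < order.size(); start += batch_size) {
      const int B = std::min((size_t)batch_size, order.size() - start);
      int Tmax = 0;
      for (int bcol = 0; bcol < B; ++bcol)
        Tmax = std::max(Tmax, (int)X[order[start + bcol]].n_cols);
      cube Xc(D, B, Tmax, arma::fill::zeros);
      arma::imat Yb(B, Tmax, arma::fill::zeros), Mb(B, Tmax, arma::fill::zeros);
      for (int bcol = 0; bcol < B; ++bcol) {
        const mat& xi = X[order[start + bcol]];
        const arma::ivec& yi = Y[order[start + bcol]];
        for (int t = 0; t < (int)xi.n_cols; ++t) {
          Xc.slice(t).col(bcol) = xi.col(t);
          Yb(bcol, t) = yi[t];
          Mb(bcol, t) = 1;
        }
      }
      Grads g;
      ep_loss += fwd_bwd(net, Xc, Yb, Mb, g);
      adam_step(net, g, st, lr);
      ++nb;
      Rcpp::checkUserInterrupt();
    }
    double vloss = va.empty() ? ep_loss / std::max(1, nb) : eval_set(va);
    train_log.push_back(ep_loss / std::max(1, nb));
    val_log.push_back(vloss);
    if (verbose)
      Rcout << "epoch " << epoch << " train " << ep_loss / std::max(1, nb)
            << " val " << vloss << "\n";
    if (vloss < best_val) {
      best_val = vloss; best = net; best_epoch = epoch;
    } else {
      ++exceed;
      if (exceed > patience) break;
    }
  }

  return List::create(
      _["W"] = best.W, _["b"] = best.b, _["Wo"] = best.Wo, _["bo"] = best.bo,
      _["train_loss"] = train_log, _["val_loss"] = val_log,
      _["best_epoch"] = best_epoch, _["hidden"] = hidden);
}

// per-sample class-P probability for one sequence
// [[Rcpp::export]]
NumericVector cpp_lstm_predict(NumericMatrix Wr, NumericVector br,
                               NumericMatrix Wor, NumericVector bor,
                               NumericMatrix xr) {
  Net net;
  net.W = as<mat>(Wr); net.b = as<arma::vec>(br);
  net.Wo = as<mat>(Wor); net.bo = as<arma::vec>(bor);
  mat x = as<mat>(xr);
  const int H = net.Wo.n_cols, T = x.n_cols;
  mat h(H, 1, arma::fill::zeros), c(H, 1, arma::fill::zeros);
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    mat zin = arma::join_cols(x.col(t), h);
    mat z = net.W * zin;
    z.each_col() += net.b;
    mat gi = sigm(z.rows(0, H - 1));
    mat gf = sigm(z.rows(H, 2 * H - 1));
    mat gg = arma::tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigm(z.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % arma::tanh(c);
    arma::vec logits = net.Wo * h + net.bo;
    const double mx = logits.max();
    const double e0 = std::exp(logits[0] - mx), e1 = std::exp(logits[1] - mx);
    out[t] = e1 / (e0 + e1);   // class P = index 1
  }
  return out;
}
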