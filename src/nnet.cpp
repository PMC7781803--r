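// Minimal feed-forward and convolutional network trainers (Adam, early
// stopping on a held-out validation split), written directly against
// Armadillo. Single-threaded and seeded: two runs with the same data and
// seed produce identical weights.
#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Adam {
  arma::mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const arma::mat& p) {
    m.zeros(p.n_rows, p.n_cols);
    v.zeros(p.n_rows, p.n_cols);
  }
  void step(arma::mat& p, const arma::mat& g, double lr, long t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * (g % g);
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

arma::mat he_init(int rows, int cols, std::mt19937_64& rng) {
  double limit = std::sqrt(6.0 / (double)cols);
  std::uniform_real_distribution<double> unif(-limit, limit);
  arma::mat w(rows, cols);
  for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = unif(rng);
  return w;
}

arma::mat softmax_rows(const arma::mat& z) {
  arma::mat out = z;
  out.each_col() -= arma::max(z, 1);
  out = arma::exp(out);
  out.each_col() /= arma::sum(out, 1);
  return out;
}

inline arma::mat sigmoid_mat(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-arma::clamp(z, -30.0, 30.0)));
}

double mean_loss(const arma::mat& probs, const arma::mat& y, bool multilabel) {
  const double eps = 1e-12;
  if (multilabel) {
    arma::mat l = -(y % arma::log(probs + eps) +
                    (1.0 - y) % arma::log(1.0 - probs + eps));
    return arma::accu(l) / (double)probs.n_rows;
  }
  arma::mat l = -(y % arma::log(probs + eps));
  return arma::accu(l) / (double)probs.n_rows;
}

std::vector<arma::uword> shuffled(arma::uword n, std::mt19937_64& rng) {
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;
  for (arma::uword i = n - 1; i > 0; --i) {
    std::uniform_int_distribution<arma::uword> u(0, i);
    std::swap(idx[i], idx[u(rng)]);
  }
  return idx;
}

} // namespace

// ---------------------------------------------------------------- MLP ----

static arma::mat mlp_forward(const arma::mat& X,
                             const std::vector<arma::mat>& W,
                             const std::vector<arma::rowvec>& b,
                             bool multilabel,
                             std::vector<arma::mat>* acts = nullptr) {
  arma::mat a = X;
  if (acts) acts->push_back(a);
  for (size_t l = 0; l < W.size(); ++l) {
    arma::mat z = a * W[l].t();
    z.each_row() += b[l];
    if (l + 1 < W.size()) {
      a = arma::clamp(z, 0.0, arma::datum::inf); // ReLU
    } else {
      a = multilabel ? sigmoid_mat(z) : softmax_rows(z);
    }
    if (acts) acts->push_back(a);
  }
  return a;
}

// [[Rcpp::export]]
List cpp_mlp_train(arma::mat X, arma::mat Y, IntegerVector hidden,
                   bool multilabel, int epochs, int batch, double lr,
                   double val_frac, int patience, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  arma::uword n = X.n_rows;
  std::vector<int> sizes;
  sizes.push_back((int)X.n_cols);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back((int)Y.n_cols);
  size_t L = sizes.size() - 1;

  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  std::vector<Adam> aW(L), ab(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = he_init(sizes[l + 1], sizes[l], rng);
    b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    aW[l].init(W[l]);
    arma::mat bm(1, sizes[l + 1]);
    ab[l].init(bm);
  }

  std::vector<arma::uword> perm = shuffled(n, rng);
  arma::uword n_val = (arma::uword)std::floor(val_frac * (double)n);
  bool use_val = n_val >= 1 && n_val < n;
  arma::uvec tr_idx(use_val ? n - n_val : n), va_idx(use_val ? n_val : 0);
  for (arma::uword i = 0; i < tr_idx.n_elem; ++i) tr_idx[i] = perm[i];
  for (arma::uword i = 0; i < va_idx.n_elem; ++i)
    va_idx[i] = perm[tr_idx.n_elem + i];
  arma::mat Xtr = X.rows(tr_idx), Ytr = Y.rows(tr_idx);
  arma::mat Xva, Yva;
  if (use_val) { Xva = X.rows(va_idx); Yva = Y.rows(va_idx); }

  long t = 0;
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0;
  std::vector<arma::mat> bestW = W;
  std::vector<arma::rowvec> bestb = b;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::vector<arma::uword> ord = shuffled(Xtr.n_rows, rng);
    for (arma::uword start = 0; start < Xtr.n_rows;
         start += (arma::uword)batch) {
      arma::uword end = std::min(start + (arma::uword)batch, Xtr.n_rows);
      arma::uvec bi(end - start);
      for (arma::uword i = start; i < end; ++i) bi[i - start] = ord[i];
      arma::mat Xb = Xtr.rows(bi), Yb = Ytr.rows(bi);

      std::vector<arma::mat> acts;
      arma::mat P = mlp_forward(Xb, W, b, multilabel, &acts);
      arma::mat delta = (P - Yb) / (double)Xb.n_rows;
      ++t;
      for (int l = (int)L - 1; l >= 0; --l) {
        arma::mat gW = delta.t() * acts[l];
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l];
          delta %= arma::conv_to<arma::mat>::from(acts[l] > 0.0);
        }
        aW[l].step(W[l], gW, lr, t);
        arma::mat bmat = arma::conv_to<arma::mat>::from(b[l]);
        arma::mat gbm = arma::conv_to<arma::mat>::from(gb);
        ab[l].step(bmat, gbm, lr, t);
        b[l] = bmat.row(0);
      }
    }
    if (use_val) {
      double vl = mean_loss(mlp_forward(Xva, W, b, multilabel), Yva,
                            multilabel);
      if (vl < best_val - 1e-6) {
        best_val = vl;
        best_epoch = ep;
        bestW = W;
        bestb = b;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    } else {
      bestW = W;
      bestb = b;
      best_epoch = ep;
    }
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = bestW[l];
    bout[l] = arma::conv_to<arma::mat>::from(bestb[l]);
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["best_epoch"] = best_epoch,
                      _["val_loss"] = best_val);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_predict(arma::mat X, List Wlist, List blist,
                          bool multilabel) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  for (int l = 0; l < Wlist.size(); ++l) {
    W.push_back(as<arma::mat>(Wlist[l]));
    arma::mat bm = as<arma::mat>(blist[l]);
    b.push_back(bm.row(0));
  }
  return mlp_forward(X, W, b, multilabel);
}

// ---------------------------------------------------------------- CNN ----

struct CnnParams {
  arma::mat emb;        // (V+1) x D, row 0 = padding (kept at zero)
  arma::mat Wc;         // F x (kw*D)
  arma::rowvec bc;      // F
  arma::mat W1;         // H x F
  arma::rowvec b1;      // H
  arma::mat W2;         // K x H
  arma::rowvec b2;      // K
};

// forward pass for one sequence; optionally records pooling argmax and the
// hidden activations needed for backprop
static arma::rowvec cnn_forward_one(const arma::irowvec& ids,
                                    const CnnParams& P, int kw,
                                    bool multilabel,
                                    arma::uvec* argmax = nullptr,
                                    arma::rowvec* pooled_out = nullptr,
                                    arma::rowvec* a1_out = nullptr) {
  int L = (int)ids.n_elem;
  int D = (int)P.emb.n_cols;
  int F = (int)P.Wc.n_rows;
  int npos = L - kw + 1;
  arma::rowvec pooled(F, arma::fill::zeros);
  arma::uvec amax(F, arma::fill::zeros);
  arma::vec x(kw * D);
  bool first = true;
  for (int tpos = 0; tpos < npos; ++tpos) {
    for (int j = 0; j < kw; ++j)
      x.subvec(j * D, (j + 1) * D - 1) = P.emb.row(ids[tpos + j]).t();
    arma::vec z = P.Wc * x + P.bc.t();
    z = arma::clamp(z, 0.0, arma::datum::inf);
    for (int f = 0; f < F; ++f) {
      if (first || z[f] > pooled[f]) {
        pooled[f] = z[f];
        amax[f] = tpos;
      }
    }
    first = false;
  }
  arma::rowvec a1 = pooled * P.W1.t() + P.b1;
  a1 = arma::clamp(a1, 0.0, arma::datum::inf);
  arma::rowvec logits = a1 * P.W2.t() + P.b2;
  arma::rowvec probs;
  if (multilabel) {
    probs = sigmoid_mat(arma::conv_to<arma::mat>::from(logits)).row(0);
  } else {
    probs = softmax_rows(arma::conv_to<arma::mat>::from(logits)).row(0);
  }
  if (argmax) *argmax = amax;
  if (pooled_out) *pooled_out = pooled;
  if (a1_out) *a1_out = a1;
  return probs;
}

// [[Rcpp::export]]
List cpp_cnn_train(arma::imat ids, arma::mat emb_init, arma::mat Y,
                   bool multilabel, int kw, int dense, bool train_emb,
                   int epochs, int batch, double lr, double val_frac,
                   int patience, int seed, int filters) {
  std::mt19937_64 rng((uint64_t)seed);
  arma::uword n = ids.n_rows;
  int D = (int)emb_init.n_cols;
  int K = (int)Y.n_cols;

  CnnParams P;
  P.emb = emb_init;
  P.emb.row(0).zeros();
  P.Wc = he_init(filters, kw * D, rng);
  P.bc = arma::rowvec(filters, arma::fill::zeros);
  P.W1 = he_init(dense, filters, rng);
  P.b1 = arma::rowvec(dense, arma::fill::zeros);
  P.W2 = he_init(K, dense, rng);
  P.b2 = arma::rowvec(K, arma::fill::zeros);

  Adam aE, aWc, abc, aW1, ab1, aW2, ab2;
  aE.init(P.emb);
  aWc.init(P.Wc);
  arma::mat tmp;
  tmp = arma::conv_to<arma::mat>::from(P.bc); abc.init(tmp);
  aW1.init(P.W1);
  tmp = arma::conv_to<arma::mat>::from(P.b1); ab1.init(tmp);
  aW2.init(P.W2);
  tmp = arma::conv_to<arma::mat>::from(P.b2); ab2.init(tmp);

  std::vector<arma::uword> perm = shuffled(n, rng);
  arma::uword n_val = (arma::uword)std::floor(val_frac * (double)n);
  bool use_val = n_val >= 1 && n_val < n;
  std::vector<arma::uword> tr(perm.begin(),
                              perm.end() - (use_val ? n_val : 0));
  std::vector<arma::uword> va;
  if (use_val) va.assign(perm.end() - n_val, perm.end());

  auto eval_loss = [&](const std::vector<arma::uword>& idx) {
    double tot = 0.0;
    const double eps = 1e-12;
    for (arma::uword i : idx) {
      arma::rowvec p = cnn_forward_one(ids.row(i), P, kw, multilabel);
      arma::rowvec y = Y.row(i);
      if (multilabel) {
        tot += -arma::accu(y % arma::log(p + eps) +
                           (1.0 - y) % arma::log(1.0 - p + eps));
      } else {
        tot += -arma::accu(y % arma::log(p + eps));
      }
    }
    return tot / (double)idx.size();
  };

  long t = 0;
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0;
  CnnParams best = P;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::vector<arma::uword> ord = tr;
    for (arma::uword i = ord.size() - 1; i > 0; --i) {
      std::uniform_int_distribution<arma::uword> u(0, i);
      std::swap(ord[i], ord[u(rng)]);
    }
    for (size_t start = 0; start < ord.size(); start += (size_t)batch) {
      size_t end = std::min(start + (size_t)batch, ord.size());
      double B = (double)(end - start);
      arma::mat gE(P.emb.n_rows, D, arma::fill::zeros);
      arma::mat gWc(P.Wc.n_rows, P.Wc.n_cols, arma::fill::zeros);
      arma::rowvec gbc(P.bc.n_elem, arma::fill::zeros);
      arma::mat gW1(P.W1.n_rows, P.W1.n_cols, arma::fill::zeros);
      arma::rowvec gb1(P.b1.n_elem, arma::fill::zeros);
      arma::mat gW2(P.W2.n_rows, P.W2.n_cols, arma::fill::zeros);
      arma::rowvec gb2(P.b2.n_elem, arma::fill::zeros);

      for (size_t ii = start; ii < end; ++ii) {
        arma::uword i = ord[ii];
        arma::irowvec row = ids.row(i);
        arma::uvec amax;
        arma::rowvec pooled, a1;
        arma::rowvec probs =
            cnn_forward_one(row, P, kw, multilabel, &amax, &pooled, &a1);
        arma::rowvec dlogit = (probs - Y.row(i)) / B;
        gW2 += dlogit.t() * a1;
        gb2 += dlogit;
        arma::rowvec da1 = dlogit * P.W2;
        da1 %= arma::conv_to<arma::rowvec>::from(a1 > 0.0);
        gW1 += da1.t() * pooled;
        gb1 += da1;
        arma::rowvec dpool = da1 * P.W1;
        int F = (int)P.Wc.n_rows;
        arma::vec x(kw * D);
        for (int f = 0; f < F; ++f) {
          double g = dpool[f];
          if (g == 0.0 || pooled[f] <= 0.0) continue; // ReLU gate at the max
          int tpos = (int)amax[f];
          for (int j = 0; j < kw; ++j)
            x.subvec(j * D, (j + 1) * D - 1) = P.emb.row(row[tpos + j]).t();
          gWc.row(f) += g * x.t();
          gbc[f] += g;
          if (train_emb) {
            for (int j = 0; j < kw; ++j) {
              int id = row[tpos + j];
              if (id == 0) continue; // padding row stays zero
              gE.row(id) +=
                  g * P.Wc.row(f).subvec(j * D, (j + 1) * D - 1);
            }
          }
        }
      }

      ++t;
      aWc.step(P.Wc, gWc, lr, t);
      tmp = arma::conv_to<arma::mat>::from(P.bc);
      abc.step(tmp, arma::conv_to<arma::mat>::from(gbc), lr, t);
      P.bc = tmp.row(0);
      aW1.step(P.W1, gW1, lr, t);
      tmp = arma::conv_to<arma::mat>::from(P.b1);
      ab1.step(tmp, arma::conv_to<arma::mat>::from(gb1), lr, t);
      P.b1 = tmp.row(0);
      aW2.step(P.W2, gW2, lr, t);
      tmp = arma::conv_to<arma::mat>::from(P.b2);
      ab2.step(tmp, arma::conv_to<arma::mat>::from(gb2), lr, t);
      P.b2 = tmp.row(0);
      if (train_emb) {
        aE.step(P.emb, gE, lr, t);
        P.emb.row(0).zeros();
      }
    }

    if (use_val) {
      double vl = eval_loss(va);
      if (vl < best_val - 1e-6) {
        best_val = vl;
        best_epoch = ep;
        best = P;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    } else {
      best = P;
      best_epoch = ep;
    }
  }

  return List::create(
      _["emb"] = best.emb, _["Wc"] = best.Wc,
      _["bc"] = arma::conv_to<arma::mat>::from(best.bc),
      _["W1"] = best.W1,
      _["b1"] = arma::conv_to<arma::mat>::from(best.b1),
      _["W2"] = best.W2,
      _["b2"] = arma::conv_to<arma::mat>::from(best.b2),
      _["best_epoch"] = best_epoch, _["val_loss"] = best_val);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(arma::imat ids, arma::mat emb, arma::mat Wc,
                          arma::mat bc, arma::mat W1, arma::mat b1,
                          arma::mat W2, arma::mat b2, int kw,
                          bool multilabel) {
  CnnParams P;
  P.emb = emb;
  P.Wc = Wc;
  P.bc = bc.row(0);
  P.W1 = W1;
  P.b1 = b1.row(0);
  P.W2 = W2;
  P.b2 = b2.row(0);
  arma::mat out(ids.n_rows, W2.n_rows);
  for (arma::uword i = 0; i < ids.n_rows; ++i)
    out.row(i) = cnn_forward_one(ids.row(i), P, kw, multilabel);
  return out;
}
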