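// Adversarial training loops for the counterfactual-imputation and ITE blocks.
// Both generator and discriminator are two-stage feedforward nets:
//   input -> hidden -> hidden -> [concat extra inputs] -> hidden -> hidden -> out
// all activations sigmoid, output sigmoid or identity.  Adam updates, inverted
// dropout on hidden layers, exponential learning-rate decay to `decay_rate` of
// the initial rate over the first `decay_frac` of batches, flat afterwards.
// Randomness comes from R's RNG so a set.seed() in the caller fixes a run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat &x) { return 1.0 / (1.0 + exp(-x)); }
static inline mat clamp01(const mat &p, double eps) {
  return arma::clamp(p, eps, 1.0 - eps);
}
static const double EPSP = 1e-7;

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
  long step = 0;
  int h = 0;
  bool out_sigmoid = true;

  void init(int d_in, int d_extra, int d_out, int hidden) {
    h = hidden;
    int fin[5] = {d_in, hidden, hidden + d_extra, hidden, hidden};
    int fout[5] = {hidden, hidden, hidden, hidden, d_out};
    for (int l = 0; l < 5; ++l) {
      double lim = std::sqrt(6.0 / (fin[l] + fout[l]));
      mat w(fin[l], fout[l]);
      // column-major fill, matches matrix(runif(...)) in the R reference
      for (uword j = 0; j < w.n_cols; ++j)
        for (uword i = 0; i < w.n_rows; ++i)
          w(i, j) = (2.0 * unif_rand() - 1.0) * lim;
      W.push_back(w);
      b.push_back(rowvec(fout[l], fill::zeros));
      mW.push_back(mat(arma::size(w), fill::zeros));
      vW.push_back(mat(arma::size(w), fill::zeros));
      mb.push_back(rowvec(fout[l], fill::zeros));
      vb.push_back(rowvec(fout[l], fill::zeros));
    }
  }
};

struct Cache {
  mat X, E;
  mat A[4];    // post-dropout activations
  mat Araw[4]; // pre-dropout activations
  mat Msk[4];  // dropout masks (empty when not training)
  mat out;
};

static void forward(const Net &net, const mat &X, const mat &E, double drop,
                    bool train, Cache &c) {
  c.X = X;
  c.E = E;
  mat Z = X;
  for (int l = 0; l < 4; ++l) {
    if (l == 2)
      Z = join_rows(Z, E);
    mat P = Z * net.W[l];
    P.each_row() += net.b[l];
    mat A = sigm(P);
    c.Araw[l] = A;
    if (train && drop > 0) {
      mat m(arma::size(A));
      double keep = 1.0 - drop;
      for (uword k = 0; k < m.n_elem; ++k)
        m(k) = (unif_rand() < drop) ? 0.0 : 1.0 / keep;
      A %= m;
      c.Msk[l] = m;
    } else {
      c.Msk[l].reset();
    }
    c.A[l] = A;
    Z = A;
  }
  mat out = Z * net.W[4];
  out.each_row() += net.b[4];
  c.out = net.out_sigmoid ? sigm(out) : out;
}

struct Grads {
  std::vector<mat> gW;
  std::vector<rowvec> gb;
  mat dE; // gradient w.r.t. the concatenated extra inputs
};

// dOut is the gradient w.r.t. the PRE-activation of the output layer.
static void backward(const Net &net, const Cache &c, const mat &dOut,
                     Grads &g) {
  g.gW.assign(5, mat());
  g.gb.assign(5, rowvec());
  g.gW[4] = c.A[3].t() * dOut;
  g.gb[4] = sum(dOut, 0);
  mat d = dOut * net.W[4].t();
  for (int l = 3; l >= 0; --l) {
    if (c.Msk[l].n_elem)
      d %= c.Msk[l];
    d %= c.Araw[l] % (1.0 - c.Araw[l]);
    mat inp = (l == 0) ? c.X : (l == 2 ? join_rows(c.A[1], c.E) : c.A[l - 1]);
    g.gW[l] = inp.t() * d;
    g.gb[l] = sum(d, 0);
    d = d * net.W[l].t();
    if (l == 2) {
      g.dE = d.cols(net.h, d.n_cols - 1);
      d = d.cols(0, net.h - 1);
    }
  }
}

static void accumulate(Grads &a, const Grads &b) {
  for (int l = 0; l < 5; ++l) {
    a.gW[l] += b.gW[l];
    a.gb[l] += b.gb[l];
  }
}

static void adam_step(Net &net, const Grads &g, double lr, double b1,
                      double b2, double eps) {
  net.step++;
  double c1 = 1.0 - std::pow(b1, (double)net.step);
  double c2 = 1.0 - std::pow(b2, (double)net.step);
  for (int l = 0; l < 5; ++l) {
    net.mW[l] = b1 * net.mW[l] + (1.0 - b1) * g.gW[l];
    net.vW[l] = b2 * net.vW[l] + (1.0 - b2) * square(g.gW[l]);
    net.W[l] -= lr * (net.mW[l] / c1) / (sqrt(net.vW[l] / c2) + eps);
    net.mb[l] = b1 * net.mb[l] + (1.0 - b1) * g.gb[l];
    net.vb[l] = b2 * net.vb[l] + (1.0 - b2) * square(g.gb[l]);
    net.b[l] -= lr * (net.mb[l] / c1) / (sqrt(net.vb[l] / c2) + eps);
  }
}

static double lr_factor(long i, long total, double decay_rate,
                        double decay_frac) {
  double cut = decay_frac * (double)total;
  if (cut <= 0)
    return decay_rate;
  if ((double)i <= cut)
    return std::pow(decay_rate, (double)i / cut);
  return decay_rate;
}

static List net_to_list(const Net &net) {
  List W(5), b(5);
  for (int l = 0; l < 5; ++l) {
    W[l] = wrap(net.W[l]);
    b[l] = wrap(net.b[l]);
  }
  return List::create(_["W"] = W, _["b"] = b,
                      _["out_sigmoid"] = net.out_sigmoid,
                      _["hidden"] = net.h);
}

static uvec draw_batch(int n, int B, long i, bool sequential) {
  uvec idx(B);
  if (sequential) {
    for (int j = 0; j < B; ++j)
      idx(j) = (uword)(((i - 1) * (long)B + j) % n);
  } else {
    for (int j = 0; j < B; ++j)
      idx(j) = (uword)std::floor(unif_rand() * n);
  }
  return idx;
}

static mat draw_unif(int nr, int nc) {
  mat z(nr, nc);
  for (uword j = 0; j < z.n_cols; ++j)
    for (uword i = 0; i < z.n_rows; ++i)
      z(i, j) = 2.0 * unif_rand() - 1.0;
  return z;
}

// X and Tm arrive standardized by the R wrapper (covariates centred/scaled,
// dose columns scale-only so structural zeros stay zero); yf is raw (it is
// the supervised target and fills the complete data), yf_in its standardized
// copy used as a network input, and y_center/y_scale standardize the outcome
// values shown to the discriminator.
// [[Rcpp::export]]
List cpp_train_imputation(const arma::mat &X, const arma::mat &M,
                          const arma::mat &Tm, const arma::vec &yf,
                          const arma::vec &yf_in, double y_center,
                          double y_scale, int hidden, double lr_d,
                          double lr_g, double decay_rate, double decay_frac,
                          long total_batches, int batch_size, double dropout,
                          double sup_weight, bool binary_outcome,
                          bool disc_sees_tm, long trace_every, double adam_b1,
                          double adam_b2, bool sequential_batches) {
  const int n = X.n_rows, q = X.n_cols, K = M.n_cols, B = batch_size;
  Net G, D;
  G.out_sigmoid = binary_outcome;
  G.init(q, 1 + K + K + K, K, hidden); // extra: [yf | T.M | M | (1-M).z]
  D.out_sigmoid = true;
  D.init(q, disc_sees_tm ? 3 * K : K, K, hidden);

  // evaluation subset for the trace: a deterministic stride subsample
  int n_eval = std::min(n, 2000);
  uvec eidx(n_eval);
  for (int i = 0; i < n_eval; ++i)
    eidx(i) = (uword)((long)i * n / n_eval);
  mat Xe = X.rows(eidx), Me = M.rows(eidx), Te = Tm.rows(eidx);
  vec ye = yf(eidx), yie = yf_in(eidx);

  long n_trace = trace_every > 0 ? total_batches / trace_every : 0;
  mat trace(n_trace, 5); // batch, disc_acc, repl_err, sep_dist, loss_v
  long tr = 0;

  Cache cG, cD;
  Grads gG, gD;
  for (long i = 1; i <= total_batches; ++i) {
    if (i % 4096 == 0)
      Rcpp::checkUserInterrupt();
    uvec idx = draw_batch(n, B, i, sequential_batches);
    mat Xb = X.rows(idx), Mb = M.rows(idx), Tb = Tm.rows(idx);
    vec yb = yf(idx), ybi = yf_in(idx);
    mat z = draw_unif(B, K);
    mat Eg = join_rows(join_rows(mat(ybi), Tb % Mb),
                       join_rows(Mb, (1.0 - Mb) % z));
    forward(G, Xb, Eg, dropout, true, cG);
    mat Yt = cG.out;
    mat MbY = Mb;
    MbY.each_col() %= yb;
    mat Ybar = Yt % (1.0 - Mb) + MbY;
    mat Ybar_s = (Ybar - y_center) / y_scale;

    double fac = lr_factor(i, total_batches, decay_rate, decay_frac);

    // discriminator ascent step on V
    mat Ed = disc_sees_tm ? join_rows(Ybar_s, join_rows(Tb, Mb)) : Ybar_s;
    forward(D, Xb, Ed, dropout, true, cD);
    mat p = clamp01(cD.out, EPSP);
    backward(D, cD, (p - Mb) / B, gD);
    adam_step(D, gD, lr_d * fac, adam_b1, adam_b2, 1e-8);

    // generator descent step on V + supervised factual reconstruction
    forward(D, Xb, Ed, dropout, true, cD);
    mat p2 = clamp01(cD.out, EPSP);
    backward(D, cD, (Mb - p2) / B, gD);
    mat dYbar = (gD.dE.cols(0, K - 1) / y_scale) % (1.0 - Mb);
    mat dPre;
    if (binary_outcome) {
      dPre = dYbar % Yt % (1.0 - Yt) +
             sup_weight * ((clamp01(Yt, EPSP) - MbY) % Mb) / B;
    } else {
      dPre = dYbar + sup_weight * (2.0 * (Yt - MbY) % Mb) / B;
    }
    backward(G, cG, dPre, gG);
    adam_step(G, gG, lr_g * fac, adam_b1, adam_b2, 1e-8);

    if (!std::isfinite(accu(cG.out)))
      stop("non-finite generator output at batch %ld", i);

    if (trace_every > 0 && i % trace_every == 0 && tr < n_trace) {
      mat ze = draw_unif(n_eval, K);
      mat Ege = join_rows(join_rows(mat(yie), Te % Me),
                          join_rows(Me, (1.0 - Me) % ze));
      Cache ce;
      forward(G, Xe, Ege, 0, false, ce);
      mat MeY = Me;
      MeY.each_col() %= ye;
      mat Ybe = (ce.out % (1.0 - Me) + MeY - y_center) / y_scale;
      mat Ede = disc_sees_tm ? join_rows(Ybe, join_rows(Te, Me)) : Ybe;
      Cache cde;
      forward(D, Xe, Ede, 0, false, cde);
      mat pe = clamp01(cde.out, EPSP);
      double dacc = accu(conv_to<mat>::from((pe >= 0.5)) == Me) /
                    (double)(n_eval * K);
      vec yhf = sum(ce.out % Me, 1);
      double repl = binary_outcome
                        ? accu(-ye % log(arma::clamp(yhf, EPSP, 1.0)))
                              / n_eval
                        : accu(square(ye - yhf)) / n_eval;
      vec sep = sum(abs((ce.out.each_col() - ye)) % (1.0 - Me), 1) /
                sum(1.0 - Me, 1);
      double v = accu(Me % log(pe) + (1.0 - Me) % log(1.0 - pe)) / n_eval;
      trace(tr, 0) = (double)i;
      trace(tr, 1) = dacc;
      trace(tr, 2) = repl;
      trace(tr, 3) = mean(sep);
      trace(tr, 4) = v;
      tr++;
    }
  }
  mat tr_out = tr > 0 ? mat(trace.rows(0, tr - 1)) : mat(0, 5);
  return List::create(_["generator"] = net_to_list(G),
                      _["discriminator"] = net_to_list(D),
                      _["trace"] = wrap(tr_out));
}

// X and Tm standardized as in cpp_train_imputation; Ybar raw (supervised
// target), shown to the discriminator standardized by y_center/y_scale.
// [[Rcpp::export]]
List cpp_train_ite(const arma::mat &X, const arma::mat &Tm,
                   const arma::mat &Ybar, double y_center, double y_scale,
                   int hidden, double lr_d,
                   double lr_g, double decay_rate, double decay_frac,
                   long total_batches, int batch_size, double dropout,
                   double sup_weight, bool binary_outcome, long trace_every,
                   double adam_b1, double adam_b2, bool sequential_batches) {
  const int n = X.n_rows, q = X.n_cols, K = Tm.n_cols, B = batch_size;
  Net G, D;
  G.out_sigmoid = binary_outcome;
  G.init(q, 2 * K, K, hidden); // extra: [T | Z]
  D.out_sigmoid = true;
  D.init(q, 2 * K, 1, hidden); // extra: [T | Y*]

  long n_trace = trace_every > 0 ? total_batches / trace_every : 0;
  mat trace(n_trace, 4); // batch, disc_acc, sup_loss, v
  long tr = 0;

  Cache cG, cDr, cDf;
  Grads gG, gD, g2;
  for (long i = 1; i <= total_batches; ++i) {
    if (i % 4096 == 0)
      Rcpp::checkUserInterrupt();
    uvec idx = draw_batch(n, B, i, sequential_batches);
    mat Xb = X.rows(idx), Tb = Tm.rows(idx), Yb = Ybar.rows(idx);
    mat z = draw_unif(B, K);
    forward(G, Xb, join_rows(Tb, z), dropout, true, cG);
    mat Yhat = cG.out;
    mat Yhat_s = (Yhat - y_center) / y_scale;
    mat Yb_s = (Yb - y_center) / y_scale;

    double fac = lr_factor(i, total_batches, decay_rate, decay_frac);

    // discriminator: real (X,T,Ybar) up, fake (X,T,Yhat) down
    forward(D, Xb, join_rows(Tb, Yb_s), dropout, true, cDr);
    mat pr = clamp01(cDr.out, EPSP);
    backward(D, cDr, (pr - 1.0) / B, gD);
    forward(D, Xb, join_rows(Tb, Yhat_s), dropout, true, cDf);
    mat pf = clamp01(cDf.out, EPSP);
    backward(D, cDf, pf / B, g2);
    accumulate(gD, g2);
    adam_step(D, gD, lr_d * fac, adam_b1, adam_b2, 1e-8);

    // generator: minimize log(1 - D(fake)) + supervised match to Ybar
    forward(D, Xb, join_rows(Tb, Yhat_s), dropout, true, cDf);
    mat pf2 = clamp01(cDf.out, EPSP);
    backward(D, cDf, -pf2 / B, gD);
    mat dY = gD.dE.cols(K, 2 * K - 1) / y_scale;
    mat dPre;
    if (binary_outcome) {
      dPre = dY % Yhat % (1.0 - Yhat) +
             sup_weight * (clamp01(Yhat, EPSP) - Yb) / B;
    } else {
      dPre = dY + sup_weight * (2.0 * (Yhat - Yb)) / B;
    }
    backward(G, cG, dPre, gG);
    adam_step(G, gG, lr_g * fac, adam_b1, adam_b2, 1e-8);

    if (!std::isfinite(accu(cG.out)))
      stop("non-finite generator output at batch %ld", i);

    if (trace_every > 0 && i % trace_every == 0 && tr < n_trace) {
      double dacc =
          (accu(conv_to<mat>::from(pr >= 0.5)) +
           accu(conv_to<mat>::from(pf < 0.5))) /
          (2.0 * B);
      double sup = binary_outcome
                       ? accu(-Yb % log(clamp01(Yhat, EPSP)) -
                              (1.0 - Yb) % log(1.0 - clamp01(Yhat, EPSP))) /
                             B
                       : accu(square(Yhat - Yb)) / B;
      double v = accu(log(pr) + log(1.0 - pf)) / B;
      trace(tr, 0) = (double)i;
      trace(tr, 1) = dacc;
      trace(tr, 2) = sup;
      trace(tr, 3) = v;
      tr++;
    }
  }
  mat tr_out = tr > 0 ? mat(trace.rows(0, tr - 1)) : mat(0, 4);
  return List::create(_["generator"] = net_to_list(G),
                      _["discriminator"] = net_to_list(D),
                      _["trace"] = wrap(tr_out));
}
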