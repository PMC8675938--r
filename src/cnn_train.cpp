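// Full training loop of the per-channel 1D CNN: mini-batch Adam on softmax
// cross-entropy with per-epoch validation, keeping the weights of the best
// validation epoch (earliest on ties). All randomness (batch shuffling,
// dropout masks) comes from R's RNG, so training is reproducible from the
// R-side seed. The network mirrors R/cnn.R exactly: three conv blocks
// (conv -> ReLU [-> BN after ReLU in block 1] -> maxpool [-> dropout in
// blocks 2, 3]), two FC+ReLU+dropout layers, softmax output.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct AdamState {
  std::vector<mat> m, v;
  void init(const std::vector<mat*>& ps) {
    for (auto p : ps) { m.emplace_back(size(*p), fill::zeros);
                        v.emplace_back(size(*p), fill::zeros); }
  }
};

// im2col for same-padded 1D conv; layout (B*L) x C, row index b + l*B
void im2col(const mat& X2, mat& Xc, int B, int L, int k, int Cin) {
  const int pl = (k - 1) / 2;
  Xc.zeros();
  for (int d = 0; d < k; ++d) {
    const int shift = d - pl;
    const int l_lo = std::max(0, -shift);
    const int l_hi = std::min(L, L - shift);
    if (l_lo >= l_hi) continue;
    for (int c = 0; c < Cin; ++c)
      std::memcpy(Xc.colptr((size_t)d * Cin + c) + (size_t)l_lo * B,
                  X2.colptr(c) + (size_t)(l_lo + shift) * B,
                  sizeof(double) * (size_t)(l_hi - l_lo) * B);
  }
}

void col2im_add(const mat& dXc, mat& dX2, int B, int L, int k, int Cin) {
  const int pl = (k - 1) / 2;
  dX2.zeros();
  for (int d = 0; d < k; ++d) {
    const int shift = d - pl;
    const int l_lo = std::max(0, -shift);
    const int l_hi = std::min(L, L - shift);
    if (l_lo >= l_hi) continue;
    for (int c = 0; c < Cin; ++c) {
      double* dst = dX2.colptr(c) + (size_t)(l_lo + shift) * B;
      const double* src = dXc.colptr((size_t)d * Cin + c) + (size_t)l_lo * B;
      const size_t nn = (size_t)(l_hi - l_lo) * B;
      for (size_t i = 0; i < nn; ++i) dst[i] += src[i];
    }
  }
}

void maxpool(const mat& X, mat& Y, Mat<int>& idx, int B, int L, int p) {
  const int C = X.n_cols, Lo = L / p;
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    int* ic = idx.colptr(c);
    for (int lo = 0; lo < Lo; ++lo)
      for (int b = 0; b < B; ++b) {
        double best = xc[(size_t)(lo * p) * B + b];
        int bj = 0;
        for (int j = 1; j < p; ++j) {
          const double v = xc[(size_t)(lo * p + j) * B + b];
          if (v > best) { best = v; bj = j; }
        }
        yc[(size_t)lo * B + b] = best;
        ic[(size_t)lo * B + b] = bj;
      }
  }
}

void maxpool_bwd(const mat& dY, const Mat<int>& idx, mat& dX,
                 int B, int L, int p) {
  const int C = dY.n_cols, Lo = L / p;
  dX.zeros();
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.colptr(c);
    const int* ic = idx.colptr(c);
    double* dxc = dX.colptr(c);
    for (int lo = 0; lo < Lo; ++lo)
      for (int b = 0; b < B; ++b) {
        const size_t r = (size_t)lo * B + b;
        dxc[(size_t)(lo * p + ic[r]) * B + b] = dyc[r];
      }
  }
}

mat dropout_mask(size_t nr, size_t nc, double rate) {
  mat m(nr, nc);
  const double scale = 1.0 / (1.0 - rate);
  for (size_t i = 0; i < nr * nc; ++i)
    m(i) = (unif_rand() >= rate) ? scale : 0.0;
  return m;
}

struct Net {
  // parameters
  mat W1, W2, W3, Wf1, Wf2, Wo;
  vec b1, b2, b3, bf1, bf2, bo;
  vec gamma, beta, run_mean, run_var;
  int k, p, L0, L1, L2, L3, F1, F2, F3, U1, U2;
  double conv_drop, fc_drop;
  static const constexpr double bn_eps = 1e-5, bn_mom = 0.9;

  std::vector<mat*> param_ptrs() {
    return {&W1, &W2, &W3, &Wf1, &Wf2, &Wo};
  }
  std::vector<vec*> vec_ptrs() {
    return {&b1, &b2, &b3, &bf1, &bf2, &bo, &gamma, &beta};
  }

  // evaluation-mode forward: returns CAD-class probabilities
  vec forward_eval(const mat& X) const {
    const int B = X.n_rows;
    mat A(const_cast<double*>(X.memptr()), (size_t)B * L0, 1, false, true);
    mat Xc1((size_t)B * L0, (size_t)k, fill::none);
    im2col(A, Xc1, B, L0, k, 1);
    mat h = Xc1 * W1; h.each_row() += b1.t();
    h.transform([](double v){ return v > 0 ? v : 0; });
    for (int c = 0; c < F1; ++c) {
      const double sc = gamma(c) / std::sqrt(run_var(c) + bn_eps);
      const double sh = beta(c) - run_mean(c) * sc;
      h.col(c) = h.col(c) * sc + sh;
    }
    mat p1((size_t)B * L1, F1); Mat<int> i1((size_t)B * L1, F1);
    maxpool(h, p1, i1, B, L0, p);
    mat Xc2((size_t)B * L1, (size_t)k * F1, fill::none);
    im2col(p1, Xc2, B, L1, k, F1);
    mat h2 = Xc2 * W2; h2.each_row() += b2.t();
    h2.transform([](double v){ return v > 0 ? v : 0; });
    mat p2((size_t)B * L2, F2); Mat<int> i2((size_t)B * L2, F2);
    maxpool(h2, p2, i2, B, L1, p);
    mat Xc3((size_t)B * L2, (size_t)k * F2, fill::none);
    im2col(p2, Xc3, B, L2, k, F2);
    mat h3 = Xc3 * W3; h3.each_row() += b3.t();
    h3.transform([](double v){ return v > 0 ? v : 0; });
    mat p3((size_t)B * L3, F3); Mat<int> i3((size_t)B * L3, F3);
    maxpool(h3, p3, i3, B, L2, p);
    mat flat(p3.memptr(), B, (size_t)L3 * F3, false, true);
    mat z1 = flat * Wf1; z1.each_row() += bf1.t();
    z1.transform([](double v){ return v > 0 ? v : 0; });
    mat z2 = z1 * Wf2; z2.each_row() += bf2.t();
    z2.transform([](double v){ return v > 0 ? v : 0; });
    mat lg = z2 * Wo; lg.each_row() += bo.t();
    vec out(B);
    for (int i = 0; i < B; ++i) {
      const double mx = std::max(lg(i, 0), lg(i, 1));
      const double e0 = std::exp(lg(i, 0) - mx), e1 = std::exp(lg(i, 1) - mx);
      out(i) = e1 / (e0 + e1);
    }
    return out;
  }
};

}  // namespace

// params: named list of weight matrices / bias vectors (R init_params
// layout: conv W is (k*Cin) x F; fc W is in x out).
// Returns best-epoch params and the training history.
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List params_in, const arma::mat& Xtr,
                         const arma::ivec& ytr, const arma::mat& Xva,
                         const arma::ivec& yva, int k, int pool,
                         double conv_drop, double fc_drop, double lr,
                         int batch, int epochs) {
  Net net;
  {
    Rcpp::List c1 = params_in["conv1"], bn = params_in["bn1"],
               c2 = params_in["conv2"], c3 = params_in["conv3"],
               f1 = params_in["fc1"], f2 = params_in["fc2"],
               oo = params_in["out"];
    net.W1 = Rcpp::as<mat>(c1["W"]);  net.b1 = Rcpp::as<vec>(c1["b"]);
    net.W2 = Rcpp::as<mat>(c2["W"]);  net.b2 = Rcpp::as<vec>(c2["b"]);
    net.W3 = Rcpp::as<mat>(c3["W"]);  net.b3 = Rcpp::as<vec>(c3["b"]);
    net.Wf1 = Rcpp::as<mat>(f1["W"]); net.bf1 = Rcpp::as<vec>(f1["b"]);
    net.Wf2 = Rcpp::as<mat>(f2["W"]); net.bf2 = Rcpp::as<vec>(f2["b"]);
    net.Wo = Rcpp::as<mat>(oo["W"]);  net.bo = Rcpp::as<vec>(oo["b"]);
    net.gamma = Rcpp::as<vec>(bn["gamma"]); net.beta = Rcpp::as<vec>(bn["beta"]);
    net.run_mean = Rcpp::as<vec>(bn["run_mean"]);
    net.run_var = Rcpp::as<vec>(bn["run_var"]);
  }
  net.k = k; net.p = pool;
  net.L0 = Xtr.n_cols; net.L1 = net.L0 / pool; net.L2 = net.L1 / pool;
  net.L3 = net.L2 / pool;
  net.F1 = net.W1.n_cols; net.F2 = net.W2.n_cols; net.F3 = net.W3.n_cols;
  net.conv_drop = conv_drop; net.fc_drop = fc_drop;

  const int n = Xtr.n_rows;
  // Adam state over all parameters (matrices and vectors uniformly)
  std::vector<mat> theta_m, theta_v;
  auto mats = net.param_ptrs();
  auto vecs = net.vec_ptrs();
  std::vector<mat> vm, vv;
  for (auto pm : mats) { vm.emplace_back(size(*pm), fill::zeros);
                         vv.emplace_back(size(*pm), fill::zeros); }
  std::vector<vec> bm, bv;
  for (auto pv : vecs) { bm.emplace_back(size(*pv), fill::zeros);
                         bv.emplace_back(size(*pv), fill::zeros); }
  const double be1 = 0.9, be2 = 0.999, aeps = 1e-8;
  long tstep = 0;

  Rcpp::NumericVector train_loss(epochs), val_acc(epochs);
  double best_acc = -1.0; int best_epoch = 0;
  Net best = net;

  Rcpp::RNGScope rng;  // use R's RNG for shuffling and dropout

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with R RNG (equivalent determinism to R-side sampling)
    ivec ord = regspace<ivec>(0, n - 1);
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord(i), ord(j));
    }
    double loss_sum = 0; int loss_cnt = 0;
    for (int start = 0; start < n; start += batch) {
      const int B = std::min(batch, n - start);
      if (B < 2) continue;  // batch norm needs > 1 sample
      mat X(B, net.L0);
      ivec y(B);
      for (int i = 0; i < B; ++i) {
        X.row(i) = Xtr.row(ord(start + i));
        y(i) = ytr(ord(start + i));
      }
      // ---- forward (training mode, caches kept) ----
      mat A(X.memptr(), (size_t)B * net.L0, 1, false, true);
      mat Xc1((size_t)B * net.L0, (size_t)k, fill::none);
      im2col(A, Xc1, B, net.L0, k, 1);
      mat z1c = Xc1 * net.W1; z1c.each_row() += net.b1.t();
      mat r1 = z1c; r1.transform([](double v){ return v > 0 ? v : 0; });
      // batch norm (training statistics)
      rowvec mu = mean(r1, 0);
      mat xc = r1; xc.each_row() -= mu;
      rowvec var_ = mean(square(xc), 0);
      rowvec istd = 1.0 / sqrt(var_ + Net::bn_eps);
      mat xhat = xc; xhat.each_row() %= istd;
      mat bn = xhat; bn.each_row() %= net.gamma.t(); bn.each_row() += net.beta.t();
      net.run_mean = Net::bn_mom * net.run_mean + (1 - Net::bn_mom) * mu.t();
      net.run_var = Net::bn_mom * net.run_var + (1 - Net::bn_mom) * var_.t();
      mat p1((size_t)B * net.L1, net.F1); Mat<int> i1((size_t)B * net.L1, net.F1);
      maxpool(bn, p1, i1, B, net.L0, pool);

      mat Xc2((size_t)B * net.L1, (size_t)k * net.F1, fill::none);
      im2col(p1, Xc2, B, net.L1, k, net.F1);
      mat z2c = Xc2 * net.W2; z2c.each_row() += net.b2.t();
      mat r2 = z2c; r2.transform([](double v){ return v > 0 ? v : 0; });
      mat p2((size_t)B * net.L2, net.F2); Mat<int> i2((size_t)B * net.L2, net.F2);
      maxpool(r2, p2, i2, B, net.L1, pool);
      mat m2, a2;
      if (conv_drop > 0) { m2 = dropout_mask(p2.n_rows, p2.n_cols, conv_drop);
                           a2 = p2 % m2; } else a2 = p2;

      mat Xc3((size_t)B * net.L2, (size_t)k * net.F2, fill::none);
      im2col(a2, Xc3, B, net.L2, k, net.F2);
      mat z3c = Xc3 * net.W3; z3c.each_row() += net.b3.t();
      mat r3 = z3c; r3.transform([](double v){ return v > 0 ? v : 0; });
      mat p3((size_t)B * net.L3, net.F3); Mat<int> i3((size_t)B * net.L3, net.F3);
      maxpool(r3, p3, i3, B, net.L2, pool);
      mat m3, a3;
      if (conv_drop > 0) { m3 = dropout_mask(p3.n_rows, p3.n_cols, conv_drop);
                           a3 = p3 % m3; } else a3 = p3;

      mat flat(a3.memptr(), B, (size_t)net.L3 * net.F3, false, true);
      mat zf1 = flat * net.Wf1; zf1.each_row() += net.bf1.t();
      mat h1 = zf1; h1.transform([](double v){ return v > 0 ? v : 0; });
      mat mf1, d1;
      if (fc_drop > 0) { mf1 = dropout_mask(h1.n_rows, h1.n_cols, fc_drop);
                         d1 = h1 % mf1; } else d1 = h1;
      mat zf2 = d1 * net.Wf2; zf2.each_row() += net.bf2.t();
      mat h2 = zf2; h2.transform([](double v){ return v > 0 ? v : 0; });
      mat mf2, d2;
      if (fc_drop > 0) { mf2 = dropout_mask(h2.n_rows, h2.n_cols, fc_drop);
                         d2 = h2 % mf2; } else d2 = h2;
      mat lg = d2 * net.Wo; lg.each_row() += net.bo.t();
      mat probs(B, 2);
      double bloss = 0;
      for (int i = 0; i < B; ++i) {
        const double mx = std::max(lg(i, 0), lg(i, 1));
        const double e0 = std::exp(lg(i, 0) - mx), e1 = std::exp(lg(i, 1) - mx);
        probs(i, 0) = e0 / (e0 + e1); probs(i, 1) = e1 / (e0 + e1);
        bloss -= std::log(std::max(probs(i, y(i)), 1e-12));
      }
      loss_sum += bloss / B; ++loss_cnt;

      // ---- backward ----
      mat dlg = probs;
      for (int i = 0; i < B; ++i) dlg(i, y(i)) -= 1.0;
      dlg /= B;
      mat gWo = d2.t() * dlg;
      vec gbo = sum(dlg, 0).t();
      mat dd2 = dlg * net.Wo.t();
      if (fc_drop > 0) dd2 %= mf2;
      dd2 %= conv_to<mat>::from(zf2 > 0);
      mat gWf2 = d1.t() * dd2;
      vec gbf2 = sum(dd2, 0).t();
      mat dd1 = dd2 * net.Wf2.t();
      if (fc_drop > 0) dd1 %= mf1;
      dd1 %= conv_to<mat>::from(zf1 > 0);
      mat gWf1 = flat.t() * dd1;
      vec gbf1 = sum(dd1, 0).t();
      mat dflat = dd1 * net.Wf1.t();

      mat da3(dflat.memptr(), (size_t)B * net.L3, net.F3, false, true);
      mat da3c = da3;  // may be modified by dropout
      if (conv_drop > 0) da3c %= m3;
      mat dr3((size_t)B * net.L2, net.F3);
      maxpool_bwd(da3c, i3, dr3, B, net.L2, pool);
      dr3 %= conv_to<mat>::from(z3c > 0);
      mat gW3 = Xc3.t() * dr3;
      vec gb3 = sum(dr3, 0).t();
      mat dXc3 = dr3 * net.W3.t();
      mat da2((size_t)B * net.L2, net.F2);
      col2im_add(dXc3, da2, B, net.L2, k, net.F2);
      if (conv_drop > 0) da2 %= m2;
      mat dr2((size_t)B * net.L1, net.F2);
      maxpool_bwd(da2, i2, dr2, B, net.L1, pool);
      dr2 %= conv_to<mat>::from(z2c > 0);
      mat gW2 = Xc2.t() * dr2;
      vec gb2 = sum(dr2, 0).t();
      mat dXc2 = dr2 * net.W2.t();
      mat dp1((size_t)B * net.L1, net.F1);
      col2im_add(dXc2, dp1, B, net.L1, k, net.F1);
      mat dbn((size_t)B * net.L0, net.F1);
      maxpool_bwd(dp1, i1, dbn, B, net.L0, pool);
      // batch-norm backward
      vec ggamma = sum(dbn % xhat, 0).t();
      vec gbeta = sum(dbn, 0).t();
      mat dxhat = dbn; dxhat.each_row() %= net.gamma.t();
      rowvec mdx = mean(dxhat, 0);
      rowvec mdxx = mean(dxhat % xhat, 0);
      mat dr1 = dxhat; dr1.each_row() -= mdx;
      dr1 -= xhat.each_row() % mdxx;
      dr1.each_row() %= istd;
      dr1 %= conv_to<mat>::from(z1c > 0);
      mat gW1 = Xc1.t() * dr1;
      vec gb1 = sum(dr1, 0).t();

      // ---- Adam update ----
      ++tstep;
      const double c1b = 1 - std::pow(be1, (double)tstep);
      const double c2b = 1 - std::pow(be2, (double)tstep);
      mat* gm[6] = {&gW1, &gW2, &gW3, &gWf1, &gWf2, &gWo};
      for (int i = 0; i < 6; ++i) {
        vm[i] = be1 * vm[i] + (1 - be1) * (*gm[i]);
        vv[i] = be2 * vv[i] + (1 - be2) * square(*gm[i]);
        *mats[i] -= lr * (vm[i] / c1b) / (sqrt(vv[i] / c2b) + aeps);
      }
      vec* gv[8] = {&gb1, &gb2, &gb3, &gbf1, &gbf2, &gbo, &ggamma, &gbeta};
      for (int i = 0; i < 8; ++i) {
        bm[i] = be1 * bm[i] + (1 - be1) * (*gv[i]);
        bv[i] = be2 * bv[i] + (1 - be2) * square(*gv[i]);
        *vecs[i] -= lr * (bm[i] / c1b) / (sqrt(bv[i] / c2b) + aeps);
      }
    }
    train_loss[ep] = loss_cnt ? loss_sum / loss_cnt : NA_REAL;
    vec pv = net.forward_eval(Xva);
    int correct = 0;
    for (size_t i = 0; i < pv.n_elem; ++i)
      if ((pv(i) > 0.5) == (yva(i) == 1)) ++correct;
    val_acc[ep] = (double)correct / pv.n_elem;
    if (val_acc[ep] > best_acc) {
      best_acc = val_acc[ep];
      best_epoch = ep + 1;
      best = net;
    }
  }

  auto wrap_params = [](const Net& nn) {
    return Rcpp::List::create(
      Rcpp::Named("conv1") = Rcpp::List::create(Rcpp::Named("W") = nn.W1,
                                                Rcpp::Named("b") = nn.b1),
      Rcpp::Named("bn1") = Rcpp::List::create(
        Rcpp::Named("gamma") = nn.gamma, Rcpp::Named("beta") = nn.beta,
        Rcpp::Named("run_mean") = nn.run_mean,
        Rcpp::Named("run_var") = nn.run_var),
      Rcpp::Named("conv2") = Rcpp::List::create(Rcpp::Named("W") = nn.W2,
                                                Rcpp::Named("b") = nn.b2),
      Rcpp::Named("conv3") = Rcpp::List::create(Rcpp::Named("W") = nn.W3,
                                                Rcpp::Named("b") = nn.b3),
      Rcpp::Named("fc1") = Rcpp::List::create(Rcpp::Named("W") = nn.Wf1,
                                              Rcpp::Named("b") = nn.bf1),
      Rcpp::Named("fc2") = Rcpp::List::create(Rcpp::Named("W") = nn.Wf2,
                                              Rcpp::Named("b") = nn.bf2),
      Rcpp::Named("out") = Rcpp::List::create(Rcpp::Named("W") = nn.Wo,
                                              Rcpp::Named("b") = nn.bo));
  };
  return Rcpp::List::create(
    Rcpp::Named("params") = wrap_params(best),
    Rcpp::Named("train_loss") = train_loss,
    Rcpp::Named("val_acc") = val_acc,
    Rcpp::Named("selected_epoch") = best_epoch);
}
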