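// Joint trainer for the regression-guided neural network.
//
// Model:  yhat = c0 + Xl * beta + cn * xf + cint * f(Xp) * xf
// where f is a fully-connected MLP with rectifier hidden units and a
// linear scalar output.  Regression parameters and network parameters
// are updated with distinct learning rates from a (weighted) MSE loss,
// mini-batch stochastic gradient descent (optionally Adam).
//
// All randomness (batch shuffling, dropout masks) draws from R's RNG so
// results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat list_to_mat(SEXP x) { return as<arma::mat>(x); }

// Forward pass without dropout; X is n x d (rows = observations).
static arma::vec mlp_forward_impl(const std::vector<arma::mat>& W,
                                  const std::vector<arma::vec>& b,
                                  const arma::mat& X) {
  arma::mat A = X;
  const size_t L = W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    A = A * W[l].t();
    A.each_row() += b[l].t();
    A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  arma::mat out = A * W[L - 1].t();
  out.each_row() += b[L - 1].t();
  return out.col(0);
}

static void unpack_params(const List& Wl, const List& bl,
                          std::vector<arma::mat>& W, std::vector<arma::vec>& b) {
  const int L = Wl.size();
  W.resize(L); b.resize(L);
  for (int l = 0; l < L; ++l) {
    W[l] = list_to_mat(Wl[l]);
    b[l] = as<arma::vec>(bl[l]);
  }
}

// [[Rcpp::export(name = ".mlp_forward_cpp")]]
arma::vec mlp_forward_cpp(List W, List b, arma::mat X) {
  std::vector<arma::mat> Wv; std::vector<arma::vec> bv;
  unpack_params(W, b, Wv, bv);
  if (X.n_cols != Wv[0].n_cols)
    stop("input width (%d) does not match network input size (%d)",
         (int)X.n_cols, (int)Wv[0].n_cols);
  return mlp_forward_impl(Wv, bv, X);
}

// Shuffled 0-based index order using R's RNG.
static arma::uvec r_shuffle(const arma::uword n) {
  NumericVector keys = runif(n);
  return arma::sort_index(as<arma::vec>(keys));
}

// [[Rcpp::export(name = ".regnn_train_cpp")]]
List regnn_train_cpp(const arma::mat& Xl, const arma::vec& xf,
                     const arma::mat& Xp, const arma::vec& y,
                     const arma::vec& w,
                     List W0, List b0, const arma::vec& reg0,
                     double dropout, double lr_reg, double lr_net,
                     double weight_decay, int epochs, int batch_size,
                     std::string optimizer, double momentum,
                     const arma::mat& Xp_full, const arma::vec& trace_target) {
  std::vector<arma::mat> W; std::vector<arma::vec> b;
  unpack_params(W0, b0, W, b);
  const int L = (int)W.size();          // number of weight layers
  const arma::uword n = y.n_elem;
  const arma::uword m = Xl.n_cols;
  if (Xp.n_cols != W[0].n_cols) stop("moderator-input width does not match network input size");
  if ((arma::uword)batch_size > n) stop("batch_size exceeds the number of training rows");

  // regression parameters: c0, beta (m), cn, cint
  double c0 = reg0(0);
  arma::vec beta = (m > 0) ? reg0.subvec(1, m) : arma::vec();
  double cn = reg0(m + 1);
  double cint = reg0(m + 2);

  const bool adam = (optimizer == "adam");
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  // Adam / momentum state
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  arma::vec mreg(m + 3, arma::fill::zeros), vreg(m + 3, arma::fill::zeros);
  if (adam || momentum > 0.0) {
    for (int l = 0; l < L; ++l) {
      mW[l].zeros(W[l].n_rows, W[l].n_cols); vW[l].zeros(W[l].n_rows, W[l].n_cols);
      mb[l].zeros(b[l].n_elem); vb[l].zeros(b[l].n_elem);
    }
  }
  long step = 0;

  const bool trace_rho = trace_target.n_elem > 0;
  arma::vec ep_loss(epochs), ep_l2(epochs);
  arma::vec ep_rho(trace_rho ? epochs : 0);

  const double keep = 1.0 - dropout;

  std::vector<arma::mat> A(L), Dmask(L - 1), Zpre(L - 1);

  for (int ep = 0; ep < epochs; ++ep) {
    arma::uvec order = r_shuffle(n);
    double loss_sum = 0.0; long nb = 0;
    for (arma::uword start = 0; start + batch_size <= n; start += batch_size) {
      arma::uvec idx = order.subvec(start, start + batch_size - 1);
      const arma::mat Xlb = Xl.rows(idx);
      const arma::vec xfb = xf.elem(idx);
      const arma::mat Xpb = Xp.rows(idx);
      const arma::vec yb = y.elem(idx);
      const arma::vec wb = w.elem(idx);
      const double wsum = arma::accu(wb);

      // ---- forward with inverted dropout on hidden activations
      A[0] = Xpb;
      for (int l = 0; l < L - 1; ++l) {
        arma::mat Z = A[l] * W[l].t();
        Z.each_row() += b[l].t();
        Zpre[l] = Z;
        Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
        if (dropout > 0.0) {
          NumericVector u = runif(Z.n_elem);
          arma::mat mask(Z.n_rows, Z.n_cols);
          std::copy(u.begin(), u.end(), mask.memptr());
          mask.transform([keep](double v) { return v < keep ? 1.0 / keep : 0.0; });
          Dmask[l] = mask;
          Z %= mask;
        } else {
          Dmask[l].ones(Z.n_rows, Z.n_cols);
        }
        A[l + 1] = Z;
      }
      arma::vec zb = A[L - 1] * W[L - 1].t() + arma::as_scalar(b[L - 1](0)) * arma::ones(batch_size);

      arma::vec yhat = c0 + cn * xfb + cint * (zb % xfb);
      if (m > 0) yhat += Xlb * beta;
      arma::vec resid = yb - yhat;
      double loss = arma::accu(wb % arma::square(resid)) / wsum;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      loss_sum += loss; ++nb;

      // ---- gradients
      arma::vec g = (-2.0 / wsum) * (wb % resid);     // dLoss/dyhat
      double g_c0 = arma::accu(g);
      arma::vec g_beta = (m > 0) ? arma::vec(Xlb.t() * g) : arma::vec();
      double g_cn = arma::dot(xfb, g);
      double g_cint = arma::dot(zb % xfb, g);

      // backprop through the network
      arma::mat delta = (cint * (xfb % g));           // b x 1 at output
      std::vector<arma::mat> gW(L); std::vector<arma::vec> gb(L);
      gW[L - 1] = delta.t() * A[L - 1];
      gb[L - 1] = arma::vec{arma::accu(delta)};
      arma::mat dA = delta * W[L - 1];
      for (int l = L - 2; l >= 0; --l) {
        arma::mat dZ = dA % Dmask[l];
        dZ %= arma::conv_to<arma::mat>::from(Zpre[l] > 0.0);
        gW[l] = dZ.t() * A[l];
        gb[l] = arma::sum(dZ, 0).t();
        if (l > 0) dA = dZ * W[l];
      }

      // ---- updates
      ++step;
      if (adam) {
        auto upd = [&](arma::mat& P, arma::mat& mP, arma::mat& vP,
                       const arma::mat& gP, double lr) {
          mP = b1 * mP + (1 - b1) * gP;
          vP = b2 * vP + (1 - b2) * arma::square(gP);
          arma::mat mh = mP / (1 - std::pow(b1, (double)step));
          arma::mat vh = vP / (1 - std::pow(b2, (double)step));
          P -= lr * mh / (arma::sqrt(vh) + eps);
        };
        for (int l = 0; l < L; ++l) {
          arma::mat gWl = gW[l] + weight_decay * W[l];
          upd(W[l], mW[l], vW[l], gWl, lr_net);
          arma::mat bm(b[l].memptr(), b[l].n_elem, 1, false);
          arma::mat mbm(mb[l].memptr(), mb[l].n_elem, 1, false);
          arma::mat vbm(vb[l].memptr(), vb[l].n_elem, 1, false);
          upd(bm, mbm, vbm, arma::mat(gb[l]), lr_net);
        }
        arma::vec greg(m + 3);
        greg(0) = g_c0;
        if (m > 0) greg.subvec(1, m) = g_beta;
        greg(m + 1) = g_cn; greg(m + 2) = g_cint;
        mreg = b1 * mreg + (1 - b1) * greg;
        vreg = b2 * vreg + (1 - b2) * arma::square(greg);
        arma::vec mh = mreg / (1 - std::pow(b1, (double)step));
        arma::vec vh = vreg / (1 - std::pow(b2, (double)step));
        arma::vec updv = lr_reg * mh / (arma::sqrt(vh) + eps);
        c0 -= updv(0);
        if (m > 0) beta -= updv.subvec(1, m);
        cn -= updv(m + 1); cint -= updv(m + 2);
      } else if (momentum > 0.0) {
        // classical momentum: v <- mu v + g; p <- p - lr v
        for (int l = 0; l < L; ++l) {
          mW[l] = momentum * mW[l] + (gW[l] + weight_decay * W[l]);
          W[l] -= lr_net * mW[l];
          mb[l] = momentum * mb[l] + gb[l];
          b[l] -= lr_net * mb[l];
        }
        arma::vec greg(m + 3);
        greg(0) = g_c0;
        if (m > 0) greg.subvec(1, m) = g_beta;
        greg(m + 1) = g_cn; greg(m + 2) = g_cint;
        mreg = momentum * mreg + greg;
        c0 -= lr_reg * mreg(0);
        if (m > 0) beta -= lr_reg * mreg.subvec(1, m);
        cn -= lr_reg * mreg(m + 1);
        cint -= lr_reg * mreg(m + 2);
      } else {
        for (int l = 0; l < L; ++l) {
          W[l] -= lr_net * (gW[l] + weight_decay * W[l]);
          b[l] -= lr_net * gb[l];
        }
        c0 -= lr_reg * g_c0;
        if (m > 0) beta -= lr_reg * g_beta;
        cn -= lr_reg * g_cn;
        cint -= lr_reg * g_cint;
      }
    }
    ep_loss(ep) = nb > 0 ? loss_sum / nb : NA_REAL;
    double l2 = c0 * c0 + cn * cn + cint * cint;
    if (m > 0) l2 += arma::dot(beta, beta);
    ep_l2(ep) = std::sqrt(l2);
    if (trace_rho) {
      arma::vec zfull = mlp_forward_impl(W, b, Xp_full);
      ep_rho(ep) = arma::as_scalar(arma::cor(zfull, trace_target));
    }
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  arma::vec reg(m + 3);
  reg(0) = c0;
  if (m > 0) reg.subvec(1, m) = beta;
  reg(m + 1) = cn; reg(m + 2) = cint;
  return List::create(_["W"] = Wout, _["b"] = bout, _["reg"] = reg,
                      _["loss"] = ep_loss, _["reg_l2"] = ep_l2,
                      _["rho"] = ep_rho);
}
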