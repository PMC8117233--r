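// Two-stream recurrent network: three stacked bidirectional GRU layers over
// the (p_x, p_y, s_x, s_y) sequence, a dense tanh transform of the two
// categorical flags (contrast, pursuit), a per-step point-wise softmax head
// (obstructed vs. unobstructed) and a temporally mean-pooled 4-class
// shape head.  Forward pass and analytic backpropagation are implemented
// here; the (RMSprop) update loop lives in R.  Gradients are verified
// against finite differences in the test suite.
//
// Sequences are held as (B*T) x width matrices with the rows of step t in
// block [t*B, (t+1)*B): input projections, weight gradients and both heads
// then reduce to single large GEMMs, leaving only the O(T) recurrent
// hidden-state updates as small per-step products.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruCache {
  mat Hprev, Z, R, N;   // (B*T) x H, indexed by time block
};

// GRU (Cho et al. formulation), gate column blocks ordered [z | r | n]:
//   z = sigmoid(x Wz + h Uz + bz)
//   r = sigmoid(x Wr + h Ur + br)
//   n = tanh  (x Wn + (r .* h) Un + bn)
//   h' = (1 - z) .* h + z .* n
static void gru_fwd(const mat& Xstack, const mat& W, const mat& U,
                    const rowvec& b, bool rev, unsigned int B,
                    unsigned int T, GruCache& cc, mat& Ystack,
                    unsigned int off) {
  unsigned int Hh = U.n_rows;
  mat Uzr = U.cols(0, 2 * Hh - 1);
  mat Un = U.cols(2 * Hh, 3 * Hh - 1);
  mat Aall = Xstack * W;
  Aall.each_row() += b;
  cc.Hprev.set_size(B * T, Hh); cc.Z.set_size(B * T, Hh);
  cc.R.set_size(B * T, Hh);     cc.N.set_size(B * T, Hh);
  mat h(B, Hh, fill::zeros);
  for (unsigned int s = 0; s < T; ++s) {
    unsigned int t = rev ? (T - 1 - s) : s;
    unsigned int r0 = t * B, r1 = (t + 1) * B - 1;
    mat G = h * Uzr;                       // B x 2H
    mat z = sigm(Aall.submat(r0, 0, r1, Hh - 1) + G.cols(0, Hh - 1));
    mat r = sigm(Aall.submat(r0, Hh, r1, 2 * Hh - 1) +
                 G.cols(Hh, 2 * Hh - 1));
    mat n = tanh(Aall.submat(r0, 2 * Hh, r1, 3 * Hh - 1) + (r % h) * Un);
    cc.Hprev.rows(r0, r1) = h;
    cc.Z.rows(r0, r1) = z;
    cc.R.rows(r0, r1) = r;
    cc.N.rows(r0, r1) = n;
    h = (1.0 - z) % h + z % n;
    Ystack.submat(r0, off, r1, off + Hh - 1) = h;
  }
}

static void gru_bwd(const mat& Xstack, const mat& W, const mat& U, bool rev,
                    unsigned int B, unsigned int T, const GruCache& cc,
                    const mat& dY, unsigned int off,
                    mat& dW, mat& dU, rowvec& db, mat& dXstack,
                    bool want_dx) {
  unsigned int Hh = U.n_rows;
  mat Uzr = U.cols(0, 2 * Hh - 1);
  mat Un = U.cols(2 * Hh, 3 * Hh - 1);
  mat dAall(B * T, 3 * Hh);
  mat dh(B, Hh, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    unsigned int t = rev ? (T - 1 - s) : (unsigned int)s;
    unsigned int r0 = t * B, r1 = (t + 1) * B - 1;
    dh += dY.submat(r0, off, r1, off + Hh - 1);
    mat h = cc.Hprev.rows(r0, r1);
    mat z = cc.Z.rows(r0, r1);
    mat r = cc.R.rows(r0, r1);
    mat n = cc.N.rows(r0, r1);
    mat dAn = (dh % z) % (1.0 - n % n);
    mat dAz = (dh % (n - h)) % (z % (1.0 - z));
    mat tmp = dAn * Un.t();
    mat dAr = (tmp % h) % (r % (1.0 - r));
    mat dAzr = join_rows(dAz, dAr);
    dh = dh % (1.0 - z) + dAzr * Uzr.t() + tmp % r;
    dAall.submat(r0, 0, r1, Hh - 1) = dAz;
    dAall.submat(r0, Hh, r1, 2 * Hh - 1) = dAr;
    dAall.submat(r0, 2 * Hh, r1, 3 * Hh - 1) = dAn;
  }
  dW += Xstack.t() * dAall;
  db += sum(dAall, 0);
  dU.cols(0, Hh - 1)          += cc.Hprev.t() * dAall.cols(0, Hh - 1);
  dU.cols(Hh, 2 * Hh - 1)     += cc.Hprev.t() * dAall.cols(Hh, 2 * Hh - 1);
  dU.cols(2 * Hh, 3 * Hh - 1) +=
      (cc.R % cc.Hprev).t() * dAall.cols(2 * Hh, 3 * Hh - 1);
  if (want_dx) dXstack += dAall * W.t();
}

static mat softmax_rows(mat L) {
  L.each_col() -= max(L, 1);
  L = exp(L);
  L.each_col() /= sum(L, 1);
  return L;
}

static const double EPS_LOG = 1e-12;

// Full forward (and optionally backward) pass on one batch.
//   X:   B x D x T cube (already scaled), D = 4
//   cat: B x 2 matrix of binary flags
//   ys:  B x T point-wise labels in {0, 1}
//   yd:  length-B shape labels in {0, 1, 2, 3}
// Returns loss (J = alpha * pointwise CE + beta * shape CE), both partial
// losses, predicted distributions, and (if want_grad) gradients for every
// parameter under the same names.
// [[Rcpp::export]]
List rnn_pass_cpp(List params, arma::cube X, arma::mat cat,
                  arma::mat ys, arma::vec yd,
                  double alpha, double beta, bool want_grad) {
  unsigned int B = X.n_rows, T = X.n_slices, D = X.n_cols;
  const int L = 3;
  mat Wc = as<mat>(params["Wc"]);
  rowvec bc = as<rowvec>(params["bc"]);
  mat Wp = as<mat>(params["Wp"]);
  rowvec bp = as<rowvec>(params["bp"]);
  mat Wd = as<mat>(params["Wd"]);
  rowvec bd = as<rowvec>(params["bd"]);
  unsigned int Cc = Wc.n_cols;
  unsigned int H2 = Wp.n_rows - Cc;       // 2 * hidden
  unsigned int Hh = H2 / 2;

  // stack the input cube: row block t holds X[, , t]
  mat X0(B * T, D);
  for (unsigned int t = 0; t < T; ++t) X0.rows(t * B, (t + 1) * B - 1) =
      X.slice(t);

  std::vector<mat> Xs(L + 1);
  Xs[0] = std::move(X0);
  std::vector<GruCache> cc(2 * L);
  std::vector<mat> Wl(2 * L), Ul(2 * L);
  std::vector<rowvec> bl(2 * L);
  const char* dn[2] = {"f", "b"};
  for (int l = 0; l < L; ++l) {
    mat Y(B * T, 2 * Hh);
    for (int d = 0; d < 2; ++d) {
      int k = 2 * l + d;
      std::string suf = std::to_string(l + 1) + dn[d];
      Wl[k] = as<mat>(params[std::string("W") + suf]);
      Ul[k] = as<mat>(params[std::string("U") + suf]);
      bl[k] = as<rowvec>(params[std::string("b") + suf]);
      gru_fwd(Xs[l], Wl[k], Ul[k], bl[k], d == 1, B, T, cc[k], Y, d * Hh);
    }
    Xs[l + 1] = std::move(Y);
  }
  const mat& Y3 = Xs[L];

  // categorical stream
  mat Clin = cat * Wc;
  Clin.each_row() += bc;
  mat C = tanh(Clin);

  // shape head on mean-pooled sequential features + categorical features
  mat pooled(B, H2, fill::zeros);
  for (unsigned int t = 0; t < T; ++t) pooled += Y3.rows(t * B,
                                                         (t + 1) * B - 1);
  pooled /= (double)T;
  mat featd = join_rows(pooled, C);
  mat Ldl = featd * Wd;
  Ldl.each_row() += bd;
  mat Pd = softmax_rows(Ldl);

  double loss_d = 0.0;
  for (unsigned int b = 0; b < B; ++b) {
    double p = Pd(b, (unsigned int)yd(b));
    loss_d -= std::log(std::max(p, EPS_LOG));
  }
  loss_d /= (double)B;

  // point-wise head over all steps at once
  mat Lp = Y3 * Wp.rows(0, H2 - 1);
  mat CWp = C * Wp.rows(H2, H2 + Cc - 1);  // B x 2, same for every step
  for (unsigned int t = 0; t < T; ++t) Lp.rows(t * B, (t + 1) * B - 1) += CWp;
  Lp.each_row() += bp;
  mat Ps = softmax_rows(Lp);               // (B*T) x 2
  double loss_s = 0.0;
  for (unsigned int t = 0; t < T; ++t) {
    for (unsigned int b = 0; b < B; ++b) {
      double p = Ps(t * B + b, (unsigned int)ys(b, t));
      loss_s -= std::log(std::max(p, EPS_LOG));
    }
  }
  loss_s /= (double)(B * T);

  double J = alpha * loss_s + beta * loss_d;

  // point-wise probabilities back in B x 2 x T layout for the caller
  cube PsCube(B, 2, T);
  for (unsigned int t = 0; t < T; ++t) PsCube.slice(t) =
      Ps.rows(t * B, (t + 1) * B - 1);

  List out = List::create(
      _["loss"] = J, _["loss_pointwise"] = loss_s, _["loss_shape"] = loss_d,
      _["shape_probs"] = Pd, _["pointwise_probs"] = PsCube);
  if (!want_grad) return out;

  // ---- backward ----
  mat dLd = Pd;
  for (unsigned int b = 0; b < B; ++b) dLd(b, (unsigned int)yd(b)) -= 1.0;
  dLd *= beta / (double)B;
  mat dWd = featd.t() * dLd;
  rowvec dbd = sum(dLd, 0);
  mat dpooled = dLd * Wd.rows(0, H2 - 1).t();
  mat dC = dLd * Wd.rows(H2, H2 + Cc - 1).t();

  mat dLs = Ps;
  for (unsigned int t = 0; t < T; ++t) {
    for (unsigned int b = 0; b < B; ++b) {
      dLs(t * B + b, (unsigned int)ys(b, t)) -= 1.0;
    }
  }
  dLs *= alpha / (double)(B * T);
  mat dWp(size(Wp), fill::zeros);
  dWp.rows(0, H2 - 1) = Y3.t() * dLs;
  rowvec dbp = sum(dLs, 0);
  mat dY3 = dLs * Wp.rows(0, H2 - 1).t();
  mat dCWp(B, 2, fill::zeros);
  for (unsigned int t = 0; t < T; ++t) {
    dY3.rows(t * B, (t + 1) * B - 1) += dpooled / (double)T;
    dCWp += dLs.rows(t * B, (t + 1) * B - 1);
  }
  dWp.rows(H2, H2 + Cc - 1) = C.t() * dCWp;
  dC += dCWp * Wp.rows(H2, H2 + Cc - 1).t();
  mat dClin = dC % (1.0 - C % C);
  mat dWc = cat.t() * dClin;
  rowvec dbc = sum(dClin, 0);

  List grads = List::create(
      _["Wc"] = dWc, _["bc"] = dbc, _["Wp"] = dWp, _["bp"] = dbp,
      _["Wd"] = dWd, _["bd"] = dbd);

  mat dcur = std::move(dY3);
  for (int l = L - 1; l >= 0; --l) {
    mat dXl(B * T, Xs[l].n_cols, fill::zeros);
    for (int d = 0; d < 2; ++d) {
      int k = 2 * l + d;
      std::string suf = std::to_string(l + 1) + dn[d];
      mat dW(size(Wl[k]), fill::zeros);
      mat dU(size(Ul[k]), fill::zeros);
      rowvec db(bl[k].n_elem, fill::zeros);
      gru_bwd(Xs[l], Wl[k], Ul[k], d == 1, B, T, cc[k], dcur, d * Hh,
              dW, dU, db, dXl, l > 0);
      grads[std::string("W") + suf] = dW;
      grads[std::string("U") + suf] = dU;
      grads[std::string("b") + suf] = db;
    }
    dcur = std::move(dXl);
  }
  out["grads"] = grads;
  return out;
}
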