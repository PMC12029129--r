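// Encoder-only transformer forward/backward in Armadillo. The R level
// handles binning, positional encodings, parameter storage and the
// optimiser; these kernels do the dense algebra without R-level
// allocation churn. Layout matches the R conventions: activations are
// (B * S) x D with rows spectrum-major, sequence position fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

static inline mat pget(const List& p, const std::string& nm) {
  return as<mat>(p[nm]);
}

static inline rowvec pgetv(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  return rowvec(v.begin(), v.size());
}

static inline std::string idx(const std::string& base, int l) {
  return base + std::to_string(l);
}

static inline NumericVector as_rvec(const rowvec& r) {
  return NumericVector(r.begin(), r.end());
}

static inline mat relu_mask(const mat& Z) {
  return arma::conv_to<mat>::from(Z > 0);
}

static const double LN_EPS = 1e-5;

// layer norm over rows; fills xhat and sig, returns the normalised output
static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b,
                  mat& xhat, vec& sig) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  sig = arma::sqrt(arma::mean(arma::square(Xc), 1) + LN_EPS);
  xhat = Xc.each_col() / sig;
  mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& xhat, const vec& sig,
                  const rowvec& g, rowvec& dg, rowvec& db) {
  dg = arma::sum(dY % xhat, 0);
  db = arma::sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() /= sig;
  return dX;
}

// [[Rcpp::export(name = ".tx_forward_cpp")]]
List tx_forward_cpp(const List& params, const List& config,
                    const arma::mat& Xb, const arma::mat& pe,
                    bool want_cache) {
  const int S = as<int>(config["n_bins"]);
  const int D = as<int>(config["embed_dim"]);
  const int nh = as<int>(config["n_heads"]);
  const int dh = as<int>(config["head_dim"]);
  const int nl = as<int>(config["n_encoder_layers"]);
  const int head_layers = as<int>(config["n_head_layers"]);
  const int B = Xb.n_rows / S;
  const double scale = 1.0 / std::sqrt((double)dh);

  mat H = Xb * pget(params, "We");
  H.each_row() += pgetv(params, "be");
  for (int b = 0; b < B; ++b) {
    H.rows(b * S, (b + 1) * S - 1) += pe;
  }

  List layers(nl);
  for (int l = 1; l <= nl; ++l) {
    mat H_in = H;
    mat Q = H * pget(params, idx("Wq", l));
    Q.each_row() += pgetv(params, idx("bq", l));
    mat K = H * pget(params, idx("Wk", l));
    K.each_row() += pgetv(params, idx("bk", l));
    mat V = H * pget(params, idx("Wv", l));
    V.each_row() += pgetv(params, idx("bv", l));
    mat O(B * S, D);
    cube A(S, S, (size_t)B * nh);
    for (int b = 0; b < B; ++b) {
      const int r0 = b * S, r1 = (b + 1) * S - 1;
      for (int h = 0; h < nh; ++h) {
        const int c0 = h * dh, c1 = (h + 1) * dh - 1;
        mat Sc = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() *
          scale;
        vec mx = arma::max(Sc, 1);
        Sc.each_col() -= mx;
        Sc = arma::exp(Sc);
        Sc.each_col() /= arma::sum(Sc, 1);
        A.slice((size_t)b * nh + h) = Sc;
        O.submat(r0, c0, r1, c1) = Sc * V.submat(r0, c0, r1, c1);
      }
    }
    mat attY = O * pget(params, idx("Wo", l));
    attY.each_row() += pgetv(params, idx("bo", l));

    mat xhat1;
    vec sig1;
    mat H1 = ln_fwd(H + attY, pgetv(params, idx("g1_", l)),
                    pgetv(params, idx("be1_", l)), xhat1, sig1);
    mat Z1 = H1 * pget(params, idx("Wf1_", l));
    Z1.each_row() += pgetv(params, idx("bf1_", l));
    mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
    mat Z2 = A1 * pget(params, idx("Wf2_", l));
    Z2.each_row() += pgetv(params, idx("bf2_", l));
    mat xhat2;
    vec sig2;
    H = ln_fwd(H1 + Z2, pgetv(params, idx("g2_", l)),
               pgetv(params, idx("be2_", l)), xhat2, sig2);
    if (want_cache) {
      layers[l - 1] = List::create(
        _["H_in"] = H_in, _["Q"] = Q, _["K"] = K, _["V"] = V, _["O"] = O,
        _["A"] = A, _["xhat1"] = xhat1, _["sig1"] = sig1, _["H1"] = H1,
        _["Z1"] = Z1, _["A1"] = A1, _["xhat2"] = xhat2, _["sig2"] = sig2);
    }
  }

  mat flat(B, S * D);
  for (int b = 0; b < B; ++b) {
    flat.row(b) = arma::vectorise(H.rows(b * S, (b + 1) * S - 1)).t();
  }
  mat Y;
  mat Zh, Ah;
  if (head_layers == 2) {
    Zh = flat * pget(params, "Wh1");
    Zh.each_row() += pgetv(params, "bh1");
    Ah = arma::clamp(Zh, 0.0, arma::datum::inf);
    Y = Ah * pget(params, "Wh2");
    Y.each_row() += pgetv(params, "bh2");
  } else {
    Y = flat * pget(params, "Wh");
    Y.each_row() += pgetv(params, "bh");
  }
  if (!want_cache) return List::create(_["Y"] = Y);
  return List::create(_["Y"] = Y, _["layers"] = layers, _["flat"] = flat,
                      _["Zh"] = Zh, _["Ah"] = Ah, _["B"] = B);
}

// [[Rcpp::export(name = ".tx_backward_cpp")]]
List tx_backward_cpp(const List& params, const List& config,
                     const List& cache, const arma::mat& Xb,
                     const arma::mat& dY) {
  const int S = as<int>(config["n_bins"]);
  const int D = as<int>(config["embed_dim"]);
  const int nh = as<int>(config["n_heads"]);
  const int dh = as<int>(config["head_dim"]);
  const int nl = as<int>(config["n_encoder_layers"]);
  const int head_layers = as<int>(config["n_head_layers"]);
  const int B = as<int>(cache["B"]);
  const double scale = 1.0 / std::sqrt((double)dh);

  List grads;
  mat flat = as<mat>(cache["flat"]);
  mat dflat;
  if (head_layers == 2) {
    mat Ah = as<mat>(cache["Ah"]);
    mat Zh = as<mat>(cache["Zh"]);
    grads["Wh2"] = Ah.t() * dY;
    grads["bh2"] = as_rvec(arma::sum(dY, 0));
    mat dAh = dY * pget(params, "Wh2").t();
    mat dZh = dAh % relu_mask(Zh);
    grads["Wh1"] = flat.t() * dZh;
    grads["bh1"] = as_rvec(arma::sum(dZh, 0));
    dflat = dZh * pget(params, "Wh1").t();
  } else {
    grads["Wh"] = flat.t() * dY;
    grads["bh"] = as_rvec(arma::sum(dY, 0));
    dflat = dY * pget(params, "Wh").t();
  }

  mat dH(B * S, D);
  for (int b = 0; b < B; ++b) {
    dH.rows(b * S, (b + 1) * S - 1) =
      arma::reshape(dflat.row(b).t(), S, D);
  }

  List layers = cache["layers"];
  for (int l = nl; l >= 1; --l) {
    List lc = layers[l - 1];
    mat xhat2 = as<mat>(lc["xhat2"]);
    vec sig2 = as<vec>(lc["sig2"]);
    rowvec dg2, db2;
    mat dR2 = ln_bwd(dH, xhat2, sig2, pgetv(params, idx("g2_", l)),
                     dg2, db2);
    grads[idx("g2_", l)] = as_rvec(dg2);
    grads[idx("be2_", l)] = as_rvec(db2);

    mat A1 = as<mat>(lc["A1"]);
    mat Z1 = as<mat>(lc["Z1"]);
    mat H1 = as<mat>(lc["H1"]);
    grads[idx("Wf2_", l)] = A1.t() * dR2;
    grads[idx("bf2_", l)] = as_rvec(arma::sum(dR2, 0));
    mat dA1 = dR2 * pget(params, idx("Wf2_", l)).t();
    mat dZ1 = dA1 % relu_mask(Z1);
    grads[idx("Wf1_", l)] = H1.t() * dZ1;
    grads[idx("bf1_", l)] = as_rvec(arma::sum(dZ1, 0));
    mat dH1 = dR2 + dZ1 * pget(params, idx("Wf1_", l)).t();

    mat xhat1 = as<mat>(lc["xhat1"]);
    vec sig1 = as<vec>(lc["sig1"]);
    rowvec dg1, db1;
    mat dR1 = ln_bwd(dH1, xhat1, sig1, pgetv(params, idx("g1_", l)),
                     dg1, db1);
    grads[idx("g1_", l)] = as_rvec(dg1);
    grads[idx("be1_", l)] = as_rvec(db1);

    mat O = as<mat>(lc["O"]);
    mat Q = as<mat>(lc["Q"]);
    mat K = as<mat>(lc["K"]);
    mat V = as<mat>(lc["V"]);
    cube A = as<cube>(lc["A"]);
    mat H_in = as<mat>(lc["H_in"]);

    grads[idx("Wo", l)] = O.t() * dR1;
    grads[idx("bo", l)] = as_rvec(arma::sum(dR1, 0));
    mat dO = dR1 * pget(params, idx("Wo", l)).t();
    mat dQ(B * S, D), dK(B * S, D), dV(B * S, D);
    for (int b = 0; b < B; ++b) {
      const int r0 = b * S, r1 = (b + 1) * S - 1;
      for (int h = 0; h < nh; ++h) {
        const int c0 = h * dh, c1 = (h + 1) * dh - 1;
        const mat& Ab = A.slice((size_t)b * nh + h);
        mat dOb = dO.submat(r0, c0, r1, c1);
        mat Vb = V.submat(r0, c0, r1, c1);
        mat dA = dOb * Vb.t();
        dV.submat(r0, c0, r1, c1) = Ab.t() * dOb;
        mat dS = dA;
        dS.each_col() -= arma::sum(dA % Ab, 1);
        dS %= Ab;
        dQ.submat(r0, c0, r1, c1) =
          dS * K.submat(r0, c0, r1, c1) * scale;
        dK.submat(r0, c0, r1, c1) =
          dS.t() * Q.submat(r0, c0, r1, c1) * scale;
      }
    }
    grads[idx("Wq", l)] = H_in.t() * dQ;
    grads[idx("bq", l)] = as_rvec(arma::sum(dQ, 0));
    grads[idx("Wk", l)] = H_in.t() * dK;
    grads[idx("bk", l)] = as_rvec(arma::sum(dK, 0));
    grads[idx("Wv", l)] = H_in.t() * dV;
    grads[idx("bv", l)] = as_rvec(arma::sum(dV, 0));
    dH = dR1 + dQ * pget(params, idx("Wq", l)).t() +
      dK * pget(params, idx("Wk", l)).t() +
      dV * pget(params, idx("Wv", l)).t();
  }

  grads["be"] = as_rvec(arma::sum(dH, 0));
  grads["We"] = Xb.t() * dH;
  return grads;
}
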