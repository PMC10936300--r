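// Mini-batch forward/backward pass of the 31-layer moment-regression CNN:
// seven conv/batch-norm/ReLU sets (average pooling after sets 1-6), dropout,
// one fully connected output, mean-squared-error regression loss.
// Convolution is 'same'-padded stride-1 via im2col + GEMM; pooling is
// size `pool`, stride `pool`, no padding. All randomness (weight init,
// shuffling, dropout masks) is drawn on the R side so results are
// bit-reproducible for a given seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double BN_EPS = 1e-5;

// columns indexed j*H + i (column-major pixel order); rows c*k*k + (di+r)*k + (dj+r)
static mat im2col_same(const cube& A, uword n, uword C, int k) {
  uword H = A.n_rows, W = A.n_cols;
  int r = k / 2;
  mat out(C * k * k, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& S = A.slice(n * C + c);
    for (int di = -r; di <= r; ++di) {
      for (int dj = -r; dj <= r; ++dj) {
        uword row = c * k * k + (uword)((di + r) * k + (dj + r));
        for (uword j = 0; j < W; ++j) {
          long jj = (long)j + dj;
          if (jj < 0 || jj >= (long)W) continue;
          long i0 = std::max(0L, -(long)di);
          long i1 = std::min((long)H - 1, (long)H - 1 - (long)di);
          for (long i = i0; i <= i1; ++i) {
            out(row, j * H + (uword)i) = S((uword)(i + di), (uword)jj);
          }
        }
      }
    }
  }
  return out;
}

static void col2im_same(const mat& dcol, cube& dA, uword n, uword C, int k) {
  uword H = dA.n_rows, W = dA.n_cols;
  int r = k / 2;
  for (uword c = 0; c < C; ++c) {
    mat& S = dA.slice(n * C + c);
    for (int di = -r; di <= r; ++di) {
      for (int dj = -r; dj <= r; ++dj) {
        uword row = c * k * k + (uword)((di + r) * k + (dj + r));
        for (uword j = 0; j < W; ++j) {
          long jj = (long)j + dj;
          if (jj < 0 || jj >= (long)W) continue;
          long i0 = std::max(0L, -(long)di);
          long i1 = std::min((long)H - 1, (long)H - 1 - (long)di);
          for (long i = i0; i <= i1; ++i) {
            S((uword)(i + di), (uword)jj) += dcol(row, j * H + (uword)i);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cnn_pass(const arma::cube& X, const arma::vec& y, List params,
              int kernel, int pool, bool training, bool want_grads,
              const arma::mat& dropout_mask, double dropout_p) {
  List conv_w = params["conv_w"], conv_b = params["conv_b"];
  List bn_gamma = params["bn_gamma"], bn_beta = params["bn_beta"];
  List bn_rmean = params["bn_rmean"], bn_rvar = params["bn_rvar"];
  vec fc_w = Rcpp::as<vec>(params["fc_w"]);
  double fc_b = Rcpp::as<double>(params["fc_b"]);
  int nsets = conv_w.size();
  uword N = X.n_slices;

  std::vector<cube> conv_in(nsets), xhat_s(nsets), relu_s(nsets);
  std::vector<vec> bmu(nsets), bvar(nsets);

  cube cur = X;
  uword C = 1;
  for (int s = 0; s < nsets; ++s) {
    mat Wm = Rcpp::as<mat>(conv_w[s]);
    vec b = Rcpp::as<vec>(conv_b[s]);
    uword K = Wm.n_rows;
    uword H = cur.n_rows, W = cur.n_cols;
    if (want_grads) conv_in[s] = cur;

    cube Z(H, W, K * N);
    for (uword n = 0; n < N; ++n) {
      mat col = im2col_same(cur, n, C, kernel);
      mat out = Wm * col;
      out.each_col() += b;
      for (uword kk = 0; kk < K; ++kk) {
        Z.slice(n * K + kk) = reshape(out.row(kk).t(), H, W);
      }
    }

    vec gamma = Rcpp::as<vec>(bn_gamma[s]);
    vec beta = Rcpp::as<vec>(bn_beta[s]);
    vec mu(K), va(K);
    double m = (double)(H * W * N);
    if (training) {
      for (uword kk = 0; kk < K; ++kk) {
        double su = 0, sq = 0;
        for (uword n = 0; n < N; ++n) {
          const mat& S = Z.slice(n * K + kk);
          su += accu(S);
          sq += accu(square(S));
        }
        mu(kk) = su / m;
        va(kk) = std::max(sq / m - mu(kk) * mu(kk), 0.0);
      }
    } else {
      mu = Rcpp::as<vec>(bn_rmean[s]);
      va = Rcpp::as<vec>(bn_rvar[s]);
    }

    cube Xh(H, W, K * N);
    cube R(H, W, K * N);
    for (uword kk = 0; kk < K; ++kk) {
      double inv = 1.0 / std::sqrt(va(kk) + BN_EPS);
      for (uword n = 0; n < N; ++n) {
        mat xh = (Z.slice(n * K + kk) - mu(kk)) * inv;
        Xh.slice(n * K + kk) = xh;
        mat bo = gamma(kk) * xh + beta(kk);
        R.slice(n * K + kk) = clamp(bo, 0.0, datum::inf);
      }
    }
    if (want_grads) { xhat_s[s] = Xh; bmu[s] = mu; bvar[s] = va; relu_s[s] = R; }

    if (s < nsets - 1) {
      uword Ho = (H - (uword)pool) / pool + 1;
      uword Wo = (W - (uword)pool) / pool + 1;
      cube P(Ho, Wo, K * N);
      double pp = (double)(pool * pool);
      for (uword sl = 0; sl < K * N; ++sl) {
        const mat& S = R.slice(sl);
        mat& O = P.slice(sl);
        for (uword oj = 0; oj < Wo; ++oj) {
          for (uword oi = 0; oi < Ho; ++oi) {
            double acc = 0;
            for (int a = 0; a < pool; ++a)
              for (int bcol = 0; bcol < pool; ++bcol)
                acc += S(oi * pool + a, oj * pool + bcol);
            O(oi, oj) = acc / pp;
          }
        }
      }
      cur = P;
    } else {
      cur = R;
    }
    C = K;
  }

  uword Hs = cur.n_rows, Ws = cur.n_cols;
  uword HW = Hs * Ws;
  uword D = HW * C;
  mat F(D, N);
  for (uword n = 0; n < N; ++n) {
    for (uword c = 0; c < C; ++c) {
      F.col(n).subvec(c * HW, (c + 1) * HW - 1) = vectorise(cur.slice(n * C + c));
    }
  }
  mat Fd = F;
  bool use_dropout = training && dropout_p > 0;
  if (use_dropout) Fd = (F % dropout_mask) / (1.0 - dropout_p);

  vec preds = Fd.t() * fc_w + fc_b;

  double loss = NA_REAL;
  if (y.n_elem == N) loss = mean(square(preds - y));

  if (!want_grads) {
    return List::create(Named("preds") = preds, Named("loss") = loss);
  }

  // ----- backward -----
  vec dpred = 2.0 * (preds - y) / (double)N;
  vec d_fcw = Fd * dpred;
  double d_fcb = accu(dpred);
  mat dF = fc_w * dpred.t();
  if (use_dropout) dF = (dF % dropout_mask) / (1.0 - dropout_p);

  cube dcur(Hs, Ws, C * N);
  for (uword n = 0; n < N; ++n) {
    for (uword c = 0; c < C; ++c) {
      dcur.slice(n * C + c) = reshape(dF.col(n).subvec(c * HW, (c + 1) * HW - 1), Hs, Ws);
    }
  }

  List g_conv_w(nsets), g_conv_b(nsets), g_bn_gamma(nsets), g_bn_beta(nsets);
  List out_bn_mu(nsets), out_bn_var(nsets);

  for (int s = nsets - 1; s >= 0; --s) {
    mat Wm = Rcpp::as<mat>(conv_w[s]);
    vec gamma = Rcpp::as<vec>(bn_gamma[s]);
    uword K = Wm.n_rows;
    uword Hr = relu_s[s].n_rows, Wr = relu_s[s].n_cols;
    uword Cin = conv_in[s].n_slices / N;

    cube dRelu(Hr, Wr, K * N);
    if (s < nsets - 1) {
      dRelu.zeros();
      uword Ho = dcur.n_rows, Wo = dcur.n_cols;
      double pp = (double)(pool * pool);
      for (uword sl = 0; sl < K * N; ++sl) {
        const mat& DO = dcur.slice(sl);
        mat& DR = dRelu.slice(sl);
        for (uword oj = 0; oj < Wo; ++oj) {
          for (uword oi = 0; oi < Ho; ++oi) {
            double v = DO(oi, oj) / pp;
            for (int a = 0; a < pool; ++a)
              for (int bcol = 0; bcol < pool; ++bcol)
                DR(oi * pool + a, oj * pool + bcol) += v;
          }
        }
      }
    } else {
      dRelu = dcur;
    }
    // ReLU gate
    for (uword sl = 0; sl < K * N; ++sl) {
      dRelu.slice(sl) %= conv_to<mat>::from(relu_s[s].slice(sl) > 0);
    }

    // batch-norm backward
    vec dgamma(K), dbeta(K);
    cube dz(Hr, Wr, K * N);
    double m = (double)(Hr * Wr * N);
    for (uword kk = 0; kk < K; ++kk) {
      double inv = 1.0 / std::sqrt(bvar[s](kk) + BN_EPS);
      double s_dxh = 0, s_dxh_xh = 0, s_dg = 0, s_db = 0;
      for (uword n = 0; n < N; ++n) {
        const mat& dY = dRelu.slice(n * K + kk);
        const mat& xh = xhat_s[s].slice(n * K + kk);
        s_dg += accu(dY % xh);
        s_db += accu(dY);
        s_dxh += accu(dY) * gamma(kk);
        s_dxh_xh += accu(dY % xh) * gamma(kk);
      }
      dgamma(kk) = s_dg;
      dbeta(kk) = s_db;
      for (uword n = 0; n < N; ++n) {
        const mat& dY = dRelu.slice(n * K + kk);
        const mat& xh = xhat_s[s].slice(n * K + kk);
        dz.slice(n * K + kk) =
          (inv / m) * (m * gamma(kk) * dY - s_dxh - xh * s_dxh_xh);
      }
    }

    // conv backward
    uword HWc = Hr * Wr;
    mat dWm(K, Cin * kernel * kernel, fill::zeros);
    vec db(K, fill::zeros);
    cube dIn(Hr, Wr, Cin * N, fill::zeros);
    mat dZn(K, HWc);
    for (uword n = 0; n < N; ++n) {
      mat col = im2col_same(conv_in[s], n, Cin, kernel);
      for (uword kk = 0; kk < K; ++kk) {
        dZn.row(kk) = vectorise(dz.slice(n * K + kk)).t();
      }
      dWm += dZn * col.t();
      db += sum(dZn, 1);
      mat dcol = Wm.t() * dZn;
      col2im_same(dcol, dIn, n, Cin, kernel);
    }

    g_conv_w[s] = dWm;
    g_conv_b[s] = db;
    g_bn_gamma[s] = dgamma;
    g_bn_beta[s] = dbeta;
    out_bn_mu[s] = bmu[s];
    out_bn_var[s] = bvar[s];
    dcur = dIn;
  }

  return List::create(
    Named("preds") = preds, Named("loss") = loss,
    Named("grads") = List::create(
      Named("conv_w") = g_conv_w, Named("conv_b") = g_conv_b,
      Named("bn_gamma") = g_bn_gamma, Named("bn_beta") = g_bn_beta,
      Named("fc_w") = d_fcw, Named("fc_b") = d_fcb),
    Named("bn_mu") = out_bn_mu, Named("bn_var") = out_bn_var);
}
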