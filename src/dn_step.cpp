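// Fast path for one training step of the center divisive-normalization
// model when the subunit filters are frozen (driving maps precomputed).
// Mirrors the reference implementation in R/gradients.R exactly; the test
// suite asserts agreement of loss and every gradient to ~1e-10.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double POW_EPS_C = 1e-6;

// Zero-padded stride-1 box average (fixed divisor pool^2) of one oh x ow
// slice stored column-major (i fastest).
static void boxpool_slice(const double* src, double* dst, int oh, int ow,
                          int pool, double* rowbuf) {
  int half = (pool - 1) / 2;
  double inv = 1.0 / (double)(pool * pool);
  // pass 1: sliding sum along i for every j -> rowbuf (oh x ow)
  for (int j = 0; j < ow; ++j) {
    const double* s = src + (size_t)j * oh;
    double* rb = rowbuf + (size_t)j * oh;
    double acc = 0.0;
    for (int i = 0; i < std::min(half, oh); ++i) acc += s[i];
    for (int i = 0; i < oh; ++i) {
      int add = i + half;
      if (add < oh) acc += s[add];
      rb[i] = acc;
      int drop = i - half;
      if (drop >= 0) acc -= s[drop];
    }
  }
  // pass 2: sliding sum along j for every i
  for (int i = 0; i < oh; ++i) {
    double acc = 0.0;
    for (int j = 0; j < std::min(half, ow); ++j) acc += rowbuf[(size_t)j * oh + i];
    for (int j = 0; j < ow; ++j) {
      int add = j + half;
      if (add < ow) acc += rowbuf[(size_t)add * oh + i];
      dst[(size_t)j * oh + i] = acc * inv;
      int drop = j - half;
      if (drop >= 0) acc -= rowbuf[(size_t)drop * oh + i];
    }
  }
}

// Box average applied to every (image, channel) slice of an M x C matrix,
// M = oh * ow * N.
static mat boxpool_all(const mat& X, int oh, int ow, int N, int pool) {
  mat out(X.n_rows, X.n_cols);
  std::vector<double> rowbuf((size_t)oh * ow);
  int npix = oh * ow;
  for (uword c = 0; c < X.n_cols; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    for (int nn = 0; nn < N; ++nn)
      boxpool_slice(src + (size_t)nn * npix, dst + (size_t)nn * npix,
                    oh, ow, pool, rowbuf.data());
  }
  return out;
}

// Gather the rows of `full` (npix-row blocks per image, M_full x C) for the
// 1-based image indices in `idx`. Blockwise contiguous copies.
// [[Rcpp::export(name = ".gather_images")]]
arma::mat gather_images(const arma::mat& full, const arma::uvec& idx,
                        int npix) {
  const int C = (int)full.n_cols;
  const int N = (int)idx.n_elem;
  arma::mat out((size_t)npix * N, C);
  for (int c = 0; c < C; ++c) {
    const double* src = full.colptr(c);
    double* dst = out.colptr(c);
    for (int j = 0; j < N; ++j)
      std::memcpy(dst + (size_t)j * npix,
                  src + (size_t)(idx(j) - 1) * npix,
                  sizeof(double) * npix);
  }
  return out;
}

// [[Rcpp::export(name = ".dn_step_frozen")]]
Rcpp::List dn_step_frozen(const arma::mat& Y, const arma::mat& logY,
                          int oh, int ow, int N, int pool,
                          const arma::vec& n, const arma::vec& sigma,
                          const arma::mat& P,
                          const arma::mat& A, const arma::mat& B,
                          const arma::vec& q,
                          const arma::mat& alpha, const arma::mat& r,
                          double grid_lo, double grid_hi, double grid_dx,
                          double lambda_sparse, double lambda_out,
                          bool nonspecific) {
  const int C = (int)Y.n_cols;
  const int npix = oh * ow;
  const int I = (int)A.n_cols;
  const int J = (int)alpha.n_rows;
  const uword M = Y.n_rows;

  // ---- forward: DN stage ----
  mat T(M, C);
  for (int c = 0; c < C; ++c) T.col(c) = exp(n(c) * logY.col(c));
  mat Q = boxpool_all(T, oh, ow, N, pool);
  mat den = Q * P;
  rowvec sig_n(C);
  for (int c = 0; c < C; ++c) sig_n(c) = std::pow(sigma(c), n(c));
  den.each_row() += sig_n;
  mat Z = T / den;

  // ---- forward: readout ----
  // Z's memory reinterpreted as npix x (N*C): column (nn + N*c) is image
  // nn's map of channel c.
  mat Zv(const_cast<double*>(Z.memptr()), npix, (size_t)N * C, false, true);
  mat U = A.t() * Zv;                    // I x (N*C)
  mat g(N, I, fill::zeros);
  for (int i = 0; i < I; ++i)
    for (int c = 0; c < C; ++c) {
      const double b = B(c, i);
      if (b == 0.0) continue;
      for (int nn = 0; nn < N; ++nn) g(nn, i) += b * U(i, (size_t)c * N + nn);
    }
  g.each_row() += q.t();

  // ---- forward: output nonlinearity (two nonzero tent weights) ----
  mat ea = exp(alpha);
  mat E(N, I), Ep(N, I), h(N, I), hp(N, I), rhat(N, I);
  umat j0m(N, I);
  mat w2m(N, I);
  for (int i = 0; i < I; ++i) {
    for (int nn = 0; nn < N; ++nn) {
      double gv = g(nn, i);
      double gc = std::min(std::max(gv, grid_lo), grid_hi);
      double t = (gc - grid_lo) / grid_dx;
      int j0 = (int)std::floor(t);
      if (j0 > J - 2) j0 = J - 2;
      double w2 = t - j0;
      double e1 = ea(j0, i), e2 = ea(j0 + 1, i);
      double hv = (1.0 - w2) * e1 + w2 * e2;
      bool inside = (gv > grid_lo) && (gv < grid_hi);
      double hpv = inside ? (e2 - e1) / grid_dx : 0.0;
      double Ev = (gv >= 1.0) ? gv : std::exp(gv - 1.0);
      double Epv = (gv >= 1.0) ? 1.0 : Ev;
      E(nn, i) = Ev; Ep(nn, i) = Epv; h(nn, i) = hv; hp(nn, i) = hpv;
      rhat(nn, i) = hv * Ev;
      j0m(nn, i) = j0; w2m(nn, i) = w2;
    }
  }

  // ---- loss ----
  double lp = 0.0;
  for (uword k = 0; k < rhat.n_elem; ++k) {
    double rh = rhat(k);
    double rf = std::max(rh, 1e-8);
    lp += rh - r(k) * std::log(rf);
  }
  vec sa = sum(abs(A), 0).t();
  vec sb = sum(abs(B), 0).t();
  double lsp = dot(sa, sb);
  double lout = 0.0;
  for (int i = 0; i < I; ++i) {
    for (int j = 1; j < J; ++j) {
      double d1 = alpha(j, i) - alpha(j - 1, i);
      lout += d1 * d1;
    }
    for (int j = 1; j < J - 1; ++j) {
      double d2 = 2.0 * alpha(j, i) - alpha(j - 1, i) - alpha(j + 1, i);
      lout += d2 * d2;
    }
  }
  lout /= (double)J;
  double loss = lp + lambda_sparse * lsp + lambda_out * lout;

  // ---- backward: Poisson + output nonlinearity ----
  mat dR(N, I), dG(N, I);
  mat dalpha(J, I, fill::zeros);
  for (int i = 0; i < I; ++i) {
    for (int nn = 0; nn < N; ++nn) {
      double drv = 1.0 - r(nn, i) / std::max(rhat(nn, i), 1e-8);
      dR(nn, i) = drv;
      dG(nn, i) = drv * (hp(nn, i) * E(nn, i) + h(nn, i) * Ep(nn, i));
      double coef = drv * E(nn, i);
      int j0 = (int)j0m(nn, i);
      double w2 = w2m(nn, i);
      dalpha(j0, i) += coef * (1.0 - w2) * ea(j0, i);
      dalpha(j0 + 1, i) += coef * w2 * ea(j0 + 1, i);
    }
  }
  // smoothness penalty gradient on alpha
  for (int i = 0; i < I; ++i) {
    for (int j = 1; j < J; ++j) {
      double d1 = 2.0 * (alpha(j, i) - alpha(j - 1, i)) / (double)J;
      dalpha(j, i) += lambda_out * d1;
      dalpha(j - 1, i) -= lambda_out * d1;
    }
    for (int j = 1; j < J - 1; ++j) {
      double d2 = 2.0 * (2.0 * alpha(j, i) - alpha(j - 1, i) -
                         alpha(j + 1, i)) / (double)J;
      dalpha(j, i) += lambda_out * 2.0 * d2;
      dalpha(j - 1, i) -= lambda_out * d2;
      dalpha(j + 1, i) -= lambda_out * d2;
    }
  }

  // ---- backward: readout ----
  mat V(I, (size_t)N * C);
  for (int i = 0; i < I; ++i)
    for (int c = 0; c < C; ++c) {
      const double b = B(c, i);
      for (int nn = 0; nn < N; ++nn) V(i, (size_t)c * N + nn) = b * dG(nn, i);
    }
  mat da = Zv * V.t();                    // npix x I
  da.each_row() += (lambda_sparse * sb).t();
  mat db(C, I, fill::zeros);
  for (int i = 0; i < I; ++i) {
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int nn = 0; nn < N; ++nn) acc += U(i, (size_t)c * N + nn) * dG(nn, i);
      db(c, i) = acc + lambda_sparse * sa(i);
    }
  }
  vec dq = sum(dG, 0).t();
  mat dZv = A * V;                        // npix x (N*C)
  mat dZ(dZv.memptr(), M, C, false, true);

  // ---- backward: DN stage ----
  mat dnum = dZ / den;
  mat dden = -dZ % Z / den;
  rowvec dden_sum = sum(dden, 0);
  vec dsigma(C), dn_sig(C);
  for (int c = 0; c < C; ++c) {
    dsigma(c) = dden_sum(c) * n(c) * std::pow(sigma(c), n(c) - 1.0);
    dn_sig(c) = (sigma(c) > 0)
      ? dden_sum(c) * sig_n(c) * std::log(std::max(sigma(c), POW_EPS_C))
      : 0.0;
  }
  mat dp = Q.t() * dden;
  if (nonspecific) {
    rowvec cm = mean(dp, 0);
    dp.each_row() = cm;
  }
  mat dA_pool = dden * P.t();
  mat dT = dnum + boxpool_all(dA_pool, oh, ow, N, pool);
  vec dn_grad(C);
  for (int c = 0; c < C; ++c)
    dn_grad(c) = accu(dT.col(c) % T.col(c) % logY.col(c)) + dn_sig(c);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("poisson") = lp,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("n") = dn_grad, Rcpp::Named("sigma") = dsigma,
      Rcpp::Named("p") = dp, Rcpp::Named("a") = da, Rcpp::Named("b") = db,
      Rcpp::Named("q") = dq, Rcpp::Named("alpha") = dalpha));
}

// Blocked variant: processes one image at a time so all intermediates stay
// cache-resident, gathering batch images directly from the full driving
// matrices. Numerically identical to dn_step_frozen (and to the R
// reference); asserted in the test suite.
// [[Rcpp::export(name = ".dn_step_frozen_blocked")]]
Rcpp::List dn_step_frozen_blocked(const arma::mat& Yfull,
                                  const arma::mat& logYfull,
                                  const arma::uvec& idx,
                                  int oh, int ow, int pool,
                                  const arma::vec& n, const arma::vec& sigma,
                                  const arma::mat& P,
                                  const arma::mat& A, const arma::mat& B,
                                  const arma::vec& q,
                                  const arma::mat& alpha, const arma::mat& r,
                                  double grid_lo, double grid_hi,
                                  double grid_dx,
                                  double lambda_sparse, double lambda_out,
                                  bool nonspecific) {
  const int C = (int)Yfull.n_cols;
  const int npix = oh * ow;
  const int I = (int)A.n_cols;
  const int J = (int)alpha.n_rows;
  const int N = (int)idx.n_elem;
  const size_t M = (size_t)npix * N;

  // persistent big buffers (exponentiated and pooled drives for pass 2)
  static thread_local mat T_all, Q_all;
  if (T_all.n_rows != M || T_all.n_cols != (uword)C) {
    T_all.set_size(M, C);
    Q_all.set_size(M, C);
  }
  static thread_local cube U_all;
  if ((int)U_all.n_rows != I || (int)U_all.n_cols != C ||
      (int)U_all.n_slices != N)
    U_all.set_size(I, C, N);

  std::vector<double> rowbuf((size_t)npix);
  mat Yj(npix, C), Tj(npix, C), Qj(npix, C), denj(npix, C), Zj(npix, C);
  mat g(N, I);

  rowvec sig_n(C);
  for (int c = 0; c < C; ++c) sig_n(c) = std::pow(sigma(c), n(c));

  // ---- pass 1: forward ----
  for (int j = 0; j < N; ++j) {
    const size_t src_off = (size_t)(idx(j) - 1) * npix;
    for (int c = 0; c < C; ++c) {
      const double* ly = logYfull.colptr(c) + src_off;
      double* t = Tj.colptr(c);
      const double nc = n(c);
      for (int pix = 0; pix < npix; ++pix) t[pix] = std::exp(nc * ly[pix]);
      boxpool_slice(Tj.colptr(c), Qj.colptr(c), oh, ow, pool, rowbuf.data());
    }
    denj = Qj * P;
    denj.each_row() += sig_n;
    Zj = Tj / denj;
    T_all.rows((size_t)j * npix, (size_t)(j + 1) * npix - 1) = Tj;
    Q_all.rows((size_t)j * npix, (size_t)(j + 1) * npix - 1) = Qj;
    mat Uj = A.t() * Zj;              // I x C
    U_all.slice(j) = Uj;
    for (int i = 0; i < I; ++i) {
      double acc = q(i);
      for (int c = 0; c < C; ++c) acc += Uj(i, c) * B(c, i);
      g(j, i) = acc;
    }
  }

  // ---- output nonlinearity, loss, dG, dalpha (identical to unblocked) ----
  mat ea = exp(alpha);
  mat E(N, I), h(N, I), hp(N, I), rhat(N, I), Ep(N, I);
  umat j0m(N, I); mat w2m(N, I);
  for (int i = 0; i < I; ++i)
    for (int nn = 0; nn < N; ++nn) {
      double gv = g(nn, i);
      double gc = std::min(std::max(gv, grid_lo), grid_hi);
      double t = (gc - grid_lo) / grid_dx;
      int j0 = (int)std::floor(t);
      if (j0 > J - 2) j0 = J - 2;
      double w2 = t - j0;
      double e1 = ea(j0, i), e2 = ea(j0 + 1, i);
      bool inside = (gv > grid_lo) && (gv < grid_hi);
      double Ev = (gv >= 1.0) ? gv : std::exp(gv - 1.0);
      E(nn, i) = Ev; Ep(nn, i) = (gv >= 1.0) ? 1.0 : Ev;
      h(nn, i) = (1.0 - w2) * e1 + w2 * e2;
      hp(nn, i) = inside ? (e2 - e1) / grid_dx : 0.0;
      rhat(nn, i) = h(nn, i) * Ev;
      j0m(nn, i) = j0; w2m(nn, i) = w2;
    }

  double lp = 0.0;
  for (uword k = 0; k < rhat.n_elem; ++k)
    lp += rhat(k) - r(k) * std::log(std::max(rhat(k), 1e-8));
  vec sa = sum(abs(A), 0).t();
  vec sb = sum(abs(B), 0).t();
  double lsp = dot(sa, sb);
  double lout = 0.0;
  for (int i = 0; i < I; ++i) {
    for (int j = 1; j < J; ++j) {
      double d1 = alpha(j, i) - alpha(j - 1, i);
      lout += d1 * d1;
    }
    for (int j = 1; j < J - 1; ++j) {
      double d2 = 2.0 * alpha(j, i) - alpha(j - 1, i) - alpha(j + 1, i);
      lout += d2 * d2;
    }
  }
  lout /= (double)J;
  double loss = lp + lambda_sparse * lsp + lambda_out * lout;

  mat dG(N, I);
  mat dalpha(J, I, fill::zeros);
  for (int i = 0; i < I; ++i)
    for (int nn = 0; nn < N; ++nn) {
      double drv = 1.0 - r(nn, i) / std::max(rhat(nn, i), 1e-8);
      dG(nn, i) = drv * (hp(nn, i) * E(nn, i) + h(nn, i) * Ep(nn, i));
      double coef = drv * E(nn, i);
      int j0 = (int)j0m(nn, i);
      double w2 = w2m(nn, i);
      dalpha(j0, i) += coef * (1.0 - w2) * ea(j0, i);
      dalpha(j0 + 1, i) += coef * w2 * ea(j0 + 1, i);
    }
  for (int i = 0; i < I; ++i) {
    for (int j = 1; j < J; ++j) {
      double d1 = 2.0 * (alpha(j, i) - alpha(j - 1, i)) / (double)J;
      dalpha(j, i) += lambda_out * d1;
      dalpha(j - 1, i) -= lambda_out * d1;
    }
    for (int j = 1; j < J - 1; ++j) {
      double d2 = 2.0 * (2.0 * alpha(j, i) - alpha(j - 1, i) -
                         alpha(j + 1, i)) / (double)J;
      dalpha(j, i) += lambda_out * 2.0 * d2;
      dalpha(j - 1, i) -= lambda_out * d2;
      dalpha(j + 1, i) -= lambda_out * d2;
    }
  }

  // ---- pass 2: backward per image ----
  mat da(npix, I, fill::zeros), db(C, I, fill::zeros);
  mat dp(C, C, fill::zeros);
  vec dsig_acc(C, fill::zeros), dn_acc(C, fill::zeros);
  mat Wj(I, C), dZj(npix, C), dnumj(npix, C), ddenj(npix, C), dAj(npix, C),
      dTj(npix, C), pb(npix, C);
  for (int j = 0; j < N; ++j) {
    const size_t row0 = (size_t)j * npix;
    Tj = T_all.rows(row0, row0 + npix - 1);
    Qj = Q_all.rows(row0, row0 + npix - 1);
    denj = Qj * P;
    denj.each_row() += sig_n;
    Zj = Tj / denj;
    for (int i = 0; i < I; ++i)
      for (int c = 0; c < C; ++c) Wj(i, c) = dG(j, i) * B(c, i);
    dZj = A * Wj;
    da += Zj * Wj.t();
    for (int i = 0; i < I; ++i)
      for (int c = 0; c < C; ++c) db(c, i) += U_all(i, c, j) * dG(j, i);
    dnumj = dZj / denj;
    ddenj = -dZj % Zj / denj;
    dsig_acc += sum(ddenj, 0).t();
    dp += Qj.t() * ddenj;
    dAj = ddenj * P.t();
    for (int c = 0; c < C; ++c)
      boxpool_slice(dAj.colptr(c), pb.colptr(c), oh, ow, pool, rowbuf.data());
    dTj = dnumj + pb;
    const size_t src_off = (size_t)(idx(j) - 1) * npix;
    for (int c = 0; c < C; ++c) {
      const double* ly = logYfull.colptr(c) + src_off;
      const double* t = Tj.colptr(c);
      const double* dt = dTj.colptr(c);
      double acc = 0.0;
      for (int pix = 0; pix < npix; ++pix) acc += dt[pix] * t[pix] * ly[pix];
      dn_acc(c) += acc;
    }
  }
  da.each_row() += (lambda_sparse * sb).t();
  db.each_row() += (lambda_sparse * sa).t();
  vec dq = sum(dG, 0).t();

  vec dsigma(C), dn_grad(C);
  for (int c = 0; c < C; ++c) {
    dsigma(c) = dsig_acc(c) * n(c) * std::pow(sigma(c), n(c) - 1.0);
    double sig_term = (sigma(c) > 0)
      ? dsig_acc(c) * sig_n(c) * std::log(std::max(sigma(c), POW_EPS_C))
      : 0.0;
    dn_grad(c) = dn_acc(c) + sig_term;
  }
  if (nonspecific) {
    rowvec cm = mean(dp, 0);
    dp.each_row() = cm;
  }

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("poisson") = lp,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("n") = dn_grad, Rcpp::Named("sigma") = dsigma,
      Rcpp::Named("p") = dp, Rcpp::Named("a") = da, Rcpp::Named("b") = db,
      Rcpp::Named("q") = dq, Rcpp::Named("alpha") = dalpha));
}
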