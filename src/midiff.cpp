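// Batched numerics for training: leaky-integrator RNN and GRU rollouts with
// hand-written backpropagation through time, and the feed-forward statistics
// network (forward + backprop w.r.t. parameters and inputs).
//
// Layout conventions:
//   state cubes are (N x n_batch x L): slice t holds the states at step t;
//   input cubes are (N_in x n_batch x L);
//   MLP data matrices are (n_samples x d) with one sample per row;
//   MLP weights are (out x in), so a layer computes relu(X * W' + b).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------- leaky RNN

// [[Rcpp::export]]
Rcpp::List cpp_leaky_forward(const arma::mat& Wrec, const arma::mat& Win, const arma::vec& b,
                             double alpha, const arma::cube& X, const arma::cube& Noise,
                             const arma::vec& h0) {
  const uword N = Wrec.n_rows, nb = X.n_cols, L = X.n_slices;
  cube H(N, nb, L), R(N, nb, L);
  mat h = repmat(h0, 1, nb);
  mat r = tanh(h);
  for (uword t = 0; t < L; ++t) {
    mat drive = Wrec * r + Win * X.slice(t) + Noise.slice(t);
    drive.each_col() += b;
    h = (1.0 - alpha) * h + alpha * drive;
    r = tanh(h);
    H.slice(t) = h;
    R.slice(t) = r;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("R") = R);
}

// dH_ext holds dLoss/dh_t from all per-step loss terms (readout + MI).
// [[Rcpp::export]]
Rcpp::List cpp_leaky_bptt(const arma::mat& Wrec, double alpha, const arma::cube& X,
                          const arma::cube& R, const arma::cube& dH_ext) {
  const uword N = Wrec.n_rows, Nin = X.n_rows, L = X.n_slices;
  mat dWrec(N, N, fill::zeros), dWin(N, Nin, fill::zeros);
  vec db(N, fill::zeros);
  mat carry(N, dH_ext.n_cols, fill::zeros);
  for (uword t = L; t-- > 0;) {
    mat d = dH_ext.slice(t) + carry;
    db += alpha * sum(d, 1);
    dWin += alpha * d * X.slice(t).t();
    if (t > 0) {
      const arma::mat& rprev = R.slice(t - 1);
      dWrec += alpha * d * rprev.t();
      carry = (1.0 - alpha) * d + (1.0 - square(rprev)) % (alpha * (Wrec.t() * d));
    }
  }
  return Rcpp::List::create(Rcpp::Named("dWrec") = dWrec,
                            Rcpp::Named("dWin") = dWin,
                            Rcpp::Named("db") = db);
}

// --------------------------------------------------------------------- GRU

// [[Rcpp::export]]
Rcpp::List cpp_gru_forward(const arma::mat& Wz, const arma::mat& Uz, const arma::vec& bz,
                           const arma::mat& Wr, const arma::mat& Ur, const arma::vec& br,
                           const arma::mat& Wc, const arma::mat& Uc, const arma::vec& bc,
                           const arma::cube& X, const arma::vec& h0) {
  const uword N = Uz.n_rows, nb = X.n_cols, L = X.n_slices;
  cube H(N, nb, L), Z(N, nb, L), Rg(N, nb, L), Hc(N, nb, L);
  mat h = repmat(h0, 1, nb);
  for (uword t = 0; t < L; ++t) {
    mat az = Wz * X.slice(t) + Uz * h;  az.each_col() += bz;
    mat ar = Wr * X.slice(t) + Ur * h;  ar.each_col() += br;
    mat z = 1.0 / (1.0 + exp(-az));
    mat rg = 1.0 / (1.0 + exp(-ar));
    mat ac = Wc * X.slice(t) + Uc * (rg % h);  ac.each_col() += bc;
    mat hc = tanh(ac);
    h = (1.0 - z) % h + z % hc;
    H.slice(t) = h; Z.slice(t) = z; Rg.slice(t) = rg; Hc.slice(t) = hc;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Z") = Z,
                            Rcpp::Named("Rg") = Rg, Rcpp::Named("Hc") = Hc);
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_bptt(const arma::mat& Uz, const arma::mat& Ur, const arma::mat& Uc,
                        const arma::cube& X, const arma::cube& H, const arma::cube& Z,
                        const arma::cube& Rg, const arma::cube& Hc, const arma::cube& dH_ext) {
  const uword N = Uz.n_rows, Nin = X.n_rows, nb = X.n_cols, L = X.n_slices;
  mat dWz(N, Nin, fill::zeros), dUz(N, N, fill::zeros);
  mat dWr(N, Nin, fill::zeros), dUr(N, N, fill::zeros);
  mat dWc(N, Nin, fill::zeros), dUc(N, N, fill::zeros);
  vec dbz(N, fill::zeros), dbr(N, fill::zeros), dbc(N, fill::zeros);
  mat carry(N, nb, fill::zeros);
  for (uword t = L; t-- > 0;) {
    mat dh = dH_ext.slice(t) + carry;
    mat hprev = (t > 0) ? H.slice(t - 1) : mat(N, nb, fill::zeros);
    const arma::mat& z = Z.slice(t);
    const arma::mat& rg = Rg.slice(t);
    const arma::mat& hc = Hc.slice(t);
    mat daz = (dh % (hc - hprev)) % z % (1.0 - z);
    mat dac = (dh % z) % (1.0 - square(hc));
    mat v = Uc.t() * dac;
    mat dar = (v % hprev) % rg % (1.0 - rg);
    dWz += daz * X.slice(t).t();  dUz += daz * hprev.t();  dbz += sum(daz, 1);
    dWr += dar * X.slice(t).t();  dUr += dar * hprev.t();  dbr += sum(dar, 1);
    dWc += dac * X.slice(t).t();  dUc += dac * (rg % hprev).t();
    dbc += sum(dac, 1);
    if (t > 0) {
      carry = dh % (1.0 - z) + Uz.t() * daz + Ur.t() * dar + v % rg;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("dWz") = dWz, Rcpp::Named("dUz") = dUz, Rcpp::Named("dbz") = dbz,
      Rcpp::Named("dWr") = dWr, Rcpp::Named("dUr") = dUr, Rcpp::Named("dbr") = dbr,
      Rcpp::Named("dWc") = dWc, Rcpp::Named("dUc") = dUc, Rcpp::Named("dbc") = dbc);
}

// ------------------------------------------------- statistics network (MLP)

// ReLU hidden layers, linear scalar head.
// [[Rcpp::export]]
arma::vec cpp_mlp_forward(const Rcpp::List& W, const Rcpp::List& b, const arma::mat& X) {
  const int nl = W.size();
  mat A = X;
  for (int l = 0; l < nl; ++l) {
    mat Wl = W[l];
    vec bl = b[l];
    A = A * Wl.t();
    A.each_row() += bl.t();
    if (l < nl - 1) A = clamp(A, 0.0, datum::inf);
  }
  return A.col(0);
}

// Fused Donsker-Varadhan pass: evaluates the DV objective on joint (X1) and
// shuffled (X2) datasets and its ascent gradient w.r.t. the critic
// parameters (and optionally the inputs), with one forward per dataset and
// activations shared with the backward sweep.
// [[Rcpp::export]]
Rcpp::List cpp_dv_pass(const Rcpp::List& W, const Rcpp::List& b,
                       const arma::mat& X1, const arma::mat& X2,
                       bool want_inputs) {
  const int nl = W.size();
  const uword n = X1.n_rows;
  std::vector<mat> Ws(nl);
  std::vector<vec> bs(nl);
  for (int l = 0; l < nl; ++l) { Ws[l] = Rcpp::as<mat>(W[l]); bs[l] = Rcpp::as<vec>(b[l]); }

  auto forward = [&](const mat& X, std::vector<mat>& acts) {
    acts[0] = X;
    for (int l = 0; l < nl; ++l) {
      mat A = acts[l] * Ws[l].t();
      A.each_row() += bs[l].t();
      if (l < nl - 1) A = clamp(A, 0.0, datum::inf);
      acts[l + 1] = A;
    }
  };
  std::vector<mat> a1(nl + 1), a2(nl + 1);
  forward(X1, a1);
  forward(X2, a2);
  vec t1 = a1[nl].col(0), t2 = a2[nl].col(0);
  double term_joint = mean(t1);
  double m = t2.max();
  double lme = m + std::log(mean(exp(t2 - m)));
  vec w = exp(t2 - lme) / double(n);  // softmax weights, sum to 1

  auto backward = [&](const std::vector<mat>& acts, const vec& cvec,
                      std::vector<mat>& dWs, std::vector<vec>& dbs) -> mat {
    mat delta = cvec;
    for (int l = nl - 1; l >= 0; --l) {
      dWs[l] += delta.t() * acts[l];
      dbs[l] += sum(delta, 0).t();
      delta = delta * Ws[l];
      if (l > 0) delta %= conv_to<mat>::from(acts[l] > 0.0);
    }
    return delta;
  };
  std::vector<mat> dWs(nl);
  std::vector<vec> dbs(nl);
  for (int l = 0; l < nl; ++l) {
    dWs[l] = mat(Ws[l].n_rows, Ws[l].n_cols, fill::zeros);
    dbs[l] = vec(bs[l].n_elem, fill::zeros);
  }
  mat dX1 = backward(a1, vec(n, fill::value(1.0 / double(n))), dWs, dbs);
  mat dX2 = backward(a2, -w, dWs, dbs);

  Rcpp::List dW(nl), db(nl);
  for (int l = 0; l < nl; ++l) { dW[l] = dWs[l]; db[l] = dbs[l]; }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("value") = term_joint - lme,
      Rcpp::Named("term_joint") = term_joint,
      Rcpp::Named("term_marginal") = lme,
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
  if (want_inputs) {
    out["dX1"] = dX1;
    out["dX2"] = dX2;
  }
  return out;
}

// Gradient of sum_i c_i * T(x_i) w.r.t. parameters and inputs.
// [[Rcpp::export]]
Rcpp::List cpp_mlp_backward(const Rcpp::List& W, const Rcpp::List& b,
                            const arma::mat& X, const arma::vec& cvec) {
  const int nl = W.size();
  std::vector<mat> acts(nl + 1);  // acts[l] = input to layer l
  acts[0] = X;
  for (int l = 0; l < nl; ++l) {
    mat Wl = W[l];
    vec bl = b[l];
    mat A = acts[l] * Wl.t();
    A.each_row() += bl.t();
    if (l < nl - 1) A = clamp(A, 0.0, datum::inf);
    acts[l + 1] = A;
  }
  Rcpp::List dW(nl), db(nl);
  mat delta = cvec;  // n x 1, gradient at the scalar head
  for (int l = nl - 1; l >= 0; --l) {
    mat Wl = W[l];
    dW[l] = delta.t() * acts[l];
    db[l] = sum(delta, 0).t();
    delta = delta * Wl;
    if (l > 0) delta %= conv_to<mat>::from(acts[l] > 0.0);  // ReLU mask
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = delta);
}
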