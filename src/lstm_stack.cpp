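// Stacked LSTM sequence classifier: forward pass, backpropagation through time,
// batch normalization and (inverted) dropout. Layer layout, for units u[1..K]:
//   LSTM(u1, sequences) -> BN -> Drop -> ... -> LSTM(uK, final state) -> BN ->
//   Drop -> Dense(1, sigmoid)
// Gate order inside each 4u block: input, forget, cell, output.
// Parameter vector layout (column-major), per layer l with input width d_l:
//   Wx (4u x d_l), Wh (4u x u), b (4u), gamma (u), beta (u)
// followed by the dense weights w (u_K) and bias (1).
// BN state vector: per layer, running mean (u) then running variance (u).
// Dropout masks are drawn from R's RNG so set.seed() governs reproducibility.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Layer {
  mat Wx, Wh;
  vec b, gam, bet;
};

struct Unpacked {
  std::vector<Layer> layers;
  vec w_out;
  double b_out;
};

static Unpacked unpack_params(const vec& params, const ivec& units, int d) {
  Unpacked up;
  uword pos = 0;
  int din = d;
  for (uword l = 0; l < units.n_elem; ++l) {
    int u = units(l);
    Layer L;
    L.Wx = reshape(params.subvec(pos, pos + 4 * u * din - 1), 4 * u, din);
    pos += 4 * u * din;
    L.Wh = reshape(params.subvec(pos, pos + 4 * u * u - 1), 4 * u, u);
    pos += 4 * u * u;
    L.b = params.subvec(pos, pos + 4 * u - 1); pos += 4 * u;
    L.gam = params.subvec(pos, pos + u - 1); pos += u;
    L.bet = params.subvec(pos, pos + u - 1); pos += u;
    up.layers.push_back(L);
    din = u;
  }
  up.w_out = params.subvec(pos, pos + din - 1); pos += din;
  up.b_out = params(pos); pos += 1;
  if (pos != params.n_elem) Rcpp::stop("parameter vector has wrong length");
  return up;
}

// caches kept per layer for the backward pass
struct LayerCache {
  cube I, F, G, O, C, TC, H;  // gates, cell, tanh(cell), hidden (u, N, T)
  mat xhat;                   // BN normalized output, (u, N*T) or (u, N) last
  vec mu, invstd;
  mat mask;                   // dropout mask, same shape as xhat
};

static void bn_forward(const mat& X, const vec& gam, const vec& bet,
                       vec& rmean, vec& rvar, double momentum, double eps,
                       bool training, mat& xhat, vec& mu, vec& invstd,
                       mat& out) {
  const double m = (double)X.n_cols;
  if (training) {
    mu = mean(X, 1);
    mat cent = X.each_col() - mu;
    vec var_ = sum(cent % cent, 1) / m;  // biased
    invstd = 1.0 / sqrt(var_ + eps);
    xhat = cent.each_col() % invstd;
    rmean = momentum * rmean + (1.0 - momentum) * mu;
    rvar = momentum * rvar + (1.0 - momentum) * var_;
  } else {
    mu = rmean;
    invstd = 1.0 / sqrt(rvar + eps);
    xhat = (X.each_col() - mu).each_col() % invstd;
  }
  out = xhat.each_col() % gam;
  out.each_col() += bet;
}

// dX for BN given upstream dY (both (u, m)); biased-variance formulation
static mat bn_backward(const mat& dY, const mat& xhat, const vec& invstd,
                       const vec& gam, vec& dgam, vec& dbet) {
  const double m = (double)dY.n_cols;
  dgam = sum(dY % xhat, 1);
  dbet = sum(dY, 1);
  mat dxhat = dY.each_col() % gam;
  vec s1 = sum(dxhat, 1) / m;
  vec s2 = sum(dxhat % xhat, 1) / m;
  mat dX = dxhat;
  dX.each_col() -= s1;
  dX -= xhat.each_col() % s2;
  dX.each_col() %= invstd;
  return dX;
}

static mat dropout_mask(uword r, uword c, double rate, bool training) {
  mat m(r, c);
  if (training && rate > 0.0) {
    const double keep = 1.0 - rate;
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i)
        m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  } else {
    m.ones();
  }
  return m;
}

// [[Rcpp::export]]
Rcpp::List lstm_stack_run(const arma::vec& params, const arma::cube& X,
                          const arma::vec& y, const arma::ivec& units,
                          double dropout, double bn_momentum, double bn_eps,
                          const arma::vec& state, bool training,
                          bool compute_grad) {
  const int d = X.n_rows, N = X.n_cols, T = X.n_slices;
  const uword nl = units.n_elem;
  Unpacked up = unpack_params(params, units, d);

  // unpack BN running stats
  std::vector<vec> rmean(nl), rvar(nl);
  {
    uword pos = 0;
    for (uword l = 0; l < nl; ++l) {
      int u = units(l);
      rmean[l] = state.subvec(pos, pos + u - 1); pos += u;
      rvar[l] = state.subvec(pos, pos + u - 1); pos += u;
    }
    if (pos != state.n_elem) Rcpp::stop("state vector has wrong length");
  }

  std::vector<LayerCache> cache(nl);
  std::vector<cube> inputs(nl);  // LSTM input per layer (d_l, N, T)

  cube cur = X;
  mat h_final;  // post-dropout final hidden state (u_K, N)
  for (uword l = 0; l < nl; ++l) {
    const int u = units(l);
    const int din = cur.n_rows;
    if (compute_grad) inputs[l] = cur;
    LayerCache& cc = cache[l];
    cc.I.set_size(u, N, T); cc.F.set_size(u, N, T); cc.G.set_size(u, N, T);
    cc.O.set_size(u, N, T); cc.C.set_size(u, N, T); cc.TC.set_size(u, N, T);
    cc.H.set_size(u, N, T);

    // input projection for all timesteps at once
    mat curmat(cur.memptr(), din, (uword)N * T, false, true);
    mat A = up.layers[l].Wx * curmat;
    A.each_col() += up.layers[l].b;

    mat hprev(u, N, fill::zeros), cprev(u, N, fill::zeros);
    for (int t = 0; t < T; ++t) {
      mat a = A.cols((uword)t * N, (uword)(t + 1) * N - 1) +
              up.layers[l].Wh * hprev;
      mat i = sigm(a.rows(0, u - 1));
      mat f = sigm(a.rows(u, 2 * u - 1));
      mat g = tanh(a.rows(2 * u, 3 * u - 1));
      mat o = sigm(a.rows(3 * u, 4 * u - 1));
      mat c = f % cprev + i % g;
      mat tc = tanh(c);
      mat h = o % tc;
      cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
      cc.O.slice(t) = o; cc.C.slice(t) = c; cc.TC.slice(t) = tc;
      cc.H.slice(t) = h;
      hprev = h; cprev = c;
    }

    if (l < nl - 1) {
      mat Hmat(cc.H.memptr(), u, (uword)N * T, false, true);
      mat out;
      bn_forward(Hmat, up.layers[l].gam, up.layers[l].bet, rmean[l], rvar[l],
                 bn_momentum, bn_eps, training, cc.xhat, cc.mu, cc.invstd, out);
      cc.mask = dropout_mask(u, (uword)N * T, dropout, training);
      out %= cc.mask;
      cur = cube(out.memptr(), u, N, T);
    } else {
      mat hT = cc.H.slice(T - 1);
      mat out;
      bn_forward(hT, up.layers[l].gam, up.layers[l].bet, rmean[l], rvar[l],
                 bn_momentum, bn_eps, training, cc.xhat, cc.mu, cc.invstd, out);
      cc.mask = dropout_mask(u, N, dropout, training);
      out %= cc.mask;
      h_final = out;
    }
  }

  rowvec z = up.w_out.t() * h_final + up.b_out;
  rowvec p = 1.0 / (1.0 + exp(-z));

  double loss = NA_REAL;
  if (y.n_elem == (uword)N) {
    rowvec pc = clamp(p, 1e-7, 1.0 - 1e-7);
    loss = -accu(y.t() % log(pc) + (1.0 - y.t()) % log(1.0 - pc)) / N;
  }

  // pack updated running stats
  vec state_out(state.n_elem);
  {
    uword pos = 0;
    for (uword l = 0; l < nl; ++l) {
      int u = units(l);
      state_out.subvec(pos, pos + u - 1) = rmean[l]; pos += u;
      state_out.subvec(pos, pos + u - 1) = rvar[l]; pos += u;
    }
  }

  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("probs") = Rcpp::NumericVector(p.begin(), p.end()),
      Rcpp::Named("loss") = loss,
      Rcpp::Named("state") = Rcpp::NumericVector(state_out.begin(),
                                                 state_out.end()));
  if (!compute_grad) return res;
  if (y.n_elem != (uword)N) Rcpp::stop("targets required to compute gradients");

  // ---- backward ----
  vec grad(params.n_elem, fill::zeros);
  rowvec dz = (p - y.t()) / (double)N;
  vec dw_out = h_final * dz.t();
  double db_out = accu(dz);
  mat dh = up.w_out * dz;  // (u_K, N)

  // upstream sequence gradient for the layer below, filled per iteration
  cube dHext;
  for (int l = nl - 1; l >= 0; --l) {
    const int u = units(l);
    LayerCache& cc = cache[l];
    vec dgam, dbet;
    cube dHseq(u, N, T, fill::zeros);
    if ((uword)l == nl - 1) {
      mat dmask = dh % cc.mask;
      mat dhT = bn_backward(dmask, cc.xhat, cc.invstd, up.layers[l].gam,
                            dgam, dbet);
      dHseq.slice(T - 1) = dhT;
    } else {
      mat dOut(dHext.memptr(), u, (uword)N * T, false, true);
      mat dmask = dOut % cc.mask;
      mat dHmat = bn_backward(dmask, cc.xhat, cc.invstd, up.layers[l].gam,
                              dgam, dbet);
      dHseq = cube(dHmat.memptr(), u, N, T);
    }

    // BPTT
    cube dA(4 * u, N, T);
    mat dhnext(u, N, fill::zeros), dcnext(u, N, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dht = dHseq.slice(t) + dhnext;
      const mat& i = cc.I.slice(t); const mat& f = cc.F.slice(t);
      const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
      const mat& tc = cc.TC.slice(t);
      mat do_ = dht % tc;
      mat dc = dht % o % (1.0 - tc % tc) + dcnext;
      mat cprev = (t > 0) ? cc.C.slice(t - 1) : mat(u, N, fill::zeros);
      mat di = dc % g, df = dc % cprev, dg = dc % i;
      mat& dAt = dA.slice(t);
      dAt.rows(0, u - 1) = di % i % (1.0 - i);
      dAt.rows(u, 2 * u - 1) = df % f % (1.0 - f);
      dAt.rows(2 * u, 3 * u - 1) = dg % (1.0 - g % g);
      dAt.rows(3 * u, 4 * u - 1) = do_ % o % (1.0 - o);
      dhnext = up.layers[l].Wh.t() * dAt;
      dcnext = dc % f;
    }

    const int din = inputs[l].n_rows;
    mat dAmat(dA.memptr(), 4 * u, (uword)N * T, false, true);
    mat Xinmat(inputs[l].memptr(), din, (uword)N * T, false, true);
    mat Hmat(cc.H.memptr(), u, (uword)N * T, false, true);
    mat dWx = dAmat * Xinmat.t();
    mat dWh(4 * u, u, fill::zeros);
    if (T > 1)
      dWh = dAmat.cols(N, (uword)N * T - 1) *
            Hmat.cols(0, (uword)N * (T - 1) - 1).t();
    vec db = sum(dAmat, 1);

    // place grads: compute this layer's offset
    uword pos = 0;
    int dprev = d;
    for (int k = 0; k < l; ++k) {
      int uk = units(k);
      pos += 4 * uk * dprev + 4 * uk * uk + 4 * uk + 2 * uk;
      dprev = uk;
    }
    grad.subvec(pos, pos + 4 * u * din - 1) = vectorise(dWx);
    pos += 4 * u * din;
    grad.subvec(pos, pos + 4 * u * u - 1) = vectorise(dWh);
    pos += 4 * u * u;
    grad.subvec(pos, pos + 4 * u - 1) = db; pos += 4 * u;
    grad.subvec(pos, pos + u - 1) = dgam; pos += u;
    grad.subvec(pos, pos + u - 1) = dbet; pos += u;

    if (l > 0) {
      mat dXin = up.layers[l].Wx.t() * dAmat;  // (din, N*T)
      dHext = cube(dXin.memptr(), din, N, T);
    }
  }

  // dense grads at the tail of the vector
  uword pos = params.n_elem - up.w_out.n_elem - 1;
  grad.subvec(pos, pos + up.w_out.n_elem - 1) = dw_out;
  grad(params.n_elem - 1) = db_out;

  res["grad"] = Rcpp::NumericVector(grad.begin(), grad.end());
  return res;
}
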