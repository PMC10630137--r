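// Alternating max-min training of the dual ICNN potential pair.
//
// The R level owns initialization, configuration, and all user-facing
// semantics; this file only implements the per-iteration numerics (forward
// passes, exact input-gradients, parameter gradients of the dual objectives
// including the forward-over-reverse second-order terms through the gradient
// map, Adam, and the loop itself). The R implementations of the same
// primitives serve as independent oracles in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  std::vector<mat> Wx;      // layer i: d x w_i
  std::vector<mat> Wz;      // layer i >= 1: w_{i-1} x w_i (Wz[0] unused)
  std::vector<rowvec> b;    // layer i: w_i
  int act;                  // 0 = leaky rectifier, 1 = softplus
  double slope;
  int L;                    // number of layers incl. final linear layer
};

struct Grads {
  std::vector<mat> Wx, Wz;
  std::vector<rowvec> b;
};

Grads zero_grads(const Net& n) {
  Grads g;
  g.Wx.resize(n.L);
  g.Wz.resize(n.L);
  g.b.resize(n.L);
  for (int i = 0; i < n.L; ++i) {
    g.Wx[i] = zeros<mat>(n.Wx[i].n_rows, n.Wx[i].n_cols);
    if (i > 0) g.Wz[i] = zeros<mat>(n.Wz[i].n_rows, n.Wz[i].n_cols);
    g.b[i] = zeros<rowvec>(n.b[i].n_elem);
  }
  return g;
}

mat act_f(const Net& n, const mat& Z) {
  if (n.act == 0) return max(Z, zeros<mat>(size(Z))) + n.slope * min(Z, zeros<mat>(size(Z)));
  return log1p(exp(-abs(Z))) + max(Z, zeros<mat>(size(Z)));
}

mat act_d1(const Net& n, const mat& Z) {
  if (n.act == 0) {
    mat D(size(Z));
    D.fill(n.slope);
    D.elem(find(Z > 0)).fill(1.0);
    return D;
  }
  return 1.0 / (1.0 + exp(-Z));
}

mat act_d2(const Net& n, const mat& Z) {
  if (n.act == 0) return zeros<mat>(size(Z));
  mat p = 1.0 / (1.0 + exp(-Z));
  return p % (1.0 - p);
}

// Forward pass keeping pre-activations (Z) and activations (H).
void forward_cache(const Net& net, const mat& X,
                   std::vector<mat>& Z, std::vector<mat>& H) {
  Z.resize(net.L);
  H.resize(net.L);
  for (int i = 0; i < net.L; ++i) {
    mat Zi = X * net.Wx[i];
    if (i > 0) Zi += H[i - 1] * net.Wz[i];
    Zi.each_row() += net.b[i];
    Z[i] = Zi;
    H[i] = (i < net.L - 1) ? act_f(net, Zi) : Zi;  // final layer linear
  }
}

vec forward_value(const Net& net, const mat& X) {
  std::vector<mat> Z, H;
  forward_cache(net, X, Z, H);
  return H[net.L - 1].col(0);
}

// grad_x of the scalar potential, per row of X, given a forward cache.
mat grad_x(const Net& net, const std::vector<mat>& Z) {
  int L = net.L;
  const uword n = Z[0].n_rows;
  mat G = ones<mat>(n, 1);
  mat grad = G * net.Wx[L - 1].t();
  for (int i = L - 2; i >= 0; --i) {
    mat GH = G * net.Wz[i + 1].t();
    G = act_d1(net, Z[i]) % GH;
    grad += G * net.Wx[i].t();
  }
  return grad;
}

mat grad_x_full(const Net& net, const mat& X) {
  std::vector<mat> Z, H;
  forward_cache(net, X, Z, H);
  return grad_x(net, Z);
}

// Accumulate parameter gradients of sum_j c_j * f(x_j).
void value_param_grads(const Net& net, const mat& X,
                       const std::vector<mat>& Z, const std::vector<mat>& H,
                       const vec& cvec, Grads& g) {
  mat G = cvec;  // n x 1
  for (int i = net.L - 1; i >= 0; --i) {
    g.Wx[i] += X.t() * G;
    g.b[i] += sum(G, 0);
    if (i > 0) {
      g.Wz[i] += H[i - 1].t() * G;
      G = act_d1(net, Z[i - 1]) % (G * net.Wz[i].t());
    }
  }
}

// Accumulate parameter gradients of sum_j u_j . grad_x f(x_j)
// (forward-over-reverse; needed because the dual objective differentiates
// through the gradient map of g).
void gvp_param_grads(const Net& net, const mat& X,
                     const std::vector<mat>& Z, const std::vector<mat>& H,
                     const mat& U, Grads& g) {
  int L = net.L;
  const uword n = X.n_rows;
  std::vector<mat> Zdot(L), Hdot(L), D1(L), D2(L);
  for (int i = 0; i < L - 1; ++i) {
    mat zd = U * net.Wx[i];
    if (i > 0) zd += Hdot[i - 1] * net.Wz[i];
    Zdot[i] = zd;
    D1[i] = act_d1(net, Z[i]);
    D2[i] = act_d2(net, Z[i]);
    Hdot[i] = D1[i] % zd;
  }
  mat ones_n = ones<mat>(n, 1);
  g.Wx[L - 1] += U.t() * ones_n;
  g.Wz[L - 1] += Hdot[L - 2].t() * ones_n;
  mat GHdot = ones_n * net.Wz[L - 1].t();
  mat GH;  // empty until the primal chain first contributes
  for (int i = L - 2; i >= 0; --i) {
    mat GZdot = D1[i] % GHdot;
    mat GZ = D2[i] % Zdot[i] % GHdot;
    if (GH.n_elem > 0) GZ += D1[i] % GH;
    g.Wx[i] += U.t() * GZdot + X.t() * GZ;
    g.b[i] += sum(GZ, 0);
    if (i > 0) {
      g.Wz[i] += Hdot[i - 1].t() * GZdot + H[i - 1].t() * GZ;
      GHdot = GZdot * net.Wz[i].t();
      GH = GZ * net.Wz[i].t();
    }
  }
}

double penalty(const Net& net) {
  double tot = 0.0;
  for (int i = 1; i < net.L; ++i) {
    mat neg = min(net.Wz[i], zeros<mat>(size(net.Wz[i])));
    tot += accu(neg % neg);
  }
  return tot;
}

void add_penalty_grads(const Net& net, double lambda, Grads& g) {
  for (int i = 1; i < net.L; ++i)
    g.Wz[i] += 2.0 * lambda * min(net.Wz[i], zeros<mat>(size(net.Wz[i])));
}

struct Adam {
  Grads m, v;
  long t = 0;
};

void adam_step(Net& net, const Grads& g, Adam& st,
               double lr, double b1, double b2, double eps = 1e-8) {
  st.t += 1;
  const double c1 = 1.0 - std::pow(b1, (double)st.t);
  const double c2 = 1.0 - std::pow(b2, (double)st.t);
  for (int i = 0; i < net.L; ++i) {
    st.m.Wx[i] = b1 * st.m.Wx[i] + (1 - b1) * g.Wx[i];
    st.v.Wx[i] = b2 * st.v.Wx[i] + (1 - b2) * (g.Wx[i] % g.Wx[i]);
    net.Wx[i] -= lr * (st.m.Wx[i] / c1) / (sqrt(st.v.Wx[i] / c2) + eps);
    st.m.b[i] = b1 * st.m.b[i] + (1 - b1) * g.b[i];
    st.v.b[i] = b2 * st.v.b[i] + (1 - b2) * (g.b[i] % g.b[i]);
    net.b[i] -= lr * (st.m.b[i] / c1) / (sqrt(st.v.b[i] / c2) + eps);
    if (i > 0) {
      st.m.Wz[i] = b1 * st.m.Wz[i] + (1 - b1) * g.Wz[i];
      st.v.Wz[i] = b2 * st.v.Wz[i] + (1 - b2) * (g.Wz[i] % g.Wz[i]);
      net.Wz[i] -= lr * (st.m.Wz[i] / c1) / (sqrt(st.v.Wz[i] / c2) + eps);
    }
  }
}

void project_nonneg(Net& net) {
  for (int i = 1; i < net.L; ++i)
    net.Wz[i] = max(net.Wz[i], zeros<mat>(size(net.Wz[i])));
}

// Replacement-free epoch shuffler driven by R's RNG (deterministic under
// set.seed on the R side).
struct Sampler {
  uvec perm;
  uword pos = 0, n = 0, bs = 0;
  void reshuffle() {
    Rcpp::IntegerVector p = Rcpp::sample((int)n, (int)n);
    perm.set_size(n);
    for (uword i = 0; i < n; ++i) perm[i] = (uword)(p[i] - 1);
    pos = 0;
  }
  uvec next() {
    if (pos + bs > n) reshuffle();
    uvec idx = perm.subvec(pos, pos + bs - 1);
    pos += bs;
    return idx;
  }
};

Net net_from_r(Rcpp::List params, Rcpp::List meta) {
  Net n;
  Rcpp::IntegerVector widths = meta["widths"];
  n.L = widths.size();
  n.act = Rcpp::as<int>(meta["act"]);
  n.slope = Rcpp::as<double>(meta["slope"]);
  n.Wx.resize(n.L);
  n.Wz.resize(n.L);
  n.b.resize(n.L);
  for (int i = 0; i < n.L; ++i) {
    n.Wx[i] = Rcpp::as<mat>(params["Wx" + std::to_string(i + 1)]);
    if (i > 0) n.Wz[i] = Rcpp::as<mat>(params["Wz" + std::to_string(i + 1)]);
    n.b[i] = Rcpp::as<rowvec>(params["b" + std::to_string(i + 1)]);
  }
  return n;
}

Rcpp::List net_to_r(const Net& n) {
  Rcpp::List out;
  for (int i = 0; i < n.L; ++i) {
    out["Wx" + std::to_string(i + 1)] = n.Wx[i];
    if (i > 0) out["Wz" + std::to_string(i + 1)] = n.Wz[i];
    out["b" + std::to_string(i + 1)] = Rcpp::NumericVector(n.b[i].begin(), n.b[i].end());
  }
  return out;
}

// Unbiased multiscale MMD averaged over gammas (checkpoint selection).
double mmd_mean_multiscale(const mat& X, const mat& Y, const vec& gammas) {
  const uword n = X.n_rows, m = Y.n_rows;
  vec sx = sum(X % X, 1), sy = sum(Y % Y, 1);
  mat Dxx = repmat(sx, 1, n) + repmat(sx.t(), n, 1) - 2.0 * X * X.t();
  mat Dyy = repmat(sy, 1, m) + repmat(sy.t(), m, 1) - 2.0 * Y * Y.t();
  mat Dxy = repmat(sx, 1, m) + repmat(sy.t(), n, 1) - 2.0 * X * Y.t();
  Dxx = max(Dxx, zeros<mat>(size(Dxx)));
  Dyy = max(Dyy, zeros<mat>(size(Dyy)));
  Dxy = max(Dxy, zeros<mat>(size(Dxy)));
  double acc = 0.0;
  for (uword k = 0; k < gammas.n_elem; ++k) {
    const double g = gammas[k];
    const double kxx = (accu(exp(-g * Dxx)) - n) / ((double)n * (n - 1));
    const double kyy = (accu(exp(-g * Dyy)) - m) / ((double)m * (m - 1));
    const double kxy = accu(exp(-g * Dxy)) / ((double)n * m);
    acc += kxx + kyy - 2.0 * kxy;
  }
  return acc / gammas.n_elem;
}

double dual_loss_f_val(const Net& g, const Net& f, const mat& Xb, const mat& Yb) {
  mat Tx = grad_x_full(g, Xb);
  return mean(forward_value(f, Tx)) - mean(forward_value(f, Yb));
}

double dual_loss_g_val(const Net& g, const Net& f, const mat& Xb, double lambda) {
  mat Tx = grad_x_full(g, Xb);
  vec fv = forward_value(f, Tx);
  return mean(fv - sum(Xb % Tx, 1)) + lambda * penalty(g);
}

}  // namespace

// [[Rcpp::export(rng = true)]]
Rcpp::List train_dual_cpp(const arma::mat& X, const arma::mat& Y,
                          Rcpp::List g_init, Rcpp::List f_init,
                          Rcpp::List meta, Rcpp::List cfg,
                          const arma::mat& Xe, const arma::mat& Ye,
                          const arma::vec& gammas) {
  Net g = net_from_r(g_init, meta);
  Net f = net_from_r(f_init, meta);

  const int n_iter = Rcpp::as<int>(cfg["n_iter"]);
  const int inner = Rcpp::as<int>(cfg["inner_g_steps"]);
  const int warm = Rcpp::as<int>(cfg["warmstart_steps"]);
  const double lr = Rcpp::as<double>(cfg["lr"]);
  const double warm_lr = Rcpp::as<double>(cfg["warm_lr"]);
  const double b1 = Rcpp::as<double>(cfg["beta1"]);
  const double b2 = Rcpp::as<double>(cfg["beta2"]);
  const double lambda = Rcpp::as<double>(cfg["lambda"]);
  const int log_every = Rcpp::as<int>(cfg["log_every"]);
  const int ckpt_every = Rcpp::as<int>(cfg["checkpoint_every"]);
  const bool select = Rcpp::as<bool>(cfg["select_by_eval_mmd"]);
  const uword bs_s = std::min((uword)Rcpp::as<int>(cfg["batch_size"]), X.n_rows);
  const uword bs_t = std::min((uword)Rcpp::as<int>(cfg["batch_size"]), Y.n_rows);

  Sampler smp_s; smp_s.n = X.n_rows; smp_s.bs = bs_s; smp_s.reshuffle();
  Sampler smp_t; smp_t.n = Y.n_rows; smp_t.bs = bs_t; smp_t.reshuffle();

  Adam ag; ag.m = zero_grads(g); ag.v = zero_grads(g);
  Adam af; af.m = zero_grads(f); af.v = zero_grads(f);

  // identity warm-start: fit grad g ~ id on source batches (and, so that the
  // alternation starts from the identity coupling on both sides, grad f ~ id
  // on target batches), by minimizing mean ||grad(.) - x||^2 (+ penalty)
  const bool warm_f = Rcpp::as<bool>(cfg["warmstart_f"]);
  if (warm > 0) {
    Adam aw; aw.m = zero_grads(g); aw.v = zero_grads(g);
    Adam awf; awf.m = zero_grads(f); awf.v = zero_grads(f);
    for (int it = 0; it < warm; ++it) {
      uvec idx = smp_s.next();
      mat Xb = X.rows(idx);
      std::vector<mat> Z, H;
      forward_cache(g, Xb, Z, H);
      mat Tx = grad_x(g, Z);
      mat U = 2.0 * (Tx - Xb) / (double)Xb.n_rows;
      Grads gr = zero_grads(g);
      gvp_param_grads(g, Xb, Z, H, U, gr);
      add_penalty_grads(g, lambda, gr);
      adam_step(g, gr, aw, warm_lr, b1, b2);
      if (warm_f) {
        uvec idy = smp_t.next();
        mat Yb = Y.rows(idy);
        std::vector<mat> Zf, Hf;
        forward_cache(f, Yb, Zf, Hf);
        mat Ty = grad_x(f, Zf);
        mat Uf = 2.0 * (Ty - Yb) / (double)Yb.n_rows;
        Grads grf = zero_grads(f);
        gvp_param_grads(f, Yb, Zf, Hf, Uf, grf);
        adam_step(f, grf, awf, warm_lr, b1, b2);
        project_nonneg(f);
      }
    }
  }

  const int n_logs = (log_every > 0) ? (n_iter / log_every + 2) : 2;
  mat logm(n_logs, 4);
  int log_row = 0;

  Rcpp::List best_g, best_f;
  double best_mmd = datum::inf;
  int best_iter = -1;

  for (int it = 1; it <= n_iter; ++it) {
    // ---- f step: single ascent update, then hard projection ----
    uvec is = smp_s.next(), itn = smp_t.next();
    mat Xb = X.rows(is), Yb = Y.rows(itn);
    {
      std::vector<mat> Zg, Hg;
      forward_cache(g, Xb, Zg, Hg);
      mat Tx = grad_x(g, Zg);
      std::vector<mat> Zx, Hx, Zy, Hy;
      forward_cache(f, Tx, Zx, Hx);
      forward_cache(f, Yb, Zy, Hy);
      Grads gr = zero_grads(f);
      vec cx(Tx.n_rows); cx.fill(-1.0 / Tx.n_rows);  // minimize the negation
      vec cy(Yb.n_rows); cy.fill(1.0 / Yb.n_rows);
      value_param_grads(f, Tx, Zx, Hx, cx, gr);
      value_param_grads(f, Yb, Zy, Hy, cy, gr);
      adam_step(f, gr, af, lr, b1, b2);
      project_nonneg(f);
    }

    // ---- inner g steps ----
    for (int j = 0; j < inner; ++j) {
      uvec ig = smp_s.next();
      mat Xg = X.rows(ig);
      std::vector<mat> Zg, Hg;
      forward_cache(g, Xg, Zg, Hg);
      mat Tx = grad_x(g, Zg);
      mat v = grad_x_full(f, Tx);
      mat U = (v - Xg) / (double)Xg.n_rows;
      Grads gr = zero_grads(g);
      gvp_param_grads(g, Xg, Zg, Hg, U, gr);
      add_penalty_grads(g, lambda, gr);
      adam_step(g, gr, ag, lr, b1, b2);
    }

    if ((log_every > 0 && it % log_every == 0) || it == n_iter) {
      const double lf = dual_loss_f_val(g, f, Xb, Yb);
      const double lg = dual_loss_g_val(g, f, Xb, lambda);
      if (!std::isfinite(lf))
        Rcpp::stop("non-finite f-objective (mean f(T(x)) - mean f(y)) at iteration %d", it);
      if (!std::isfinite(lg))
        Rcpp::stop("non-finite g-objective (f(T(x)) - <x,T(x)> + penalty) at iteration %d", it);
      if (log_row < n_logs && (log_row == 0 || logm(log_row - 1, 0) != it)) {
        logm(log_row, 0) = it;
        logm(log_row, 1) = lf;
        logm(log_row, 2) = lg;
        logm(log_row, 3) = penalty(g);
        ++log_row;
      }
    }

    if (select && it % ckpt_every == 0) {
      mat pred = grad_x_full(g, Xe);
      const double m = mmd_mean_multiscale(pred, Ye, gammas);
      if (m < best_mmd) {
        best_mmd = m;
        best_iter = it;
        best_g = net_to_r(g);
        best_f = net_to_r(f);
      }
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("g") = net_to_r(g),
    Rcpp::Named("f") = net_to_r(f),
    Rcpp::Named("log") = logm.rows(0, std::max(log_row - 1, 0)),
    Rcpp::Named("selected_iteration") = n_iter,
    Rcpp::Named("eval_mmd") = R_NilValue);
  if (select && best_iter > 0) {
    out["g"] = best_g;
    out["f"] = best_f;
    out["selected_iteration"] = best_iter;
    out["eval_mmd"] = best_mmd;
  }
  return out;
}

// Thin wrappers so the test suite can cross-check the compiled primitives
// against the plain-R implementations.

// [[Rcpp::export]]
arma::vec icnn_forward_cpp(Rcpp::List params, Rcpp::List meta, const arma::mat& X) {
  Net n = net_from_r(params, meta);
  return forward_value(n, X);
}

// [[Rcpp::export]]
arma::mat icnn_gradient_cpp(Rcpp::List params, Rcpp::List meta, const arma::mat& X) {
  Net n = net_from_r(params, meta);
  return grad_x_full(n, X);
}

// [[Rcpp::export]]
double mmd_mean_cpp(const arma::mat& X, const arma::mat& Y, const arma::vec& gammas) {
  return mmd_mean_multiscale(X, Y, gammas);
}
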