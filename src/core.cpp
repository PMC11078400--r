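// Gibbs sampler core for the conservation-state / trait-variance model.
//
// Node convention (0-based here, 1-based on the R side): leaves 0..L-1,
// internals L..N-1 in postorder, root = N-1.  Edge quantities (state z,
// branch length t, rate multiplier) are indexed by the child node; the
// root carries no edge.  States: 0 = background, 1 = conserved,
// 2 = accelerated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;
static const double PFLOOR = 1e-300;

// ---------------------------------------------------------------------------
// tree

struct TreeC {
  int L, N;
  std::vector<int> parent, child1, child2, post;
  std::vector<double> tlen;
  double med_tlen;
};

static TreeC tree_from_list(List t) {
  TreeC tr;
  tr.L = as<int>(t["L"]);
  tr.N = as<int>(t["N"]);
  IntegerVector p = t["parent"], c1 = t["child1"], c2 = t["child2"],
                po = t["postorder"];
  NumericVector tl = t["tlen"];
  tr.parent.resize(tr.N); tr.child1.resize(tr.N); tr.child2.resize(tr.N);
  tr.post.resize(tr.N);   tr.tlen.resize(tr.N);
  for (int i = 0; i < tr.N; ++i) {
    tr.parent[i] = p[i] - 1;  // root encoded as 0 -> -1
    tr.child1[i] = c1[i] - 1;
    tr.child2[i] = c2[i] - 1;
    tr.post[i]   = po[i] - 1;
    tr.tlen[i]   = tl[i];
  }
  std::vector<double> v(tr.tlen.begin(), tr.tlen.end() - 1);  // root last
  std::sort(v.begin(), v.end());
  int m = (int)v.size();
  tr.med_tlen = (m % 2 == 1) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
  return tr;
}

// ---------------------------------------------------------------------------
// substitution model: P(s) = expm(Q * s) via eigendecomposition when stable

struct QModel {
  arma::mat Q;
  arma::vec pi;
  bool use_eig;
  std::complex<double> U[4][4], Uinv[4][4], ev[4];
};

static void pmat_fill(const QModel& M, double s, double* P);  // row-major 16

static QModel qmodel_build(const arma::mat& Q, const arma::vec& pi) {
  QModel M; M.Q = Q; M.pi = pi; M.use_eig = false;
  arma::cx_vec ev; arma::cx_mat U;
  if (arma::eig_gen(ev, U, Q)) {
    arma::cx_mat Ui;
    if (arma::inv(Ui, U)) {
      for (int i = 0; i < 4; ++i) {
        M.ev[i] = ev(i);
        for (int j = 0; j < 4; ++j) { M.U[i][j] = U(i, j); M.Uinv[i][j] = Ui(i, j); }
      }
      M.use_eig = true;
      double A[16];
      pmat_fill(M, 0.37, A);
      arma::mat B = arma::expmat(Q * 0.37);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j)
          if (std::abs(A[i * 4 + j] - B(i, j)) > 1e-10) M.use_eig = false;
    }
  }
  return M;
}

// fill row-major 4x4 transition matrix expm(Q*s), clamped and row-normalized
static void pmat_fill(const QModel& M, double s, double* P) {
  if (M.use_eig) {
    std::complex<double> e[4];
    for (int k = 0; k < 4; ++k) e[k] = std::exp(M.ev[k] * s);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        std::complex<double> sum(0, 0);
        for (int k = 0; k < 4; ++k) sum += M.U[i][k] * e[k] * M.Uinv[k][j];
        P[i * 4 + j] = sum.real();
      }
  } else {
    arma::mat E = arma::expmat(M.Q * s);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) P[i * 4 + j] = E(i, j);
  }
  for (int i = 0; i < 4; ++i) {
    double rs = 0;
    for (int j = 0; j < 4; ++j) {
      if (P[i * 4 + j] < 0) P[i * 4 + j] = 0;
      rs += P[i * 4 + j];
    }
    if (!(rs > 0) || !std::isfinite(rs))
      stop("non-finite branch transition matrix (s = %f)", s);
    for (int j = 0; j < 4; ++j) P[i * 4 + j] /= rs;
  }
}

static arma::mat pmat(const QModel& M, double s) {
  double buf[16];
  pmat_fill(M, s, buf);
  arma::mat P(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) P(i, j) = buf[i * 4 + j];
  return P;
}

// ---------------------------------------------------------------------------
// chain state

struct Priors {
  double r2_shape, r2_scale, r3_shape, r3_scale;
  double ls2_var, lb_var, rooty_var;
  double phi_alpha, phi_beta;
  double rootz[3];
};

static Priors priors_from_list(List p) {
  Priors pr;
  pr.r2_shape = as<double>(p["r2_shape"]); pr.r2_scale = as<double>(p["r2_scale"]);
  pr.r3_shape = as<double>(p["r3_shape"]); pr.r3_scale = as<double>(p["r3_scale"]);
  pr.ls2_var = as<double>(p["log_sigma2_var"]);
  pr.lb_var  = as<double>(p["log_beta_var"]);
  pr.rooty_var = as<double>(p["root_trait_var"]);
  pr.phi_alpha = as<double>(p["phi_alpha"]);
  pr.phi_beta  = as<double>(p["phi_beta"]);
  NumericVector rz = p["root_state_prior"];
  for (int k = 0; k < 3; ++k) pr.rootz[k] = rz[k];
  return pr;
}

struct ChainC {
  TreeC tr; QModel M; Priors pr;
  int S;
  arma::imat X;    // N x S current nucleotides (0..3)
  arma::imat obs;  // N x S, 1 = fixed observed leaf entry
  arma::vec y;
  std::vector<int> obsy;     // length N, 1 = observed trait
  std::vector<int> latenty;  // node list with latent y
  std::vector<int> z;        // length N
  double r2, r3, s2, b2, b3, a, b, c;
  std::vector<arma::mat> P, LP;  // (node*3 + state); root slots unused
  arma::cube part;               // 4 x S x N scaled partial likelihoods
  arma::mat lsc;                 // S x N cumulative log scale
  std::vector<arma::mat> C;      // per-edge 4x4 site transition counts
  double n_k[3], Sd_k[3], Tl_k[3];
};

static double rate_of(const ChainC& ch, int k) {
  return k == 0 ? 1.0 : (k == 1 ? ch.r2 : ch.r3);
}
static double v_of(const ChainC& ch, int k) {
  return k == 0 ? ch.s2 : (k == 1 ? ch.b2 * ch.s2 : ch.b3 * ch.s2);
}

static void rebuildP(ChainC& ch, int state = -1) {
  int R = ch.tr.N - 1;
  double buf[16];
  for (int i = 0; i < ch.tr.N; ++i) {
    if (i == R) continue;
    for (int k = 0; k < 3; ++k) {
      if (state >= 0 && k != state) continue;
      pmat_fill(ch.M, rate_of(ch, k) * ch.tr.tlen[i], buf);
      arma::mat& P = ch.P[i * 3 + k];
      arma::mat& LP = ch.LP[i * 3 + k];
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          P(a, b) = buf[a * 4 + b];
          LP(a, b) = std::log(std::max(buf[a * 4 + b], PFLOOR));
        }
    }
  }
}

static void rebuild_trait_stats(ChainC& ch) {
  for (int k = 0; k < 3; ++k) { ch.n_k[k] = 0; ch.Sd_k[k] = 0; ch.Tl_k[k] = 0; }
  int R = ch.tr.N - 1;
  for (int j = 0; j < ch.tr.N; ++j) {
    if (j == R) continue;
    int k = ch.z[j];
    double d = ch.y[j] - ch.y[ch.tr.parent[j]];
    ch.n_k[k]  += 1.0;
    ch.Sd_k[k] += d * d / ch.tr.tlen[j];
    ch.Tl_k[k] += std::log(ch.tr.tlen[j]);
  }
}

static double trait_loglik(const ChainC& ch) {
  double ll = 0;
  for (int k = 0; k < 3; ++k) {
    double v = v_of(ch, k);
    ll += -0.5 * ch.n_k[k] * LOG2PI - 0.5 * ch.Tl_k[k]
          - 0.5 * ch.n_k[k] * std::log(v) - ch.Sd_k[k] / (2.0 * v);
  }
  double yR = ch.y[ch.tr.N - 1];
  ll += -0.5 * LOG2PI - 0.5 * std::log(ch.pr.rooty_var)
        - yR * yR / (2.0 * ch.pr.rooty_var);
  return ll;
}

// ---------------------------------------------------------------------------
// Step 2: pruning + forward sampling of ancestral nucleotides

static void prune(ChainC& ch) {
  int N = ch.tr.N, L = ch.tr.L, S = ch.S;
  ch.part.set_size(4, S, N);
  ch.lsc.set_size(S, N);
  for (int idx = 0; idx < N; ++idx) {
    int i = ch.tr.post[idx];
    if (i < L) {
      for (int s = 0; s < S; ++s) {
        double* p = &ch.part(0, s, i);
        if (ch.obs(i, s)) {
          p[0] = p[1] = p[2] = p[3] = 0.0;
          p[ch.X(i, s)] = 1.0;
        } else {
          p[0] = p[1] = p[2] = p[3] = 1.0;
        }
        ch.lsc(s, i) = 0.0;
      }
    } else {
      int c1 = ch.tr.child1[i], c2 = ch.tr.child2[i];
      const arma::mat& P1 = ch.P[c1 * 3 + ch.z[c1]];
      const arma::mat& P2 = ch.P[c2 * 3 + ch.z[c2]];
      for (int s = 0; s < S; ++s) {
        double* out = &ch.part(0, s, i);
        const double* q1 = &ch.part(0, s, c1);
        const double* q2 = &ch.part(0, s, c2);
        double m = 0;
        for (int x = 0; x < 4; ++x) {
          double a1 = 0, a2 = 0;
          for (int w = 0; w < 4; ++w) {
            a1 += P1(x, w) * q1[w];
            a2 += P2(x, w) * q2[w];
          }
          out[x] = a1 * a2;
          if (out[x] > m) m = out[x];
        }
        if (!(m > 0)) stop("zero partial likelihood during pruning");
        for (int x = 0; x < 4; ++x) out[x] /= m;
        ch.lsc(s, i) = std::log(m) + ch.lsc(s, c1) + ch.lsc(s, c2);
      }
    }
  }
}

static double root_loglik(const ChainC& ch) {
  int R = ch.tr.N - 1;
  double ll = 0;
  for (int s = 0; s < ch.S; ++s) {
    double tot = 0;
    for (int x = 0; x < 4; ++x) tot += ch.M.pi(x) * ch.part(x, s, R);
    ll += std::log(tot) + ch.lsc(s, R);
  }
  return ll;
}

static int draw4(const double* w) {
  double tot = w[0] + w[1] + w[2] + w[3];
  if (!(tot > 0)) stop("zero total probability in nucleotide draw");
  double u = R::unif_rand() * tot;
  int x = 0;
  while (x < 3 && u > w[x]) { u -= w[x]; ++x; }
  return x;
}

static void sample_ancestors(ChainC& ch) {
  int N = ch.tr.N, L = ch.tr.L, S = ch.S, R = N - 1;
  for (int s = 0; s < S; ++s) {
    double w[4];
    for (int x = 0; x < 4; ++x) w[x] = ch.M.pi(x) * ch.part(x, s, R);
    ch.X(R, s) = draw4(w);
  }
  for (int idx = N - 1; idx >= 0; --idx) {  // reverse postorder = preorder
    int j = ch.tr.post[idx];
    if (j == R) continue;
    int i = ch.tr.parent[j];
    const arma::mat& Pj = ch.P[j * 3 + ch.z[j]];
    bool leaf = j < L;
    for (int s = 0; s < S; ++s) {
      if (leaf && ch.obs(j, s)) continue;
      int xp = ch.X(i, s);
      double w[4];
      for (int x = 0; x < 4; ++x) w[x] = Pj(xp, x) * ch.part(x, s, j);
      ch.X(j, s) = draw4(w);
    }
  }
}

static void compute_counts(ChainC& ch) {
  int N = ch.tr.N, R = N - 1;
  for (int j = 0; j < N; ++j) {
    if (j == R) continue;
    arma::mat& Cj = ch.C[j];
    Cj.zeros();
    int i = ch.tr.parent[j];
    for (int s = 0; s < ch.S; ++s) Cj(ch.X(i, s), ch.X(j, s)) += 1.0;
  }
}

static double seq_emission(const ChainC& ch, int j, int k) {
  const arma::mat& C = ch.C[j];
  const arma::mat& LP = ch.LP[j * 3 + k];
  double s = 0;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (C(a, b) != 0) s += C(a, b) * LP(a, b);
  return s;
}

static double trait_emission(const ChainC& ch, int j, int k) {
  double tv = ch.tr.tlen[j] * v_of(ch, k);
  double d = ch.y[j] - ch.y[ch.tr.parent[j]];
  return -0.5 * (LOG2PI + std::log(tv)) - d * d / (2.0 * tv);
}

// ---------------------------------------------------------------------------
// Step 3: backward messages over conservation states + root-to-tip sampling

static void phi_matrix(double a, double b, double c, double phi[3][3]) {
  phi[0][0] = 1 - c; phi[0][1] = c;     phi[0][2] = 0;
  phi[1][0] = 0;     phi[1][1] = 1 - a; phi[1][2] = a;
  phi[2][0] = 0;     phi[2][1] = b;     phi[2][2] = 1 - b;
}

static double lse3(const double* v) {
  double m = std::max(v[0], std::max(v[1], v[2]));
  if (!std::isfinite(m)) return -INFINITY;
  return m + std::log(std::exp(v[0] - m) + std::exp(v[1] - m) +
                      std::exp(v[2] - m));
}

static void backward_messages(ChainC& ch, arma::mat& msg) {
  int N = ch.tr.N, L = ch.tr.L, R = N - 1;
  double phi[3][3], lphi[3][3];
  phi_matrix(ch.a, ch.b, ch.c, phi);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      lphi[i][j] = phi[i][j] > 0 ? std::log(phi[i][j]) : -INFINITY;
  msg.set_size(3, N);
  msg.zeros();
  for (int idx = 0; idx < N; ++idx) {
    int i = ch.tr.post[idx];
    if (i == R) continue;
    double childterm[3] = {0, 0, 0};
    if (i >= L) {
      int cs[2] = {ch.tr.child1[i], ch.tr.child2[i]};
      for (int ci = 0; ci < 2; ++ci) {
        int cnode = cs[ci];
        for (int k = 0; k < 3; ++k) {
          double t[3];
          for (int kp = 0; kp < 3; ++kp) t[kp] = lphi[k][kp] + msg(kp, cnode);
          childterm[k] += lse3(t);
        }
      }
    }
    for (int k = 0; k < 3; ++k)
      msg(k, i) = seq_emission(ch, i, k) + trait_emission(ch, i, k) +
                  childterm[k];
  }
}

static int draw3(const double* logw) {
  double m = std::max(logw[0], std::max(logw[1], logw[2]));
  double w[3], tot = 0;
  for (int k = 0; k < 3; ++k) {
    w[k] = std::isfinite(logw[k]) ? std::exp(logw[k] - m) : 0.0;
    tot += w[k];
  }
  if (!(tot > 0)) stop("zero total probability in state draw");
  double u = R::unif_rand() * tot;
  int k = 0;
  while (k < 2 && u > w[k]) { u -= w[k]; ++k; }
  return k;
}

static void sample_states(ChainC& ch, const arma::mat& msg) {
  int N = ch.tr.N, R = N - 1;
  double phi[3][3], lphi[3][3];
  phi_matrix(ch.a, ch.b, ch.c, phi);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      lphi[i][j] = phi[i][j] > 0 ? std::log(phi[i][j]) : -INFINITY;
  double lr[3];
  int cs[2] = {ch.tr.child1[R], ch.tr.child2[R]};
  for (int k = 0; k < 3; ++k) {
    lr[k] = ch.pr.rootz[k] > 0 ? std::log(ch.pr.rootz[k]) : -INFINITY;
    if (!std::isfinite(lr[k])) continue;
    for (int ci = 0; ci < 2; ++ci) {
      double t[3];
      for (int kp = 0; kp < 3; ++kp) t[kp] = lphi[k][kp] + msg(kp, cs[ci]);
      lr[k] += lse3(t);
    }
  }
  ch.z[R] = draw3(lr);
  for (int idx = N - 1; idx >= 0; --idx) {
    int j = ch.tr.post[idx];
    if (j == R) continue;
    int i = ch.tr.parent[j];
    double lw[3];
    for (int kp = 0; kp < 3; ++kp) lw[kp] = lphi[ch.z[i]][kp] + msg(kp, j);
    ch.z[j] = draw3(lw);
  }
}

// ---------------------------------------------------------------------------
// Step 1: Metropolis on (sigma2, beta2, beta3) and latent trait values

static void step1(ChainC& ch, int n_inner, double mix, double sd_par,
                  double sd_y_factor, double* acc) {
  // acc: {par_acc, par_prop, y_acc, y_prop}
  int nl = (int)ch.latenty.size();
  for (int it = 0; it < n_inner; ++it) {
    if (R::unif_rand() < mix) {
      acc[1] += 1;
      int which = (int)(R::unif_rand() * 3.0); if (which > 2) which = 2;
      double dlt = R::norm_rand() * sd_par;
      double lacc = 0;
      double ed = std::exp(dlt);
      if (which == 0) {
        for (int k = 0; k < 3; ++k) {
          double v = v_of(ch, k);
          lacc += -0.5 * ch.n_k[k] * dlt
                  - 0.5 * ch.Sd_k[k] * (1.0 / (v * ed) - 1.0 / v);
        }
        double x = std::log(ch.s2);
        lacc += (x * x - (x + dlt) * (x + dlt)) / (2.0 * ch.pr.ls2_var);
        if (lacc >= 0 || R::unif_rand() < std::exp(lacc)) {
          ch.s2 *= ed; acc[0] += 1;
        }
      } else {
        int k = which;  // state index equals parameter index here
        double v = v_of(ch, k);
        double lacc2 = -0.5 * ch.n_k[k] * dlt
                       - 0.5 * ch.Sd_k[k] * (1.0 / (v * ed) - 1.0 / v);
        double x = std::log(which == 1 ? ch.b2 : ch.b3);
        lacc2 += (x * x - (x + dlt) * (x + dlt)) / (2.0 * ch.pr.lb_var);
        if (lacc2 >= 0 || R::unif_rand() < std::exp(lacc2)) {
          if (which == 1) ch.b2 *= ed; else ch.b3 *= ed;
          acc[0] += 1;
        }
      }
    } else {
      acc[3] += 1;
      int m = ch.latenty[(int)(R::unif_rand() * nl) % nl];
      double sdy = sd_y_factor * std::sqrt(ch.tr.med_tlen * ch.s2);
      double yn = ch.y[m] + R::norm_rand() * sdy;
      double lacc = 0;
      int R = ch.tr.N - 1;
      if (m != R) {
        int i = ch.tr.parent[m];
        double tv = ch.tr.tlen[m] * v_of(ch, ch.z[m]);
        double d0 = ch.y[m] - ch.y[i], d1 = yn - ch.y[i];
        lacc += (d0 * d0 - d1 * d1) / (2.0 * tv);
      } else {
        lacc += (ch.y[m] * ch.y[m] - yn * yn) / (2.0 * ch.pr.rooty_var);
      }
      if (m >= ch.tr.L) {
        int cs[2] = {ch.tr.child1[m], ch.tr.child2[m]};
        for (int ci = 0; ci < 2; ++ci) {
          int cnode = cs[ci];
          double tv = ch.tr.tlen[cnode] * v_of(ch, ch.z[cnode]);
          double d0 = ch.y[cnode] - ch.y[m], d1 = ch.y[cnode] - yn;
          lacc += (d0 * d0 - d1 * d1) / (2.0 * tv);
        }
      }
      if (lacc >= 0 || R::unif_rand() < std::exp(lacc)) {
        // update sufficient statistics for affected branches
        if (m != R) {
          int i = ch.tr.parent[m], k = ch.z[m];
          double d0 = ch.y[m] - ch.y[i], d1 = yn - ch.y[i];
          ch.Sd_k[k] += (d1 * d1 - d0 * d0) / ch.tr.tlen[m];
        }
        if (m >= ch.tr.L) {
          int cs[2] = {ch.tr.child1[m], ch.tr.child2[m]};
          for (int ci = 0; ci < 2; ++ci) {
            int cnode = cs[ci], k = ch.z[cnode];
            double d0 = ch.y[cnode] - ch.y[m], d1 = ch.y[cnode] - yn;
            ch.Sd_k[k] += (d1 * d1 - d0 * d0) / ch.tr.tlen[cnode];
          }
        }
        ch.y[m] = yn;
        acc[2] += 1;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Step 4: Metropolis on rate multipliers r2, r3 (log random walk)

static void step4(ChainC& ch, double sd_r, double* acc) {
  // acc: {r2_acc, r2_prop, r3_acc, r3_prop}
  int R = ch.tr.N - 1;
  for (int k = 1; k <= 2; ++k) {
    acc[2 * (k - 1) + 1] += 1;
    double r = (k == 1) ? ch.r2 : ch.r3;
    double shape = (k == 1) ? ch.pr.r2_shape : ch.pr.r3_shape;
    double scale = (k == 1) ? ch.pr.r2_scale : ch.pr.r3_scale;
    double lr = std::log(r);
    double lrn = lr + R::norm_rand() * sd_r;
    double rn = std::exp(lrn);
    double lacc = 0;
    double buf[16];
    for (int j = 0; j < ch.tr.N; ++j) {
      if (j == R || ch.z[j] != k) continue;
      pmat_fill(ch.M, rn * ch.tr.tlen[j], buf);
      const arma::mat& C = ch.C[j];
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          if (C(a, b) != 0)
            lacc += C(a, b) * std::log(std::max(buf[a * 4 + b], PFLOOR));
      lacc -= seq_emission(ch, j, k);
    }
    lacc += R::dgamma(rn, shape, scale, 1) - R::dgamma(r, shape, scale, 1)
            + lrn - lr;  // Jacobian of the log-scale walk
    if (lacc >= 0 || R::unif_rand() < std::exp(lacc)) {
      if (k == 1) ch.r2 = rn; else ch.r3 = rn;
      rebuildP(ch, k);
      acc[2 * (k - 1)] += 1;
    }
  }
}

// ---------------------------------------------------------------------------
// Step 5: conjugate Beta update of the state transition parameters

static void count_transitions(const ChainC& ch, double n[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) n[i][j] = 0;
  int R = ch.tr.N - 1;
  for (int j = 0; j < ch.tr.N; ++j) {
    if (j == R) continue;
    n[ch.z[ch.tr.parent[j]]][ch.z[j]] += 1.0;
  }
}

static void step5(ChainC& ch) {
  double n[3][3];
  count_transitions(ch, n);
  if (n[1][0] > 0 || n[2][0] > 0 || n[0][2] > 0)
    stop("sampled states contain a structurally forbidden transition");
  double al = ch.pr.phi_alpha, be = ch.pr.phi_beta;
  ch.c = R::rbeta(al + n[0][1], be + n[0][0]);
  ch.a = R::rbeta(al + n[1][2], be + n[1][1]);
  ch.b = R::rbeta(al + n[2][1], be + n[2][2]);
}

// ---------------------------------------------------------------------------
// log joint (Eq. 3 style decomposition, densities of log-scale parameters
// for sigma2/beta2/beta3)

static double log_joint(ChainC& ch) {
  int R = ch.tr.N - 1;
  double phi[3][3];
  phi_matrix(ch.a, ch.b, ch.c, phi);
  double seq = 0, st = 0;
  for (int j = 0; j < ch.tr.N; ++j) {
    if (j == R) continue;
    seq += seq_emission(ch, j, ch.z[j]);
    double p = phi[ch.z[ch.tr.parent[j]]][ch.z[j]];
    st += p > 0 ? std::log(p) : -INFINITY;
  }
  for (int s = 0; s < ch.S; ++s) seq += std::log(ch.M.pi(ch.X(R, s)));
  st += ch.pr.rootz[ch.z[R]] > 0 ? std::log(ch.pr.rootz[ch.z[R]]) : -INFINITY;
  double tra = trait_loglik(ch);
  double pri =
      R::dgamma(ch.r2, ch.pr.r2_shape, ch.pr.r2_scale, 1) +
      R::dgamma(ch.r3, ch.pr.r3_shape, ch.pr.r3_scale, 1) +
      R::dnorm(std::log(ch.s2), 0.0, std::sqrt(ch.pr.ls2_var), 1) +
      R::dnorm(std::log(ch.b2), 0.0, std::sqrt(ch.pr.lb_var), 1) +
      R::dnorm(std::log(ch.b3), 0.0, std::sqrt(ch.pr.lb_var), 1) +
      R::dbeta(ch.a, ch.pr.phi_alpha, ch.pr.phi_beta, 1) +
      R::dbeta(ch.b, ch.pr.phi_alpha, ch.pr.phi_beta, 1) +
      R::dbeta(ch.c, ch.pr.phi_alpha, ch.pr.phi_beta, 1);
  return seq + tra + st + pri;
}

// ---------------------------------------------------------------------------
// assembly

static ChainC chain_build(List tree, const arma::mat& Q, const arma::vec& pi,
                          const arma::imat& X, const arma::imat& obs,
                          const arma::vec& y, IntegerVector obsy,
                          IntegerVector z, NumericVector params, List priors) {
  ChainC ch;
  ch.tr = tree_from_list(tree);
  ch.M = qmodel_build(Q, pi);
  ch.pr = priors_from_list(priors);
  ch.S = X.n_cols;
  ch.X = X - 1;  // R codes 1..4 -> 0..3
  ch.obs = obs; ch.y = y;
  ch.obsy.assign(obsy.begin(), obsy.end());
  ch.z.resize(ch.tr.N);
  for (int i = 0; i < ch.tr.N; ++i) ch.z[i] = z[i] - 1;
  ch.r2 = params["r2"]; ch.r3 = params["r3"];
  ch.s2 = params["sigma2"]; ch.b2 = params["beta2"]; ch.b3 = params["beta3"];
  ch.a = params["a"]; ch.b = params["b"]; ch.c = params["c"];
  for (int i = 0; i < ch.tr.N; ++i)
    if (i >= ch.tr.L || !ch.obsy[i]) ch.latenty.push_back(i);
  ch.P.assign(3 * ch.tr.N, arma::mat(4, 4));
  ch.LP.assign(3 * ch.tr.N, arma::mat(4, 4));
  ch.C.assign(ch.tr.N, arma::mat(4, 4, arma::fill::zeros));
  rebuildP(ch);
  compute_counts(ch);
  rebuild_trait_stats(ch);
  return ch;
}

static NumericVector state_params(const ChainC& ch) {
  return NumericVector::create(
      _["r2"] = ch.r2, _["r3"] = ch.r3, _["sigma2"] = ch.s2,
      _["beta2"] = ch.b2, _["beta3"] = ch.b3, _["a"] = ch.a, _["b"] = ch.b,
      _["c"] = ch.c);
}

// [[Rcpp::export]]
List cpp_run_chain(List tree, arma::mat Q, arma::vec pi, arma::imat X,
                   arma::imat obs, arma::vec y, IntegerVector obsy,
                   IntegerVector z, NumericVector params, List priors,
                   List config) {
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  int n_iter = as<int>(config["n_iter"]);
  int thin = as<int>(config["thin"]);
  int n_inner = as<int>(config["step1_inner"]);
  double mix = as<double>(config["step1_mix"]);
  double sd_par = as<double>(config["prop_sd_log_param"]);
  double sd_yf = as<double>(config["prop_sd_trait_factor"]);
  double sd_r = as<double>(config["prop_sd_log_rate"]);
  int zfreq_from = as<int>(config["zfreq_from"]);  // 1-based iter, 0 = never

  int n_rec = n_iter / thin;
  arma::mat trace(n_rec, 10);
  arma::mat msg;
  arma::mat zfreq(ch.tr.N, 3, arma::fill::zeros);
  int nzrec = 0;
  double acc1[4] = {0, 0, 0, 0}, acc4[4] = {0, 0, 0, 0};
  int row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    step1(ch, n_inner, mix, sd_par, sd_yf, acc1);
    prune(ch);
    sample_ancestors(ch);
    compute_counts(ch);
    backward_messages(ch, msg);
    sample_states(ch, msg);
    rebuild_trait_stats(ch);
    step4(ch, sd_r, acc4);
    step5(ch);
    if (zfreq_from > 0 && it >= zfreq_from) {
      for (int i = 0; i < ch.tr.N; ++i) zfreq(i, ch.z[i]) += 1.0;
      ++nzrec;
    }
    if (it % thin == 0) {
      double lj = log_joint(ch);
      trace(row, 0) = std::log(ch.s2);
      trace(row, 1) = std::log(ch.b2);
      trace(row, 2) = std::log(ch.b3);
      trace(row, 3) = std::log(ch.b3) - std::log(ch.b2);
      trace(row, 4) = ch.r2;
      trace(row, 5) = ch.r3;
      trace(row, 6) = ch.a;
      trace(row, 7) = ch.b;
      trace(row, 8) = ch.c;
      trace(row, 9) = lj;
      ++row;
    }
  }
  if (nzrec > 0) zfreq /= (double)nzrec;
  IntegerVector zout(ch.tr.N);
  for (int i = 0; i < ch.tr.N; ++i) zout[i] = ch.z[i] + 1;
  return List::create(
      _["trace"] = trace,
      _["accept"] = NumericVector::create(
          _["step1_param_acc"] = acc1[0], _["step1_param_prop"] = acc1[1],
          _["step1_trait_acc"] = acc1[2], _["step1_trait_prop"] = acc1[3],
          _["r2_acc"] = acc4[0], _["r2_prop"] = acc4[1],
          _["r3_acc"] = acc4[2], _["r3_prop"] = acc4[3]),
      _["final_params"] = state_params(ch),
      _["final_z"] = zout,
      _["final_y"] = NumericVector(ch.y.begin(), ch.y.end()),
      _["final_X"] = wrap(arma::imat(ch.X + 1)),
      _["zfreq"] = zfreq);
}

// ---------------------------------------------------------------------------
// exported kernels for unit testing and the public R operations

// [[Rcpp::export]]
arma::mat cpp_branch_matrix(arma::mat Q, arma::vec pi, double rate, double t) {
  QModel M = qmodel_build(Q, pi);
  return pmat(M, rate * t);
}

// [[Rcpp::export]]
List cpp_prune(List tree, arma::mat Q, arma::vec pi, arma::imat X,
               arma::imat obs, IntegerVector z, double r2, double r3,
               List priors) {
  arma::vec y(X.n_rows, arma::fill::zeros);
  IntegerVector obsy(X.n_rows);
  NumericVector params = NumericVector::create(
      _["r2"] = r2, _["r3"] = r3, _["sigma2"] = 1.0, _["beta2"] = 1.0,
      _["beta3"] = 1.0, _["a"] = 0.5, _["b"] = 0.5, _["c"] = 0.5);
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  prune(ch);
  int N = ch.tr.N, S = ch.S;
  arma::cube lp(4, S, N);
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < S; ++s)
      for (int x = 0; x < 4; ++x)
        lp(x, s, i) = std::log(std::max(ch.part(x, s, i), PFLOOR)) +
                      ch.lsc(s, i);
  arma::vec site_ll(S);
  int R = N - 1;
  for (int s = 0; s < S; ++s) {
    double tot = 0;
    for (int x = 0; x < 4; ++x) tot += pi(x) * ch.part(x, s, R);
    site_ll(s) = std::log(tot) + ch.lsc(s, R);
  }
  return List::create(_["log_partials"] = lp, _["site_loglik"] = site_ll,
                      _["loglik"] = arma::accu(site_ll));
}

// [[Rcpp::export]]
List cpp_sample_ancestors(List tree, arma::mat Q, arma::vec pi, arma::imat X,
                          arma::imat obs, IntegerVector z, double r2,
                          double r3, List priors, int ndraws) {
  arma::vec y(X.n_rows, arma::fill::zeros);
  IntegerVector obsy(X.n_rows);
  NumericVector params = NumericVector::create(
      _["r2"] = r2, _["r3"] = r3, _["sigma2"] = 1.0, _["beta2"] = 1.0,
      _["beta3"] = 1.0, _["a"] = 0.5, _["b"] = 0.5, _["c"] = 0.5);
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  prune(ch);
  int N = ch.tr.N, S = ch.S;
  arma::cube counts(4, S, N, arma::fill::zeros);
  for (int d = 0; d < ndraws; ++d) {
    sample_ancestors(ch);
    for (int i = 0; i < N; ++i)
      for (int s = 0; s < S; ++s) counts(ch.X(i, s), s, i) += 1.0;
  }
  return List::create(_["counts"] = counts, _["last_X"] = wrap(arma::imat(ch.X + 1)));
}

// [[Rcpp::export]]
List cpp_messages(List tree, arma::mat Q, arma::vec pi, arma::imat X,
                  arma::imat obs, arma::vec y, IntegerVector obsy,
                  IntegerVector z, NumericVector params, List priors) {
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  arma::mat msg;
  backward_messages(ch, msg);
  return List::create(_["messages"] = msg.t());
}

// [[Rcpp::export]]
List cpp_sample_states(List tree, arma::mat Q, arma::vec pi, arma::imat X,
                       arma::imat obs, arma::vec y, IntegerVector obsy,
                       IntegerVector z, NumericVector params, List priors,
                       int ndraws) {
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  arma::mat msg;
  backward_messages(ch, msg);
  arma::mat counts(ch.tr.N, 3, arma::fill::zeros);
  IntegerVector zout(ch.tr.N);
  for (int d = 0; d < ndraws; ++d) {
    sample_states(ch, msg);
    for (int i = 0; i < ch.tr.N; ++i) counts(i, ch.z[i]) += 1.0;
  }
  for (int i = 0; i < ch.tr.N; ++i) zout[i] = ch.z[i] + 1;
  return List::create(_["counts"] = counts, _["last_z"] = zout);
}

// [[Rcpp::export]]
List cpp_step1(List tree, arma::mat Q, arma::vec pi, arma::imat X,
               arma::imat obs, arma::vec y, IntegerVector obsy,
               IntegerVector z, NumericVector params, List priors, int n_inner,
               double mix, double sd_par, double sd_y_factor) {
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  double acc[4] = {0, 0, 0, 0};
  step1(ch, n_inner, mix, sd_par, sd_y_factor, acc);
  return List::create(
      _["params"] = state_params(ch),
      _["y"] = NumericVector(ch.y.begin(), ch.y.end()),
      _["accept"] = NumericVector::create(
          _["param_acc"] = acc[0], _["param_prop"] = acc[1],
          _["trait_acc"] = acc[2], _["trait_prop"] = acc[3]));
}

// [[Rcpp::export]]
List cpp_step4(List tree, arma::mat Q, arma::vec pi, arma::imat X,
               arma::imat obs, arma::vec y, IntegerVector obsy,
               IntegerVector z, NumericVector params, List priors,
               double sd_r) {
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  double acc[4] = {0, 0, 0, 0};
  step4(ch, sd_r, acc);
  return List::create(
      _["params"] = state_params(ch),
      _["accept"] = NumericVector::create(
          _["r2_acc"] = acc[0], _["r2_prop"] = acc[1], _["r3_acc"] = acc[2],
          _["r3_prop"] = acc[3]));
}

// [[Rcpp::export]]
double cpp_log_joint(List tree, arma::mat Q, arma::vec pi, arma::imat X,
                     arma::imat obs, arma::vec y, IntegerVector obsy,
                     IntegerVector z, NumericVector params, List priors) {
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  return log_joint(ch);
}

// [[Rcpp::export]]
double cpp_seq_loglik_pruned(List tree, arma::mat Q, arma::vec pi,
                             arma::imat X, arma::imat obs, IntegerVector z,
                             double r2, double r3, List priors) {
  arma::vec y(X.n_rows, arma::fill::zeros);
  IntegerVector obsy(X.n_rows);
  NumericVector params = NumericVector::create(
      _["r2"] = r2, _["r3"] = r3, _["sigma2"] = 1.0, _["beta2"] = 1.0,
      _["beta3"] = 1.0, _["a"] = 0.5, _["b"] = 0.5, _["c"] = 0.5);
  ChainC ch = chain_build(tree, Q, pi, X, obs, y, obsy, z, params, priors);
  prune(ch);
  return root_loglik(ch);
}
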