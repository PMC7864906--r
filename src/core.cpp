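// Method-of-lines core for the polymerization-distribution model.
// State layout (normalized by the reference mass):
//   [class 1 accessible (n), class 1 inaccessible (n), ..., biomass (m),
//    cumulative CO2, untracked residues (m)]
// Classic RK4 with stability-limited internal sub-stepping; after every
// sub-step tiny negative densities are clipped and the deficit restored
// proportionally within the pool so each pool's carbon is preserved.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

struct Model {
  int n, nc, nm, ne;
  double dp;
  arma::uvec du;                 // indices of uptake-domain bins
  std::vector<arma::mat> K;      // cleavage operators per enzyme
  arma::ivec enz_target;         // 0-based class index per enzyme
  arma::vec enz_tau0;
  arma::mat W;                   // ne x nm producer weights
  arma::mat u0, e0;              // nm x nc
  arma::vec m0, resid_frac;      // nm
  std::vector<arma::mat> sig;    // per community: n x nc necromass density
  arma::vec tau_ac, tau_in;      // nc
  arma::imat gate;               // g x 2: target class, enzyme (0-based)
  arma::vec gate_coef;           // g
  arma::mat inp_ac, inp_in;      // n x nc
};

static Model build_model(const List& plan) {
  Model M;
  M.n = as<int>(plan["n"]);
  M.nc = as<int>(plan["n_class"]);
  M.nm = as<int>(plan["n_mic"]);
  M.ne = as<int>(plan["n_enz"]);
  M.dp = as<double>(plan["dp"]);
  LogicalVector du = plan["du"];
  std::vector<arma::uword> idx;
  for (int i = 0; i < M.n; ++i) if (du[i]) idx.push_back(i);
  M.du = arma::uvec(idx);
  List Klist = plan["K"];
  for (int e = 0; e < M.ne; ++e) M.K.push_back(as<arma::mat>(Klist[e]));
  M.enz_target = as<arma::ivec>(plan["enz_target"]) - 1;
  M.enz_tau0 = as<arma::vec>(plan["enz_tau0"]);
  M.W = as<arma::mat>(plan["W"]);
  M.u0 = as<arma::mat>(plan["u0"]);
  M.e0 = as<arma::mat>(plan["e0"]);
  M.m0 = as<arma::vec>(plan["m0"]);
  M.resid_frac = as<arma::vec>(plan["resid_frac"]);
  List sig = plan["sig"];
  for (int m = 0; m < M.nm; ++m) M.sig.push_back(as<arma::mat>(sig[m]));
  M.tau_ac = as<arma::vec>(plan["tau_ac"]);
  M.tau_in = as<arma::vec>(plan["tau_in"]);
  List gates = plan["gates"];
  int ng = gates.size();
  M.gate.set_size(ng, 2);
  M.gate_coef.set_size(ng);
  for (int g = 0; g < ng; ++g) {
    List gt = gates[g];
    M.gate(g, 0) = as<int>(gt["target"]) - 1;
    M.gate(g, 1) = as<int>(gt["enzyme"]) - 1;
    M.gate_coef(g) = as<double>(gt["coef"]);
  }
  M.inp_ac = as<arma::mat>(plan["inp_ac"]);
  M.inp_in = as<arma::mat>(plan["inp_in"]);
  return M;
}

// views into the packed state
static inline arma::vec ac(const arma::vec& y, const Model& M, int c) {
  return y.subvec(2 * M.n * c, 2 * M.n * c + M.n - 1);
}
static inline arma::vec in(const arma::vec& y, const Model& M, int c) {
  return y.subvec(2 * M.n * c + M.n, 2 * M.n * (c + 1) - 1);
}

static arma::vec deriv(const arma::vec& y, const Model& M) {
  const int n = M.n, nc = M.nc, nm = M.nm;
  arma::vec B = y.subvec(2 * n * nc, 2 * n * nc + nm - 1);
  arma::vec dy(y.n_elem, arma::fill::zeros);

  arma::vec taus = M.enz_tau0 % (M.W * B);
  arma::vec tac = M.tau_ac;
  for (arma::uword g = 0; g < M.gate_coef.n_elem; ++g) {
    int src = M.enz_target(M.gate(g, 1));
    tac(M.gate(g, 0)) += M.gate_coef(g) * taus(M.gate(g, 1)) *
      arma::accu(ac(y, M, src)) * M.dp;
  }
  arma::vec U(nc), upt = M.u0.t() * B;  // per-class uptake C and rate
  for (int c = 0; c < nc; ++c) U(c) = arma::accu(ac(y, M, c).elem(M.du)) * M.dp;

  for (int c = 0; c < nc; ++c) {
    arma::vec xac = ac(y, M, c), xin = in(y, M, c);
    arma::vec dac = tac(c) * xin - M.tau_in(c) * xac + M.inp_ac.col(c);
    dac.elem(M.du) -= upt(c) * xac.elem(M.du);
    arma::vec din = M.tau_in(c) * xac - tac(c) * xin + M.inp_in.col(c);
    for (int e = 0; e < M.ne; ++e) {
      if (M.enz_target(e) == c && taus(e) > 0.0)
        dac += taus(e) * (M.K[e] * xac - xac);
    }
    for (int m = 0; m < nm; ++m) dac += M.m0(m) * B(m) * M.sig[m].col(c);
    dy.subvec(2 * n * c, 2 * n * c + n - 1) = dac;
    dy.subvec(2 * n * c + n, 2 * n * (c + 1) - 1) = din;
  }

  arma::vec assim = (M.u0 % M.e0) * U;            // per community, 1/d
  arma::vec resp = (M.u0 % (1.0 - M.e0)) * U;
  dy.subvec(2 * n * nc, 2 * n * nc + nm - 1) = -M.m0 % B + B % assim;
  dy(2 * n * nc + nm) = arma::accu(B % resp);
  dy.subvec(2 * n * nc + nm + 1, 2 * n * nc + 2 * nm) =
    M.m0 % B % M.resid_frac;
  return dy;
}

// largest biomass-driven decay rate (bounds the stable explicit step)
static double stiffness(const arma::vec& y, const Model& M) {
  const int nc = M.nc, nm = M.nm;
  arma::vec B = y.subvec(2 * M.n * nc, 2 * M.n * nc + nm - 1);
  arma::vec taus = M.enz_tau0 % (M.W * B);
  arma::vec lam(nc, arma::fill::zeros);
  for (int e = 0; e < M.ne; ++e) lam(M.enz_target(e)) += taus(e);
  lam += M.u0.t() * B + M.tau_in;
  double mx = lam.max();
  arma::vec tac = M.tau_ac;
  for (arma::uword g = 0; g < M.gate_coef.n_elem; ++g) {
    int src = M.enz_target(M.gate(g, 1));
    tac(M.gate(g, 0)) += M.gate_coef(g) * taus(M.gate(g, 1)) *
      arma::accu(ac(y, M, src)) * M.dp;
  }
  mx = std::max(mx, tac.max());
  if (M.m0.n_elem) mx = std::max(mx, M.m0.max());
  return mx;
}

// clip tiny negative densities, restoring the deficit proportionally
static void clip_state(arma::vec& y, const Model& M, double clip_tol,
                       double t) {
  const int n = M.n, nc = M.nc, nm = M.nm;
  for (int pool = 0; pool < 2 * nc; ++pool) {
    double* v = y.memptr() + pool * n;
    double neg = 0.0, pos = 0.0;
    for (int i = 0; i < n; ++i) (v[i] < 0.0 ? neg : pos) += v[i];
    if (neg == 0.0) continue;
    if (-neg * M.dp > clip_tol) {
      stop("negative density beyond tolerance (%g g_C) in pool %d at t = %g d",
           -neg * M.dp, pool + 1, t);
    }
    double scale = pos > 0.0 ? (pos + neg) / pos : 0.0;
    for (int i = 0; i < n; ++i) v[i] = v[i] < 0.0 ? 0.0 : v[i] * scale;
  }
  for (int m = 0; m < nm; ++m) {
    double& b = y(2 * n * nc + m);
    if (b < 0.0) {
      if (-b > clip_tol)
        stop("negative biomass (%g) in community %d at t = %g d", b, m + 1, t);
      b = 0.0;
    }
  }
}

// [[Rcpp::export]]
List simulate_core(List plan, NumericVector state0, double dt,
                   double output_every, int n_out, IntegerVector snap_at,
                   double clip_tol, double stab_safety) {
  Model M = build_model(plan);
  arma::vec y = as<arma::vec>(state0);
  const int nc = M.nc, nm = M.nm;
  const int steps_per_out = std::max(1, (int)std::lround(output_every / dt));
  const double h_out = output_every / steps_per_out;

  const int nagg = 3 * nc + 2 * nm + 1;
  arma::mat agg(n_out + 1, nagg);
  arma::vec times(n_out + 1);
  std::vector<arma::vec> snaps;
  std::vector<double> snap_times;

  auto record = [&](int k, double t) {
    times(k) = t;
    int j = 0;
    for (int c = 0; c < nc; ++c) {
      agg(k, j++) = arma::accu(ac(y, M, c)) * M.dp;
      agg(k, j++) = arma::accu(in(y, M, c)) * M.dp;
      agg(k, j++) = arma::accu(ac(y, M, c).elem(M.du)) * M.dp;
    }
    for (int m = 0; m < nm; ++m) agg(k, j++) = y(2 * M.n * nc + m);
    agg(k, j++) = y(2 * M.n * nc + nm);
    for (int m = 0; m < nm; ++m) agg(k, j++) = y(2 * M.n * nc + nm + 1 + m);
    for (int s = 0; s < snap_at.size(); ++s) {
      if (snap_at[s] == k) {
        snaps.push_back(y);
        snap_times.push_back(t);
      }
    }
  };

  record(0, 0.0);
  double t = 0.0;
  for (int k = 1; k <= n_out; ++k) {
    double lam = stiffness(y, M);
    int nsub = std::max(1, (int)std::ceil(h_out * lam / stab_safety));
    double h = h_out / nsub;
    for (int s = 0; s < steps_per_out * nsub; ++s) {
      arma::vec k1 = deriv(y, M);
      arma::vec k2 = deriv(y + 0.5 * h * k1, M);
      arma::vec k3 = deriv(y + 0.5 * h * k2, M);
      arma::vec k4 = deriv(y + h * k3, M);
      y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      clip_state(y, M, clip_tol, t);
      t += h;
    }
    if (!y.is_finite())
      stop("non-finite state at t = %g d (instability; reduce dt)", t);
    record(k, k * output_every);
  }

  arma::mat snap_mat(snaps.size(), y.n_elem);
  for (size_t i = 0; i < snaps.size(); ++i) snap_mat.row(i) = snaps[i].t();
  return List::create(_["times"] = times, _["agg"] = agg,
                      _["snapshots"] = snap_mat,
                      _["snap_times"] = snap_times,
                      _["final_state"] = y);
}
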