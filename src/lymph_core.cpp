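// Numerical core: constitutive relations, nonlinear segment/junction flow
// solves, and the diameter ODE right-hand side for the whole network.
// Kept in C++ because the inner scalar root-finds run inside every RHS
// evaluation of a stiff integration.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Params {
  double mu, L, Pd, M0, f, tr, RVn, RVx, sf, so, dpf, dpo;
  double c1, c2, c3, c4, c5, c6, c7, c8, c10;
  double c9, sd, Da, Db;
  bool md_literal;
  double half_factor;  // 1 = full-L resistance in each half drop, 0.5 = L/2
  double T, Tc;
};

inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// passive tube law f_p(D), dyn/cm^2
inline double tube_law(double D, const Params& pp) {
  double x = D / pp.c9;
  double r = pp.c9 / D;
  return pp.Pd * (pp.c1 * (x - pp.c2) * (x - pp.c2) +
                  pp.c3 * std::exp(pp.c4 * (x - pp.c5)) + pp.c6 +
                  pp.c7 * (x - pp.c8) + pp.c10 * r * r * r);
}

// diameter-dependent muscle length factor M_d(D), dimensionless
inline double muscle_shape(double D, const Params& pp) {
  double first = sigmoid(pp.sd * (D - pp.Da));
  double second = pp.md_literal ? sigmoid(-pp.sd * (D - pp.Da))
                                : sigmoid(-pp.sd * (D - pp.Db));
  return first + second - 1.0;
}

// normalized contraction waveform M_t(t) given contraction start offset
inline double muscle_time(double t, double offset, const Params& pp) {
  double u = t - offset;
  double tau = u - std::floor(u / pp.T) * pp.T;
  if (tau < 0.0) tau += pp.T;
  if (tau >= pp.T) tau -= pp.T;
  if (tau >= pp.Tc) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * pp.f * tau));
}

// valve resistance RV(dp) and its derivative wrt dp
inline double valve_res(double dp, const Params& pp, double* deriv = nullptr) {
  double s1 = sigmoid(pp.sf * (dp - pp.dpf));
  double s2 = sigmoid(-pp.so * (dp - pp.dpo));
  if (deriv)
    *deriv = pp.RVx * (pp.sf * s1 * (1.0 - s1) - pp.so * s2 * (1.0 - s2));
  return pp.RVn + pp.RVx * (s1 + s2 - 1.0);
}

inline double poiseuille(double D, const Params& pp) {
  double D2 = D * D;
  return 64.0 * pp.mu * pp.L / (M_PI * D2 * D2) * pp.half_factor;
}

struct SegState {
  double Q, dpv, RV;
};

// Solve Q*(Rs + RV(dpv)) = dpt with dpv = dpt - Rs*Q (valve present).
// The root is bracketed by [0, dpt/(Rs + 0.9*RVn)] because RV >= RVn - 1e-6*RVx.
// Safeguarded Newton with bisection fallback; warm-started.
SegState solve_valved(double dpt, double Rs, const Params& pp, double warm) {
  SegState st;
  if (dpt == 0.0) {
    st.Q = 0.0;
    st.dpv = 0.0;
    st.RV = valve_res(0.0, pp);
    return st;
  }
  double Qb = dpt / (Rs + 0.9 * pp.RVn);
  double lo = std::min(0.0, Qb), hi = std::max(0.0, Qb);
  // g(lo or hi at the zero end) = -dpt; sign(g(Qb)) = sign(dpt)
  double x = warm;
  if (!std::isfinite(x) || x < lo || x > hi) x = 0.5 * (lo + hi);
  double g = 0.0, RV = 0.0, dpv = 0.0;
  double gscale = std::fabs(dpt);
  for (int it = 0; it < 200; ++it) {
    dpv = dpt - Rs * x;
    double RVp;
    RV = valve_res(dpv, pp, &RVp);
    g = x * (Rs + RV) - dpt;
    if (std::fabs(g) <= 1e-14 * gscale) break;
    // shrink bracket: g has sign -sign(dpt) at the Q = 0 end
    if ((g < 0.0) == (dpt > 0.0)) {
      // same sign as at the zero end -> root is above x (toward Qb side)
      if (dpt > 0.0) lo = x; else hi = x;
    } else {
      if (dpt > 0.0) hi = x; else lo = x;
    }
    double gp = Rs + RV - x * RVp * Rs;
    double xn = (gp != 0.0 && std::isfinite(gp)) ? x - g / gp : lo - 1.0;
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::fabs(xn - x) <= 1e-15 * std::max(std::fabs(x), 1e-300)) {
      x = xn;
      break;
    }
    x = xn;
    if (hi - lo <= 1e-15 * std::max(std::fabs(lo), std::fabs(hi))) break;
  }
  st.Q = x;
  st.dpv = dpt - Rs * x;
  st.RV = valve_res(st.dpv, pp);
  return st;
}

// One resistive path from an upstream pressure through optional valve to a
// downstream pressure. Ru/Rd are the Poiseuille half resistances on each side.
SegState solve_segment(double pu, double pd, double Ru, double Rd, bool valve,
                       const Params& pp, double warm) {
  double dpt = pu - pd, Rs = Ru + Rd;
  if (!valve) {
    SegState st;
    st.Q = dpt / Rs;
    st.dpv = 0.0;
    st.RV = 0.0;
    return st;
  }
  return solve_valved(dpt, Rs, pp, warm);
}

class NetworkModel {
 public:
  Params pp;
  int nlymph = 0, nseg = 0, njunc = 0;
  // segments: kinds 0 = inlet boundary (pa), 1 = lymphangion midpoint,
  //           2 = junction node, 3 = outlet boundary (pb)
  std::vector<int> up_kind, up_idx, dn_kind, dn_idx, has_valve;
  std::vector<int> in_seg, out_seg;          // per lymphangion (0-based)
  std::vector<int> j_c1, j_c2, j_par;        // per junction: segment ids
  std::vector<double> offset;                // contraction start per lymphangion
  double pa = 0, pb = 0, pe = 0;
  // warm starts
  std::vector<double> Qw, pJw;
  // scratch
  std::vector<double> pm, Rv, mt, Q, dpv, RVs, pJ;

  void alloc() {
    Qw.assign(nseg, NA_REAL);
    pJw.assign(njunc, NA_REAL);
    pm.resize(nlymph);
    Rv.resize(nlymph);
    mt.resize(nlymph);
    Q.resize(nseg);
    dpv.resize(nseg);
    RVs.resize(nseg);
    pJ.resize(njunc);
  }

  double node_p(int kind, int idx) const {
    switch (kind) {
      case 0: return pa;
      case 1: return pm[idx];
      case 2: return pJ[idx];
      default: return pb;
    }
  }
  double node_R(int kind, int idx) const {
    return kind == 1 ? Rv[idx] : 0.0;
  }

  void midpoints(double t, const double* D) {
    for (int i = 0; i < nlymph; ++i) {
      if (!(D[i] > 0.0))
        stop("nonpositive diameter encountered (lymphangion %d)", i + 1);
      mt[i] = muscle_time(t, offset[i], pp);
      double fa = 2.0 * pp.M0 * muscle_shape(D[i], pp) * mt[i] / D[i];
      pm[i] = pe + tube_law(D[i], pp) + fa;
      Rv[i] = poiseuille(D[i], pp);
    }
  }

  // junction: two child terminal segments (upstream, valved) meet the
  // parent vessel's first lymphangion (downstream, no valve).
  void solve_junction(int j) {
    int s1 = j_c1[j], s2 = j_c2[j], sp = j_par[j];
    double p1 = pm[up_idx[s1]], R1 = Rv[up_idx[s1]];
    double p2 = pm[up_idx[s2]], R2 = Rv[up_idx[s2]];
    double pp_m = pm[dn_idx[sp]], Rp = Rv[dn_idx[sp]];
    double lo = std::min({p1, p2, pp_m}) - 10.0;
    double hi = std::max({p1, p2, pp_m}) + 10.0;
    double x = pJw[j];
    if (!std::isfinite(x) || x < lo || x > hi) x = 0.5 * (lo + hi);
    SegState a, b;
    double h = 0.0;
    for (int it = 0; it < 200; ++it) {
      a = solve_valved(p1 - x, R1, pp, Qw[s1]);
      b = solve_valved(p2 - x, R2, pp, Qw[s2]);
      Qw[s1] = a.Q;
      Qw[s2] = b.Q;
      double Qp = (x - pp_m) / Rp;
      h = a.Q + b.Q - Qp;
      double qsc = std::max({std::fabs(a.Q), std::fabs(b.Q), std::fabs(Qp),
                             1e-12});
      if (std::fabs(h) <= 1e-13 * qsc) break;
      if (h > 0.0) lo = x; else hi = x;  // h is decreasing in pJ
      // implicit derivatives of the child flows wrt pJ
      double hp = -1.0 / Rp;
      {
        double RVp1, RVp2;
        double RV1 = valve_res(a.dpv, pp, &RVp1);
        double RV2 = valve_res(b.dpv, pp, &RVp2);
        double d1 = R1 + RV1 - a.Q * RVp1 * R1;
        double d2 = R2 + RV2 - b.Q * RVp2 * R2;
        if (d1 != 0.0) hp += (a.Q * RVp1 - 1.0) / d1;
        if (d2 != 0.0) hp += (b.Q * RVp2 - 1.0) / d2;
      }
      double xn = (hp != 0.0 && std::isfinite(hp)) ? x - h / hp : lo - 1.0;
      if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
      if (std::fabs(xn - x) <= 4e-16 * std::max(std::fabs(x), 1.0)) {
        x = xn;
        break;
      }
      x = xn;
      if (hi - lo <= 4e-16 * std::max(std::fabs(lo) + std::fabs(hi), 1.0))
        break;
    }
    pJ[j] = x;
    pJw[j] = x;
    a = solve_valved(p1 - x, R1, pp, Qw[s1]);
    b = solve_valved(p2 - x, R2, pp, Qw[s2]);
    Q[s1] = a.Q; dpv[s1] = a.dpv; RVs[s1] = a.RV; Qw[s1] = a.Q;
    Q[s2] = b.Q; dpv[s2] = b.dpv; RVs[s2] = b.RV; Qw[s2] = b.Q;
    // mass balance holds exactly by construction; the residual of the
    // converged root find lands in the parent momentum equation instead,
    // where it is checked against the monolithic oracle.
    Q[sp] = a.Q + b.Q; dpv[sp] = 0.0; RVs[sp] = 0.0;
  }

  void flows(double t, const double* D) {
    midpoints(t, D);
    for (int j = 0; j < njunc; ++j) solve_junction(j);
    for (int s = 0; s < nseg; ++s) {
      if (up_kind[s] == 2 || dn_kind[s] == 2) continue;  // junction-owned
      double pu = node_p(up_kind[s], up_idx[s]);
      double pd = node_p(dn_kind[s], dn_idx[s]);
      double Ru = node_R(up_kind[s], up_idx[s]);
      double Rd = node_R(dn_kind[s], dn_idx[s]);
      SegState st = solve_segment(pu, pd, Ru, Rd, has_valve[s] != 0, pp, Qw[s]);
      Q[s] = st.Q; dpv[s] = st.dpv; RVs[s] = st.RV;
      Qw[s] = st.Q;
    }
  }

  void rhs(double t, const double* D, double* dDdt) {
    flows(t, D);
    for (int i = 0; i < nlymph; ++i)
      dDdt[i] = 2.0 * (Q[in_seg[i]] - Q[out_seg[i]]) / (M_PI * D[i] * pp.L);
  }
};

Params params_from_list(const List& p) {
  Params pp;
  pp.mu = p["mu"]; pp.L = p["L"]; pp.Pd = p["Pd"]; pp.M0 = p["M0"];
  pp.f = p["f"]; pp.tr = p["tr"]; pp.RVn = p["RVn"]; pp.RVx = p["RVx"];
  pp.sf = p["sf"]; pp.so = p["so"]; pp.dpf = p["dpf"]; pp.dpo = p["dpo"];
  pp.c1 = p["c1"]; pp.c2 = p["c2"]; pp.c3 = p["c3"]; pp.c4 = p["c4"];
  pp.c5 = p["c5"]; pp.c6 = p["c6"]; pp.c7 = p["c7"]; pp.c8 = p["c8"];
  pp.c10 = p["c10"]; pp.c9 = p["c9"]; pp.sd = p["sd"];
  pp.Da = p["Da"]; pp.Db = p["Db"];
  pp.md_literal = as<bool>(p["md_literal"]);
  pp.half_factor = as<bool>(p["half_segment"]) ? 0.5 : 1.0;
  pp.Tc = 1.0 / pp.f;
  pp.T = pp.Tc + pp.tr;
  return pp;
}

}  // namespace

// [[Rcpp::export(name = ".model_build")]]
SEXP model_build(List params, List segs, IntegerVector in_seg,
                 IntegerVector out_seg, List juncs, NumericVector offsets,
                 double pa, double pb, double pe) {
  NetworkModel* m = new NetworkModel();
  m->pp = params_from_list(params);
  m->nlymph = in_seg.size();
  IntegerVector uk = segs["up_kind"], ui = segs["up_idx"],
                dk = segs["dn_kind"], di = segs["dn_idx"],
                hv = segs["has_valve"];
  m->nseg = uk.size();
  m->up_kind.assign(uk.begin(), uk.end());
  m->up_idx.assign(ui.begin(), ui.end());
  m->dn_kind.assign(dk.begin(), dk.end());
  m->dn_idx.assign(di.begin(), di.end());
  m->has_valve.assign(hv.begin(), hv.end());
  m->in_seg.assign(in_seg.begin(), in_seg.end());
  m->out_seg.assign(out_seg.begin(), out_seg.end());
  IntegerVector c1 = juncs["child_seg1"], c2 = juncs["child_seg2"],
                jp = juncs["parent_seg"];
  m->njunc = c1.size();
  m->j_c1.assign(c1.begin(), c1.end());
  m->j_c2.assign(c2.begin(), c2.end());
  m->j_par.assign(jp.begin(), jp.end());
  m->offset.assign(offsets.begin(), offsets.end());
  m->pa = pa; m->pb = pb; m->pe = pe;
  m->alloc();
  XPtr<NetworkModel> ptr(m, true);
  return ptr;
}

// [[Rcpp::export(name = ".model_rhs")]]
NumericVector model_rhs(SEXP ptr, double t, NumericVector D) {
  XPtr<NetworkModel> m(ptr);
  NumericVector out(m->nlymph);
  m->rhs(t, D.begin(), out.begin());
  return out;
}

// [[Rcpp::export(name = ".model_flow")]]
List model_flow(SEXP ptr, double t, NumericVector D) {
  XPtr<NetworkModel> m(ptr);
  std::vector<double> dDdt(m->nlymph);
  m->rhs(t, D.begin(), dDdt.data());
  NumericVector p1(m->nlymph), p2(m->nlymph);
  for (int i = 0; i < m->nlymph; ++i) {
    p1[i] = m->pm[i] + m->Rv[i] * m->Q[m->in_seg[i]];
    p2[i] = m->pm[i] - m->Rv[i] * m->Q[m->out_seg[i]];
  }
  return List::create(
      _["dDdt"] = NumericVector(dDdt.begin(), dDdt.end()),
      _["Q"] = NumericVector(m->Q.begin(), m->Q.end()),
      _["dp_valve"] = NumericVector(m->dpv.begin(), m->dpv.end()),
      _["RV"] = NumericVector(m->RVs.begin(), m->RVs.end()),
      _["p_mid"] = NumericVector(m->pm.begin(), m->pm.end()),
      _["p_up"] = p1, _["p_dn"] = p2,
      _["p_junction"] = NumericVector(m->pJ.begin(), m->pJ.end()),
      _["Mt"] = NumericVector(m->mt.begin(), m->mt.end()),
      _["R_half"] = NumericVector(m->Rv.begin(), m->Rv.end()));
}

// [[Rcpp::export(name = ".model_outlet_flow")]]
NumericVector model_outlet_flow(SEXP ptr, NumericVector t, NumericMatrix D,
                                int outlet_seg) {
  XPtr<NetworkModel> m(ptr);
  int nt = t.size();
  NumericVector out(nt);
  std::vector<double> dDdt(m->nlymph);
  for (int k = 0; k < nt; ++k) {
    NumericMatrix::Row row = D(k, _);
    std::vector<double> d(row.begin(), row.end());
    m->flows(t[k], d.data());
    out[k] = m->Q[outlet_seg];
  }
  return out;
}

// [[Rcpp::export(name = ".model_reset_warm")]]
void model_reset_warm(SEXP ptr) {
  XPtr<NetworkModel> m(ptr);
  std::fill(m->Qw.begin(), m->Qw.end(), NA_REAL);
  std::fill(m->pJw.begin(), m->pJw.end(), NA_REAL);
}

// scalar helpers exposed for cross-checking the R-level formulas
// [[Rcpp::export(name = ".core_segment_flow")]]
List core_segment_flow(double p_up, double p_down, double R_up, double R_down,
                       bool has_valve, List params) {
  Params pp = params_from_list(params);
  SegState st = solve_segment(p_up, p_down, R_up, R_down, has_valve, pp,
                              NA_REAL);
  return List::create(_["Q"] = st.Q, _["dp_valve"] = st.dpv,
                      _["RV"] = st.RV);
}
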