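// Computational core of the 3D vertex model: polygonal-face geometry,
// analytic energy gradients, the overdamped integration loop with active-T1
// triggering, a 3D convex hull (for Thomson-dual seeding), and the
// triangle-intersection self-overlap screen.
//
// Vertex layout: positions are a (2V x 3) matrix; rows 0..V-1 are apical
// vertices, rows V..2V-1 the basal partners (identical index correspondence).
// Cell faces are cyclic apical-vertex index lists, counterclockwise as seen
// from outside the shell, so that
//   - the apical face in stored order has its normal pointing away from the
//     lumen (used for the lumen volume),
//   - the basal face in stored order points away from the cell,
//   - the lateral quad (a_u, a_v, b_v, b_u) of a junction whose first cell
//     traverses u->v points outward from that cell.
// All faces (generally non-planar) are triangulated by a fan from the vertex
// centroid; signed volumes use the divergence theorem about the origin.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

struct Topology {
  int nv;                  // apical vertex count (total vertices = 2*nv)
  int nc;                  // cells
  int ne;                  // junctions
  std::vector<int> cptr;   // nc+1 offsets into cvert
  std::vector<int> cvert;  // concatenated apical vertex ids (0-based)
  std::vector<int> ju, jv, jcu, jcv;  // junction edge (u,v); cells (u->v, v->u)
};

static Topology make_topology(int nv, const IntegerVector& cell_ptr,
                              const IntegerVector& cell_vert,
                              const IntegerMatrix& junc) {
  Topology T;
  T.nv = nv;
  T.nc = cell_ptr.size() - 1;
  T.ne = junc.nrow();
  T.cptr.assign(cell_ptr.begin(), cell_ptr.end());
  T.cvert.assign(cell_vert.begin(), cell_vert.end());
  T.ju.resize(T.ne); T.jv.resize(T.ne); T.jcu.resize(T.ne); T.jcv.resize(T.ne);
  for (int j = 0; j < T.ne; ++j) {
    T.ju[j] = junc(j, 0); T.jv[j] = junc(j, 1);
    T.jcu[j] = junc(j, 2); T.jcv[j] = junc(j, 3);
  }
  return T;
}

// area and signed fan volume (about origin) of the polygon with vertex
// positions P[idx[k]] in stored order
static void polygon_area_volume(const double* P, const int* idx, int m,
                                double* area, double* vol) {
  double g[3] = {0, 0, 0};
  for (int k = 0; k < m; ++k)
    for (int d = 0; d < 3; ++d) g[d] += P[3 * idx[k] + d];
  for (int d = 0; d < 3; ++d) g[d] /= m;
  double A = 0, V = 0, n[3], e1[3], e2[3], ab[3];
  for (int k = 0; k < m; ++k) {
    const double* a = P + 3 * idx[k];
    const double* b = P + 3 * idx[(k + 1) % m];
    for (int d = 0; d < 3; ++d) { e1[d] = a[d] - g[d]; e2[d] = b[d] - g[d]; }
    cross3(e1, e2, n);
    A += 0.5 * norm3(n);
    cross3(a, b, ab);
    V += dot3(g, ab) / 6.0;
  }
  *area = A;
  *vol = V;
}

// accumulate wA * dA/dx + wV * dV/dx into G for the same fan triangulation
static void polygon_grad(const double* P, const int* idx, int m,
                         double wA, double wV, double* G) {
  if (wA == 0.0 && wV == 0.0) return;
  double g[3] = {0, 0, 0};
  for (int k = 0; k < m; ++k)
    for (int d = 0; d < 3; ++d) g[d] += P[3 * idx[k] + d];
  for (int d = 0; d < 3; ++d) g[d] /= m;
  double gg[3] = {0, 0, 0};  // gradient wrt the centroid
  double e1[3], e2[3], n[3], u[3], t[3], c1[3], c2[3];
  for (int k = 0; k < m; ++k) {
    int ia = idx[k], ib = idx[(k + 1) % m];
    const double* a = P + 3 * ia;
    const double* b = P + 3 * ib;
    double* Ga = G + 3 * ia;
    double* Gb = G + 3 * ib;
    if (wA != 0.0) {
      for (int d = 0; d < 3; ++d) { e1[d] = a[d] - g[d]; e2[d] = b[d] - g[d]; }
      cross3(e1, e2, n);
      double nn = norm3(n);
      if (nn > 1e-30) {
        for (int d = 0; d < 3; ++d) u[d] = n[d] / nn;
        // triangle (g, a, b): dA/db = u x (a-g)/2, dA/da = (b-g) x u /2
        cross3(u, e1, c1);  // -> dA/db * 2
        cross3(e2, u, c2);  // -> dA/da * 2
        for (int d = 0; d < 3; ++d) {
          double da = 0.5 * c2[d], db = 0.5 * c1[d];
          Ga[d] += wA * da;
          Gb[d] += wA * db;
          gg[d] += wA * (-da - db);
        }
      }
    }
    if (wV != 0.0) {
      // V = g.(a x b)/6: dV/dg = (a x b)/6, dV/da = (b x g)/6, dV/db = (g x a)/6
      cross3(a, b, c1);
      for (int d = 0; d < 3; ++d) gg[d] += wV * c1[d] / 6.0;
      cross3(b, g, c1);
      cross3(g, a, c2);
      for (int d = 0; d < 3; ++d) {
        Ga[d] += wV * c1[d] / 6.0;
        Gb[d] += wV * c2[d] / 6.0;
      }
    }
    (void)t;
  }
  // centroid depends on every face vertex with weight 1/m
  for (int k = 0; k < m; ++k) {
    double* Gk = G + 3 * idx[k];
    for (int d = 0; d < 3; ++d) Gk[d] += gg[d] / m;
  }
}

struct GeomState {
  std::vector<double> area_ap, area_ba, vol_cell;     // per cell
  std::vector<double> area_lat, la, lb;               // per junction
  double vol_lumen;
};

// pass 1: all areas, volumes, and edge lengths
static void compute_geometry(const double* P, const Topology& T, GeomState& S) {
  S.area_ap.assign(T.nc, 0.0);
  S.area_ba.assign(T.nc, 0.0);
  S.vol_cell.assign(T.nc, 0.0);
  S.area_lat.assign(T.ne, 0.0);
  S.la.assign(T.ne, 0.0);
  S.lb.assign(T.ne, 0.0);
  S.vol_lumen = 0.0;
  std::vector<int> buf;
  for (int c = 0; c < T.nc; ++c) {
    int m = T.cptr[c + 1] - T.cptr[c];
    const int* ids = T.cvert.data() + T.cptr[c];
    double A, V;
    polygon_area_volume(P, ids, m, &A, &V);
    S.area_ap[c] = A;
    S.vol_lumen += V;
    S.vol_cell[c] -= V;  // apical face of the cell faces the lumen (reversed)
    buf.resize(m);
    for (int k = 0; k < m; ++k) buf[k] = ids[k] + T.nv;
    polygon_area_volume(P, buf.data(), m, &A, &V);
    S.area_ba[c] = A;
    S.vol_cell[c] += V;
  }
  int q[4];
  double d[3];
  for (int j = 0; j < T.ne; ++j) {
    int u = T.ju[j], v = T.jv[j];
    q[0] = u; q[1] = v; q[2] = v + T.nv; q[3] = u + T.nv;
    double A, V;
    polygon_area_volume(P, q, 4, &A, &V);
    S.area_lat[j] = A;
    S.vol_cell[T.jcu[j]] += V;
    S.vol_cell[T.jcv[j]] -= V;
    for (int dd = 0; dd < 3; ++dd) d[dd] = P[3 * u + dd] - P[3 * v + dd];
    S.la[j] = norm3(d);
    for (int dd = 0; dd < 3; ++dd)
      d[dd] = P[3 * (u + T.nv) + dd] - P[3 * (v + T.nv) + dd];
    S.lb[j] = norm3(d);
  }
}

struct EnergyParts {
  double surface, constraint, line, total;
};

static EnergyParts compute_energy(const GeomState& S, const Topology& T,
                                  double alpha, double beta, double k_cell,
                                  double k_lumen, const double* vt,
                                  double vt_lumen, const double* gamma) {
  EnergyParts E;
  double ws = 0, wc = 0, wl = 0;
  for (int c = 0; c < T.nc; ++c) {
    ws += alpha * S.area_ap[c] + beta * S.area_ba[c];
    double dv = S.vol_cell[c] - vt[c];
    wc += 0.5 * k_cell * dv * dv;
  }
  for (int j = 0; j < T.ne; ++j) {
    ws += S.area_lat[j];  // (1/2) a_l per cell, each quad shared by two cells
    wl += gamma[j] * (S.la[j] + S.lb[j]);
  }
  double dvl = S.vol_lumen - vt_lumen;
  wc += 0.5 * k_lumen * dvl * dvl;
  E.surface = ws; E.constraint = wc; E.line = wl;
  E.total = ws + wc + wl;
  return E;
}

// pass 2: force = -grad(total energy); G must hold 3*2*nv zeroed doubles
static void compute_forces(const double* P, const Topology& T,
                           const GeomState& S, double alpha, double beta,
                           double k_cell, double k_lumen, const double* vt,
                           double vt_lumen, const double* gamma, double* G) {
  double dvl = k_lumen * (S.vol_lumen - vt_lumen);
  std::vector<double> dvc(T.nc);
  for (int c = 0; c < T.nc; ++c) dvc[c] = k_cell * (S.vol_cell[c] - vt[c]);
  std::vector<int> buf;
  for (int c = 0; c < T.nc; ++c) {
    int m = T.cptr[c + 1] - T.cptr[c];
    const int* ids = T.cvert.data() + T.cptr[c];
    polygon_grad(P, ids, m, alpha, dvl - dvc[c], G);
    buf.resize(m);
    for (int k = 0; k < m; ++k) buf[k] = ids[k] + T.nv;
    polygon_grad(P, buf.data(), m, beta, dvc[c], G);
  }
  int q[4];
  for (int j = 0; j < T.ne; ++j) {
    int u = T.ju[j], v = T.jv[j];
    q[0] = u; q[1] = v; q[2] = v + T.nv; q[3] = u + T.nv;
    polygon_grad(P, q, 4, 1.0, dvc[T.jcu[j]] - dvc[T.jcv[j]], G);
    double gj = gamma[j];
    if (gj != 0.0) {
      if (S.la[j] > 1e-30) {
        for (int d = 0; d < 3; ++d) {
          double t = gj * (P[3 * u + d] - P[3 * v + d]) / S.la[j];
          G[3 * u + d] += t;
          G[3 * v + d] -= t;
        }
      }
      if (S.lb[j] > 1e-30) {
        int ub = u + T.nv, vb = v + T.nv;
        for (int d = 0; d < 3; ++d) {
          double t = gj * (P[3 * ub + d] - P[3 * vb + d]) / S.lb[j];
          G[3 * ub + d] += t;
          G[3 * vb + d] -= t;
        }
      }
    }
  }
  int n3 = 6 * T.nv;
  for (int i = 0; i < n3; ++i) G[i] = -G[i];
}

static std::vector<double> mat_to_flat(const NumericMatrix& pos) {
  int n = pos.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) P[3 * i + d] = pos(i, d);
  return P;
}

static NumericMatrix flat_to_mat(const std::vector<double>& P) {
  int n = P.size() / 3;
  NumericMatrix M(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) M(i, d) = P[3 * i + d];
  return M;
}

// [[Rcpp::export]]
List cpp_shell_geometry(NumericMatrix pos, int nv, IntegerVector cell_ptr,
                        IntegerVector cell_vert, IntegerMatrix junc) {
  Topology T = make_topology(nv, cell_ptr, cell_vert, junc);
  std::vector<double> P = mat_to_flat(pos);
  GeomState S;
  compute_geometry(P.data(), T, S);
  return List::create(
      _["area_apical"] = NumericVector(S.area_ap.begin(), S.area_ap.end()),
      _["area_basal"] = NumericVector(S.area_ba.begin(), S.area_ba.end()),
      _["area_lateral"] = NumericVector(S.area_lat.begin(), S.area_lat.end()),
      _["vol_cell"] = NumericVector(S.vol_cell.begin(), S.vol_cell.end()),
      _["vol_lumen"] = S.vol_lumen,
      _["len_apical"] = NumericVector(S.la.begin(), S.la.end()),
      _["len_basal"] = NumericVector(S.lb.begin(), S.lb.end()));
}

// [[Rcpp::export]]
List cpp_energy_force(NumericMatrix pos, int nv, IntegerVector cell_ptr,
                      IntegerVector cell_vert, IntegerMatrix junc,
                      double alpha, double beta, double k_cell, double k_lumen,
                      NumericVector v_cell_target, double v_lumen_target,
                      NumericVector gamma, bool want_force = true) {
  Topology T = make_topology(nv, cell_ptr, cell_vert, junc);
  std::vector<double> P = mat_to_flat(pos);
  GeomState S;
  compute_geometry(P.data(), T, S);
  EnergyParts E = compute_energy(S, T, alpha, beta, k_cell, k_lumen,
                                 v_cell_target.begin(), v_lumen_target,
                                 gamma.begin());
  NumericMatrix F;
  if (want_force) {
    std::vector<double> G(6 * T.nv, 0.0);
    compute_forces(P.data(), T, S, alpha, beta, k_cell, k_lumen,
                   v_cell_target.begin(), v_lumen_target, gamma.begin(),
                   G.data());
    F = flat_to_mat(G);
  }
  return List::create(_["energy"] = E.total, _["w_surface"] = E.surface,
                      _["w_constraint"] = E.constraint, _["w_line"] = E.line,
                      _["force"] = F);
}

// [[Rcpp::export]]
NumericVector cpp_mid_lengths(NumericMatrix pos, int nv, IntegerMatrix junc) {
  int ne = junc.nrow();
  NumericVector out(ne);
  for (int j = 0; j < ne; ++j) {
    int u = junc(j, 0), v = junc(j, 1);
    double la = 0, lb = 0, d;
    for (int k = 0; k < 3; ++k) {
      d = pos(u, k) - pos(v, k); la += d * d;
      d = pos(u + nv, k) - pos(v + nv, k); lb += d * d;
    }
    out[j] = 0.5 * (std::sqrt(la) + std::sqrt(lb));
  }
  return out;
}

// solve [v + n]^{1/3} - v^{1/3} = 400^{1/3} - 100^{1/3} for v (bisection);
// n is the total tissue volume (or cell number), reference point v(300) = 100
static double lumen_target_solve(double n) {
  const double C = std::cbrt(400.0) - std::cbrt(100.0);
  double lo = 0.0, hi = 1.0;
  while (std::cbrt(hi + n) - std::cbrt(hi) > C) hi *= 2.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (std::cbrt(mid + n) - std::cbrt(mid) > C) lo = mid; else hi = mid;
    if (hi - lo < 1e-12 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double cpp_lumen_target(double n) { return lumen_target_solve(n); }

static double schedule_eval(int kind, double v0, double tmax, double t) {
  double v = 0.0;
  if (kind == 0) v = v0;                                    // constant
  else if (kind == 1) v = v0 * (tmax - t) / tmax;           // linear ramp
  else if (kind == 2) v = (t < tmax / 2.0) ? v0 : 0.0;      // step
  return v > 0.0 ? v : 0.0;
}

// Overdamped integration with per-step activity. Returns control to R at the
// end of any step in which at least one junction is selected for a T1 (or a
// cell is ready to divide), so that topology edits stay on the R side.
// Per-step draw order is fixed (OU normals by junction index, then T1
// uniforms by junction index, then growth uniforms by cell index), making
// trajectories independent of how the run is chunked.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix pos, int nv, IntegerVector cell_ptr,
                 IntegerVector cell_vert, IntegerMatrix junc,
                 double alpha, double beta, double k_cell, double k_lumen,
                 NumericVector v_cell_target, double v_lumen_target,
                 NumericVector gamma, double dt, double step0, int n_steps,
                 int scheme, int sched_kind, double sched_v0, double sched_tmax,
                 double delta_l, double trigger_len, double tau,
                 LogicalVector t1_eligible, LogicalVector refractory,
                 IntegerMatrix glue,
                 bool grow, IntegerVector phase, LogicalVector div_eligible,
                 double tau_d, double tau_g, bool lumen_follows_growth,
                 int log_every) {
  Topology T = make_topology(nv, cell_ptr, cell_vert, junc);
  std::vector<double> P = mat_to_flat(pos);
  std::vector<double> G(6 * nv);
  std::vector<double> gam(gamma.begin(), gamma.end());
  std::vector<double> vt(v_cell_target.begin(), v_cell_target.end());
  std::vector<int> ph(phase.begin(), phase.end());
  std::vector<int> refr(refractory.begin(), refractory.end());
  double vtl = v_lumen_target;
  GeomState S;
  RNGScope rng;

  std::vector<double> log_t, log_w;
  std::vector<int> selected;
  int divide_cell_id = -1;
  int reason = 0;  // 0 done, 1 T1 selected, 2 division ready, 3 non-finite
  int step;
  for (step = 0; step < n_steps; ++step) {
    double t = (step0 + step) * dt;
    compute_geometry(P.data(), T, S);
    std::fill(G.begin(), G.end(), 0.0);
    compute_forces(P.data(), T, S, alpha, beta, k_cell, k_lumen, vt.data(),
                   vtl, gam.data(), G.data());
    for (int g = 0; g < glue.nrow(); ++g) {
      int i = glue(g, 0), j = glue(g, 1);
      for (int d = 0; d < 3; ++d) {
        double f = 0.5 * (G[3 * i + d] + G[3 * j + d]);
        G[3 * i + d] = f;
        G[3 * j + d] = f;
      }
    }
    int n3 = 6 * nv;
    for (int i = 0; i < n3; ++i) P[i] += dt * G[i];

    if (scheme == 2) {  // Ornstein-Uhlenbeck junctional tensions
      double sig = schedule_eval(sched_kind, sched_v0, sched_tmax, t);
      double amp = std::sqrt(2.0 * sig * sig * dt / tau);
      double decay = 1.0 - dt / tau;
      for (int j = 0; j < T.ne; ++j)
        gam[j] = gam[j] * decay + amp * norm_rand();
    }

    // T1 selection on post-move junction mid-lengths
    double kt1 = (scheme == 1)
                     ? schedule_eval(sched_kind, sched_v0, sched_tmax, t)
                     : 0.0;
    double pflip = kt1 * dt / T.ne;
    for (int j = 0; j < T.ne; ++j) {
      double la = 0, lb = 0, d;
      int u = T.ju[j], v = T.jv[j];
      for (int k = 0; k < 3; ++k) {
        d = P[3 * u + k] - P[3 * v + k]; la += d * d;
        d = P[3 * (u + nv) + k] - P[3 * (v + nv) + k]; lb += d * d;
      }
      double mid = 0.5 * (std::sqrt(la) + std::sqrt(lb));
      // a junction freshly created by a T1 stays refractory until it has
      // regrown past its scheme's trigger length, preventing the immediate
      // reverse flip of the 5e-4-long resolved edge
      double thresh = (scheme == 2) ? trigger_len : delta_l;
      if (refr[j] && mid >= thresh) refr[j] = 0;
      if (scheme == 1) {
        if (mid < delta_l) {
          if (!refr[j] && t1_eligible[j]) selected.push_back(j);
        } else if (kt1 > 0.0) {
          if (unif_rand() < pflip && t1_eligible[j]) selected.push_back(j);
        }
      } else if (scheme == 2) {
        if (mid < trigger_len && !refr[j] && t1_eligible[j])
          selected.push_back(j);
      }
    }

    if (grow) {
      double p_enter = dt / tau_d;
      for (int c = 0; c < T.nc; ++c) {
        if (ph[c] == 0) {
          if (unif_rand() < p_enter) ph[c] = 1;
        } else {
          vt[c] += dt / tau_g;
          if (vt[c] >= 2.0) {
            vt[c] = 2.0;
            if (div_eligible[c] && divide_cell_id < 0) divide_cell_id = c;
          }
        }
      }
      if (lumen_follows_growth) {
        double tot = 0.0;
        for (int c = 0; c < T.nc; ++c) tot += vt[c];
        vtl = lumen_target_solve(tot);
      }
    }

    long gstep = (long)(step0 + step) + 1;
    if (log_every > 0 && gstep % log_every == 0) {
      compute_geometry(P.data(), T, S);
      EnergyParts E = compute_energy(S, T, alpha, beta, k_cell, k_lumen,
                                     vt.data(), vtl, gam.data());
      log_t.push_back(gstep * dt);
      log_w.push_back(E.total);
      if (!std::isfinite(E.total)) { reason = 3; ++step; break; }
    }
    if (!selected.empty()) { reason = 1; ++step; break; }
    if (divide_cell_id >= 0) { reason = 2; ++step; break; }
  }

  NumericMatrix elog(log_t.size(), 2);
  for (size_t i = 0; i < log_t.size(); ++i) {
    elog(i, 0) = log_t[i];
    elog(i, 1) = log_w[i];
  }
  IntegerVector sel(selected.begin(), selected.end());
  return List::create(
      _["pos"] = flat_to_mat(P), _["gamma"] = NumericVector(gam.begin(), gam.end()),
      _["v_cell_target"] = NumericVector(vt.begin(), vt.end()),
      _["v_lumen_target"] = vtl,
      _["phase"] = IntegerVector(ph.begin(), ph.end()),
      _["refractory"] = LogicalVector(refr.begin(), refr.end()),
      _["steps_done"] = step, _["reason"] = reason, _["selected"] = sel,
      _["divide_cell"] = divide_cell_id, _["energy_log"] = elog);
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull (points in near-general position; callers jitter
// degenerate symmetric configurations). Returns outward-oriented triangles.

struct HFace { int a, b, c; bool alive; };

// [[Rcpp::export]]
IntegerMatrix cpp_convex_hull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> P = mat_to_flat(pts);
  double scale = 0.0;
  for (int i = 0; i < 3 * n; ++i) scale = std::max(scale, std::fabs(P[i]));
  double eps = 1e-10 * (scale > 0 ? scale : 1.0);

  // initial tetrahedron: spread-out quadruple
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (P[3 * i] < P[3 * i0]) i0 = i;
  int i1 = -1; double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d2 = 0;
    for (int d = 0; d < 3; ++d) {
      double e = P[3 * i + d] - P[3 * i0 + d];
      d2 += e * e;
    }
    if (d2 > best) { best = d2; i1 = i; }
  }
  int i2 = -1; best = -1.0;
  double e01[3];
  for (int d = 0; d < 3; ++d) e01[d] = P[3 * i1 + d] - P[3 * i0 + d];
  for (int i = 0; i < n; ++i) {
    double e[3], c[3];
    for (int d = 0; d < 3; ++d) e[d] = P[3 * i + d] - P[3 * i0 + d];
    cross3(e01, e, c);
    double d2 = dot3(c, c);
    if (d2 > best) { best = d2; i2 = i; }
  }
  double e02[3], nrm[3];
  for (int d = 0; d < 3; ++d) e02[d] = P[3 * i2 + d] - P[3 * i0 + d];
  cross3(e01, e02, nrm);
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double e[3];
    for (int d = 0; d < 3; ++d) e[d] = P[3 * i + d] - P[3 * i0 + d];
    double h = std::fabs(dot3(nrm, e));
    if (h > best) { best = h; i3 = i; }
  }
  if (i1 < 0 || i2 < 0 || i3 < 0 || best <= eps)
    stop("degenerate point set for convex hull");

  double ctr[3];
  for (int d = 0; d < 3; ++d)
    ctr[d] = 0.25 * (P[3 * i0 + d] + P[3 * i1 + d] + P[3 * i2 + d] +
                     P[3 * i3 + d]);
  std::vector<HFace> faces;
  int tet[4][3] = {{i0, i1, i2}, {i0, i3, i1}, {i0, i2, i3}, {i1, i3, i2}};
  for (int f = 0; f < 4; ++f) {
    int a = tet[f][0], b = tet[f][1], c = tet[f][2];
    double u[3], v[3], nn[3], w[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = P[3 * b + d] - P[3 * a + d];
      v[d] = P[3 * c + d] - P[3 * a + d];
      w[d] = ctr[d] - P[3 * a + d];
    }
    cross3(u, v, nn);
    if (dot3(nn, w) > 0) std::swap(b, c);  // make normal face away from center
    faces.push_back({a, b, c, true});
  }

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;
  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      const HFace& F = faces[f];
      double u[3], v[3], nn[3], w[3];
      for (int d = 0; d < 3; ++d) {
        u[d] = P[3 * F.b + d] - P[3 * F.a + d];
        v[d] = P[3 * F.c + d] - P[3 * F.a + d];
        w[d] = P[3 * p + d] - P[3 * F.a + d];
      }
      cross3(u, v, nn);
      if (dot3(nn, w) > eps) vis.push_back(f);
    }
    if (vis.empty()) continue;  // interior/coplanar point: not a hull vertex
    // horizon = directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int>> edges;
    for (int fi : vis) {
      const HFace& F = faces[fi];
      edges.push_back({F.a, F.b});
      edges.push_back({F.b, F.c});
      edges.push_back({F.c, F.a});
    }
    for (int fi : vis) faces[fi].alive = false;
    for (auto& e : edges) {
      bool reversed = false;
      for (auto& e2 : edges)
        if (e2.first == e.second && e2.second == e.first) { reversed = true; break; }
      if (!reversed) faces.push_back({e.first, e.second, p, true});
    }
  }
  int m = 0;
  for (auto& f : faces) if (f.alive) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (auto& f : faces)
    if (f.alive) { out(r, 0) = f.a; out(r, 1) = f.b; out(r, 2) = f.c; ++r; }
  return out;
}

// ---------------------------------------------------------------------------
// Self-overlap screen: do any two vertex-disjoint triangles of the
// (fan-triangulated) apical + basal surfaces intersect?

static bool tri_tri_overlap(const double* p1, const double* q1,
                            const double* r1, const double* p2,
                            const double* q2, const double* r2);

// triangles are shrunk slightly toward their centroid before testing, so
// surfaces in mere contact (the model has no steric repulsion) do not count
// as interpenetration; a wall pushed through another still does
// [[Rcpp::export]]
bool cpp_self_overlap(NumericMatrix pos, int nv, IntegerVector cell_ptr,
                      IntegerVector cell_vert, double shrink = 0.95) {
  int nc = cell_ptr.size() - 1;
  std::vector<double> P = mat_to_flat(pos);
  // triangles: (centroid, v_k, v_k+1) per face; centroid gets synthetic id
  struct Tri { double v[9]; int id[3]; double lo[3], hi[3]; };
  std::vector<Tri> tris;
  for (int surf = 0; surf < 2; ++surf) {
    int off = surf * nv;
    for (int c = 0; c < nc; ++c) {
      int m = cell_ptr[c + 1] - cell_ptr[c];
      const int* ids = &cell_vert[cell_ptr[c]];
      double g[3] = {0, 0, 0};
      for (int k = 0; k < m; ++k)
        for (int d = 0; d < 3; ++d) g[d] += P[3 * (ids[k] + off) + d];
      for (int d = 0; d < 3; ++d) g[d] /= m;
      int gid = 2 * nv + surf * nc + c;
      for (int k = 0; k < m; ++k) {
        Tri t;
        int a = ids[k] + off, b = ids[(k + 1) % m] + off;
        for (int d = 0; d < 3; ++d) {
          t.v[d] = g[d];
          t.v[3 + d] = P[3 * a + d];
          t.v[6 + d] = P[3 * b + d];
        }
        double tc[3];
        for (int d = 0; d < 3; ++d)
          tc[d] = (t.v[d] + t.v[3 + d] + t.v[6 + d]) / 3.0;
        for (int w = 0; w < 3; ++w)
          for (int d = 0; d < 3; ++d)
            t.v[3 * w + d] = tc[d] + shrink * (t.v[3 * w + d] - tc[d]);
        t.id[0] = gid; t.id[1] = a; t.id[2] = b;
        for (int d = 0; d < 3; ++d) {
          t.lo[d] = std::min({t.v[d], t.v[3 + d], t.v[6 + d]});
          t.hi[d] = std::max({t.v[d], t.v[3 + d], t.v[6 + d]});
        }
        tris.push_back(t);
      }
    }
  }
  int nt = tris.size();
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      const Tri& A = tris[i];
      const Tri& B = tris[j];
      bool sep = false;
      for (int d = 0; d < 3; ++d)
        if (A.hi[d] < B.lo[d] || B.hi[d] < A.lo[d]) { sep = true; break; }
      if (sep) continue;
      bool share = false;
      for (int a = 0; a < 3 && !share; ++a)
        for (int b = 0; b < 3; ++b)
          if (A.id[a] == B.id[b]) { share = true; break; }
      if (share) continue;
      if (tri_tri_overlap(A.v, A.v + 3, A.v + 6, B.v, B.v + 3, B.v + 6))
        return true;
    }
  }
  return false;
}

// segment-triangle intersection based tri-tri test: two disjoint triangles
// intersect iff an edge of one crosses the plane of the other inside it
static bool seg_tri_cross(const double* a, const double* b, const double* p,
                          const double* q, const double* r) {
  double n[3], u[3], v[3], w[3];
  for (int d = 0; d < 3; ++d) { u[d] = q[d] - p[d]; v[d] = r[d] - p[d]; }
  cross3(u, v, n);
  double da = 0, db = 0;
  for (int d = 0; d < 3; ++d) {
    da += n[d] * (a[d] - p[d]);
    db += n[d] * (b[d] - p[d]);
  }
  if (da * db > 0) return false;
  double denom = da - db;
  if (std::fabs(denom) < 1e-300) return false;  // coplanar: ignore
  double t = da / denom;
  double x[3];
  for (int d = 0; d < 3; ++d) x[d] = a[d] + t * (b[d] - a[d]);
  // barycentric inside-test
  for (int d = 0; d < 3; ++d) w[d] = x[d] - p[d];
  double uu = dot3(u, u), vv = dot3(v, v), uv = dot3(u, v);
  double wu = dot3(w, u), wv = dot3(w, v);
  double det = uu * vv - uv * uv;
  if (std::fabs(det) < 1e-300) return false;
  double s1 = (wu * vv - wv * uv) / det;
  double s2 = (wv * uu - wu * uv) / det;
  return s1 >= 0 && s2 >= 0 && s1 + s2 <= 1;
}

static bool tri_tri_overlap(const double* p1, const double* q1,
                            const double* r1, const double* p2,
                            const double* q2, const double* r2) {
  return seg_tri_cross(p1, q1, p2, q2, r2) ||
         seg_tri_cross(q1, r1, p2, q2, r2) ||
         seg_tri_cross(r1, p1, p2, q2, r2) ||
         seg_tri_cross(p2, q2, p1, q1, r1) ||
         seg_tri_cross(q2, r2, p1, q1, r1) ||
         seg_tri_cross(r2, p2, p1, q1, r1);
}
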