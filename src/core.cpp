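// Monte-Carlo core: NeRF torsion->Cartesian rebuild, centroid pair-energy
// scoring, and the inner simulation loops (rigid-body, backbone, MCM
// refinement). All randomness comes from R's RNG so a set.seed() in R
// fixes the full trajectory.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  Vec3 unit() const { double n = norm(); return Vec3(x / n, y / n, z / n); }
};

// Place atom D given A-B-C, bond length |CD|, angle B-C-D, torsion A-B-C-D.
static Vec3 nerf_place(const Vec3& a, const Vec3& b, const Vec3& c,
                       double blen, double bang_deg, double tor_deg) {
  double theta = bang_deg * DEG, chi = tor_deg * DEG;
  Vec3 bc = (c - b).unit();
  Vec3 n = ((b - a).cross(bc)).unit();
  Vec3 m = n.cross(bc);
  Vec3 d = bc * (-blen * std::cos(theta)) +
           m * (blen * std::sin(theta) * std::cos(chi)) +
           n * (blen * std::sin(theta) * std::sin(chi));
  return c + d;
}

static double dihedral_rad(const Vec3& p1, const Vec3& p2, const Vec3& p3,
                           const Vec3& p4) {
  Vec3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
  Vec3 m1 = n1.cross(b2.unit());
  return std::atan2(-m1.dot(n2), n1.dot(n2));
}

// [[Rcpp::export]]
double cpp_dihedral(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  return dihedral_rad(Vec3(p1[0], p1[1], p1[2]), Vec3(p2[0], p2[1], p2[2]),
                      Vec3(p3[0], p3[1], p3[2]), Vec3(p4[0], p4[1], p4[2])) / DEG;
}

// Extrapolated C-beta direction (unit vector) from backbone N, CA, C.
static Vec3 cb_direction(const Vec3& n, const Vec3& ca, const Vec3& c) {
  Vec3 b = ca - n, cc = c - ca;
  Vec3 a = b.cross(cc);
  Vec3 d = a * (-0.58273431) + b * 0.56802827 - cc * 0.54067466;
  return d.unit();
}

// geom: n_ca, ca_c, c_n, c_o, ang_c_n_ca, ang_n_ca_c, ang_ca_c_n, ang_ca_c_o
// torsions: n x 3 (phi, psi, omega) degrees.
// Returns (5n) x 3 local-frame coords, atom order N, CA, C, O, CEN per residue.
// First-residue frame: N at origin, CA on +x, C in the xy-plane (y > 0).
static void build_local(const double* tor, int n, const double* cen_dist,
                        const double* geom, double* out /* 5n x 3 col-major */) {
  std::vector<Vec3> N(n), CA(n), C(n), O(n), CEN(n);
  double b_nca = geom[0], b_cac = geom[1], b_cn = geom[2], b_co = geom[3];
  double a_cnca = geom[4], a_ncac = geom[5], a_cacn = geom[6], a_caco = geom[7];
  N[0] = Vec3(0, 0, 0);
  CA[0] = Vec3(b_nca, 0, 0);
  double th = a_ncac * DEG;
  C[0] = CA[0] + Vec3(-std::cos(th), std::sin(th), 0) * b_cac;
  for (int i = 1; i < n; ++i) {
    double psi_prev = tor[(i - 1) + n];      // psi of i-1
    double omg_prev = tor[(i - 1) + 2 * n];  // omega of i-1
    double phi_i = tor[i];
    N[i] = nerf_place(N[i - 1], CA[i - 1], C[i - 1], b_cn, a_cacn, psi_prev);
    CA[i] = nerf_place(CA[i - 1], C[i - 1], N[i], b_nca, a_cnca, omg_prev);
    C[i] = nerf_place(C[i - 1], N[i], CA[i], b_cac, a_ncac, phi_i);
  }
  for (int i = 0; i < n; ++i) {
    // carbonyl O anti to the next amide N: torsion psi + 180
    double psi_i = tor[i + n];
    O[i] = nerf_place(N[i], CA[i], C[i], b_co, a_caco, psi_i + 180.0);
    CEN[i] = CA[i] + cb_direction(N[i], CA[i], C[i]) * cen_dist[i];
  }
  int rows = 5 * n;
  for (int i = 0; i < n; ++i) {
    const Vec3* at[5] = { &N[i], &CA[i], &C[i], &O[i], &CEN[i] };
    for (int k = 0; k < 5; ++k) {
      int r = 5 * i + k;
      out[r] = at[k]->x;
      out[r + rows] = at[k]->y;
      out[r + 2 * rows] = at[k]->z;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_build_coords(NumericMatrix torsions, NumericVector cen_dist,
                               NumericVector geom) {
  int n = torsions.nrow();
  NumericMatrix out(5 * n, 3);
  build_local(REAL(torsions), n, REAL(cen_dist), REAL(geom), REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// Scoring

struct Weights {
  double w_rep, w_att, w_rama, f_rep, f_att;
};

// soft-sphere repulsion + symmetric short-range attractive well centred on
// the contact distance: the well fades out both beyond contact and inside
// it, so over-penetration loses attraction as well as paying repulsion;
// continuous at r0 and at both rims
static inline void pair_terms(double d, double r0, double& rep, double& att) {
  if (d < r0) {
    double x = (r0 - d) / r0;
    rep = x * x;
  } else {
    rep = 0.0;
  }
  double u = (d - r0) / 2.0;
  att = (u > -1.0 && u < 1.0) ? -(1.0 - u * u) : 0.0;
}

static inline int rama_bin(double ang) {
  double x = ang + 180.0;
  double a = x - 360.0 * std::floor(x / 360.0);
  int i = (int)std::floor(a / 20.0);
  if (i > 17) i = 17;
  return i;
}

struct System {
  // receptor (fixed, world frame)
  std::vector<Vec3> rec;
  std::vector<double> rec_rad;
  std::vector<int> rec_cen;
  // peptide metadata
  int n;  // residues
  std::vector<double> pep_rad;   // 5n
  std::vector<int> pep_res;      // 5n, 0-based residue index
  std::vector<int> pep_cen;      // 5n
  std::vector<double> cen_dist;  // n
  std::vector<int> rama_class;   // n, 0 generic 1 gly 2 pro
  std::vector<int> rama_mask;    // n, evaluate rama?
  std::vector<double> rama_tab;  // 3 * 18 * 18 levels
  double geom[8];
  int anchor;  // 0-based residue rooting the local frame
};

static void root_at_anchor(std::vector<Vec3>& local, int anchor);

struct Breakdown {
  double e_rep, e_att, e_rama, e_interface, e_pep_pair;
  double total() const { return e_rep + e_att + e_rama; }
  double e_peptide() const { return e_pep_pair + e_rama + e_interface; }
};

struct State {
  std::vector<double> tor;    // n x 3 col-major (phi, psi, omega)
  std::vector<Vec3> local;    // 5n
  double R[9];                // row-major rotation
  Vec3 t;
  std::vector<Vec3> world;    // 5n
  double e;                   // cached e_total
};

static void state_world(State& s) {
  size_t m = s.local.size();
  s.world.resize(m);
  const double* R = s.R;
  for (size_t i = 0; i < m; ++i) {
    const Vec3& p = s.local[i];
    s.world[i] = Vec3(R[0] * p.x + R[1] * p.y + R[2] * p.z + s.t.x,
                      R[3] * p.x + R[4] * p.y + R[5] * p.z + s.t.y,
                      R[6] * p.x + R[7] * p.y + R[8] * p.z + s.t.z);
  }
}

static void state_rebuild(State& s, const System& sys) {
  int n = sys.n;
  std::vector<double> xyz(5 * n * 3);
  build_local(s.tor.data(), n, sys.cen_dist.data(), sys.geom, xyz.data());
  s.local.resize(5 * n);
  int rows = 5 * n;
  for (int r = 0; r < rows; ++r)
    s.local[r] = Vec3(xyz[r], xyz[r + rows], xyz[r + 2 * rows]);
  root_at_anchor(s.local, sys.anchor);
  state_world(s);
}

// orthonormal frame of a residue triad (N, CA, C): origin N, x along
// N->CA, z normal to the N-CA-C plane
static void residue_frame(const Vec3& n, const Vec3& ca, const Vec3& c,
                          double* F /* 9, row-major */) {
  Vec3 ex = (ca - n).unit();
  Vec3 v = c - n;
  Vec3 ez = ex.cross(v).unit();
  Vec3 ey = ez.cross(ex);
  F[0] = ex.x; F[1] = ey.x; F[2] = ez.x;
  F[3] = ex.y; F[4] = ey.y; F[5] = ez.y;
  F[6] = ex.z; F[7] = ey.z; F[8] = ez.z;
}

// Re-express freshly built local coordinates in the anchor residue's
// canonical frame (anchor N at the origin, CA on +x, C in the xy-plane):
// with the rigid transform untouched, torsion moves then fold the chain
// around a fixed anchor residue, fold-tree style.
static void root_at_anchor(std::vector<Vec3>& local, int anchor) {
  if (anchor <= 0) return;  // residue 1 is already the frame root
  int a = 5 * anchor;
  double F[9];
  residue_frame(local[a], local[a + 1], local[a + 2], F);
  Vec3 na = local[a];
  for (size_t i = 0; i < local.size(); ++i) {
    Vec3 d = local[i] - na;
    // local' = F^T * d (F columns are the frame axes)
    local[i] = Vec3(F[0] * d.x + F[3] * d.y + F[6] * d.z,
                    F[1] * d.x + F[4] * d.y + F[7] * d.z,
                    F[2] * d.x + F[5] * d.y + F[8] * d.z);
  }
}

static double rama_level(const System& sys, int res, double phi, double psi) {
  int cls = sys.rama_class[res];
  return sys.rama_tab[cls * 324 + rama_bin(phi) * 18 + rama_bin(psi)];
}

static Breakdown score_state(const State& s, const System& sys, const Weights& w) {
  Breakdown b = {0, 0, 0, 0, 0};
  int np = (int)s.world.size();
  int nr = (int)sys.rec.size();
  double wr = w.w_rep * w.f_rep, wa = w.w_att * w.f_att;
  // intra-peptide pairs at sequence separation >= 3; backbone-backbone
  // pairs are excluded (the helical i->i+4 hydrogen bond would otherwise
  // register as a permanent clash)
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j) {
      if (!(sys.pep_cen[i] || sys.pep_cen[j])) continue;
      int sep = sys.pep_res[j] - sys.pep_res[i];
      if (sep < 3 && sep > -3) continue;
      double r0 = sys.pep_rad[i] + sys.pep_rad[j];
      Vec3 d = s.world[i] - s.world[j];
      double dd = d.dot(d), rmax = r0 + 2.0;
      if (dd >= rmax * rmax) continue;
      double rep, att;
      pair_terms(std::sqrt(dd), r0, rep, att);
      b.e_rep += wr * rep;
      b.e_att += wa * att;
      b.e_pep_pair += wr * rep + wa * att;
    }
  }
  // all peptide x receptor pairs
  for (int i = 0; i < np; ++i) {
    const Vec3& pi = s.world[i];
    double ri = sys.pep_rad[i];
    for (int j = 0; j < nr; ++j) {
      double r0 = ri + sys.rec_rad[j];
      Vec3 d = pi - sys.rec[j];
      double dd = d.dot(d), rmax = r0 + 2.0;
      if (dd >= rmax * rmax) continue;
      double rep, att;
      pair_terms(std::sqrt(dd), r0, rep, att);
      b.e_rep += wr * rep;
      b.e_att += wa * att;
      b.e_interface += wr * rep + wa * att;
    }
  }
  for (int i = 0; i < sys.n; ++i) {
    if (!sys.rama_mask[i]) continue;
    b.e_rama += w.w_rama * rama_level(sys, i, s.tor[i], s.tor[i + sys.n]);
  }
  return b;
}

static System unpack_system(List sys_l) {
  System sys;
  NumericMatrix rec = sys_l["rec_xyz"];
  NumericVector rrad = sys_l["rec_rad"];
  IntegerVector rcen = sys_l["rec_is_cen"];
  int nr = rec.nrow();
  sys.rec.resize(nr);
  for (int i = 0; i < nr; ++i) sys.rec[i] = Vec3(rec(i, 0), rec(i, 1), rec(i, 2));
  sys.rec_rad = as<std::vector<double> >(rrad);
  sys.rec_cen = as<std::vector<int> >(rcen);
  sys.pep_rad = as<std::vector<double> >(sys_l["pep_rad"]);
  sys.pep_res = as<std::vector<int> >(sys_l["pep_res"]);
  sys.pep_cen = as<std::vector<int> >(sys_l["pep_is_cen"]);
  sys.cen_dist = as<std::vector<double> >(sys_l["cen_dist"]);
  sys.rama_class = as<std::vector<int> >(sys_l["rama_class"]);
  sys.rama_mask = as<std::vector<int> >(sys_l["rama_mask"]);
  sys.rama_tab = as<std::vector<double> >(sys_l["rama_tab"]);
  NumericVector g = sys_l["geom"];
  for (int i = 0; i < 8; ++i) sys.geom[i] = g[i];
  sys.n = (int)sys.cen_dist.size();
  sys.anchor = as<int>(sys_l["anchor"]);
  return sys;
}

static Weights unpack_weights(NumericVector w) {
  Weights ww = { w[0], w[1], w[2], w[3], w[4] };
  return ww;
}

static State unpack_state(NumericMatrix torsions, NumericMatrix Rmat,
                          NumericVector tvec, const System& sys) {
  State s;
  int n = torsions.nrow();
  s.tor.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) s.tor[i + k * n] = torsions(i, k);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) s.R[3 * i + j] = Rmat(i, j);
  s.t = Vec3(tvec[0], tvec[1], tvec[2]);
  state_rebuild(s, sys);
  return s;
}

static NumericVector breakdown_vec(const Breakdown& b) {
  return NumericVector::create(
      _["e_rep"] = b.e_rep, _["e_att"] = b.e_att, _["e_rama"] = b.e_rama,
      _["e_total"] = b.total(), _["e_interface"] = b.e_interface,
      _["e_peptide"] = b.e_peptide());
}

// [[Rcpp::export]]
NumericVector cpp_score(List sys_l, NumericMatrix torsions, NumericMatrix Rmat,
                        NumericVector tvec, NumericVector wvec) {
  System sys = unpack_system(sys_l);
  Weights w = unpack_weights(wvec);
  State s = unpack_state(torsions, Rmat, tvec, sys);
  return breakdown_vec(score_state(s, sys, w));
}

// Score at given world coordinates (no rebuild): used when coordinates are
// authoritative (e.g. structures read from a PDB file).
// [[Rcpp::export]]
NumericVector cpp_score_xyz(List sys_l, NumericMatrix pep_world,
                            NumericMatrix torsions, NumericVector wvec) {
  System sys = unpack_system(sys_l);
  Weights w = unpack_weights(wvec);
  State s;
  int n = torsions.nrow();
  s.tor.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) s.tor[i + k * n] = torsions(i, k);
  int m = pep_world.nrow();
  s.world.resize(m);
  for (int i = 0; i < m; ++i)
    s.world[i] = Vec3(pep_world(i, 0), pep_world(i, 1), pep_world(i, 2));
  return breakdown_vec(score_state(s, sys, w));
}

// ---------------------------------------------------------------------------
// Moves

static bool metropolis_accept(double delta_e, double T) {
  if (delta_e <= 0) return true;
  return unif_rand() < std::exp(-delta_e / T);
}

static Vec3 random_unit_vec() {
  // marsaglia rejection
  for (;;) {
    double u = 2.0 * unif_rand() - 1.0, v = 2.0 * unif_rand() - 1.0;
    double s = u * u + v * v;
    if (s >= 1.0 || s == 0.0) continue;
    double f = 2.0 * std::sqrt(1.0 - s);
    return Vec3(u * f, v * f, 1.0 - 2.0 * s);
  }
}

static void axis_angle_matrix(const Vec3& axis, double ang_rad, double* M) {
  double c = std::cos(ang_rad), s = std::sin(ang_rad), t = 1.0 - c;
  double x = axis.x, y = axis.y, z = axis.z;
  M[0] = t * x * x + c;     M[1] = t * x * y - s * z; M[2] = t * x * z + s * y;
  M[3] = t * x * y + s * z; M[4] = t * y * y + c;     M[5] = t * y * z - s * x;
  M[6] = t * x * z - s * y; M[7] = t * y * z + s * x; M[8] = t * z * z + c;
}

static void matmul3(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

// Gram-Schmidt re-orthonormalization to keep det = +1 over long runs
static void reorthonormalize(double* R) {
  Vec3 r1(R[0], R[1], R[2]), r2(R[3], R[4], R[5]);
  r1 = r1.unit();
  r2 = (r2 - r1 * r2.dot(r1)).unit();
  Vec3 r3 = r1.cross(r2);
  R[0] = r1.x; R[1] = r1.y; R[2] = r1.z;
  R[3] = r2.x; R[4] = r2.y; R[5] = r2.z;
  R[6] = r3.x; R[7] = r3.y; R[8] = r3.z;
}

static Vec3 peptide_centroid(const State& s) {
  Vec3 c(0, 0, 0);
  for (size_t i = 0; i < s.world.size(); ++i) c = c + s.world[i];
  return c * (1.0 / (double)s.world.size());
}

// rotate about world-frame axis through the peptide centroid, then translate
static void apply_rigid(State& s, const Vec3& axis, double ang_rad,
                        const Vec3& dt) {
  Vec3 c = peptide_centroid(s);
  double Rot[9], Rnew[9];
  axis_angle_matrix(axis, ang_rad, Rot);
  matmul3(Rot, s.R, Rnew);
  for (int i = 0; i < 9; ++i) s.R[i] = Rnew[i];
  Vec3 tc = s.t - c;
  Vec3 trot(Rot[0] * tc.x + Rot[1] * tc.y + Rot[2] * tc.z,
            Rot[3] * tc.x + Rot[4] * tc.y + Rot[5] * tc.z,
            Rot[6] * tc.x + Rot[7] * tc.y + Rot[8] * tc.z);
  s.t = trot + c + dt;
  reorthonormalize(s.R);
  state_world(s);
}

struct BestTracker {
  std::vector<double> tor;
  double R[9];
  Vec3 t;
  double e;
  bool set;
  BestTracker() : e(0), set(false) {}
  void consider(const State& s) {
    if (!set || s.e < e) {
      tor = s.tor;
      for (int i = 0; i < 9; ++i) R[i] = s.R[i];
      t = s.t;
      e = s.e;
      set = true;
    }
  }
};

static List pack_result(const State& s, const BestTracker& best, int n,
                        int n_accept, const std::vector<double>& log_rows) {
  NumericMatrix tor(n, 3), btor(n, 3), Rm(3, 3), bRm(3, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      tor(i, k) = s.tor[i + k * n];
      btor(i, k) = best.tor[i + k * n];
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      Rm(i, j) = s.R[3 * i + j];
      bRm(i, j) = best.R[3 * i + j];
    }
  int nlog = (int)log_rows.size() / 4;
  NumericMatrix log(nlog, 4);
  for (int r = 0; r < nlog; ++r)
    for (int c = 0; c < 4; ++c) log(r, c) = log_rows[4 * r + c];
  colnames(log) = CharacterVector::create("kind", "accepted", "delta_e", "temp");
  return List::create(
      _["torsions"] = tor, _["R"] = Rm,
      _["t"] = NumericVector::create(s.t.x, s.t.y, s.t.z), _["e_total"] = s.e,
      _["best_torsions"] = btor, _["best_R"] = bRm,
      _["best_t"] = NumericVector::create(best.t.x, best.t.y, best.t.z),
      _["best_e"] = best.e, _["n_accept"] = n_accept, _["log"] = log);
}

// 50-move rigid-body Monte-Carlo ("docking" half of an outer cycle).
// [[Rcpp::export]]
List cpp_rigid_inner(List sys_l, NumericMatrix torsions, NumericMatrix Rmat,
                     NumericVector tvec, NumericVector wvec, double T,
                     int n_moves, double trans_mag, double rot_mag,
                     bool log_moves) {
  RNGScope scope;
  System sys = unpack_system(sys_l);
  Weights w = unpack_weights(wvec);
  State s = unpack_state(torsions, Rmat, tvec, sys);
  s.e = score_state(s, sys, w).total();
  BestTracker best;
  best.consider(s);
  int n_accept = 0;
  std::vector<double> log_rows;
  const double hn_trans = trans_mag * std::sqrt(M_PI / 2.0);
  const double hn_rot = rot_mag * std::sqrt(M_PI / 2.0);
  for (int mv = 0; mv < n_moves; ++mv) {
    Vec3 dir = random_unit_vec();
    double mag = std::fabs(norm_rand()) * hn_trans;
    Vec3 axis = random_unit_vec();
    double ang = std::fabs(norm_rand()) * hn_rot * DEG;
    State prop = s;
    apply_rigid(prop, axis, ang, dir * mag);
    prop.e = score_state(prop, sys, w).total();
    double de = prop.e - s.e;
    bool acc = metropolis_accept(de, T);
    if (acc) {
      s = prop;
      ++n_accept;
      best.consider(s);
    }
    if (log_moves) {
      log_rows.push_back(0);  // kind 0 = rigid body
      log_rows.push_back(acc ? 1 : 0);
      log_rows.push_back(de);
      log_rows.push_back(T);
    }
  }
  return pack_result(s, best, sys.n, n_accept, log_rows);
}

struct FragSet {
  std::vector<double> tor;  // stacked (nf * len) x 3 col-major by fragment
  int len, nf;
};

static FragSet unpack_frags(SEXP m, int len) {
  FragSet f;
  f.len = len;
  f.nf = 0;
  if (Rf_isNull(m)) return f;
  NumericMatrix fm(m);
  int rows = fm.nrow();
  f.nf = rows / len;
  f.tor.resize(rows * 3);
  for (int i = 0; i < rows; ++i)
    for (int k = 0; k < 3; ++k) f.tor[3 * i + k] = fm(i, k);
  return f;
}

// move kinds: 1 small, 2 shear, 3 trimer, 4 pentamer, 5 nonamer
static int choose_kind(double p_small, double p_shear, double p3, double p5,
                       double p9, int pep_len, const FragSet& f3,
                       const FragSet& f5, const FragSet& f9) {
  double p[5] = { p_small, p_shear, p3, p5, p9 };
  if (pep_len < 3 || f3.nf == 0) p[2] = 0;
  if (pep_len < 5 || f5.nf == 0) p[3] = 0;
  if (pep_len < 9 || f9.nf == 0) p[4] = 0;
  double tot = p[0] + p[1] + p[2] + p[3] + p[4];
  double u = unif_rand() * tot, acc = 0;
  for (int k = 0; k < 5; ++k) {
    acc += p[k];
    if (u < acc) return k + 1;
  }
  return 1;
}

// 50-move backbone Monte-Carlo ("folding" half of an outer cycle); the
// rigid-body transform is never touched.
// [[Rcpp::export]]
List cpp_backbone_inner(List sys_l, NumericMatrix torsions, NumericMatrix Rmat,
                        NumericVector tvec, NumericVector wvec, double T,
                        int n_moves, NumericVector probs, double tor_mag,
                        double t_rama, SEXP frags3, SEXP frags5, SEXP frags9,
                        bool log_moves) {
  RNGScope scope;
  System sys = unpack_system(sys_l);
  Weights w = unpack_weights(wvec);
  State s = unpack_state(torsions, Rmat, tvec, sys);
  s.e = score_state(s, sys, w).total();
  BestTracker best;
  best.consider(s);
  FragSet f3 = unpack_frags(frags3, 3), f5 = unpack_frags(frags5, 5),
          f9 = unpack_frags(frags9, 9);
  int n = sys.n, n_accept = 0;
  std::vector<double> log_rows;
  for (int mv = 0; mv < n_moves; ++mv) {
    int kind = choose_kind(probs[0], probs[1], probs[2], probs[3], probs[4],
                           n, f3, f5, f9);
    State prop = s;
    bool screened_out = false;
    if (kind == 1) {  // small
      int res = (int)std::floor(unif_rand() * n);
      if (res >= n) res = n - 1;
      double dphi = (2.0 * unif_rand() - 1.0) * tor_mag;
      double dpsi = (2.0 * unif_rand() - 1.0) * tor_mag;
      double phi0 = s.tor[res], psi0 = s.tor[res + n];
      double phi1 = phi0 + dphi, psi1 = psi0 + dpsi;
      if (sys.rama_mask[res]) {
        double dr = w.w_rama * (rama_level(sys, res, phi1, psi1) -
                                rama_level(sys, res, phi0, psi0));
        if (!metropolis_accept(dr, t_rama)) screened_out = true;
      }
      if (!screened_out) {
        prop.tor[res] = phi1;
        prop.tor[res + n] = psi1;
      }
    } else if (kind == 2) {  // shear: psi(i-1) += d, phi(i) -= d
      int res = 1 + (int)std::floor(unif_rand() * (n - 1));
      if (res >= n) res = n - 1;
      double d = (2.0 * unif_rand() - 1.0) * tor_mag;
      double psi_a0 = s.tor[(res - 1) + n], phi_b0 = s.tor[res];
      double psi_a1 = psi_a0 + d, phi_b1 = phi_b0 - d;
      double dr = 0;
      if (sys.rama_mask[res - 1])
        dr += w.w_rama * (rama_level(sys, res - 1, s.tor[res - 1], psi_a1) -
                          rama_level(sys, res - 1, s.tor[res - 1], psi_a0));
      if (sys.rama_mask[res])
        dr += w.w_rama * (rama_level(sys, res, phi_b1, s.tor[res + n]) -
                          rama_level(sys, res, phi_b0, s.tor[res + n]));
      if (!metropolis_accept(dr, t_rama)) screened_out = true;
      if (!screened_out) {
        prop.tor[(res - 1) + n] = psi_a1;
        prop.tor[res] = phi_b1;
      }
    } else {  // fragment insertion
      const FragSet& f = (kind == 3) ? f3 : (kind == 4) ? f5 : f9;
      int fi = (int)std::floor(unif_rand() * f.nf);
      if (fi >= f.nf) fi = f.nf - 1;
      int nstart = n - f.len + 1;
      int st = (int)std::floor(unif_rand() * nstart);
      if (st >= nstart) st = nstart - 1;
      for (int k = 0; k < f.len; ++k) {
        prop.tor[st + k] = f.tor[3 * (fi * f.len + k)];
        prop.tor[st + k + n] = f.tor[3 * (fi * f.len + k) + 1];
        prop.tor[st + k + 2 * n] = f.tor[3 * (fi * f.len + k) + 2];
      }
    }
    bool acc = false;
    double de = 0;
    if (!screened_out) {
      state_rebuild(prop, sys);
      prop.e = score_state(prop, sys, w).total();
      de = prop.e - s.e;
      acc = metropolis_accept(de, T);
      if (acc) {
        s = prop;
        ++n_accept;
        best.consider(s);
      }
    }
    if (log_moves) {
      log_rows.push_back(kind);
      log_rows.push_back(acc ? 1 : 0);
      log_rows.push_back(de);
      log_rows.push_back(T);
    }
  }
  return pack_result(s, best, n, n_accept, log_rows);
}

// ---------------------------------------------------------------------------
// MCM refinement: small perturbation, coordinate-descent minimization over
// the perturbed degrees of freedom, then Metropolis on the minimized energy.

struct DofCtx {
  State* s;
  const System* sys;
  const Weights* w;
};

static double eval_state(State& s, const System& sys, const Weights& w) {
  s.e = score_state(s, sys, w).total();
  return s.e;
}

// one-dimensional step-halving line search over a generic dof mutator
template <typename Apply>
static double line_search(State& s, const System& sys, const Weights& w,
                          double e0, double step0, double tol, Apply apply) {
  double e = e0, step = step0;
  while (step > tol) {
    bool moved = false;
    for (int dir = 0; dir < 2; ++dir) {
      double d = dir == 0 ? step : -step;
      State trial = s;
      apply(trial, d);
      double et = eval_state(trial, sys, w);
      if (et < e - 1e-12) {
        s = trial;
        e = et;
        moved = true;
        break;
      }
    }
    if (!moved) step *= 0.5;
  }
  s.e = e;
  return e;
}

static double minimize_rigid(State& s, const System& sys, const Weights& w,
                             double tol) {
  double e = eval_state(s, sys, w);
  Vec3 axes[3] = { Vec3(1, 0, 0), Vec3(0, 1, 0), Vec3(0, 0, 1) };
  for (int sweep = 0; sweep < 3; ++sweep) {
    double e_in = e;
    for (int k = 0; k < 3; ++k) {
      Vec3 ax = axes[k];
      e = line_search(s, sys, w, e, 0.1, tol, [&](State& st, double d) {
        st.t = st.t + ax * d;
        state_world(st);
      });
    }
    for (int k = 0; k < 3; ++k) {
      Vec3 ax = axes[k];
      e = line_search(s, sys, w, e, 1.0 * DEG, tol * DEG, [&](State& st, double d) {
        apply_rigid(st, ax, d, Vec3(0, 0, 0));
      });
    }
    if (e_in - e < 1e-3) break;
  }
  return e;
}

static double minimize_torsions(State& s, const System& sys, const Weights& w,
                                const std::vector<std::pair<int, int> >& dofs,
                                double tol) {
  int n = sys.n;
  double e = eval_state(s, sys, w);
  for (int sweep = 0; sweep < 3; ++sweep) {
    double e_in = e;
    for (size_t k = 0; k < dofs.size(); ++k) {
      int idx = dofs[k].first + dofs[k].second * n;
      e = line_search(s, sys, w, e, 1.0, tol, [&](State& st, double d) {
        st.tor[idx] += d;
        state_rebuild(st, sys);
      });
    }
    if (e_in - e < 1e-3) break;
  }
  return e;
}

// One refinement cycle at the given (already ramped) weights.
// [[Rcpp::export]]
List cpp_refine_cycle(List sys_l, NumericMatrix torsions, NumericMatrix Rmat,
                      NumericVector tvec, NumericVector wvec, double T,
                      int n_moves, double trans_mag, double rot_mag,
                      double tor_mag, double min_tol, bool log_moves) {
  RNGScope scope;
  System sys = unpack_system(sys_l);
  Weights w = unpack_weights(wvec);
  State s = unpack_state(torsions, Rmat, tvec, sys);
  s.e = score_state(s, sys, w).total();
  BestTracker best;
  best.consider(s);
  int n = sys.n, n_accept = 0;
  std::vector<double> log_rows;
  const double hn_trans = trans_mag * std::sqrt(M_PI / 2.0);
  const double hn_rot = rot_mag * std::sqrt(M_PI / 2.0);
  for (int mv = 0; mv < n_moves; ++mv) {
    State prop = s;
    bool rigid = unif_rand() < 0.5;
    int kind;
    if (rigid) {
      kind = 0;
      Vec3 dir = random_unit_vec();
      double mag = std::fabs(norm_rand()) * hn_trans;
      Vec3 axis = random_unit_vec();
      double ang = std::fabs(norm_rand()) * hn_rot * DEG;
      apply_rigid(prop, axis, ang, dir * mag);
      minimize_rigid(prop, sys, w, min_tol);
    } else {
      std::vector<std::pair<int, int> > dofs;
      if (unif_rand() < 0.5 || n < 2) {  // small
        kind = 1;
        int res = (int)std::floor(unif_rand() * n);
        if (res >= n) res = n - 1;
        prop.tor[res] += (2.0 * unif_rand() - 1.0) * tor_mag;
        prop.tor[res + n] += (2.0 * unif_rand() - 1.0) * tor_mag;
        dofs.push_back(std::make_pair(res, 0));
        dofs.push_back(std::make_pair(res, 1));
      } else {  // shear
        kind = 2;
        int res = 1 + (int)std::floor(unif_rand() * (n - 1));
        if (res >= n) res = n - 1;
        double d = (2.0 * unif_rand() - 1.0) * tor_mag;
        prop.tor[(res - 1) + n] += d;
        prop.tor[res] -= d;
        dofs.push_back(std::make_pair(res - 1, 1));
        dofs.push_back(std::make_pair(res, 0));
      }
      state_rebuild(prop, sys);
      minimize_torsions(prop, sys, w, dofs, min_tol);
    }
    double de = prop.e - s.e;
    bool acc = metropolis_accept(de, T);
    if (acc) {
      s = prop;
      ++n_accept;
      best.consider(s);
    }
    if (log_moves) {
      log_rows.push_back(kind);
      log_rows.push_back(acc ? 1 : 0);
      log_rows.push_back(de);
      log_rows.push_back(T);
    }
  }
  return pack_result(s, best, n, n_accept, log_rows);
}
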