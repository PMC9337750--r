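#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Structure evaluation path with flexible torsions: like the rigid path but
// each molecule's reference geometry is first driven to the parameter
// vector's torsion values (rotation of the far-side atom set about the
// central bond, then re-centring on the centroid, matching set_torsions()),
// and the interpolated LAM intramolecular energy is added.
//
// par layout: free cell parameters, then per molecule
//   [fx, fy, fz, qw, qx, qy, qz, t_1..t_k].

double cpp_exp6_energy(NumericMatrix xyz, IntegerVector molid,
                       IntegerVector type, NumericMatrix A, NumericMatrix B,
                       NumericMatrix C, NumericMatrix cell, double cutoff,
                       bool tail);
double cpp_ewald_energy(NumericMatrix xyz, IntegerVector molid,
                        NumericVector q, NumericMatrix cell, double alpha,
                        double rcut, double kcut);
double cpp_min_contact_ratio(NumericMatrix xyz, IntegerVector molid,
                             NumericVector rcov, NumericMatrix cell,
                             double search);

static bool build_cellmat2(const double *cp, int system, double M[3][3]) {
  double a = cp[0], b = cp[1], c = cp[2];
  double al = 90, be = 90, ga = 90;
  if (system == 0) { al = cp[3]; be = cp[4]; ga = cp[5]; }
  else if (system == 1) { be = cp[3]; }
  if (a <= 0 || b <= 0 || c <= 0) return false;
  double d2r = M_PI / 180.0;
  double ca = std::cos(al * d2r), cb = std::cos(be * d2r);
  double cg = std::cos(ga * d2r), sg = std::sin(ga * d2r);
  if (std::fabs(sg) < 1e-12) return false;
  double cx = c * cb, cy = c * (ca - cb * cg) / sg;
  double cz2 = c * c - cx * cx - cy * cy;
  if (cz2 <= 0) return false;
  M[0][0] = a;      M[0][1] = 0;      M[0][2] = 0;
  M[1][0] = b * cg; M[1][1] = b * sg; M[1][2] = 0;
  M[2][0] = cx;     M[2][1] = cy;     M[2][2] = std::sqrt(cz2);
  return true;
}

static void invert3b(const double M[3][3], double I[3][3]) {
  double det = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
             - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
             + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  double d = 1.0 / det;
  I[0][0] =  (M[1][1]*M[2][2]-M[1][2]*M[2][1]) * d;
  I[0][1] = -(M[0][1]*M[2][2]-M[0][2]*M[2][1]) * d;
  I[0][2] =  (M[0][1]*M[1][2]-M[0][2]*M[1][1]) * d;
  I[1][0] = -(M[1][0]*M[2][2]-M[1][2]*M[2][0]) * d;
  I[1][1] =  (M[0][0]*M[2][2]-M[0][2]*M[2][0]) * d;
  I[1][2] = -(M[0][0]*M[1][2]-M[0][2]*M[1][0]) * d;
  I[2][0] =  (M[1][0]*M[2][1]-M[1][1]*M[2][0]) * d;
  I[2][1] = -(M[0][0]*M[2][1]-M[0][1]*M[2][0]) * d;
  I[2][2] =  (M[0][0]*M[1][1]-M[0][1]*M[1][0]) * d;
}

static double dihedral_deg(const double *p1, const double *p2,
                           const double *p3, const double *p4) {
  double b1[3], b2[3], b3[3];
  for (int c = 0; c < 3; ++c) {
    b1[c] = p2[c] - p1[c]; b2[c] = p3[c] - p2[c]; b3[c] = p4[c] - p3[c];
  }
  double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                  b1[0]*b2[1]-b1[1]*b2[0]};
  double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                  b2[0]*b3[1]-b2[1]*b3[0]};
  double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  double u[3] = {b2[0]/b2n, b2[1]/b2n, b2[2]/b2n};
  double m1[3] = {n1[1]*u[2]-n1[2]*u[1], n1[2]*u[0]-n1[0]*u[2],
                  n1[0]*u[1]-n1[1]*u[0]};
  double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  double y = m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2];
  return std::atan2(y, x) * 180.0 / M_PI;
}

static void rotate_about(double *xyz, int n_atoms, const int *moving,
                         int n_moving, const double *axis_from,
                         const double *axis_to, double theta) {
  double u[3] = {axis_to[0]-axis_from[0], axis_to[1]-axis_from[1],
                 axis_to[2]-axis_from[2]};
  double un = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
  for (int c = 0; c < 3; ++c) u[c] /= un;
  double ct = std::cos(theta), st = std::sin(theta);
  double R[3][3] = {
    {ct + u[0]*u[0]*(1-ct), u[0]*u[1]*(1-ct) - u[2]*st, u[0]*u[2]*(1-ct) + u[1]*st},
    {u[1]*u[0]*(1-ct) + u[2]*st, ct + u[1]*u[1]*(1-ct), u[1]*u[2]*(1-ct) - u[0]*st},
    {u[2]*u[0]*(1-ct) - u[1]*st, u[2]*u[1]*(1-ct) + u[0]*st, ct + u[2]*u[2]*(1-ct)}};
  for (int m = 0; m < n_moving; ++m) {
    double *p = xyz + 3 * moving[m];
    double v[3] = {p[0]-axis_to[0], p[1]-axis_to[1], p[2]-axis_to[2]};
    for (int c = 0; c < 3; ++c)
      p[c] = axis_to[c] + R[c][0]*v[0] + R[c][1]*v[1] + R[c][2]*v[2];
  }
}

// periodic multilinear interpolation on a LAM grid (expand.grid order:
// first torsion varies fastest)
static double lam_interp(const double *vals, const int *dims,
                         const double *spacing, int nt, const double *query) {
  if (nt == 0) return 0.0;
  int lo[8]; double fr[8];
  for (int k = 0; k < nt; ++k) {
    double pos = query[k] - 360.0 * std::floor(query[k] / 360.0);
    pos /= spacing[k];
    lo[k] = (int)std::floor(pos);
    fr[k] = pos - lo[k];
  }
  double e = 0.0;
  int ncorner = 1 << nt;
  for (int corner = 0; corner < ncorner; ++corner) {
    double w = 1.0;
    int flat = 0, stride = 1;
    for (int k = 0; k < nt; ++k) {
      int bit = (corner >> k) & 1;
      w *= bit ? fr[k] : (1.0 - fr[k]);
      int idx = (lo[k] + bit) % dims[k];
      flat += idx * stride;
      stride *= dims[k];
    }
    if (w != 0.0) e += w * vals[flat];
  }
  return e;
}

struct FlexEvalData {
  int system, ncell, nmol;
  const NumericMatrix *coords0;
  const IntegerVector *atoms_per_mol, *ntors;
  const IntegerVector *type;
  const NumericVector *q, *rcov;
  const NumericMatrix *opsR, *opst;
  const NumericMatrix *A, *B, *C;
  double cutoff, alpha, kcut, guard;
  bool tail, do_elec;
  // torsion metadata, concatenated over molecules then torsions
  const IntegerVector *tor_atoms;    // 4 per torsion, molecule-local 0-based
  const IntegerVector *tor_mov_len;  // per torsion
  const IntegerVector *tor_moving;   // concatenated moving atom lists
  // LAM grids per molecule (flattened)
  const IntegerVector *lam_offsets;  // per molecule: offset into lam_vals (-1 if none)
  const NumericVector *lam_vals;
  const IntegerVector *lam_dims;     // concatenated dims per molecule
  const NumericVector *lam_spacing;  // concatenated spacing per molecule
  const IntegerVector *lam_meta_off; // per molecule: offset into lam_dims/spacing
};

static double flex_eval(const double *par, const FlexEvalData &D) {
  double M[3][3], Minv[3][3];
  if (!build_cellmat2(par, D.system, M)) return 1e8;
  {
    double cx = M[1][1]*M[2][2] - M[1][2]*M[2][1];
    double cy = M[1][2]*M[2][0] - M[1][0]*M[2][2];
    double cz = M[1][0]*M[2][1] - M[1][1]*M[2][0];
    double V = std::fabs(M[0][0]*cx + M[0][1]*cy + M[0][2]*cz);
    double wmin = R_PosInf;
    for (int i = 0; i < 3; ++i) {
      int j = (i + 1) % 3, k = (i + 2) % 3;
      double bx = M[j][1]*M[k][2] - M[j][2]*M[k][1];
      double by = M[j][2]*M[k][0] - M[j][0]*M[k][2];
      double bz = M[j][0]*M[k][1] - M[j][1]*M[k][0];
      double w = V / std::sqrt(bx*bx + by*by + bz*bz);
      if (w < wmin) wmin = w;
    }
    if (wmin < 1.0) return 1e5 * (2.0 - wmin);
  }
  invert3b(M, Minv);

  int nops = D.opst->nrow();
  int natoms0 = D.coords0->nrow();
  int N = natoms0 * nops;
  NumericMatrix xyz(N, 3);
  IntegerVector molid(N), typ(N);
  NumericVector qq(N), rc(N);
  double dU_intra = 0.0;
  std::vector<double> work(3 * 64);

  int row = 0, img = 0, off0 = 0, tor_idx = 0, tor_mov_off = 0;
  int paroff = D.ncell;
  for (int m = 0; m < D.nmol; ++m) {
    int na = (*D.atoms_per_mol)[m];
    int nt = (*D.ntors)[m];
    const double *pp = par + paroff;
    paroff += 7 + nt;
    if ((int)work.size() < 3 * na) work.resize(3 * na);
    for (int a = 0; a < na; ++a)
      for (int c = 0; c < 3; ++c)
        work[3*a + c] = (*D.coords0)(off0 + a, c);
    // apply torsions in declared order, then re-centre (mirrors the R side)
    if (nt > 0) {
      const double *tvals = pp + 7;
      for (int t = 0; t < nt; ++t, ++tor_idx) {
        int i0 = (*D.tor_atoms)[4*tor_idx + 0];
        int j0 = (*D.tor_atoms)[4*tor_idx + 1];
        int k0 = (*D.tor_atoms)[4*tor_idx + 2];
        int l0 = (*D.tor_atoms)[4*tor_idx + 3];
        double cur = dihedral_deg(&work[3*i0], &work[3*j0], &work[3*k0],
                                  &work[3*l0]);
        double delta = (cur - tvals[t]) * M_PI / 180.0;
        int nmov = (*D.tor_mov_len)[tor_idx];
        rotate_about(work.data(), na, &(*D.tor_moving)[tor_mov_off], nmov,
                     &work[3*j0], &work[3*k0], delta);
        tor_mov_off += nmov;
      }
      double ctr[3] = {0, 0, 0};
      for (int a = 0; a < na; ++a)
        for (int c = 0; c < 3; ++c) ctr[c] += work[3*a + c];
      for (int c = 0; c < 3; ++c) ctr[c] /= na;
      for (int a = 0; a < na; ++a)
        for (int c = 0; c < 3; ++c) work[3*a + c] -= ctr[c];
      // intramolecular LAM energy at these torsion values
      int lo = (*D.lam_offsets)[m];
      if (lo >= 0) {
        int mo = (*D.lam_meta_off)[m];
        dU_intra += lam_interp(&(*D.lam_vals)[lo], &(*D.lam_dims)[mo],
                               &(*D.lam_spacing)[mo], nt, tvals);
      }
    }
    double fx = pp[0], fy = pp[1], fz = pp[2];
    double qw = pp[3], qx = pp[4], qy = pp[5], qz = pp[6];
    double qn = std::sqrt(qw*qw + qx*qx + qy*qy + qz*qz);
    if (qn < 1e-8) return 1e8;
    qw /= qn; qx /= qn; qy /= qn; qz /= qn;
    double R[3][3] = {
      {1 - 2*(qy*qy + qz*qz), 2*(qx*qy - qw*qz), 2*(qx*qz + qw*qy)},
      {2*(qx*qy + qw*qz), 1 - 2*(qx*qx + qz*qz), 2*(qy*qz - qw*qx)},
      {2*(qx*qz - qw*qy), 2*(qy*qz + qw*qx), 1 - 2*(qx*qx + qy*qy)}};
    for (int o = 0; o < nops; ++o, ++img) {
      double f0[3] = {fx - std::floor(fx), fy - std::floor(fy),
                      fz - std::floor(fz)};
      double fc[3];
      for (int r = 0; r < 3; ++r) {
        fc[r] = (*D.opsR)(3*o + r, 0) * f0[0] + (*D.opsR)(3*o + r, 1) * f0[1] +
                (*D.opsR)(3*o + r, 2) * f0[2] + (*D.opst)(o, r);
        fc[r] -= std::floor(fc[r]);
      }
      double ctr[3];
      for (int c = 0; c < 3; ++c)
        ctr[c] = fc[0]*M[0][c] + fc[1]*M[1][c] + fc[2]*M[2][c];
      double Q[3][3];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) {
          double s = 0;
          for (int k = 0; k < 3; ++k)
            for (int l = 0; l < 3; ++l)
              s += Minv[r][k] * (*D.opsR)(3*o + l, k) * M[l][c];
          Q[r][c] = s;
        }
      for (int a = 0; a < na; ++a) {
        double x0 = work[3*a], y0 = work[3*a+1], z0 = work[3*a+2];
        double lx = x0*R[0][0] + y0*R[0][1] + z0*R[0][2];
        double ly = x0*R[1][0] + y0*R[1][1] + z0*R[1][2];
        double lz = x0*R[2][0] + y0*R[2][1] + z0*R[2][2];
        xyz(row, 0) = lx*Q[0][0] + ly*Q[1][0] + lz*Q[2][0] + ctr[0];
        xyz(row, 1) = lx*Q[0][1] + ly*Q[1][1] + lz*Q[2][1] + ctr[1];
        xyz(row, 2) = lx*Q[0][2] + ly*Q[1][2] + lz*Q[2][2] + ctr[2];
        molid[row] = img; typ[row] = (*D.type)[off0 + a];
        qq[row] = (*D.q)[off0 + a]; rc[row] = (*D.rcov)[off0 + a];
        ++row;
      }
    }
    off0 += na;
  }
  NumericMatrix cellM(3, 3);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) cellM(r, c) = M[r][c];
  double ratio = cpp_min_contact_ratio(xyz, molid, rc, cellM, 3.5);
  if (ratio < D.guard) return 1e5 * (1 + D.guard - ratio);
  double E;
  try {
    E = cpp_exp6_energy(xyz, molid, typ, *D.A, *D.B, *D.C, cellM, D.cutoff,
                        D.tail);
    if (D.do_elec)
      E += cpp_ewald_energy(xyz, molid, qq, cellM, D.alpha, D.cutoff, D.kcut);
  } catch (...) {
    return 1e8;
  }
  return E / nops + dU_intra;
}

// [[Rcpp::export]]
List cpp_flex_energy(NumericVector par, int system, int ncell,
                     NumericMatrix coords0, IntegerVector atoms_per_mol,
                     IntegerVector ntors, IntegerVector type, NumericVector q,
                     NumericVector rcov, NumericMatrix opsR,
                     NumericMatrix opst, NumericMatrix A, NumericMatrix B,
                     NumericMatrix C, double cutoff, bool tail, double alpha,
                     double kcut, bool do_elec, double guard,
                     IntegerVector tor_atoms, IntegerVector tor_mov_len,
                     IntegerVector tor_moving, IntegerVector lam_offsets,
                     NumericVector lam_vals, IntegerVector lam_dims,
                     NumericVector lam_spacing, IntegerVector lam_meta_off,
                     bool want_grad, bool grad_central) {
  FlexEvalData D;
  D.system = system; D.ncell = ncell; D.nmol = atoms_per_mol.size();
  D.coords0 = &coords0; D.atoms_per_mol = &atoms_per_mol; D.ntors = &ntors;
  D.type = &type; D.q = &q; D.rcov = &rcov; D.opsR = &opsR; D.opst = &opst;
  D.A = &A; D.B = &B; D.C = &C; D.cutoff = cutoff; D.tail = tail;
  D.alpha = alpha; D.kcut = kcut; D.do_elec = do_elec; D.guard = guard;
  D.tor_atoms = &tor_atoms; D.tor_mov_len = &tor_mov_len;
  D.tor_moving = &tor_moving; D.lam_offsets = &lam_offsets;
  D.lam_vals = &lam_vals; D.lam_dims = &lam_dims;
  D.lam_spacing = &lam_spacing; D.lam_meta_off = &lam_meta_off;

  int npar = par.size();
  std::vector<double> p(par.begin(), par.end());
  double f = flex_eval(p.data(), D);
  if (!want_grad) return List::create(Named("value") = f);
  NumericVector g(npar);
  for (int i = 0; i < npar; ++i) {
    double h = (grad_central ? 1e-5 : 1e-6) * std::max(1.0, std::fabs(p[i]));
    double save = p[i];
    p[i] = save + h;
    double f1 = flex_eval(p.data(), D);
    if (grad_central) {
      p[i] = save - h;
      double f2 = flex_eval(p.data(), D);
      g[i] = (f1 - f2) / (2 * h);
    } else {
      g[i] = (f1 - f) / h;
    }
    p[i] = save;
  }
  return List::create(Named("value") = f, Named("gradient") = g);
}
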