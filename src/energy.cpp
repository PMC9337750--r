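#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice-sum kernels for a molecular crystal given the symmetry-expanded
// unit-cell contents. Conventions: coordinates in angstrom, charges in e,
// energies in kJ/mol for the whole cell (the R layer divides by the number
// of asymmetric units). cell is a 3x3 matrix whose ROWS are lattice vectors.

static const double COULOMB_K = 1389.35457644382; // kJ*A/(mol*e^2)

// perpendicular widths of the cell -> image counts needed to cover a cutoff
static void image_counts(const NumericMatrix &cell, double cutoff, int n[3]) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = cell(i, j);
  // volume
  double cx = a[1][1]*a[2][2] - a[1][2]*a[2][1];
  double cy = a[1][2]*a[2][0] - a[1][0]*a[2][2];
  double cz = a[1][0]*a[2][1] - a[1][1]*a[2][0];
  double V = std::fabs(a[0][0]*cx + a[0][1]*cy + a[0][2]*cz);
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3, k = (i + 2) % 3;
    double bx = a[j][1]*a[k][2] - a[j][2]*a[k][1];
    double by = a[j][2]*a[k][0] - a[j][0]*a[k][2];
    double bz = a[j][0]*a[k][1] - a[j][1]*a[k][0];
    double area = std::sqrt(bx*bx + by*by + bz*bz);
    double width = V / area; // perpendicular width along axis i
    n[i] = (int)std::ceil(cutoff / width);
  }
}

// [[Rcpp::export]]
double cpp_exp6_energy(NumericMatrix xyz, IntegerVector molid,
                       IntegerVector type, NumericMatrix A, NumericMatrix B,
                       NumericMatrix C, NumericMatrix cell, double cutoff,
                       bool tail) {
  int N = xyz.nrow();
  int nimg[3];
  image_counts(cell, cutoff, nimg);
  double cut2 = cutoff * cutoff;
  double ron = 0.9 * cutoff;
  double ron2 = ron * ron;
  double E = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      int ti = type[i], tj = type[j];
      double Aij = A(ti, tj), Bij = B(ti, tj), Cij = C(ti, tj);
      bool samemol = (molid[i] == molid[j]);
      double dx0 = xyz(j, 0) - xyz(i, 0);
      double dy0 = xyz(j, 1) - xyz(i, 1);
      double dz0 = xyz(j, 2) - xyz(i, 2);
      for (int na = -nimg[0]; na <= nimg[0]; ++na)
        for (int nb = -nimg[1]; nb <= nimg[1]; ++nb)
          for (int nc = -nimg[2]; nc <= nimg[2]; ++nc) {
            bool home = (na == 0 && nb == 0 && nc == 0);
            if (home && (i == j || samemol)) continue; // intramolecular exclusion
            double dx = dx0 + na*cell(0,0) + nb*cell(1,0) + nc*cell(2,0);
            double dy = dy0 + na*cell(0,1) + nb*cell(1,1) + nc*cell(2,1);
            double dz = dz0 + na*cell(0,2) + nb*cell(1,2) + nc*cell(2,2);
            double r2 = dx*dx + dy*dy + dz*dz;
            if (r2 > cut2) continue;
            if (r2 < 0.25)
              stop("overlap error: intermolecular contact below 0.5 angstrom");
            double r = std::sqrt(r2);
            double w = (i == j) ? 0.5 : 1.0;
            double r6 = r2 * r2 * r2;
            double phi = Aij * std::exp(-Bij * r) - Cij / r6;
            // CHARMM-style switching over [0.9 rc, rc] keeps the energy
            // surface continuous as pairs cross the cutoff
            if (r2 > ron2) {
              double t = (cut2 - r2);
              phi *= t * t * (cut2 + 2.0 * r2 - 3.0 * ron2) /
                     ((cut2 - ron2) * (cut2 - ron2) * (cut2 - ron2));
            }
            E += w * phi;
          }
    }
  }
  if (tail) {
    // uniform-density dispersion correction beyond the cutoff
    double a00 = cell(0,0), V;
    {
      double cx = cell(1,1)*cell(2,2) - cell(1,2)*cell(2,1);
      double cy = cell(1,2)*cell(2,0) - cell(1,0)*cell(2,2);
      double cz = cell(1,0)*cell(2,1) - cell(1,1)*cell(2,0);
      V = std::fabs(a00*cx + cell(0,1)*cy + cell(0,2)*cz);
    }
    double csum = 0.0;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j) csum += C(type[i], type[j]);
    // integrate the uniform-density dispersion from the middle of the
    // switching window, which also compensates the switched-off fraction
    double rt = 0.5 * (ron + cutoff);
    E += -2.0 * M_PI * csum / (3.0 * V * rt * rt * rt);
  }
  return E;
}

// [[Rcpp::export]]
double cpp_ewald_energy(NumericMatrix xyz, IntegerVector molid,
                        NumericVector q, NumericMatrix cell, double alpha,
                        double rcut, double kcut) {
  int N = xyz.nrow();
  double qtot2 = 0.0;
  bool allzero = true;
  for (int i = 0; i < N; ++i) {
    qtot2 += q[i] * q[i];
    if (q[i] != 0.0) allzero = false;
  }
  if (allzero) return 0.0;

  int nimg[3];
  image_counts(cell, rcut, nimg);
  double rcut2 = rcut * rcut;
  double Ereal = 0.0, Eexcl = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      double qq = q[i] * q[j];
      bool samemol = (molid[i] == molid[j]);
      double dx0 = xyz(j, 0) - xyz(i, 0);
      double dy0 = xyz(j, 1) - xyz(i, 1);
      double dz0 = xyz(j, 2) - xyz(i, 2);
      if (samemol && i < j) {
        // remove the reciprocal-space contribution of the excluded pair
        double r = std::sqrt(dx0*dx0 + dy0*dy0 + dz0*dz0);
        if (r > 1e-12) Eexcl -= qq * std::erf(alpha * r) / r;
      }
      if (qq == 0.0) continue;
      for (int na = -nimg[0]; na <= nimg[0]; ++na)
        for (int nb = -nimg[1]; nb <= nimg[1]; ++nb)
          for (int nc = -nimg[2]; nc <= nimg[2]; ++nc) {
            bool home = (na == 0 && nb == 0 && nc == 0);
            if (home && (i == j || samemol)) continue;
            double dx = dx0 + na*cell(0,0) + nb*cell(1,0) + nc*cell(2,0);
            double dy = dy0 + na*cell(0,1) + nb*cell(1,1) + nc*cell(2,1);
            double dz = dz0 + na*cell(0,2) + nb*cell(1,2) + nc*cell(2,2);
            double r2 = dx*dx + dy*dy + dz*dz;
            if (r2 > rcut2) continue;
            double r = std::sqrt(r2);
            double w = (i == j) ? 0.5 : 1.0;
            Ereal += w * qq * std::erfc(alpha * r) / r;
          }
    }
  }

  // reciprocal-space sum
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = cell(i, j);
  double cx = a[1][1]*a[2][2] - a[1][2]*a[2][1];
  double cy = a[1][2]*a[2][0] - a[1][0]*a[2][2];
  double cz = a[1][0]*a[2][1] - a[1][1]*a[2][0];
  double V = std::fabs(a[0][0]*cx + a[0][1]*cy + a[0][2]*cz);
  // reciprocal vectors (rows): g_i = 2*pi * (a_j x a_k) / V
  double g[3][3];
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3, k = (i + 2) % 3;
    g[i][0] = 2.0*M_PI*(a[j][1]*a[k][2] - a[j][2]*a[k][1]) / V;
    g[i][1] = 2.0*M_PI*(a[j][2]*a[k][0] - a[j][0]*a[k][2]) / V;
    g[i][2] = 2.0*M_PI*(a[j][0]*a[k][1] - a[j][1]*a[k][0]) / V;
  }
  // sign fix: ensure a_i . g_i = 2*pi (handedness)
  for (int i = 0; i < 3; ++i) {
    double dot = a[i][0]*g[i][0] + a[i][1]*g[i][1] + a[i][2]*g[i][2];
    if (dot < 0) { g[i][0] = -g[i][0]; g[i][1] = -g[i][1]; g[i][2] = -g[i][2]; }
  }
  int kimg[3];
  for (int i = 0; i < 3; ++i) {
    double gn = std::sqrt(g[i][0]*g[i][0] + g[i][1]*g[i][1] + g[i][2]*g[i][2]);
    // widths of the reciprocal cell: project onto unit g_i direction bound
    kimg[i] = (int)std::ceil(kcut / (gn > 1e-12 ? gn : 1.0)) + 1;
  }
  double Erec = 0.0;
  double kcut2 = kcut * kcut;
  double inv4a2 = 1.0 / (4.0 * alpha * alpha);
  for (int h = -kimg[0]; h <= kimg[0]; ++h)
    for (int k = -kimg[1]; k <= kimg[1]; ++k)
      for (int l = -kimg[2]; l <= kimg[2]; ++l) {
        if (h == 0 && k == 0 && l == 0) continue;
        double kx = h*g[0][0] + k*g[1][0] + l*g[2][0];
        double ky = h*g[0][1] + k*g[1][1] + l*g[2][1];
        double kz = h*g[0][2] + k*g[1][2] + l*g[2][2];
        double k2 = kx*kx + ky*ky + kz*kz;
        if (k2 > kcut2 || k2 < 1e-14) continue;
        double sre = 0.0, sim = 0.0;
        for (int i = 0; i < N; ++i) {
          if (q[i] == 0.0) continue;
          double ph = kx*xyz(i,0) + ky*xyz(i,1) + kz*xyz(i,2);
          sre += q[i] * std::cos(ph);
          sim += q[i] * std::sin(ph);
        }
        Erec += std::exp(-k2 * inv4a2) / k2 * (sre*sre + sim*sim);
      }
  Erec *= 2.0 * M_PI / V;
  double Eself = -alpha / std::sqrt(M_PI) * qtot2;
  return COULOMB_K * (Ereal + Erec + Eself + Eexcl);
}

// minimum over intermolecular pairs of r / (rcov_i + rcov_j); the candidate
// overlap guard rejects structures where this falls below a threshold
// [[Rcpp::export]]
double cpp_min_contact_ratio(NumericMatrix xyz, IntegerVector molid,
                             NumericVector rcov, NumericMatrix cell,
                             double search) {
  int N = xyz.nrow();
  int nimg[3];
  image_counts(cell, search, nimg);
  double best = R_PosInf;
  for (int i = 0; i < N; ++i)
    for (int j = i; j < N; ++j) {
      bool samemol = (molid[i] == molid[j]);
      double rsum = rcov[i] + rcov[j];
      double dx0 = xyz(j, 0) - xyz(i, 0);
      double dy0 = xyz(j, 1) - xyz(i, 1);
      double dz0 = xyz(j, 2) - xyz(i, 2);
      for (int na = -nimg[0]; na <= nimg[0]; ++na)
        for (int nb = -nimg[1]; nb <= nimg[1]; ++nb)
          for (int nc = -nimg[2]; nc <= nimg[2]; ++nc) {
            bool home = (na == 0 && nb == 0 && nc == 0);
            if (home && (i == j || samemol)) continue;
            double dx = dx0 + na*cell(0,0) + nb*cell(1,0) + nc*cell(2,0);
            double dy = dy0 + na*cell(0,1) + nb*cell(1,1) + nc*cell(2,1);
            double dz = dz0 + na*cell(0,2) + nb*cell(1,2) + nc*cell(2,2);
            double ratio = std::sqrt(dx*dx + dy*dy + dz*dz) / rsum;
            if (ratio < best) best = ratio;
          }
    }
  return best;
}

// minimum intermolecular contact distance (capped search radius)
// [[Rcpp::export]]
double cpp_min_contact(NumericMatrix xyz, IntegerVector molid,
                       NumericMatrix cell, double search) {
  int N = xyz.nrow();
  int nimg[3];
  image_counts(cell, search, nimg);
  double best = search;
  for (int i = 0; i < N; ++i)
    for (int j = i; j < N; ++j) {
      bool samemol = (molid[i] == molid[j]);
      double dx0 = xyz(j, 0) - xyz(i, 0);
      double dy0 = xyz(j, 1) - xyz(i, 1);
      double dz0 = xyz(j, 2) - xyz(i, 2);
      for (int na = -nimg[0]; na <= nimg[0]; ++na)
        for (int nb = -nimg[1]; nb <= nimg[1]; ++nb)
          for (int nc = -nimg[2]; nc <= nimg[2]; ++nc) {
            bool home = (na == 0 && nb == 0 && nc == 0);
            if (home && (i == j || samemol)) continue;
            double dx = dx0 + na*cell(0,0) + nb*cell(1,0) + nc*cell(2,0);
            double dy = dy0 + na*cell(0,1) + nb*cell(1,1) + nc*cell(2,1);
            double dz = dz0 + na*cell(0,2) + nb*cell(1,2) + nc*cell(2,2);
            double r = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (r < best) best = r;
          }
    }
  return best;
}
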