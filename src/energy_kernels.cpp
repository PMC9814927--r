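#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice-sum kernels for the rigid-molecule exp-6 + point-charge energy model.
// Conventions shared with the R layer:
//  - `cell` is a 3x3 matrix whose COLUMNS are the lattice vectors a, b, c (Angstrom).
//  - `coords` are Cartesian positions of all atoms in one unit cell, pre-wrapped.
//  - `molid` labels the molecule INSTANCE each atom belongs to; pairs with equal
//    molid interact only through nonzero image translations (rigid-body model).
//  - energies are returned per unit cell; charge sums are in e^2/Angstrom and are
//    scaled by the Coulomb constant on the R side.

static void image_ranges(const NumericMatrix &cell, double reach, int nmax[3]) {
  // perpendicular face spacings h_i = V / |a_j x a_k|
  double ax = cell(0, 0), ay = cell(1, 0), az = cell(2, 0);
  double bx = cell(0, 1), by = cell(1, 1), bz = cell(2, 1);
  double cx = cell(0, 2), cy = cell(1, 2), cz = cell(2, 2);
  double bxc[3] = {by * cz - bz * cy, bz * cx - bx * cz, bx * cy - by * cx};
  double cxa[3] = {cy * az - cz * ay, cz * ax - cx * az, cx * ay - cy * ax};
  double axb[3] = {ay * bz - az * by, az * bx - ax * bz, ax * by - ay * bx};
  double vol = std::fabs(ax * bxc[0] + ay * bxc[1] + az * bxc[2]);
  double hn[3];
  hn[0] = vol / std::sqrt(bxc[0] * bxc[0] + bxc[1] * bxc[1] + bxc[2] * bxc[2]);
  hn[1] = vol / std::sqrt(cxa[0] * cxa[0] + cxa[1] * cxa[1] + cxa[2] * cxa[2]);
  hn[2] = vol / std::sqrt(axb[0] * axb[0] + axb[1] * axb[1] + axb[2] * axb[2]);
  for (int i = 0; i < 3; ++i) nmax[i] = (int)std::ceil(reach / hn[i]) + 1;
}

// [[Rcpp::export]]
List cpp_direct_sum(NumericMatrix coords, IntegerVector molid, IntegerVector type,
                    NumericVector q, NumericMatrix cell, double cutoff,
                    NumericMatrix Apar, NumericMatrix Bpar, NumericMatrix Cpar,
                    NumericMatrix rcat, NumericMatrix fcat, double clamp_slope,
                    double alpha, int elec_mode, double taper_w = 0.0,
                    Rcpp::Nullable<NumericMatrix> rexp = R_NilValue) {
  const int n = coords.nrow();
  int nmax[3];
  image_ranges(cell, cutoff, nmax);
  const double cut2 = cutoff * cutoff;
  const bool has_rexp = rexp.isNotNull();
  NumericMatrix rexpM = has_rexp ? NumericMatrix(rexp) : NumericMatrix(1, 1);
  double e6 = 0.0, ee = 0.0;
  // bounding radius of the wrapped cell contents around its centroid, for
  // skipping images that cannot contain any pair within the cutoff
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += coords(i,0); cy += coords(i,1); cz += coords(i,2); }
  cx /= n; cy /= n; cz /= n;
  double rad = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dx = coords(i,0)-cx, dy = coords(i,1)-cy, dz = coords(i,2)-cz;
    const double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 > rad) rad = r2;
  }
  rad = std::sqrt(rad);
  const double treach = cutoff + 2.0 * rad;
  for (int na = -nmax[0]; na <= nmax[0]; ++na)
    for (int nb = -nmax[1]; nb <= nmax[1]; ++nb)
      for (int nc = -nmax[2]; nc <= nmax[2]; ++nc) {
        const bool zero = (na == 0 && nb == 0 && nc == 0);
        const double tx = na * cell(0, 0) + nb * cell(0, 1) + nc * cell(0, 2);
        const double ty = na * cell(1, 0) + nb * cell(1, 1) + nc * cell(1, 2);
        const double tz = na * cell(2, 0) + nb * cell(2, 1) + nc * cell(2, 2);
        if (tx * tx + ty * ty + tz * tz > treach * treach) continue;
        for (int i = 0; i < n; ++i) {
          const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
          const int ti = type[i] - 1, mi = molid[i];
          const double qi = q[i];
          const int jstart = zero ? i + 1 : 0;
          for (int j = jstart; j < n; ++j) {
            if (zero && molid[j] == mi) continue; // intramolecular, same image
            const double dx = coords(j, 0) + tx - xi;
            const double dy = coords(j, 1) + ty - yi;
            const double dz = coords(j, 2) + tz - zi;
            const double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 > cut2 || r2 < 1e-12) continue;
            const double r = std::sqrt(r2);
            const int tj = type[j] - 1;
            const double w = zero ? 1.0 : 0.5; // nonzero images double-counted
            double v;
            if (r < rcat(ti, tj)) {
              v = fcat(ti, tj) + clamp_slope * (rcat(ti, tj) - r);
            } else {
              const double r6 = r2 * r2 * r2;
              v = -Cpar(ti, tj) / r6;
              // the exponential is numerically zero beyond rexp
              if (!has_rexp || r < rexpM(ti, tj)) {
                v += Apar(ti, tj) * std::exp(-Bpar(ti, tj) * r);
              }
            }
            if (taper_w > 0.0 && r > cutoff - taper_w) {
              // smoothstep switching to zero at the cutoff (C1 continuous)
              const double t = (cutoff - r) / taper_w;
              v *= t * t * (3.0 - 2.0 * t);
            }
            e6 += w * v;
            if (elec_mode == 1) {
              ee += w * qi * q[j] * std::erfc(alpha * r) / r;
            } else if (elec_mode == 2) {
              ee += w * qi * q[j] / r;
            }
          }
        }
      }
  return List::create(_["exp6"] = e6, _["elec_real"] = ee);
}

// Reciprocal-space part of the Ewald charge-charge sum (tinfoil boundary),
// in e^2/Angstrom. Self and intramolecular corrections are applied in R.
// [[Rcpp::export]]
double cpp_ewald_recip(NumericMatrix coords, NumericVector q, NumericMatrix cell,
                       double alpha, double kcut) {
  const int n = coords.nrow();
  // reciprocal lattice vectors (columns): 2*pi * inv(cell)^T
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = cell(i, j);
  double det = a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
               a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
               a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
  const double vol = std::fabs(det);
  double inv[3][3];
  inv[0][0] = (a[1][1] * a[2][2] - a[1][2] * a[2][1]) / det;
  inv[0][1] = (a[0][2] * a[2][1] - a[0][1] * a[2][2]) / det;
  inv[0][2] = (a[0][1] * a[1][2] - a[0][2] * a[1][1]) / det;
  inv[1][0] = (a[1][2] * a[2][0] - a[1][0] * a[2][2]) / det;
  inv[1][1] = (a[0][0] * a[2][2] - a[0][2] * a[2][0]) / det;
  inv[1][2] = (a[0][2] * a[1][0] - a[0][0] * a[1][2]) / det;
  inv[2][0] = (a[1][0] * a[2][1] - a[1][1] * a[2][0]) / det;
  inv[2][1] = (a[0][1] * a[2][0] - a[0][0] * a[2][1]) / det;
  inv[2][2] = (a[0][0] * a[1][1] - a[0][1] * a[1][0]) / det;
  const double twopi = 2.0 * M_PI;
  // reciprocal basis rows: g_i = 2*pi * row i of inv(cell)
  double g[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) g[i][j] = twopi * inv[i][j];
  // bound on integer indices
  double glen[3];
  for (int i = 0; i < 3; ++i)
    glen[i] = std::sqrt(g[i][0] * g[i][0] + g[i][1] * g[i][1] + g[i][2] * g[i][2]);
  int mmax[3];
  for (int i = 0; i < 3; ++i) mmax[i] = (int)std::ceil(kcut / glen[i]) + 1;
  const double kcut2 = kcut * kcut, four_a2 = 4.0 * alpha * alpha;
  double esum = 0.0;
  for (int ma = -mmax[0]; ma <= mmax[0]; ++ma)
    for (int mb = -mmax[1]; mb <= mmax[1]; ++mb)
      for (int mc = -mmax[2]; mc <= mmax[2]; ++mc) {
        if (ma == 0 && mb == 0 && mc == 0) continue;
        const double kx = ma * g[0][0] + mb * g[1][0] + mc * g[2][0];
        const double ky = ma * g[0][1] + mb * g[1][1] + mc * g[2][1];
        const double kz = ma * g[0][2] + mb * g[1][2] + mc * g[2][2];
        const double k2 = kx * kx + ky * ky + kz * kz;
        if (k2 > kcut2) continue;
        double sr = 0.0, si = 0.0;
        for (int i = 0; i < n; ++i) {
          const double ph = kx * coords(i, 0) + ky * coords(i, 1) + kz * coords(i, 2);
          sr += q[i] * std::cos(ph);
          si += q[i] * std::sin(ph);
        }
        esum += std::exp(-k2 / four_a2) / k2 * (sr * sr + si * si);
      }
  return twopi / vol * esum;
}

// Minimum intermolecular contact excess: min over intermolecular pairs (incl.
// periodic images) of (distance - threshold(elem_i, elem_j)). Returns
// c(excess, i, j, distance) with 1-based indices; i = j = 0 when no pair lies
// within reach (excess then reported as `reach`).
// [[Rcpp::export]]
NumericVector cpp_min_contact(NumericMatrix coords, IntegerVector molid,
                              IntegerVector elem, NumericMatrix thresh,
                              NumericMatrix cell, double reach) {
  const int n = coords.nrow();
  int nmax[3];
  image_ranges(cell, reach, nmax);
  double best = R_PosInf;
  int bi = 0, bj = 0;
  double bd = NA_REAL;
  for (int na = -nmax[0]; na <= nmax[0]; ++na)
    for (int nb = -nmax[1]; nb <= nmax[1]; ++nb)
      for (int nc = -nmax[2]; nc <= nmax[2]; ++nc) {
        const bool zero = (na == 0 && nb == 0 && nc == 0);
        const double tx = na * cell(0, 0) + nb * cell(0, 1) + nc * cell(0, 2);
        const double ty = na * cell(1, 0) + nb * cell(1, 1) + nc * cell(1, 2);
        const double tz = na * cell(2, 0) + nb * cell(2, 1) + nc * cell(2, 2);
        for (int i = 0; i < n; ++i) {
          const int jstart = zero ? i + 1 : 0;
          for (int j = jstart; j < n; ++j) {
            if (zero && molid[j] == molid[i]) continue;
            const double dx = coords(j, 0) + tx - coords(i, 0);
            const double dy = coords(j, 1) + ty - coords(i, 1);
            const double dz = coords(j, 2) + tz - coords(i, 2);
            const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r < 1e-12) continue;
            const double ex = r - thresh(elem[i] - 1, elem[j] - 1);
            if (ex < best) {
              best = ex;
              bi = i + 1;
              bj = j + 1;
              bd = r;
            }
          }
        }
      }
  if (!R_finite(best)) best = reach;
  return NumericVector::create(best, (double)bi, (double)bj, bd);
}

// All intermolecular contacts with distance below `dmax` (used by the
// hydrogen-bond and cluster machinery). Returns a matrix with rows
// (i, j, dist, sa, sb, sc) where s* is the fractional image shift applied
// to atom j. Ordered pairs with i over all atoms, j over all atoms/images.
// [[Rcpp::export]]
NumericMatrix cpp_contact_list(NumericMatrix coords, IntegerVector molid,
                               NumericMatrix cell, double dmax) {
  const int n = coords.nrow();
  int nmax[3];
  image_ranges(cell, dmax, nmax);
  std::vector<double> out;
  for (int na = -nmax[0]; na <= nmax[0]; ++na)
    for (int nb = -nmax[1]; nb <= nmax[1]; ++nb)
      for (int nc = -nmax[2]; nc <= nmax[2]; ++nc) {
        const bool zero = (na == 0 && nb == 0 && nc == 0);
        const double tx = na * cell(0, 0) + nb * cell(0, 1) + nc * cell(0, 2);
        const double ty = na * cell(1, 0) + nb * cell(1, 1) + nc * cell(1, 2);
        const double tz = na * cell(2, 0) + nb * cell(2, 1) + nc * cell(2, 2);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j) {
            if (zero && molid[j] == molid[i]) continue;
            const double dx = coords(j, 0) + tx - coords(i, 0);
            const double dy = coords(j, 1) + ty - coords(i, 1);
            const double dz = coords(j, 2) + tz - coords(i, 2);
            const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r < 1e-12 || r > dmax) continue;
            out.push_back(i + 1.0);
            out.push_back(j + 1.0);
            out.push_back(r);
            out.push_back((double)na);
            out.push_back((double)nb);
            out.push_back((double)nc);
          }
      }
  const int m = (int)(out.size() / 6);
  NumericMatrix res(m, 6);
  for (int k = 0; k < m; ++k)
    for (int c = 0; c < 6; ++c) res(k, c) = out[6 * k + c];
  colnames(res) = CharacterVector::create("i", "j", "dist", "sa", "sb", "sc");
  return res;
}
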