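// Gaussian-basis molecular integrals via the McMurchie-Davidson scheme.
// Contracted Cartesian shells up to l = 3; enough for double-zeta orbital
// bases (s,p) plus product-style auxiliary sets (s,p,d,[f]).
//
// Shell representation handed over from R (see R/basis.R):
//   list(l = integer, center = numeric(3), exps = numeric(k), coefs = numeric(k))
// Contraction coefficients already include primitive normalisation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_n(x)
static void boys(double x, int nmax, double* F) {
  if (x < 1e-13) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  double ex = std::exp(-x);
  if (x <= 40.0) {
    // series for F_nmax, then stable downward recursion
    double term = 1.0 / (2.0 * nmax + 1.0), sum = term;
    int k = 1;
    while (term > 1e-17 * sum && k < 500) {
      term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 1.0);
      sum += term;
      ++k;
    }
    F[nmax] = ex * sum;
    for (int n = nmax - 1; n >= 0; --n)
      F[n] = (2.0 * x * F[n + 1] + ex) / (2.0 * n + 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(PI_ / x);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
  }
}

// ------------------------------------------------- Hermite expansion E_t^{ij}
// E indexed E[(i*(lb+1)+j)*(ntot+1)+t], ntot = la+lb
static void ecoef(int la, int lb, double a, double b, double AB,
                  std::vector<double>& E) {
  int ntot = la + lb;
  int nt = ntot + 1;
  E.assign((la + 1) * (lb + 1) * nt, 0.0);
  double p = a + b, mu = a * b / p;
  double XPA = -(b / p) * AB, XPB = (a / p) * AB;
  E[0] = std::exp(-mu * AB * AB);
  // raise i with j = 0
  for (int i = 0; i < la; ++i) {
    for (int t = 0; t <= ntot; ++t) {
      double v = 0.0;
      if (t > 0)        v += E[(i * (lb + 1)) * nt + (t - 1)] / (2.0 * p);
      v += XPA * E[(i * (lb + 1)) * nt + t];
      if (t + 1 <= ntot) v += (t + 1.0) * E[(i * (lb + 1)) * nt + (t + 1)];
      E[((i + 1) * (lb + 1)) * nt + t] = v;
    }
  }
  // raise j for every i
  for (int j = 0; j < lb; ++j) {
    for (int i = 0; i <= la; ++i) {
      for (int t = 0; t <= ntot; ++t) {
        double v = 0.0;
        if (t > 0)        v += E[(i * (lb + 1) + j) * nt + (t - 1)] / (2.0 * p);
        v += XPB * E[(i * (lb + 1) + j) * nt + t];
        if (t + 1 <= ntot) v += (t + 1.0) * E[(i * (lb + 1) + j) * nt + (t + 1)];
        E[(i * (lb + 1) + (j + 1)) * nt + t] = v;
      }
    }
  }
}

// ------------------------------------------------- Hermite Coulomb R^n_{tuv}
static double rtuv(int t, int u, int v, int n, double p, const double* PQ,
                   const double* Fn) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * p;
    return f * Fn[n];
  }
  if (t > 0)
    return (t - 1) * rtuv(t - 2, u, v, n + 1, p, PQ, Fn) +
           PQ[0] * rtuv(t - 1, u, v, n + 1, p, PQ, Fn);
  if (u > 0)
    return (u - 1) * rtuv(t, u - 2, v, n + 1, p, PQ, Fn) +
           PQ[1] * rtuv(t, u - 1, v, n + 1, p, PQ, Fn);
  return (v - 1) * rtuv(t, u, v - 2, n + 1, p, PQ, Fn) +
         PQ[2] * rtuv(t, u, v - 1, n + 1, p, PQ, Fn);
}

// ----------------------------------------------------------- shell utilities
struct Shell {
  int l;
  double A[3];
  std::vector<double> exps, coefs;
};

static std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    NumericVector c = sh["center"];
    S.A[0] = c[0]; S.A[1] = c[1]; S.A[2] = c[2];
    S.exps = as<std::vector<double> >(sh["exps"]);
    S.coefs = as<std::vector<double> >(sh["coefs"]);
    out.push_back(S);
  }
  return out;
}

static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// Cartesian component exponents, lexicographic in decreasing x then y
static void cart_comps(int l, std::vector<int>& ix, std::vector<int>& iy,
                       std::vector<int>& iz) {
  ix.clear(); iy.clear(); iz.clear();
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j) {
      ix.push_back(i); iy.push_back(j); iz.push_back(l - i - j);
    }
}

// ------------------------------------------------------- one-electron blocks
// [[Rcpp::export(name = ".ao_oneints")]]
List ao_oneints(List shells, NumericMatrix atom_pos, NumericVector atom_z) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int s = 0; s < nsh; ++s) off[s + 1] = off[s] + ncart(sh[s].l);
  int nao = off[nsh];
  NumericMatrix S(nao, nao), T(nao, nao), V(nao, nao);
  NumericMatrix DX(nao, nao), DY(nao, nao), DZ(nao, nao);
  int nat = atom_pos.nrow();

  for (int sA = 0; sA < nsh; ++sA) {
    for (int sB = 0; sB <= sA; ++sB) {
      const Shell &A = sh[sA], &B = sh[sB];
      int la = A.l, lb = B.l;
      std::vector<int> ax, ay, az, bx, by, bz;
      cart_comps(la, ax, ay, az);
      cart_comps(lb, bx, by, bz);
      int na = ncart(la), nb = ncart(lb);
      std::vector<double> Sblk(na * nb, 0.0), Tblk(na * nb, 0.0),
          Vblk(na * nb, 0.0), Xblk(na * nb, 0.0), Yblk(na * nb, 0.0),
          Zblk(na * nb, 0.0);
      double ABv[3] = {A.A[0] - B.A[0], A.A[1] - B.A[1], A.A[2] - B.A[2]};
      for (size_t pa = 0; pa < A.exps.size(); ++pa) {
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb];
          double cc = A.coefs[pa] * B.coefs[pb];
          double p = a + b;
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * A.A[d] + b * B.A[d]) / p;
          // E tables per axis; need lb+2 for kinetic
          std::vector<double> Ex, Ey, Ez;
          ecoef(la, lb + 2, a, b, ABv[0], Ex);
          ecoef(la, lb + 2, a, b, ABv[1], Ey);
          ecoef(la, lb + 2, a, b, ABv[2], Ez);
          int ntE = la + lb + 3;  // stride of E tables
          int lbE = lb + 3;       // (lb+2)+1 columns
          double spi = std::sqrt(PI_ / p);
          // 1D overlap s_ij = E_0^{ij} * sqrt(pi/p); access helper lambdas
          #define E0(Etab, i, j) (Etab[((i) * lbE + (j)) * ntE + 0])
          #define E1(Etab, i, j) (Etab[((i) * lbE + (j)) * ntE + 1])
          int nF = la + lb + 1;
          std::vector<double> Fn(nF + 1);
          for (int ca = 0; ca < na; ++ca) {
            for (int cb = 0; cb < nb; ++cb) {
              int i1 = ax[ca], k1 = ay[ca], m1 = az[ca];
              int i2 = bx[cb], k2 = by[cb], m2 = bz[cb];
              double sx = E0(Ex, i1, i2) * spi;
              double sy = E0(Ey, k1, k2) * spi;
              double sz = E0(Ez, m1, m2) * spi;
              Sblk[ca * nb + cb] += cc * sx * sy * sz;
              // kinetic 1D: K_ij = b(2j+1)s_ij - 2b^2 s_{i,j+2} - j(j-1)/2 s_{i,j-2}
              double kx = b * (2.0 * i2 + 1.0) * sx -
                          2.0 * b * b * E0(Ex, i1, i2 + 2) * spi;
              if (i2 >= 2) kx -= 0.5 * i2 * (i2 - 1.0) * E0(Ex, i1, i2 - 2) * spi;
              double ky = b * (2.0 * k2 + 1.0) * sy -
                          2.0 * b * b * E0(Ey, k1, k2 + 2) * spi;
              if (k2 >= 2) ky -= 0.5 * k2 * (k2 - 1.0) * E0(Ey, k1, k2 - 2) * spi;
              double kz = b * (2.0 * m2 + 1.0) * sz -
                          2.0 * b * b * E0(Ez, m1, m2 + 2) * spi;
              if (m2 >= 2) kz -= 0.5 * m2 * (m2 - 1.0) * E0(Ez, m1, m2 - 2) * spi;
              Tblk[ca * nb + cb] += cc * (kx * sy * sz + sx * ky * sz + sx * sy * kz);
              // dipole (about the origin): <i| x |j> = (P_x E_0 + E_1) sqrt(pi/p)
              double dx = (P[0] * E0(Ex, i1, i2) + E1(Ex, i1, i2)) * spi;
              double dy = (P[1] * E0(Ey, k1, k2) + E1(Ey, k1, k2)) * spi;
              double dz = (P[2] * E0(Ez, m1, m2) + E1(Ez, m1, m2)) * spi;
              Xblk[ca * nb + cb] += cc * dx * sy * sz;
              Yblk[ca * nb + cb] += cc * sx * dy * sz;
              Zblk[ca * nb + cb] += cc * sx * sy * dz;
              // nuclear attraction
              double vsum = 0.0;
              for (int at = 0; at < nat; ++at) {
                double PC[3] = {P[0] - atom_pos(at, 0), P[1] - atom_pos(at, 1),
                                P[2] - atom_pos(at, 2)};
                double r2 = PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2];
                boys(p * r2, nF, Fn.data());
                double acc = 0.0;
                for (int t = 0; t <= i1 + i2; ++t)
                  for (int u = 0; u <= k1 + k2; ++u)
                    for (int v = 0; v <= m1 + m2; ++v)
                      acc += Ex[(i1 * lbE + i2) * ntE + t] *
                             Ey[(k1 * lbE + k2) * ntE + u] *
                             Ez[(m1 * lbE + m2) * ntE + v] *
                             rtuv(t, u, v, 0, p, PC, Fn.data());
                vsum -= atom_z[at] * acc;
              }
              Vblk[ca * nb + cb] += cc * (2.0 * PI_ / p) * vsum;
            }
          }
          #undef E0
          #undef E1
        }
      }
      for (int ca = 0; ca < na; ++ca)
        for (int cb = 0; cb < nb; ++cb) {
          int I = off[sA] + ca, J = off[sB] + cb;
          S(I, J) = S(J, I) = Sblk[ca * nb + cb];
          T(I, J) = T(J, I) = Tblk[ca * nb + cb];
          V(I, J) = V(J, I) = Vblk[ca * nb + cb];
          DX(I, J) = DX(J, I) = Xblk[ca * nb + cb];
          DY(I, J) = DY(J, I) = Yblk[ca * nb + cb];
          DZ(I, J) = DZ(J, I) = Zblk[ca * nb + cb];
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V, _["DX"] = DX,
                      _["DY"] = DY, _["DZ"] = DZ);
}

// ------------------------------------------------------------ ERI work horse
// contracted block (AB|CD) for four shells; out has dims na*nb*nc*nd
static void shell_eri(const Shell& A, const Shell& B, const Shell& C,
                      const Shell& D, std::vector<double>& out) {
  int la = A.l, lb = B.l, lc = C.l, ld = D.l;
  std::vector<int> ax, ay, az, bx, by, bz, cx, cy, cz, dx, dy, dz;
  cart_comps(la, ax, ay, az);
  cart_comps(lb, bx, by, bz);
  cart_comps(lc, cx, cy, cz);
  cart_comps(ld, dx, dy, dz);
  int na = ncart(la), nb = ncart(lb), nc = ncart(lc), nd = ncart(ld);
  out.assign((size_t)na * nb * nc * nd, 0.0);
  double ABv[3] = {A.A[0] - B.A[0], A.A[1] - B.A[1], A.A[2] - B.A[2]};
  double CDv[3] = {C.A[0] - D.A[0], C.A[1] - D.A[1], C.A[2] - D.A[2]};
  int nF = la + lb + lc + ld;
  std::vector<double> Fn(nF + 1);
  int nt1 = la + lb + 1, nt2 = lc + ld + 1;
  int lbE = lb + 1, ldE = ld + 1;
  for (size_t pa = 0; pa < A.exps.size(); ++pa)
   for (size_t pb = 0; pb < B.exps.size(); ++pb) {
    double a = A.exps[pa], b = B.exps[pb];
    double p = a + b;
    double P[3];
    for (int d = 0; d < 3; ++d) P[d] = (a * A.A[d] + b * B.A[d]) / p;
    std::vector<double> Ex1, Ey1, Ez1;
    ecoef(la, lb, a, b, ABv[0], Ex1);
    ecoef(la, lb, a, b, ABv[1], Ey1);
    ecoef(la, lb, a, b, ABv[2], Ez1);
    double cab = A.coefs[pa] * B.coefs[pb];
    for (size_t pc = 0; pc < C.exps.size(); ++pc)
     for (size_t pd = 0; pd < D.exps.size(); ++pd) {
      double c = C.exps[pc], d = D.exps[pd];
      double q = c + d;
      double Q[3];
      for (int k = 0; k < 3; ++k) Q[k] = (c * C.A[k] + d * D.A[k]) / q;
      std::vector<double> Ex2, Ey2, Ez2;
      ecoef(lc, ld, c, d, CDv[0], Ex2);
      ecoef(lc, ld, c, d, CDv[1], Ey2);
      ecoef(lc, ld, c, d, CDv[2], Ez2);
      double alpha = p * q / (p + q);
      double PQ[3] = {P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]};
      double r2 = PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2];
      boys(alpha * r2, nF, Fn.data());
      double pref = cab * C.coefs[pc] * D.coefs[pd] * 2.0 *
                    std::pow(PI_, 2.5) / (p * q * std::sqrt(p + q));
      // cache R_{tuv} on total orders
      int mt = la + lb + lc + ld;
      std::vector<double> Rc((mt + 1) * (mt + 1) * (mt + 1));
      for (int t = 0; t <= mt; ++t)
        for (int u = 0; u <= mt - t; ++u)
          for (int v = 0; v <= mt - t - u; ++v)
            Rc[(t * (mt + 1) + u) * (mt + 1) + v] =
                rtuv(t, u, v, 0, alpha, PQ, Fn.data());
      size_t idx = 0;
      for (int caI = 0; caI < na; ++caI)
       for (int cbI = 0; cbI < nb; ++cbI)
        for (int ccI = 0; ccI < nc; ++ccI)
         for (int cdI = 0; cdI < nd; ++cdI, ++idx) {
          int i1 = ax[caI], k1 = ay[caI], m1 = az[caI];
          int i2 = bx[cbI], k2 = by[cbI], m2 = bz[cbI];
          int i3 = cx[ccI], k3 = cy[ccI], m3 = cz[ccI];
          int i4 = dx[cdI], k4 = dy[cdI], m4 = dz[cdI];
          double acc = 0.0;
          for (int t = 0; t <= i1 + i2; ++t) {
            double ex1 = Ex1[(i1 * lbE + i2) * nt1 + t];
            if (ex1 == 0.0) continue;
            for (int u = 0; u <= k1 + k2; ++u) {
              double ey1 = Ey1[(k1 * lbE + k2) * nt1 + u];
              if (ey1 == 0.0) continue;
              for (int v = 0; v <= m1 + m2; ++v) {
                double ez1 = Ez1[(m1 * lbE + m2) * nt1 + v];
                if (ez1 == 0.0) continue;
                double e1 = ex1 * ey1 * ez1;
                for (int tt = 0; tt <= i3 + i4; ++tt) {
                  double ex2 = Ex2[(i3 * ldE + i4) * nt2 + tt];
                  if (ex2 == 0.0) continue;
                  for (int uu = 0; uu <= k3 + k4; ++uu) {
                    double ey2 = Ey2[(k3 * ldE + k4) * nt2 + uu];
                    if (ey2 == 0.0) continue;
                    for (int vv = 0; vv <= m3 + m4; ++vv) {
                      double ez2 = Ez2[(m3 * ldE + m4) * nt2 + vv];
                      if (ez2 == 0.0) continue;
                      double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                      acc += e1 * ex2 * ey2 * ez2 * sgn *
                             Rc[((t + tt) * (mt + 1) + (u + uu)) * (mt + 1) +
                                (v + vv)];
                    }
                  }
                }
              }
            }
          }
          out[idx] += pref * acc;
         }
     }
   }
}

// [[Rcpp::export(name = ".ao_eri_dense")]]
NumericVector ao_eri_dense(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int s = 0; s < nsh; ++s) off[s + 1] = off[s] + ncart(sh[s].l);
  int nao = off[nsh];
  NumericVector out((size_t)nao * nao * nao * nao);
  out.attr("dim") = IntegerVector::create(nao, nao, nao, nao);
  std::vector<double> blk;
  for (int sA = 0; sA < nsh; ++sA)
   for (int sB = 0; sB <= sA; ++sB)
    for (int sC = 0; sC <= sA; ++sC)
     for (int sD = 0; sD <= (sC == sA ? sB : sC); ++sD) {
      shell_eri(sh[sA], sh[sB], sh[sC], sh[sD], blk);
      int na = ncart(sh[sA].l), nb = ncart(sh[sB].l);
      int nc = ncart(sh[sC].l), nd = ncart(sh[sD].l);
      size_t idx = 0;
      for (int i = 0; i < na; ++i)
       for (int j = 0; j < nb; ++j)
        for (int k = 0; k < nc; ++k)
         for (int l = 0; l < nd; ++l, ++idx) {
          double v = blk[idx];
          size_t I = off[sA] + i, J = off[sB] + j, K = off[sC] + k,
                 L = off[sD] + l;
          size_t n = nao;
          // 8-fold symmetry
          out[I + n * (J + n * (K + n * L))] = v;
          out[J + n * (I + n * (K + n * L))] = v;
          out[I + n * (J + n * (L + n * K))] = v;
          out[J + n * (I + n * (L + n * K))] = v;
          out[K + n * (L + n * (I + n * J))] = v;
          out[L + n * (K + n * (I + n * J))] = v;
          out[K + n * (L + n * (J + n * I))] = v;
          out[L + n * (K + n * (J + n * I))] = v;
         }
     }
  return out;
}

// three-center (mu nu | P): aux shells treated as one-sided pairs with a
// dummy unit s-function (exponent 0) as the fourth index
// [[Rcpp::export(name = ".ao_eri_3c")]]
NumericVector ao_eri_3c(List shells, List aux_shells) {
  std::vector<Shell> sh = parse_shells(shells);
  std::vector<Shell> ax = parse_shells(aux_shells);
  Shell dummy;
  dummy.l = 0;
  dummy.A[0] = dummy.A[1] = dummy.A[2] = 0.0;
  dummy.exps.assign(1, 0.0);
  dummy.coefs.assign(1, 1.0);
  int nsh = sh.size(), nax = ax.size();
  std::vector<int> off(nsh + 1, 0), offa(nax + 1, 0);
  for (int s = 0; s < nsh; ++s) off[s + 1] = off[s] + ncart(sh[s].l);
  for (int s = 0; s < nax; ++s) offa[s + 1] = offa[s] + ncart(ax[s].l);
  int nao = off[nsh], naux = offa[nax];
  NumericVector out(Dimension(nao, nao, naux));
  std::vector<double> blk;
  for (int sA = 0; sA < nsh; ++sA)
   for (int sB = 0; sB <= sA; ++sB)
    for (int sP = 0; sP < nax; ++sP) {
      shell_eri(sh[sA], sh[sB], ax[sP], dummy, blk);
      int na = ncart(sh[sA].l), nb = ncart(sh[sB].l), np = ncart(ax[sP].l);
      size_t idx = 0;
      for (int i = 0; i < na; ++i)
       for (int j = 0; j < nb; ++j)
        for (int k = 0; k < np; ++k, ++idx) {
          size_t I = off[sA] + i, J = off[sB] + j, P = offa[sP] + k;
          out[I + (size_t)nao * (J + (size_t)nao * P)] = blk[idx];
          out[J + (size_t)nao * (I + (size_t)nao * P)] = blk[idx];
        }
    }
  return out;
}

// [[Rcpp::export(name = ".ao_eri_2c")]]
NumericMatrix ao_eri_2c(List aux_shells) {
  std::vector<Shell> ax = parse_shells(aux_shells);
  Shell dummy;
  dummy.l = 0;
  dummy.A[0] = dummy.A[1] = dummy.A[2] = 0.0;
  dummy.exps.assign(1, 0.0);
  dummy.coefs.assign(1, 1.0);
  int nax = ax.size();
  std::vector<int> offa(nax + 1, 0);
  for (int s = 0; s < nax; ++s) offa[s + 1] = offa[s] + ncart(ax[s].l);
  int naux = offa[nax];
  NumericMatrix out(naux, naux);
  std::vector<double> blk;
  for (int sP = 0; sP < nax; ++sP)
   for (int sQ = 0; sQ <= sP; ++sQ) {
    shell_eri(ax[sP], dummy, ax[sQ], dummy, blk);
    int np = ncart(ax[sP].l), nq = ncart(ax[sQ].l);
    size_t idx = 0;
    for (int i = 0; i < np; ++i)
     for (int k = 0; k < nq; ++k, ++idx) {
      out(offa[sP] + i, offa[sQ] + k) = blk[idx];
      out(offa[sQ] + k, offa[sP] + i) = blk[idx];
     }
   }
  return out;
}
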