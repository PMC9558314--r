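// Compact restricted Hartree-Fock engine over contracted Gaussian basis
// sets: McMurchie-Davidson integrals with per-shell-pair precomputed
// Hermite expansion data, in-core triangle-packed ERIs with Schwarz
// screening, DIIS-accelerated SCF, spherical d shells. Closed-shell only;
// used to generate benchmark electron densities for the topology pipeline.
#include <RcppArmadillo.h>
#include <vector>
#include <array>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// ---------- Boys function -------------------------------------------------
void boys(double x, int mmax, double* F) {
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1);
    return;
  }
  if (x < 35.0) {
    const double ex = std::exp(-x);
    double s = 0.0, term = 1.0 / (2 * mmax + 1);
    for (int k = 0; k < 200; ++k) {
      s += term;
      term *= 2 * x / (2 * mmax + 2 * k + 3);
      if (term < 1e-17 * s) break;
    }
    F[mmax] = s * ex;
    for (int m = mmax; m > 0; --m)
      F[m - 1] = (2 * x * F[m] + ex) / (2 * m - 1);
  } else {
    const double ex = std::exp(-x);
    F[0] = 0.5 * std::sqrt(M_PI / x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2 * m + 1) * F[m] - ex) / (2 * x);
  }
}

// ---------- Hermite expansion coefficients E(i,j,t), one direction --------
struct ECoef {
  int l1 = 0, l2 = 0;
  std::vector<double> v;
  void resize(int a, int b) {
    l1 = a; l2 = b;
    v.assign((l1 + 1) * (l2 + 1) * (l1 + l2 + 1), 0.0);
  }
  double& at(int i, int j, int t) { return v[(i * (l2 + 1) + j) * (l1 + l2 + 1) + t]; }
  double at(int i, int j, int t) const { return v[(i * (l2 + 1) + j) * (l1 + l2 + 1) + t]; }
};

void ecoef(int l1, int l2, double a, double b, double AB, ECoef& E) {
  E.resize(l1, l2);
  const double p = a + b, mu = a * b / p;
  const double PA = -b / p * AB, PB = a / p * AB;
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= l1; ++i)
    for (int j = 0; j <= l2; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          if (t > 0) val += 1.0 / (2 * p) * E.at(i - 1, j, t - 1);
          val += PA * E.at(i - 1, j, t);
          if (t + 1 <= i - 1 + j) val += (t + 1) * E.at(i - 1, j, t + 1);
        } else {
          if (t > 0) val += 1.0 / (2 * p) * E.at(i, j - 1, t - 1);
          val += PB * E.at(i, j - 1, t);
          if (t + 1 <= i + j - 1) val += (t + 1) * E.at(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
}

// ---------- Hermite Coulomb tensor R^0_{tuv} up to total order L ----------
struct RTensor {
  int L = -1;
  std::vector<double> v;
  void resize(int LL) { L = LL; v.assign((L + 1) * (L + 1) * (L + 1), 0.0); }
  double at(int t, int u, int w) const { return v[(t * (L + 1) + u) * (L + 1) + w]; }
  double& at(int t, int u, int w) { return v[(t * (L + 1) + u) * (L + 1) + w]; }
};

void rtensor(int L, double alpha, double X, double Y, double Z, RTensor& R,
             std::vector<double>& work) {
  const double T = alpha * (X * X + Y * Y + Z * Z);
  double F[32];
  boys(T, L, F);
  const int s = L + 1;
  auto idx = [s](int n, int t, int u, int w) {
    return ((n * s + t) * s + u) * s + w;
  };
  work.assign((size_t)s * s * s * s, 0.0);
  double f = 1.0;
  for (int n = 0; n <= L; ++n) { work[idx(n, 0, 0, 0)] = f * F[n]; f *= -2.0 * alpha; }
  for (int total = 1; total <= L; ++total)
    for (int t = 0; t <= total; ++t)
      for (int u = 0; u <= total - t; ++u) {
        const int w = total - t - u;
        for (int n = 0; n + total <= L; ++n) {
          double val;
          if (t > 0) {
            val = X * work[idx(n + 1, t - 1, u, w)];
            if (t > 1) val += (t - 1) * work[idx(n + 1, t - 2, u, w)];
          } else if (u > 0) {
            val = Y * work[idx(n + 1, t, u - 1, w)];
            if (u > 1) val += (u - 1) * work[idx(n + 1, t, u - 2, w)];
          } else {
            val = Z * work[idx(n + 1, t, u, w - 1)];
            if (w > 1) val += (w - 1) * work[idx(n + 1, t, u, w - 2)];
          }
          work[idx(n, t, u, w)] = val;
        }
      }
  R.resize(L);
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int w = 0; w <= L - t - u; ++w)
        R.at(t, u, w) = work[idx(0, t, u, w)];
}

// ---------- shells and basis ----------------------------------------------
bool use_cartesian_d = false;  // set per call into cpp_rhf/cpp_ao_values

struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> exps, coefs;
  int ncart() const { return (l + 1) * (l + 2) / 2; }
  int nsph() const { return use_cartesian_d ? ncart() : 2 * l + 1; }
};

void cart_comps(int l, std::vector<std::array<int, 3>>& out) {
  out.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      out.push_back({lx, ly, l - lx - ly});
}

double dfact(int n) {  // (2n-1)!!
  double r = 1;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

double prim_norm_l00(int l, double a) {
  return std::pow(2 * a / M_PI, 0.75) * std::pow(4 * a, 0.5 * l) /
         std::sqrt(dfact(l));
}

// spherical transform (nsph x ncart) assuming the (l,0,0) cartesian is
// normalized and all components share its radial scaling
arma::mat sph_transform(int l) {
  if (l == 0) return arma::mat(1, 1, arma::fill::ones);
  if (l == 1) return arma::eye(3, 3);
  if (use_cartesian_d) {
    // keep the 6 cartesian d components, individually normalized
    arma::mat T = arma::eye(6, 6);
    const double s3 = std::sqrt(3.0);
    T(1, 1) = T(2, 2) = T(4, 4) = s3;  // xy, xz, yz
    return T;
  }
  arma::mat T(5, 6, arma::fill::zeros);
  const double s3 = std::sqrt(3.0);
  T(0, 1) = s3;                                  // m=-2 : xy
  T(1, 4) = s3;                                  // m=-1 : yz
  T(2, 0) = -0.5; T(2, 3) = -0.5; T(2, 5) = 1.0; // m=0  : zz - (xx+yy)/2
  T(3, 2) = s3;                                  // m=+1 : xz
  T(4, 0) = 0.5 * s3; T(4, 3) = -0.5 * s3;       // m=+2 : sqrt3/2 (xx-yy)
  return T;
}

struct BasisSet {
  std::vector<Shell> shells;
  std::vector<int> sph_offset;
  int nsph = 0;
};

BasisSet build_basis(const List& shells_in) {
  BasisSet bs;
  for (int i = 0; i < shells_in.size(); ++i) {
    List s = shells_in[i];
    Shell sh;
    sh.l = as<int>(s["l"]);
    NumericVector cen = s["center"];
    sh.cx = cen[0]; sh.cy = cen[1]; sh.cz = cen[2];
    NumericVector e = s["exps"], c = s["coefs"];
    for (int k = 0; k < e.size(); ++k) {
      sh.exps.push_back(e[k]);
      sh.coefs.push_back(c[k] * prim_norm_l00(sh.l, e[k]));
    }
    double ss = 0;  // contracted (l,0,0) self-overlap
    for (size_t a = 0; a < sh.exps.size(); ++a)
      for (size_t b = 0; b < sh.exps.size(); ++b) {
        const double p = sh.exps[a] + sh.exps[b];
        const double s00 = std::pow(M_PI / p, 1.5) * dfact(sh.l) /
                           std::pow(2 * p, sh.l);
        ss += sh.coefs[a] * sh.coefs[b] * s00;
      }
    for (auto& c2 : sh.coefs) c2 /= std::sqrt(ss);
    bs.sph_offset.push_back(bs.nsph);
    bs.nsph += sh.nsph();
    bs.shells.push_back(sh);
  }
  return bs;
}

// ---------- precomputed shell-pair data for ERIs --------------------------
struct PrimPairData {
  double p, Px, Py, Pz, cc;
  double bound;  // |cc| * prod E(0,0,0): overlap-scale screening factor
  ECoef Ex, Ey, Ez;
};

struct ShellPair {
  int si, sj;          // canonical si >= sj
  std::vector<PrimPairData> prims;
};

std::vector<ShellPair> build_pairs(const BasisSet& bs) {
  std::vector<ShellPair> pairs;
  const int nsh = bs.shells.size();
  for (int si = 0; si < nsh; ++si)
    for (int sj = 0; sj <= si; ++sj) {
      const Shell &A = bs.shells[si], &B = bs.shells[sj];
      ShellPair sp; sp.si = si; sp.sj = sj;
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          PrimPairData d;
          const double a = A.exps[pa], b = B.exps[pb];
          d.p = a + b;
          d.cc = A.coefs[pa] * B.coefs[pb];
          d.Px = (a * A.cx + b * B.cx) / d.p;
          d.Py = (a * A.cy + b * B.cy) / d.p;
          d.Pz = (a * A.cz + b * B.cz) / d.p;
          ecoef(A.l, B.l, a, b, A.cx - B.cx, d.Ex);
          ecoef(A.l, B.l, a, b, A.cy - B.cy, d.Ey);
          ecoef(A.l, B.l, a, b, A.cz - B.cz, d.Ez);
          const double k0 = d.Ex.at(0, 0, 0) * d.Ey.at(0, 0, 0) * d.Ez.at(0, 0, 0);
          d.bound = std::fabs(d.cc) * k0;
          if (d.bound > 1e-16) sp.prims.push_back(std::move(d));
        }
      pairs.push_back(std::move(sp));
    }
  return pairs;
}

inline size_t pair_index(int i, int j) { return (size_t)i * (i + 1) / 2 + j; }

struct ERIStore {
  int n = 0;
  std::vector<double> v;
  double get(int i, int j, int k, int l) const {
    size_t ij = i >= j ? pair_index(i, j) : pair_index(j, i);
    size_t kl = k >= l ? pair_index(k, l) : pair_index(l, k);
    if (ij < kl) std::swap(ij, kl);
    return v[ij * (ij + 1) / 2 + kl];
  }
};

// cartesian ERI block for a pair of shell pairs, accumulated over
// primitives; then spherical transform and scatter into the store
void eri_quartet(const BasisSet& bs, const ShellPair& bra, const ShellPair& ket,
                 ERIStore& store, RTensor& R, std::vector<double>& work,
                 std::vector<double>& block) {
  const Shell &A = bs.shells[bra.si], &B = bs.shells[bra.sj],
              &C = bs.shells[ket.si], &D = bs.shells[ket.sj];
  static thread_local std::vector<std::array<int, 3>> ca, cb, cc_, cd;
  cart_comps(A.l, ca); cart_comps(B.l, cb);
  cart_comps(C.l, cc_); cart_comps(D.l, cd);
  const int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd.size();
  block.assign((size_t)na * nb * nc * nd, 0.0);
  const int L = A.l + B.l + C.l + D.l;
  const double two_pi_52 = 2.0 * std::pow(M_PI, 2.5);
  for (const auto& bp : bra.prims) {
    for (const auto& kp : ket.prims) {
      // primitive-level bound: F_0 <= 1, angular factors O(1)
      if (two_pi_52 * bp.bound * kp.bound /
            (bp.p * kp.p * std::sqrt(bp.p + kp.p)) < 1e-13) continue;
      const double alpha = bp.p * kp.p / (bp.p + kp.p);
      rtensor(L, alpha, bp.Px - kp.Px, bp.Py - kp.Py, bp.Pz - kp.Pz, R, work);
      const double pref = two_pi_52 * bp.cc * kp.cc /
                          (bp.p * kp.p * std::sqrt(bp.p + kp.p));
      // stage 1: half-transform R with the ket E coefficients, giving
      // K[cart_ket][bra hermite (t,u,w)]
      const int Lb = A.l + B.l, sb1 = Lb + 1;
      static thread_local std::vector<double> Khalf;
      Khalf.assign((size_t)nc * nd * sb1 * sb1 * sb1, 0.0);
      for (int ic = 0, ck = 0; ic < nc; ++ic)
        for (int id = 0; id < nd; ++id, ++ck) {
          const int l3 = cc_[ic][0], m3 = cc_[ic][1], n3 = cc_[ic][2];
          const int l4 = cd[id][0], m4 = cd[id][1], n4 = cd[id][2];
          double* Kc = &Khalf[(size_t)ck * sb1 * sb1 * sb1];
          for (int t2 = 0; t2 <= l3 + l4; ++t2) {
            const double fx = kp.Ex.at(l3, l4, t2);
            if (fx == 0) continue;
            for (int u2 = 0; u2 <= m3 + m4; ++u2) {
              const double fxy = fx * kp.Ey.at(m3, m4, u2);
              if (fxy == 0) continue;
              for (int w2 = 0; w2 <= n3 + n4; ++w2) {
                const double fxyz = fxy * kp.Ez.at(n3, n4, w2);
                if (fxyz == 0) continue;
                const double sgn = ((t2 + u2 + w2) % 2) ? -fxyz : fxyz;
                for (int t = 0; t <= Lb; ++t)
                  for (int u = 0; u + t <= Lb; ++u) {
                    double* Krow = Kc + (t * sb1 + u) * sb1;
                    for (int w = 0; w + t + u <= Lb; ++w)
                      Krow[w] += sgn * R.at(t + t2, u + u2, w + w2);
                  }
              }
            }
          }
        }
      // stage 2: contract with the bra E coefficients
      size_t bi = 0;
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          const int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
          const int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
          for (int ck = 0; ck < nc * nd; ++ck, ++bi) {
            const double* Kc = &Khalf[(size_t)ck * sb1 * sb1 * sb1];
            double sum = 0;
            for (int t = 0; t <= l1 + l2; ++t) {
              const double ex = bp.Ex.at(l1, l2, t);
              if (ex == 0) continue;
              for (int u = 0; u <= m1 + m2; ++u) {
                const double exy = ex * bp.Ey.at(m1, m2, u);
                if (exy == 0) continue;
                const double* Krow = Kc + (t * sb1 + u) * sb1;
                for (int w = 0; w <= n1 + n2; ++w) {
                  const double exyz = bp.Ez.at(n1, n2, w);
                  if (exyz != 0) sum += exy * exyz * Krow[w];
                }
              }
            }
            block[bi] += pref * sum;
          }
        }
    }
  }
  // cartesian -> spherical on all sides, scatter
  const arma::mat Ta = sph_transform(A.l), Tb = sph_transform(B.l),
                  Tc = sph_transform(C.l), Td = sph_transform(D.l);
  const int sa = A.nsph(), sb = B.nsph(), sc = C.nsph(), sd = D.nsph();
  const int oa = bs.sph_offset[bra.si], ob = bs.sph_offset[bra.sj],
            oc = bs.sph_offset[ket.si], od = bs.sph_offset[ket.sj];
  for (int ia = 0; ia < sa; ++ia)
    for (int ib = 0; ib < sb; ++ib)
      for (int ic = 0; ic < sc; ++ic)
        for (int id = 0; id < sd; ++id) {
          double acc = 0;
          for (int xa = 0; xa < na; ++xa) {
            const double wa = Ta(ia, xa);
            if (wa == 0) continue;
            for (int xb = 0; xb < nb; ++xb) {
              const double wb = wa * Tb(ib, xb);
              if (wb == 0) continue;
              for (int xc = 0; xc < nc; ++xc) {
                const double wc = wb * Tc(ic, xc);
                if (wc == 0) continue;
                for (int xd = 0; xd < nd; ++xd) {
                  const double wd = wc * Td(id, xd);
                  if (wd == 0) continue;
                  acc += wd * block[((size_t)(xa * nb + xb) * nc + xc) * nd + xd];
                }
              }
            }
          }
          const int i = oa + ia, j = ob + ib, k = oc + ic, l = od + id;
          size_t ij = i >= j ? pair_index(i, j) : pair_index(j, i);
          size_t kl = k >= l ? pair_index(k, l) : pair_index(l, k);
          if (ij < kl) std::swap(ij, kl);
          store.v[ij * (ij + 1) / 2 + kl] = acc;
        }
}

void one_electron_blocks(const Shell& A, const Shell& B, const arma::mat& ZC,
                         arma::mat& Sb, arma::mat& Tb, arma::mat& Vb) {
  static thread_local std::vector<std::array<int, 3>> ca, cb;
  cart_comps(A.l, ca); cart_comps(B.l, cb);
  const int na = ca.size(), nb = cb.size();
  Sb.zeros(na, nb); Tb.zeros(na, nb); Vb.zeros(na, nb);
  ECoef Ex, Ey, Ez;
  RTensor R; std::vector<double> work;
  const double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
  const int L = A.l + B.l;
  for (size_t pa = 0; pa < A.exps.size(); ++pa)
    for (size_t pb = 0; pb < B.exps.size(); ++pb) {
      const double a = A.exps[pa], b = B.exps[pb], p = a + b;
      const double cc = A.coefs[pa] * B.coefs[pb];
      const double Px = (a * A.cx + b * B.cx) / p,
                   Py = (a * A.cy + b * B.cy) / p,
                   Pz = (a * A.cz + b * B.cz) / p;
      ecoef(A.l + 2, B.l, a, b, ABx, Ex);
      ecoef(A.l + 2, B.l, a, b, ABy, Ey);
      ecoef(A.l + 2, B.l, a, b, ABz, Ez);
      const double pref = std::pow(M_PI / p, 1.5);
      for (int ia = 0; ia < na; ++ia) {
        const int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
        for (int ib = 0; ib < nb; ++ib) {
          const int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
          const double sx = Ex.at(l1, l2, 0), sy = Ey.at(m1, m2, 0),
                       sz = Ez.at(n1, n2, 0);
          Sb(ia, ib) += cc * pref * sx * sy * sz;
          auto t1d = [a](const ECoef& E, int i, int j) {
            double t = -2.0 * a * a * E.at(i + 2, j, 0) +
                       a * (2 * i + 1) * E.at(i, j, 0);
            if (i >= 2) t -= 0.5 * i * (i - 1) * E.at(i - 2, j, 0);
            return t;
          };
          const double tx = t1d(Ex, l1, l2), ty = t1d(Ey, m1, m2),
                       tz = t1d(Ez, n1, n2);
          Tb(ia, ib) += cc * pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
          double vsum = 0;
          for (arma::uword atom = 0; atom < ZC.n_rows; ++atom) {
            rtensor(L, p, Px - ZC(atom, 1), Py - ZC(atom, 2), Pz - ZC(atom, 3),
                    R, work);
            double v = 0;
            for (int t = 0; t <= l1 + l2; ++t)
              for (int u = 0; u <= m1 + m2; ++u)
                for (int w = 0; w <= n1 + n2; ++w)
                  v += Ex.at(l1, l2, t) * Ey.at(m1, m2, u) * Ez.at(n1, n2, w) *
                       R.at(t, u, w);
            vsum += -ZC(atom, 0) * v;
          }
          Vb(ia, ib) += cc * (2.0 * M_PI / p) * vsum;
        }
      }
    }
}

}  // namespace

// Full RHF in the spherical AO basis. shells_in: list of
// list(l, center, exps, coefs); atoms: matrix with columns (Z, x, y, z);
// nelec even. Returns energy, density matrix, MO coefficients, etc.
// [[Rcpp::export]]
List cpp_rhf(const List& shells_in, const arma::mat& atoms, int nelec,
             int max_iter = 100, double conv_e = 1e-9, double conv_err = 1e-6,
             bool cartesian_d = false) {
  use_cartesian_d = cartesian_d;
  BasisSet bs = build_basis(shells_in);
  const int n = bs.nsph, nsh = bs.shells.size();
  if (nelec % 2 != 0) stop("closed-shell RHF needs an even electron count");
  const int nocc = nelec / 2;

  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros),
            V(n, n, arma::fill::zeros);
  for (int si = 0; si < nsh; ++si)
    for (int sj = 0; sj <= si; ++sj) {
      arma::mat Sb, Tb, Vb;
      one_electron_blocks(bs.shells[si], bs.shells[sj], atoms, Sb, Tb, Vb);
      arma::mat Ti = sph_transform(bs.shells[si].l),
                Tj = sph_transform(bs.shells[sj].l);
      arma::mat Ss = Ti * Sb * Tj.t(), Ts = Ti * Tb * Tj.t(),
                Vs = Ti * Vb * Tj.t();
      for (int a = 0; a < bs.shells[si].nsph(); ++a)
        for (int b = 0; b < bs.shells[sj].nsph(); ++b) {
          const int i = bs.sph_offset[si] + a, j = bs.sph_offset[sj] + b;
          S(i, j) = S(j, i) = Ss(a, b);
          T(i, j) = T(j, i) = Ts(a, b);
          V(i, j) = V(j, i) = Vs(a, b);
        }
    }
  const arma::mat H = T + V;

  std::vector<ShellPair> pairs = build_pairs(bs);
  const size_t npair_ao = (size_t)n * (n + 1) / 2;
  ERIStore eri{n, std::vector<double>(npair_ao * (npair_ao + 1) / 2, 0.0)};
  RTensor R; std::vector<double> work, block;

  // Schwarz bounds per shell pair: sqrt(max (ij|ij))
  std::vector<double> qbound(pairs.size());
  for (size_t pp = 0; pp < pairs.size(); ++pp) {
    eri_quartet(bs, pairs[pp], pairs[pp], eri, R, work, block);
    const Shell &A = bs.shells[pairs[pp].si], &B = bs.shells[pairs[pp].sj];
    double mx = 0;
    for (int a = 0; a < A.nsph(); ++a)
      for (int b = 0; b < B.nsph(); ++b) {
        const int i = bs.sph_offset[pairs[pp].si] + a;
        const int j = bs.sph_offset[pairs[pp].sj] + b;
        mx = std::max(mx, std::fabs(eri.get(i, j, i, j)));
      }
    qbound[pp] = std::sqrt(mx);
  }
  const double eri_thresh = 1e-11;
  for (size_t bp = 0; bp < pairs.size(); ++bp)
    for (size_t kp = 0; kp <= bp; ++kp) {
      if (qbound[bp] * qbound[kp] < eri_thresh) continue;
      if (bp == kp) continue;  // diagonal quartets already done
      eri_quartet(bs, pairs[bp], pairs[kp], eri, R, work, block);
    }

  double enuc = 0;
  for (arma::uword a = 0; a < atoms.n_rows; ++a)
    for (arma::uword b = a + 1; b < atoms.n_rows; ++b) {
      const double dx = atoms(a, 1) - atoms(b, 1),
                   dy = atoms(a, 2) - atoms(b, 2),
                   dz = atoms(a, 3) - atoms(b, 3);
      enuc += atoms(a, 0) * atoms(b, 0) / std::sqrt(dx * dx + dy * dy + dz * dz);
    }

  arma::vec sval; arma::mat svec;
  arma::eig_sym(sval, svec, S);
  if (sval.min() < 1e-10) warning("near-linearly-dependent basis");
  const arma::mat X = svec * arma::diagmat(1.0 / arma::sqrt(sval)) * svec.t();

  arma::mat P;
  {
    arma::mat Fo = X.t() * H * X;
    arma::vec e0; arma::mat Cp;
    arma::eig_sym(e0, Cp, Fo);
    arma::mat Cmo0 = X * Cp;
    P = 2.0 * Cmo0.cols(0, nocc - 1) * Cmo0.cols(0, nocc - 1).t();
  }
  std::vector<arma::mat> diis_F, diis_E;
  double E_old = 0, E_tot = 0;
  arma::mat Cmo; arma::vec eps;
  bool converged = false;
  // decode tables for the packed pair index
  std::vector<int> i_of(npair_ao), j_of(npair_ao);
  for (int i = 0, c = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j, ++c) { i_of[c] = i; j_of[c] = j; }
  for (int iter = 0; iter < max_iter; ++iter) {
    // J/K scatter over unique quartets (distinct index permutations only)
    arma::mat J(n, n, arma::fill::zeros), K(n, n, arma::fill::zeros);
    size_t pos = 0;
    for (size_t ij = 0; ij < npair_ao; ++ij) {
      const int i = i_of[ij], j = j_of[ij];
      for (size_t kl = 0; kl <= ij; ++kl, ++pos) {
        const double v = eri.v[pos];
        if (v == 0) continue;
        const int k = i_of[kl], l = j_of[kl];
        long codes[8];
        const int pq[8][4] = {{i, j, k, l}, {j, i, k, l}, {i, j, l, k},
                              {j, i, l, k}, {k, l, i, j}, {l, k, i, j},
                              {k, l, j, i}, {l, k, j, i}};
        int nperm = 0;
        for (int t = 0; t < 8; ++t) {
          const long code = ((long)pq[t][0] * n + pq[t][1]) * n * n +
                            (long)pq[t][2] * n + pq[t][3];
          bool dup = false;
          for (int u = 0; u < nperm; ++u)
            if (codes[u] == code) { dup = true; break; }
          if (dup) continue;
          codes[nperm++] = code;
          const int p = pq[t][0], q = pq[t][1], r = pq[t][2], s = pq[t][3];
          J(p, q) += P(r, s) * v;
          K(p, r) += P(q, s) * v;
        }
      }
    }
    arma::mat F = H + J - 0.5 * K;
    E_tot = enuc + 0.5 * arma::accu(P % (H + F));
    arma::mat err = X.t() * (F * P * S - S * P * F) * X;
    const double err_max = arma::abs(err).max();
    if (iter > 0 && std::fabs(E_tot - E_old) < conv_e && err_max < conv_err) {
      converged = true;
      break;
    }
    E_old = E_tot;
    diis_F.push_back(F); diis_E.push_back(err);
    if (diis_F.size() > 8) { diis_F.erase(diis_F.begin()); diis_E.erase(diis_E.begin()); }
    const int m = diis_F.size();
    if (m > 1) {
      arma::mat Bm(m + 1, m + 1, arma::fill::zeros);
      arma::vec rhs(m + 1, arma::fill::zeros);
      for (int a = 0; a < m; ++a)
        for (int b = 0; b < m; ++b)
          Bm(a, b) = arma::accu(diis_E[a] % diis_E[b]);
      for (int a = 0; a < m; ++a) { Bm(a, m) = Bm(m, a) = -1; }
      rhs(m) = -1;
      arma::vec cvec;
      if (arma::solve(cvec, Bm, rhs, arma::solve_opts::no_approx)) {
        F.zeros();
        for (int a = 0; a < m; ++a) F += cvec(a) * diis_F[a];
      }
    }
    arma::mat Fo = X.t() * F * X, Cp;
    arma::eig_sym(eps, Cp, Fo);
    Cmo = X * Cp;
    P = 2.0 * Cmo.cols(0, nocc - 1) * Cmo.cols(0, nocc - 1).t();
  }
  return List::create(_["energy"] = E_tot, _["enuc"] = enuc,
                      _["converged"] = converged, _["P"] = P,
                      _["C"] = Cmo, _["eps"] = eps, _["S"] = S,
                      _["nbf"] = n);
}

// Spherical AO values at points.
// [[Rcpp::export]]
arma::mat cpp_ao_values(const List& shells_in, const arma::mat& pts,
                        bool cartesian_d = false) {
  use_cartesian_d = cartesian_d;
  BasisSet bs = build_basis(shells_in);
  const int npt = pts.n_rows;
  arma::mat out(npt, bs.nsph, arma::fill::zeros);
  std::vector<std::array<int, 3>> comps;
  for (size_t s = 0; s < bs.shells.size(); ++s) {
    const Shell& sh = bs.shells[s];
    cart_comps(sh.l, comps);
    const int nca = comps.size();
    const arma::mat Tm = sph_transform(sh.l);
    arma::mat cart(npt, nca);
    for (int q = 0; q < npt; ++q) {
      const double dx = pts(q, 0) - sh.cx, dy = pts(q, 1) - sh.cy,
                   dz = pts(q, 2) - sh.cz;
      const double r2 = dx * dx + dy * dy + dz * dz;
      double radial = 0;
      for (size_t k = 0; k < sh.exps.size(); ++k)
        radial += sh.coefs[k] * std::exp(-sh.exps[k] * r2);
      for (int c = 0; c < nca; ++c) {
        double ang = 1;
        for (int t = 0; t < comps[c][0]; ++t) ang *= dx;
        for (int t = 0; t < comps[c][1]; ++t) ang *= dy;
        for (int t = 0; t < comps[c][2]; ++t) ang *= dz;
        cart(q, c) = ang * radial;
      }
    }
    out.cols(bs.sph_offset[s], bs.sph_offset[s] + sh.nsph() - 1) = cart * Tm.t();
  }
  return out;
}

// Electron density at points from the AO density matrix.
// [[Rcpp::export]]
arma::vec cpp_density(const List& shells_in, const arma::mat& P,
                      const arma::mat& pts, bool cartesian_d = false) {
  arma::mat phi = cpp_ao_values(shells_in, pts, cartesian_d);
  return arma::sum((phi * P) % phi, 1);
}
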