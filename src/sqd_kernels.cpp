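#include <Rcpp.h>
using namespace Rcpp;

// Determinant convention: an occupation string for one spin sector is an
// integer bit mask, bit (p-1) set <=> spatial orbital p occupied.  Spin
// orbitals are ordered alpha block (orbitals 1..M) then beta block
// (orbitals 1..M); a determinant |x> is built by applying creation
// operators for the occupied spin-orbitals in descending position order,
// so the lowest position ends leftmost.  Phases below count occupied
// positions preceding the acted-on position in that global ordering.

static inline int pcnt(unsigned int x) { return __builtin_popcount(x); }
static inline unsigned int below(int p) { return (1u << p) - 1u; }

struct Op {
  bool create;
  bool beta;
  int orb; // 0-based spatial orbital
};

// Apply a string of creation/annihilation operators (given left-to-right)
// to the ket occupation (a, b); operators act right-to-left.  Returns the
// fermionic sign, or 0 if the result vanishes.  a and b are updated.
static int apply_ops(unsigned int &a, unsigned int &b, const Op *ops, int nops) {
  int sign = 1;
  for (int i = nops - 1; i >= 0; --i) {
    const Op &o = ops[i];
    unsigned int bit = 1u << o.orb;
    if (!o.beta) {
      int par = pcnt(a & below(o.orb));
      if (o.create) {
        if (a & bit) return 0;
        if (par & 1) sign = -sign;
        a |= bit;
      } else {
        if (!(a & bit)) return 0;
        if (par & 1) sign = -sign;
        a &= ~bit;
      }
    } else {
      // beta positions follow the whole (current) alpha block
      int par = pcnt(a) + pcnt(b & below(o.orb));
      if (o.create) {
        if (b & bit) return 0;
        if (par & 1) sign = -sign;
        b |= bit;
      } else {
        if (!(b & bit)) return 0;
        if (par & 1) sign = -sign;
        b &= ~bit;
      }
    }
  }
  return sign;
}

static inline double geti(const double *eri, int M, int p, int r, int q, int s) {
  // chemist-notation (pr|qs), 0-based
  return eri[((static_cast<size_t>(p) * M + r) * M + q) * M + s];
}

// Slater-Condon matrix element <bra|H|ket> including the scalar offset E0
// on the diagonal.  h is MxM; eri is the dense M^4 chemist-notation array.
static double sc_element(unsigned int a1, unsigned int b1,
                         unsigned int a2, unsigned int b2,
                         const double *h, const double *eri,
                         int M, double E0) {
  unsigned int dxa = a1 ^ a2, dxb = b1 ^ b2;
  int na = pcnt(dxa), nb = pcnt(dxb);
  if (na + nb > 4) return 0.0;

  if (na == 0 && nb == 0) {
    double val = E0;
    for (int p = 0; p < M; ++p) {
      if (a1 & (1u << p)) val += h[p + M * p];
      if (b1 & (1u << p)) val += h[p + M * p];
    }
    for (int p = 0; p < M; ++p) {
      bool pa = a1 & (1u << p), pb = b1 & (1u << p);
      if (!pa && !pb) continue;
      for (int q = 0; q < M; ++q) {
        bool qa = a1 & (1u << q), qb = b1 & (1u << q);
        double dir = geti(eri, M, p, p, q, q);
        double exc = geti(eri, M, p, q, q, p);
        if (pa && qa) val += 0.5 * (dir - exc);
        if (pb && qb) val += 0.5 * (dir - exc);
        if (pa && qb) val += dir; // both (alpha,beta) and (beta,alpha) orders
      }
    }
    return val;
  }

  if ((na == 2 && nb == 0) || (na == 0 && nb == 2)) {
    bool is_beta = (nb == 2);
    unsigned int d1 = is_beta ? b1 : a1, d2 = is_beta ? b2 : a2;
    unsigned int s1 = is_beta ? a1 : b1, s2 = is_beta ? a2 : b2; // spectator sector
    if (s1 != s2) return 0.0;
    unsigned int dx = d1 ^ d2;
    int p = -1, r = -1; // p occupied in bra only, r in ket only
    for (int k = 0; k < M; ++k) {
      if (dx & (1u << k)) {
        if (d1 & (1u << k)) p = k; else r = k;
      }
    }
    double val = h[p + M * r];
    unsigned int common = d1 & d2;
    for (int q = 0; q < M; ++q) {
      if (common & (1u << q))
        val += geti(eri, M, p, r, q, q) - geti(eri, M, p, q, q, r);
      if (s1 & (1u << q))
        val += geti(eri, M, p, r, q, q);
    }
    unsigned int aa = a2, bb = b2;
    Op ops[2] = { {true, is_beta, p}, {false, is_beta, r} };
    int sign = apply_ops(aa, bb, ops, 2);
    return sign * val;
  }

  if ((na == 4 && nb == 0) || (na == 0 && nb == 4)) {
    bool is_beta = (nb == 4);
    unsigned int d1 = is_beta ? b1 : a1, d2 = is_beta ? b2 : a2;
    if ((is_beta ? a1 : b1) != (is_beta ? a2 : b2)) return 0.0;
    unsigned int dx = d1 ^ d2;
    int p = -1, q = -1, r = -1, s = -1;
    for (int k = 0; k < M; ++k) {
      if (dx & (1u << k)) {
        if (d1 & (1u << k)) { if (p < 0) p = k; else q = k; }
        else { if (r < 0) r = k; else s = k; }
      }
    }
    double val = geti(eri, M, p, r, q, s) - geti(eri, M, p, s, q, r);
    unsigned int aa = a2, bb = b2;
    Op ops[4] = { {true, is_beta, p}, {true, is_beta, q},
                  {false, is_beta, s}, {false, is_beta, r} };
    int sign = apply_ops(aa, bb, ops, 4);
    return sign * val;
  }

  // mixed alpha-beta double excitation
  {
    int p = -1, r = -1, q = -1, s = -1;
    for (int k = 0; k < M; ++k) {
      if (dxa & (1u << k)) { if (a1 & (1u << k)) p = k; else r = k; }
      if (dxb & (1u << k)) { if (b1 & (1u << k)) q = k; else s = k; }
    }
    double val = geti(eri, M, p, r, q, s);
    unsigned int aa = a2, bb = b2;
    Op ops[4] = { {true, false, p}, {true, true, q},
                  {false, true, s}, {false, false, r} };
    int sign = apply_ops(aa, bb, ops, 4);
    return sign * val;
  }
}

// [[Rcpp::export]]
double cpp_sc_element(int a1, int b1, int a2, int b2,
                      NumericMatrix h, NumericVector eri, double E0) {
  int M = h.nrow();
  return sc_element(static_cast<unsigned int>(a1), static_cast<unsigned int>(b1),
                    static_cast<unsigned int>(a2), static_cast<unsigned int>(b2),
                    h.begin(), eri.begin(), M, E0);
}

// Dense (possibly rectangular) Hamiltonian block between two determinant
// lists given as parallel alpha/beta mask vectors.
// [[Rcpp::export]]
NumericMatrix cpp_sc_matrix(IntegerVector a_bra, IntegerVector b_bra,
                            IntegerVector a_ket, IntegerVector b_ket,
                            NumericMatrix h, NumericVector eri, double E0) {
  int M = h.nrow();
  R_xlen_t nb = a_bra.size(), nk = a_ket.size();
  NumericMatrix out(nb, nk);
  const double *hp = h.begin(), *ep = eri.begin();
  for (R_xlen_t j = 0; j < nk; ++j) {
    unsigned int aj = a_ket[j], bj = b_ket[j];
    for (R_xlen_t i = 0; i < nb; ++i) {
      unsigned int ai = a_bra[i], bi = b_bra[i];
      if (pcnt(ai ^ aj) + pcnt(bi ^ bj) > 4) continue;
      out(i, j) = sc_element(ai, bi, aj, bj, hp, ep, M, E0);
    }
  }
  return out;
}

// Matrix of a one-body operator sum_pr k[p,r] a^dag_p a_r within a single
// spin sector, in the basis of the given occupation strings.  Phases are
// intra-string (the other sector's occupations contribute an even count).
// [[Rcpp::export]]
NumericMatrix cpp_onebody_string_matrix(IntegerVector strings, NumericMatrix k) {
  int M = k.nrow();
  R_xlen_t n = strings.size();
  NumericMatrix out(n, n);
  for (R_xlen_t j = 0; j < n; ++j) {
    unsigned int sj = strings[j];
    for (R_xlen_t i = 0; i < n; ++i) {
      unsigned int si = strings[i];
      unsigned int dx = si ^ sj;
      int nd = pcnt(dx);
      if (nd == 0) {
        double v = 0.0;
        for (int p = 0; p < M; ++p)
          if (si & (1u << p)) v += k(p, p);
        out(i, j) = v;
      } else if (nd == 2) {
        int p = -1, r = -1;
        for (int t = 0; t < M; ++t) {
          if (dx & (1u << t)) {
            if (si & (1u << t)) p = t; else r = t;
          }
        }
        // sign: annihilate r from sj, then create p
        int par = pcnt(sj & below(r));
        unsigned int tmp = sj & ~(1u << r);
        par += pcnt(tmp & below(p));
        out(i, j) = (par & 1) ? -k(p, r) : k(p, r);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(IntegerVector x) {
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = pcnt(static_cast<unsigned int>(x[i]));
  return out;
}
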