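#include <Rcpp.h>
#include <complex>
#include <vector>

// Core HOPS derivative evaluation on a fixed (possibly reduced) basis.
// All arguments are used in place (no copies); Rcomplex and
// std::complex<double> share their layout.
//
// psi:   n_aux x n_act complex amplitudes (row 1 = physical wave function)
// M:     -i H_act / hbar over the active state columns (n_act x n_act)
// damp:  per-auxiliary damping k . gamma / hbar
// zt:    per-active-site effective conjugate noise (already divided by hbar)
// up, down: n_aux x n_modes neighbor rows (1-based, 0 = absent)
// cdown: per (aux, mode) down-flux coefficient (already includes k_n)
// cup:   per-mode up-flux coefficient
// mode_col: active-state column of each mode's site (1-based, 0 = inactive)
// expL:  per-mode site-projector expectation <L_n> (zeros for the linear EOM)
// shift: whether the up-flux operator is shifted by <L_n> (non-linear EOMs)
// tcoef: per (aux, mode) terminator closure coefficient (0 = no closure)

typedef std::complex<double> cplx;

static inline const cplx* cptr(const Rcpp::ComplexMatrix& x) {
  return reinterpret_cast<const cplx*>(x.begin());
}
static inline const cplx* cptr(const Rcpp::ComplexVector& x) {
  return reinterpret_cast<const cplx*>(x.begin());
}

// [[Rcpp::export]]
Rcpp::ComplexMatrix hops_deriv_core(const Rcpp::ComplexMatrix& psi,
                                    const Rcpp::ComplexMatrix& M,
                                    const Rcpp::ComplexVector& damp,
                                    const Rcpp::ComplexVector& zt,
                                    const Rcpp::IntegerMatrix& up,
                                    const Rcpp::IntegerMatrix& down,
                                    const Rcpp::ComplexMatrix& cdown,
                                    const Rcpp::ComplexVector& cup,
                                    const Rcpp::IntegerVector& mode_col,
                                    const Rcpp::ComplexVector& expL,
                                    const bool shift,
                                    const Rcpp::ComplexMatrix& tcoef,
                                    const bool terminator) {
  const int na = psi.nrow(), ns = psi.ncol(), nm = up.ncol();
  Rcpp::ComplexMatrix Dout(na, ns);
  cplx* D = reinterpret_cast<cplx*>(Dout.begin());
  const cplx* P = cptr(psi);
  const cplx* Mp = cptr(M);
  const cplx* dampp = cptr(damp);
  const cplx* ztp = cptr(zt);
  const cplx* cupp = cptr(cup);
  const cplx* expp = cptr(expL);

  // self terms: -iH/hbar phase flow, noise driving, hierarchy damping
  for (int j = 0; j < ns; ++j) {
    cplx* dj = D + static_cast<std::size_t>(j) * na;
    const cplx z = ztp[j];
    for (int l = 0; l < ns; ++l) {
      const cplx m = Mp[j + l * ns];  // M[j, l]
      if (m == cplx(0.0, 0.0)) continue;
      const cplx* pl = P + static_cast<std::size_t>(l) * na;
      for (int i = 0; i < na; ++i) dj[i] += m * pl[i];
    }
    const cplx* pj = P + static_cast<std::size_t>(j) * na;
    for (int i = 0; i < na; ++i) dj[i] += (z - dampp[i]) * pj[i];
  }

  const cplx zero(0.0, 0.0);
  std::vector<int> srow, suprow;
  std::vector<cplx> scoef;
  for (int m = 0; m < nm; ++m) {
    const int c = mode_col[m];
    if (c == 0) continue;
    const int s = c - 1;
    const cplx cu = cupp[m];
    const cplx sh = shift ? expp[m] : zero;
    const bool do_shift = shift && sh != zero;
    const int* upm = &up(0, m);
    const int* dnm = &down(0, m);
    const cplx* cd = cptr(cdown) + static_cast<std::size_t>(m) * na;
    const cplx* tc = terminator ? cptr(tcoef) + static_cast<std::size_t>(m) * na
                                : nullptr;
    cplx* ds = D + static_cast<std::size_t>(s) * na;
    const cplx* ps = P + static_cast<std::size_t>(s) * na;
    srow.clear(); suprow.clear(); scoef.clear();
    for (int i = 0; i < na; ++i) {
      const int idn = dnm[i];
      if (idn > 0) ds[i] += cd[i] * ps[idn - 1];
      const int iup = upm[i];
      if (iup > 0) {
        ds[i] -= cu * ps[iup - 1];
        if (do_shift) {
          srow.push_back(i);
          suprow.push_back(iup - 1);
          scoef.push_back(cu * sh);
        }
      } else if (tc && tc[i] != zero) {
        ds[i] -= cu * tc[i] * (1.0 - sh) * ps[i];
      }
    }
    if (!srow.empty()) {
      const std::size_t nr = srow.size();
      for (int j = 0; j < ns; ++j) {
        cplx* dj = D + static_cast<std::size_t>(j) * na;
        const cplx* pj = P + static_cast<std::size_t>(j) * na;
        for (std::size_t t = 0; t < nr; ++t)
          dj[srow[t]] += scoef[t] * pj[suprow[t]];
      }
    }
  }
  return Dout;
}
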