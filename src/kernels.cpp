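#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// All kernels operate on plain A/C/G/T strings; tags ('*') are stripped by
// the R callers before they reach this layer.

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 0;
}

// [[Rcpp::export]]
CharacterVector rc_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(x[i]);
    size_t L = std::strlen(s);
    buf.assign(L, ' ');
    for (size_t j = 0; j < L; ++j) {
      char c = comp_base(s[L - 1 - j]);
      if (c == 0)
        stop("non-ACGT character '%c' in sequence %d", s[L - 1 - j], (int)(i + 1));
      buf[j] = c;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gc_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(x[i]);
    size_t L = std::strlen(s);
    if (L == 0) stop("empty primer at position %d", (int)(i + 1));
    int gc = 0;
    for (size_t j = 0; j < L; ++j)
      if (s[j] == 'G' || s[j] == 'C') ++gc;
    out[i] = 100.0 * gc / (double)L;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector maxrun_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(x[i]);
    size_t L = std::strlen(s);
    if (L == 0) stop("empty primer at position %d", (int)(i + 1));
    int best = 1, run = 1;
    for (size_t j = 1; j < L; ++j) {
      run = (s[j] == s[j - 1]) ? run + 1 : 1;
      if (run > best) best = run;
    }
    out[i] = best;
  }
  return out;
}

// Nearest-neighbor melting temperature.  dh/ds are length-16 tables indexed
// by 4*first+second (base order A,C,G,T); initiation split by terminal base
// pair class (A/T vs G/C); entropic salt correction 0.368 * n_stacks * ln(Na).
// Tm = 1000*dH / (dS_corrected + R*ln(C/4)) - 273.15, R in cal/(mol K).
// [[Rcpp::export]]
NumericVector tm_cpp(CharacterVector x, NumericVector dh, NumericVector ds,
                     double dh_init_at, double ds_init_at,
                     double dh_init_gc, double ds_init_gc,
                     double conc, double na) {
  const double Rgas = 1.987;
  R_xlen_t n = x.size();
  NumericVector out(n);
  double lnconc = std::log(conc / 4.0);
  double lnna = std::log(na);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(x[i]);
    size_t L = std::strlen(s);
    if (L < 2) stop("primer shorter than 2 bases at position %d", (int)(i + 1));
    double H = 0.0, S = 0.0;
    for (size_t j = 0; j + 1 < L; ++j) {
      int a = base_idx(s[j]), b = base_idx(s[j + 1]);
      if (a < 0 || b < 0) stop("non-ACGT character in primer %d", (int)(i + 1));
      H += dh[4 * a + b];
      S += ds[4 * a + b];
    }
    for (int e = 0; e < 2; ++e) {
      char c = e == 0 ? s[0] : s[L - 1];
      if (c == 'G' || c == 'C') { H += dh_init_gc; S += ds_init_gc; }
      else                      { H += dh_init_at; S += ds_init_at; }
    }
    S += 0.368 * (double)(L - 1) * lnna;
    out[i] = 1000.0 * H / (S + Rgas * lnconc) - 273.15;
  }
  return out;
}

// Sum of dG37 over the `stacks` dinucleotide stacks spanned by the 3'
// terminal window (stacks+1 bases) of each primer.
// [[Rcpp::export]]
NumericVector dg3_cpp(CharacterVector x, NumericVector dg, int stacks) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(x[i]);
    size_t L = std::strlen(s);
    if ((int)L < stacks + 1)
      stop("primer shorter than %d bases at position %d", stacks + 1, (int)(i + 1));
    double G = 0.0;
    for (size_t j = L - stacks - 1; j + 1 < L; ++j) {
      int a = base_idx(s[j]), b = base_idx(s[j + 1]);
      if (a < 0 || b < 0) stop("non-ACGT character in primer %d", (int)(i + 1));
      G += dg[4 * a + b];
    }
    out[i] = G;
  }
  return out;
}

static int comp_any_one(const char *p, const char *q) {
  int lp = (int)std::strlen(p), lq = (int)std::strlen(q);
  // reverse q once
  std::string r(q);
  std::reverse(r.begin(), r.end());
  int best = 0;
  for (int off = 1 - lq; off <= lp - 1; ++off) {
    int lo = off > 0 ? off : 0;
    int hi = (off + lq - 1 < lp - 1) ? off + lq - 1 : lp - 1;
    int score = 0;
    for (int i = lo; i <= hi; ++i)
      if (comp_base(p[i]) == r[i - off]) ++score;
    if (score > best) best = score;
  }
  return best;
}

static int comp_end_one(const char *p, const char *q) {
  int lp = (int)std::strlen(p), lq = (int)std::strlen(q);
  std::string r(q);
  std::reverse(r.begin(), r.end());
  int best = 0;
  // offsets for which the 3'-terminal base of p (index lp-1) is aligned
  for (int off = lp - lq; off <= lp - 1; ++off) {
    if (comp_base(p[lp - 1]) != r[lp - 1 - off]) continue;
    int run = 0;
    int i = lp - 1;
    while (i >= 0 && i >= off && i - off <= lq - 1 &&
           comp_base(p[i]) == r[i - off]) {
      ++run;
      --i;
    }
    if (run > best) best = run;
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector comp_any_cpp(CharacterVector p, CharacterVector q) {
  R_xlen_t n = p.size();
  if (q.size() != n) stop("p and q must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = comp_any_one(CHAR(p[i]), CHAR(q[i]));
  return out;
}

// [[Rcpp::export]]
IntegerVector comp_end_cpp(CharacterVector p, CharacterVector q) {
  R_xlen_t n = p.size();
  if (q.size() != n) stop("p and q must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = comp_end_one(CHAR(p[i]), CHAR(q[i]));
  return out;
}

// Pairwise Hamming distance <= k, with early exit; errors on length mismatch
// (callers pair strings through keys that embed the length).
// [[Rcpp::export]]
LogicalVector hamming_le_cpp(CharacterVector a, CharacterVector b, int k) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(a[i]), *t = CHAR(b[i]);
    size_t la = std::strlen(s), lb = std::strlen(t);
    if (la != lb) stop("strings of unequal length at position %d", (int)(i + 1));
    int m = 0;
    bool ok = true;
    for (size_t j = 0; j < la; ++j) {
      if (s[j] != t[j] && ++m > k) { ok = false; break; }
    }
    out[i] = ok;
  }
  return out;
}

// TRUE when sidset a[i] is NOT a subset of sidset b[i]; both sorted ascending.
// [[Rcpp::export]]
LogicalVector not_subset_cpp(List a, List b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    IntegerVector x = a[i], y = b[i];
    R_xlen_t ix = 0, iy = 0;
    bool notsub = false;
    while (ix < x.size()) {
      while (iy < y.size() && y[iy] < x[ix]) ++iy;
      if (iy >= y.size() || y[iy] != x[ix]) { notsub = true; break; }
      ++ix;
    }
    out[i] = notsub;
  }
  return out;
}

static bool not_subset_raw(const int *a, int na, const int *b, int nb) {
  int ix = 0, iy = 0;
  while (ix < na) {
    while (iy < nb && b[iy] < a[ix]) ++iy;
    if (iy >= nb || b[iy] != a[ix]) return true;
    ++ix;
  }
  return false;
}

// Quadratic cross-hybridization oracle kernel: primer i is invalid iff some
// view j of the same length has Hamming distance <= k and a sidset not
// contained in the primer's sidset.  Independent of the seed-index path:
// no seeding, plain double loop over length-matched views.
// [[Rcpp::export]]
LogicalVector oracle_invalidate_cpp(CharacterVector primers, List psid,
                                    CharacterVector views, List vsid, int k) {
  R_xlen_t np = primers.size(), nv = views.size();
  if (psid.size() != np || vsid.size() != nv) stop("sidset list length mismatch");
  std::vector<const char*> vp(nv);
  std::vector<int> vl(nv), vsn(nv);
  std::vector<const int*> vs(nv);
  for (R_xlen_t j = 0; j < nv; ++j) {
    vp[j] = CHAR(STRING_ELT(views, j));
    vl[j] = (int)std::strlen(vp[j]);
    SEXP sv = VECTOR_ELT(vsid, j);
    vs[j] = INTEGER(sv);
    vsn[j] = (int)Rf_xlength(sv);
  }
  LogicalVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    const char *p = CHAR(STRING_ELT(primers, i));
    int lp = (int)std::strlen(p);
    SEXP sp = VECTOR_ELT(psid, i);
    const int *ps = INTEGER(sp);
    int psn = (int)Rf_xlength(sp);
    bool invalid = false;
    for (R_xlen_t j = 0; j < nv && !invalid; ++j) {
      if (vl[j] != lp) continue;
      int m = 0;
      bool close = true;
      const char *v = vp[j];
      for (int c = 0; c < lp; ++c)
        if (p[c] != v[c] && ++m > k) { close = false; break; }
      if (!close) continue;
      if (not_subset_raw(vs[j], vsn[j], ps, psn)) invalid = true;
    }
    out[i] = invalid;
  }
  return out;
}

// Quadratic oracle for the 3'-anchored (5' cross-hybridization) filter:
// primer i is invalid iff some view of the same length shares its suffix
// under the trim rule (drop min(trim, len-1) leading bases), differs as a
// full string, and has a sidset not contained in the primer's.  No suffix
// hashing: plain double loop.
// [[Rcpp::export]]
LogicalVector oracle_suffix_cpp(CharacterVector primers, List psid,
                                CharacterVector views, List vsid, int trim) {
  R_xlen_t np = primers.size(), nv = views.size();
  if (psid.size() != np || vsid.size() != nv) stop("sidset list length mismatch");
  std::vector<const char*> vp(nv);
  std::vector<int> vl(nv), vsn(nv);
  std::vector<const int*> vs(nv);
  for (R_xlen_t j = 0; j < nv; ++j) {
    vp[j] = CHAR(STRING_ELT(views, j));
    vl[j] = (int)std::strlen(vp[j]);
    SEXP sv = VECTOR_ELT(vsid, j);
    vs[j] = INTEGER(sv);
    vsn[j] = (int)Rf_xlength(sv);
  }
  LogicalVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    const char *p = CHAR(STRING_ELT(primers, i));
    int lp = (int)std::strlen(p);
    int t = trim < lp - 1 ? trim : lp - 1;
    SEXP sp = VECTOR_ELT(psid, i);
    const int *ps = INTEGER(sp);
    int psn = (int)Rf_xlength(sp);
    bool invalid = false;
    for (R_xlen_t j = 0; j < nv && !invalid; ++j) {
      if (vl[j] != lp) continue;
      const char *v = vp[j];
      if (std::memcmp(p + t, v + t, lp - t) != 0) continue;
      if (std::memcmp(p, v, lp) == 0) continue;
      if (not_subset_raw(vs[j], vsn[j], ps, psn)) invalid = true;
    }
    out[i] = invalid;
  }
  return out;
}

// Slice a sorted sid vector into per-group unique sidsets; starts/ends are
// 1-based inclusive row ranges of groups in an occurrence table sorted by
// (key, sid).
// [[Rcpp::export]]
List slice_sidsets_cpp(IntegerVector sid, IntegerVector starts,
                       IntegerVector ends) {
  R_xlen_t ng = starts.size();
  if (ends.size() != ng) stop("starts/ends length mismatch");
  List out(ng);
  std::vector<int> buf;
  for (R_xlen_t g = 0; g < ng; ++g) {
    buf.clear();
    int prev = NA_INTEGER;
    for (int r = starts[g] - 1; r <= ends[g] - 1; ++r) {
      if (sid[r] != prev) { buf.push_back(sid[r]); prev = sid[r]; }
    }
    out[g] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
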