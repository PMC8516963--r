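#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) of an integer-encoded amino-acid
// sequence against a position-specific score matrix.
//
// prof:   L x 20 matrix of per-column log-odds scores (bits)
// seq:    0-based residue indices; -1 encodes an unscored residue (X),
//         which contributes 0 to any column it is aligned to
// A gap of length g costs gap_open + g * gap_extend (both > 0).
//
// Tie-breaking is deterministic: diagonal > up (gap in profile) >
// left (gap in sequence); gap-open is preferred over gap-extend on ties.
// The best cell is the first maximum in row-major order (sequence outer,
// profile column inner), compared with strict '>'.

static inline double cell_score(const NumericMatrix& prof, int col, int aa) {
  if (aa < 0) return 0.0;
  return prof(col, aa);
}

// [[Rcpp::export(name = ".sw_profile_align")]]
List sw_profile_align(NumericMatrix prof, IntegerVector seq,
                      double gap_open, double gap_extend,
                      bool traceback = true) {
  const int L = prof.nrow();
  const int n = seq.size();
  if (n == 0 || L == 0) {
    return List::create(_["score"] = 0.0,
                        _["seq_start"] = 0, _["seq_end"] = -1,
                        _["col_start"] = 0, _["col_end"] = -1,
                        _["trace"] = IntegerMatrix(0, 2));
  }
  const double go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const double ge = gap_extend;
  const double NEG = -1e30;

  std::vector<double> Hprev(L + 1, 0.0), Hcur(L + 1, 0.0);
  std::vector<double> Fprev(L + 1, NEG), Fcur(L + 1, NEG);
  // pointer codes. H: 0 stop, 1 diag, 2 up(F), 3 left(E)
  //                E: 1 open(from H), 0 extend ; F likewise
  std::vector<signed char> ptrH, ptrE, ptrF;
  if (traceback) {
    ptrH.assign((size_t)(n + 1) * (L + 1), 0);
    ptrE.assign((size_t)(n + 1) * (L + 1), 0);
    ptrF.assign((size_t)(n + 1) * (L + 1), 0);
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    double E = NEG;
    Hcur[0] = 0.0;
    Fcur[0] = NEG;
    for (int j = 1; j <= L; ++j) {
      // E: gap in sequence (move left along profile columns)
      double e_open = Hcur[j - 1] - go;
      double e_ext  = E - ge;
      signed char pe;
      if (e_open >= e_ext) { E = e_open; pe = 1; } else { E = e_ext; pe = 0; }
      // F: gap in profile (consume sequence residue, move up)
      double f_open = Hprev[j] - go;
      double f_ext  = Fprev[j] - ge;
      signed char pf;
      if (f_open >= f_ext) { Fcur[j] = f_open; pf = 1; }
      else                 { Fcur[j] = f_ext;  pf = 0; }

      double diag = Hprev[j - 1] + cell_score(prof, j - 1, seq[i - 1]);
      double v = 0.0; signed char ph = 0;
      if (diag > v)    { v = diag;    ph = 1; }
      if (Fcur[j] > v) { v = Fcur[j]; ph = 2; }
      if (E > v)       { v = E;       ph = 3; }
      Hcur[j] = v;
      if (traceback) {
        size_t off = (size_t)i * (L + 1) + j;
        ptrH[off] = ph; ptrE[off] = pe; ptrF[off] = pf;
      }
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (!traceback || best <= 0.0) {
    return List::create(_["score"] = best,
                        _["seq_start"] = 0, _["seq_end"] = -1,
                        _["col_start"] = 0, _["col_end"] = -1,
                        _["trace"] = IntegerMatrix(0, 2));
  }

  // traceback from (bi, bj)
  std::vector<int> tr_seq, tr_col;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    size_t off = (size_t)i * (L + 1) + j;
    if (state == 0) {
      signed char p = ptrH[off];
      if (p == 0) break;
      if (p == 1) { tr_seq.push_back(i); tr_col.push_back(j); --i; --j; }
      else if (p == 2) state = 2;
      else state = 1;
    } else if (state == 1) {          // E: gap in sequence
      signed char p = ptrE[off];
      --j;
      if (p == 1) state = 0;
    } else {                          // F: gap in profile
      signed char p = ptrF[off];
      --i;
      if (p == 1) state = 0;
    }
  }
  const int npair = (int)tr_seq.size();
  IntegerMatrix trace(npair, 2);
  for (int k = 0; k < npair; ++k) {   // reverse into ascending order
    trace(k, 0) = tr_seq[npair - 1 - k];
    trace(k, 1) = tr_col[npair - 1 - k];
  }
  int seq_start = npair ? trace(0, 0) : 0;
  int col_start = npair ? trace(0, 1) : 0;
  return List::create(_["score"] = best,
                      _["seq_start"] = seq_start, _["seq_end"] = bi,
                      _["col_start"] = col_start, _["col_end"] = bj,
                      _["trace"] = trace);
}

// Score-only batch interface used for decoy calibration and database scans.
// [[Rcpp::export(name = ".sw_profile_scores")]]
NumericVector sw_profile_scores(NumericMatrix prof, List seqs,
                                double gap_open, double gap_extend) {
  const int m = seqs.size();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    IntegerVector seq = seqs[s];
    List r = sw_profile_align(prof, seq, gap_open, gap_extend, false);
    out[s] = as<double>(r["score"]);
  }
  return out;
}
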