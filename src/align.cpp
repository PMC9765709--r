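#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a position-specific scoring profile
// against a protein, affine gaps.  Profile rows are columns of the model,
// profile(i, a) is the log-odds of residue a at column i.  seq holds 0-based
// residue indices into the same alphabet.  Returns the best score, the number
// of profile columns consumed by match states on the best path (coverage
// numerator), and the 1-based span of the protein that is aligned.
//
// States: M (diagonal), X (gap in protein: profile column skipped),
// Y (gap in profile: protein residue skipped).

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix profile, IntegerVector seq,
                       double gap_open, double gap_extend) {
  const int L = profile.nrow();     // profile columns
  const int n = seq.size();         // protein length
  const double NEG = -1e30;

  NumericMatrix M(L + 1, n + 1), X(L + 1, n + 1), Y(L + 1, n + 1);
  // traceback: 0 none/stop, 1 from M, 2 from X, 3 from Y
  IntegerMatrix tbM(L + 1, n + 1), tbX(L + 1, n + 1), tbY(L + 1, n + 1);

  for (int i = 0; i <= L; ++i) { M(i, 0) = 0; X(i, 0) = NEG; Y(i, 0) = NEG; }
  for (int j = 0; j <= n; ++j) { M(0, j) = 0; X(0, j) = NEG; Y(0, j) = NEG; }

  double best = 0; int bi = 0, bj = 0, bs = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = profile(i - 1, seq[j - 1]);
      // M
      double m0 = M(i - 1, j - 1), x0 = X(i - 1, j - 1), y0 = Y(i - 1, j - 1);
      double mbest = m0; int mfrom = 1;
      if (x0 > mbest) { mbest = x0; mfrom = 2; }
      if (y0 > mbest) { mbest = y0; mfrom = 3; }
      if (0.0 > mbest) { mbest = 0.0; mfrom = 0; }
      M(i, j) = mbest + s; tbM(i, j) = mfrom;
      // X: skip profile column i (deletion in protein)
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 1; } else { X(i, j) = xe; tbX(i, j) = 2; }
      // Y: skip protein residue j (insertion in protein)
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 1; } else { Y(i, j) = ye; tbY(i, j) = 3; }
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; bs = 1; }
    }
  }

  int matched = 0, pstart = bj, pend = bj, cstart = bi, cend = bi;
  if (bs == 1) {
    int i = bi, j = bj, state = 1;
    while (i > 0 && j > 0) {
      if (state == 1) {
        ++matched; pstart = j; cstart = i;
        int from = tbM(i, j); --i; --j;
        if (from == 0) break;
        state = from;
      } else if (state == 2) { int from = tbX(i, j); --i; state = from; }
      else { int from = tbY(i, j); --j; state = from; }
    }
  } else { pstart = pend = cstart = cend = 0; }

  return List::create(_["score"] = best,
                      _["matched_cols"] = matched,
                      _["protein_start"] = pstart, _["protein_end"] = pend,
                      _["col_start"] = cstart, _["col_end"] = cend);
}

// Batch scan: one profile against a list of integer-encoded proteins.
// Returns a matrix with columns score, matched_cols, protein_start, protein_end.
// [[Rcpp::export]]
NumericMatrix profile_scan_cpp(NumericMatrix profile, List seqs,
                               double gap_open, double gap_extend) {
  int m = seqs.size();
  NumericMatrix out(m, 4);
  for (int k = 0; k < m; ++k) {
    IntegerVector s = seqs[k];
    List r = profile_align_cpp(profile, s, gap_open, gap_extend);
    out(k, 0) = as<double>(r["score"]);
    out(k, 1) = as<int>(r["matched_cols"]);
    out(k, 2) = as<int>(r["protein_start"]);
    out(k, 3) = as<int>(r["protein_end"]);
  }
  colnames(out) = CharacterVector::create("score", "matched_cols",
                                          "protein_start", "protein_end");
  return out;
}

// Best local-alignment score only (no traceback), rolling rows; used for
// E-value calibration where thousands of decoys are scored.
// [[Rcpp::export]]
NumericVector profile_best_scores_cpp(NumericMatrix profile, List seqs,
                                      double gap_open, double gap_extend) {
  const int L = profile.nrow();
  const double NEG = -1e30;
  int nseq = seqs.size();
  NumericVector out(nseq);
  std::vector<double> Mprev, Mcur, Xprev, Xcur, Yprev, Ycur;
  for (int k = 0; k < nseq; ++k) {
    IntegerVector s = seqs[k];
    const int n = s.size();
    Mprev.assign(n + 1, 0.0); Xprev.assign(n + 1, NEG); Yprev.assign(n + 1, NEG);
    Mcur.assign(n + 1, 0.0); Xcur.assign(n + 1, NEG); Ycur.assign(n + 1, NEG);
    double best = 0;
    for (int i = 1; i <= L; ++i) {
      Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
      const double *prow = &profile(i - 1, 0);
      const int stride = L; // column-major: profile(i-1, a) = prow[a * L]
      for (int j = 1; j <= n; ++j) {
        double sc = prow[(size_t)s[j - 1] * stride];
        double m0 = Mprev[j - 1];
        if (Xprev[j - 1] > m0) m0 = Xprev[j - 1];
        if (Yprev[j - 1] > m0) m0 = Yprev[j - 1];
        if (0.0 > m0) m0 = 0.0;
        Mcur[j] = m0 + sc;
        double xo = Mprev[j] - gap_open, xe = Xprev[j] - gap_extend;
        Xcur[j] = xo >= xe ? xo : xe;
        double yo = Mcur[j - 1] - gap_open, ye = Ycur[j - 1] - gap_extend;
        Ycur[j] = yo >= ye ? yo : ye;
        if (Mcur[j] > best) best = Mcur[j];
      }
      std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }
    out[k] = best;
  }
  return out;
}

// Simple pairwise peptide alignment (match/mismatch scores, affine gaps),
// local or global.  Returns score, number of identities, and the 1-based
// aligned spans of both sequences.  Used for mature-peptide homology matching
// and greedy sequence clustering.
// [[Rcpp::export]]
List pair_align_cpp(IntegerVector a, IntegerVector b,
                    double match, double mismatch,
                    double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0; X(0, 0) = Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = local ? 0 : NEG;
    X(i, 0) = local ? NEG : -gap_open - (i - 1) * gap_extend;
    Y(i, 0) = NEG;
    tbX(i, 0) = 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = local ? 0 : NEG;
    Y(0, j) = local ? NEG : -gap_open - (j - 1) * gap_extend;
    X(0, j) = NEG;
    tbY(0, j) = 3;
  }

  double best = local ? 0 : NEG; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double m0 = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      int mfrom = (m0 == M(i - 1, j - 1)) ? 1 : ((m0 == X(i - 1, j - 1)) ? 2 : 3);
      if (local && 0.0 > m0) { m0 = 0.0; mfrom = 0; }
      M(i, j) = m0 + s; tbM(i, j) = mfrom;
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 1; } else { X(i, j) = xe; tbX(i, j) = 2; }
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 1; } else { Y(i, j) = ye; tbY(i, j) = 3; }
      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  int state = 1;
  if (!local) {
    bi = n; bj = m;
    best = M(n, m); state = 1;
    if (X(n, m) > best) { best = X(n, m); state = 2; }
    if (Y(n, m) > best) { best = Y(n, m); state = 3; }
  }

  int nid = 0, naln = 0;
  int as_ = bi + 1, ae = bi, bs_ = bj + 1, be = bj;
  {
    int i = bi, j = bj;
    while (i > 0 || j > 0) {
      if (state == 1) {
        if (i == 0 || j == 0) break;
        ++naln;
        if (a[i - 1] == b[j - 1]) ++nid;
        as_ = i; bs_ = j;
        int from = tbM(i, j); --i; --j;
        if (local && from == 0) break;
        state = from;
      } else if (state == 2) {
        if (i == 0) break;
        ++naln; as_ = i;
        int from = tbX(i, j); --i; state = from;
      } else {
        if (j == 0) break;
        ++naln; bs_ = j;
        int from = tbY(i, j); --j; state = from;
      }
      if (local && i == 0 && j == 0) break;
      if (!local && i == 0 && j == 0) break;
      if (!local && i == 0) state = 3;
      if (!local && j == 0) state = 2;
    }
  }

  return List::create(_["score"] = best, _["n_ident"] = nid,
                      _["n_aligned"] = naln,
                      _["a_start"] = as_, _["a_end"] = ae,
                      _["b_start"] = bs_, _["b_end"] = be);
}
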