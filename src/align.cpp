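#include <Rcpp.h>
using namespace Rcpp;

// Global (end-to-end) alignment with affine gap penalties, Gotoh three-state
// recursion. Gap cost convention: a gap run of length L costs
// open + (L - 1) * ext.
//
// Tie-breaking is deterministic: match state > gap-in-b (consume a) >
// gap-in-a (consume b), applied identically in the recursion and traceback,
// so co-optimal alignments always resolve to the same traceback.
//
// Value matrices are rolled row by row; full byte matrices keep the
// traceback pointers (predecessor state per state and cell).

static const double NEG_INF = -1e300;

struct AlnResult {
  double score;
  std::vector<int> pa, pb; // 1-based positions, 0 = gap
};

template <class CellScore>
static AlnResult gotoh(int n, int m, CellScore cell,
                       double gap_open, double gap_ext) {
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  const size_t W = m + 1;
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W), tbY((n + 1) * W);

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = -gap_open - (j - 1) * gap_ext;
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = -gap_open - (i - 1) * gap_ext;
    tbX[i * W] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      // M: diagonal predecessor, preference M > X > Y
      double bm = Mp[j - 1];
      unsigned char pm = 0;
      if (Xp[j - 1] > bm) { bm = Xp[j - 1]; pm = 1; }
      if (Yp[j - 1] > bm) { bm = Yp[j - 1]; pm = 2; }
      Mc[j] = bm + cell(i - 1, j - 1);
      tbM[i * W + j] = pm;

      // X: gap in b (consume a); open from M or Y above, extend from X above
      double xo = (Mp[j] >= Yp[j] ? Mp[j] : Yp[j]) - gap_open;
      unsigned char px = (Mp[j] >= Yp[j]) ? 0 : 2;
      double xe = Xp[j] - gap_ext;
      if (xo >= xe) { Xc[j] = xo; tbX[i * W + j] = px; }
      else          { Xc[j] = xe; tbX[i * W + j] = 1; }

      // Y: gap in a (consume b); open from M or X left, extend from Y left
      double yo = (Mc[j - 1] >= Xc[j - 1] ? Mc[j - 1] : Xc[j - 1]) - gap_open;
      unsigned char py = (Mc[j - 1] >= Xc[j - 1]) ? 0 : 1;
      double ye = Yc[j - 1] - gap_ext;
      if (yo >= ye) { Yc[j] = yo; tbY[i * W + j] = py; }
      else          { Yc[j] = ye; tbY[i * W + j] = 2; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  AlnResult res;
  res.score = Mp[m];
  int state = 0;
  if (Xp[m] > res.score) { res.score = Xp[m]; state = 1; }
  if (Yp[m] > res.score) { res.score = Yp[m]; state = 2; }

  res.pa.reserve(n + m); res.pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char p = tbM[i * W + j];
      res.pa.push_back(i); res.pb.push_back(j);
      --i; --j; state = p;
    } else if (state == 1) {
      unsigned char p = tbX[i * W + j];
      res.pa.push_back(i); res.pb.push_back(0);
      --i; state = p;
    } else {
      unsigned char p = tbY[i * W + j];
      res.pa.push_back(0); res.pb.push_back(j);
      --j; state = p;
    }
  }
  std::reverse(res.pa.begin(), res.pa.end());
  std::reverse(res.pb.begin(), res.pb.end());
  return res;
}

static List as_list(const AlnResult& r) {
  return List::create(_["score"] = r.score,
                      _["pos_a"] = IntegerVector(r.pa.begin(), r.pa.end()),
                      _["pos_b"] = IntegerVector(r.pb.begin(), r.pb.end()));
}

// sequences as 1-based codes into the substitution matrix S
// [[Rcpp::export]]
List align_seqs_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int k = S.nrow();
  std::vector<double> sm(S.begin(), S.end());
  std::vector<int> ia(a.begin(), a.end()), ib(b.begin(), b.end());
  for (int i = 0; i < n; ++i) if (ia[i] < 1 || ia[i] > k) stop("code out of range");
  for (int j = 0; j < m; ++j) if (ib[j] < 1 || ib[j] > S.ncol()) stop("code out of range");
  AlnResult r = gotoh(n, m, [&](int i, int j) {
    return sm[(ia[i] - 1) + (size_t)(ib[j] - 1) * k];
  }, gap_open, gap_ext);
  return as_list(r);
}

// precomputed cell score matrix (profile-profile alignment)
// [[Rcpp::export]]
List align_cells_cpp(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  if (n == 0 || m == 0) stop("empty profile");
  std::vector<double> cm(C.begin(), C.end());
  AlnResult r = gotoh(n, m, [&](int i, int j) {
    return cm[i + (size_t)j * n];
  }, gap_open, gap_ext);
  return as_list(r);
}
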