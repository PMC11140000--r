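#include <Rcpp.h>
using namespace Rcpp;

// Gap convention throughout (matching Biostrings::pairwiseAlignment and
// BLAST): a gap of length L costs gap_open + L * gap_ext.

static const int NEG = -1000000000;

// Best local (Smith-Waterman) alignment score of one query against many
// subjects under a substitution matrix. Full dynamic programming, score
// only (no traceback); detailed alignments for passing pairs are
// recomputed in R via Biostrings.
// [[Rcpp::export]]
NumericVector cpp_sw_score_many(IntegerVector query, List subjects,
                                IntegerMatrix smat, int gap_open,
                                int gap_ext) {
  const int m = query.size();
  const int nsub = subjects.size();
  const int goe = gap_open + gap_ext;
  NumericVector out(nsub);
  const int nrow = smat.nrow();
  std::vector<int> H(m + 1), E(m + 1);
  for (int s = 0; s < nsub; ++s) {
    IntegerVector subj = subjects[s];
    const int n = subj.size();
    std::fill(H.begin(), H.end(), 0);
    std::fill(E.begin(), E.end(), NEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      int diag = 0;        // H[i-1][j-1]
      int left = 0;        // H[i][j-1]
      int F = NEG;         // gap consuming query (horizontal), per row
      const int bi = subj[i - 1];
      const int *col = &smat[0] + (R_xlen_t)bi * nrow;
      for (int j = 1; j <= m; ++j) {
        const int up = H[j];                       // H[i-1][j]
        E[j] = std::max(up - goe, E[j] - gap_ext); // vertical gap
        F = std::max(left - goe, F - gap_ext);     // horizontal gap
        int h = diag + col[query[j - 1]];
        if (E[j] > h) h = E[j];
        if (F > h) h = F;
        if (h < 0) h = 0;
        diag = up;
        H[j] = h;
        left = h;
        if (h > best) best = h;
      }
    }
    out[s] = best;
  }
  return out;
}

// --- glocal ("fitting") alignment -----------------------------------------
// The shorter sequence (pattern) is aligned globally; the longer sequence
// (subject) contributes free leading/trailing gaps. Identity is
// matches / alignment columns over the pattern's aligned extent.

struct Cell { int sc, mt, cl; };

static inline void take(Cell &dst, int sc, int mt, int cl) {
  if (sc > dst.sc || (sc == dst.sc && mt > dst.mt)) {
    dst.sc = sc; dst.mt = mt; dst.cl = cl;
  }
}

// Score-only glocal DP (used as an exact screen before the match-tracking
// pass; see cpp_cluster_greedy).
static int glocal_score(const IntegerVector &p, const IntegerVector &s,
                        int match, int mismatch, int gap_open, int gap_ext) {
  const int m = p.size(), n = s.size();
  const int goe = gap_open + gap_ext;
  std::vector<int> H(n + 1), X(n + 1);
  for (int j = 0; j <= n; ++j) { H[j] = 0; X[j] = NEG; }
  int best = NEG;
  for (int i = 1; i <= m; ++i) {
    int diag = H[0];
    H[0] = -(gap_open + i * gap_ext);
    int Y = NEG;
    const int a = p[i - 1];
    for (int j = 1; j <= n; ++j) {
      X[j] = std::max(H[j] - goe, X[j] - gap_ext);
      Y = std::max(H[j - 1] - goe, Y - gap_ext);
      const int b = s[j - 1];
      int h = diag + ((a == b && a != 4) ? match : mismatch);
      if (X[j] > h) h = X[j];
      if (Y > h) h = Y;
      diag = H[j];
      H[j] = h;
    }
  }
  for (int j = 0; j <= n; ++j) if (H[j] > best) best = H[j];
  return best;
}

// Full glocal DP tracking matches and columns along the optimal path.
// Returns (score, matches, columns, identity).
// [[Rcpp::export]]
NumericVector cpp_glocal_identity(IntegerVector pattern, IntegerVector subject,
                                  int match, int mismatch, int gap_open,
                                  int gap_ext) {
  const int m = pattern.size(), n = subject.size();
  const int goe = gap_open + gap_ext;
  std::vector<Cell> H(n + 1), Hprev(n + 1), X(n + 1);
  for (int j = 0; j <= n; ++j) {
    Hprev[j] = {0, 0, 0};            // free leading gap in subject
    X[j] = {NEG, 0, 0};
  }
  for (int i = 1; i <= m; ++i) {
    H[0] = {-(gap_open + i * gap_ext), 0, i};
    Cell Y = {NEG, 0, 0};
    const int a = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      // gap in subject (consumes pattern)
      Cell x = {NEG, 0, 0};
      take(x, Hprev[j].sc - goe, Hprev[j].mt, Hprev[j].cl + 1);
      take(x, X[j].sc - gap_ext, X[j].mt, X[j].cl + 1);
      X[j] = x;
      // gap in pattern (consumes subject)
      Cell y = {NEG, 0, 0};
      take(y, H[j - 1].sc - goe, H[j - 1].mt, H[j - 1].cl + 1);
      take(y, Y.sc - gap_ext, Y.mt, Y.cl + 1);
      Y = y;
      // diagonal
      const int b = subject[j - 1];
      const bool is_match = (a == b && a != 4);
      Cell d = {Hprev[j - 1].sc + (is_match ? match : mismatch),
                Hprev[j - 1].mt + (is_match ? 1 : 0),
                Hprev[j - 1].cl + 1};
      Cell h = d;
      take(h, x.sc, x.mt, x.cl);
      take(h, y.sc, y.mt, y.cl);
      H[j] = h;
    }
    std::swap(H, Hprev);
  }
  Cell bestc = {NEG, 0, 1};
  for (int j = 0; j <= n; ++j)
    take(bestc, Hprev[j].sc, Hprev[j].mt, Hprev[j].cl);
  const double cols = bestc.cl > 0 ? bestc.cl : 1;
  return NumericVector::create(bestc.sc, bestc.mt, bestc.cl,
                               bestc.mt / cols);
}

// Greedy incremental clustering. `seqs` must be pre-sorted (length
// descending, id ascending). Each sequence joins the first existing
// cluster whose representative aligns at identity >= threshold (first
// fit), else founds a new cluster. The score-only pass is an exact
// screen: an alignment over cols >= Ls columns with identity >= t scores
// at least cols * (t*match - (1-t)*pen) where pen = max(gap_open +
// gap_ext, -mismatch) is the worst per-column penalty, so a pair whose
// optimal score falls below Ls * (t*match - (1-t)*pen) cannot reach
// identity t and skips the match-tracking pass.
// [[Rcpp::export]]
List cpp_cluster_greedy(List seqs, double threshold, int match, int mismatch,
                        int gap_open, int gap_ext) {
  const int n = seqs.size();
  IntegerVector assign(n);   // 1-based index of representative sequence
  NumericVector ident(n);
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    IntegerVector si = seqs[i];
    int found = -1;
    double found_id = 1.0;
    for (size_t r = 0; r < reps.size(); ++r) {
      IntegerVector sr = seqs[reps[r]];
      // pattern = shorter (si, since sorted by decreasing length)
      const int Ls = si.size();
      const int pen = std::max(gap_open + gap_ext, -mismatch);
      const double bound = Ls * (threshold * match - (1.0 - threshold) * pen);
      const int sc = glocal_score(si, sr, match, mismatch, gap_open, gap_ext);
      if (sc + 1e-9 < bound) continue;
      NumericVector g = cpp_glocal_identity(si, sr, match, mismatch,
                                            gap_open, gap_ext);
      if (g[3] + 1e-12 >= threshold) { found = reps[r]; found_id = g[3]; break; }
    }
    if (found < 0) {
      reps.push_back(i);
      assign[i] = i + 1;
      ident[i] = 1.0;
    } else {
      assign[i] = found + 1;
      ident[i] = found_id;
    }
  }
  return List::create(_["assign"] = assign, _["identity"] = ident);
}
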