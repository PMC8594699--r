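#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Bisulfite-aware pairwise alignment of a read against a converted amplicon
// template.  The read is aligned globally; end gaps on the read row (template
// overhang on either side) are free, so the read "fits" inside the template.
// A read T opposite a template C scores as a match: after conversion an
// unmethylated C is sequenced as T while the template retains C at CpG sites.
//
// Affine gaps: a gap of length k costs gap_open + k * gap_ext.
// Deterministic traceback: prefer diagonal, then up (read base vs gap), then
// left (gap vs template base); among equal-scoring end columns the rightmost
// is taken (least trailing template skip).

static const int NEG_INF = INT_MIN / 4;

static inline bool bis_eq(char r, char t) {
  return r == t || (r == 'T' && t == 'C');
}

struct AlnResult {
  int score;
  int start;  // 0-based template offset of first aligned column
  int end;    // 0-based half-open template end of the aligned span
  std::string read_aln;
  std::string tmpl_aln;
};

static AlnResult align_one(const std::string &read, const std::string &tmpl,
                           int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)read.size(), m = (int)tmpl.size();
  const int W = m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> IY((size_t)(n + 1) * W, NEG_INF);  // read base vs gap ("up")
  std::vector<int> IX((size_t)(n + 1) * W, NEG_INF);  // gap vs template base ("left")
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0), tbY((size_t)(n + 1) * W, 0),
      tbX((size_t)(n + 1) * W, 0);

  for (int j = 0; j <= m; ++j) M[(size_t)j] = 0;  // free leading template skip
  for (int i = 1; i <= n; ++i) {
    IY[(size_t)i * W] = -(gap_open + i * gap_ext);
    tbY[(size_t)i * W] = (i == 1) ? 0 : 1;  // column-0 gap run ends at (0,0)
  }

  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const int sc = bis_eq(rc, tmpl[j - 1]) ? match : mismatch;
      // M: from (i-1, j-1), prefer M > IY > IX
      int best = M[prow + j - 1];
      unsigned char tb = 0;
      if (IY[prow + j - 1] > best) { best = IY[prow + j - 1]; tb = 1; }
      if (IX[prow + j - 1] > best) { best = IX[prow + j - 1]; tb = 2; }
      M[row + j] = best + sc;
      tbM[row + j] = tb;
      // IY: from (i-1, j)
      best = M[prow + j] - gap_open - gap_ext; tb = 0;
      if (IY[prow + j] - gap_ext > best) { best = IY[prow + j] - gap_ext; tb = 1; }
      if (IX[prow + j] - gap_open - gap_ext > best) {
        best = IX[prow + j] - gap_open - gap_ext; tb = 2;
      }
      IY[row + j] = best;
      tbY[row + j] = tb;
      // IX: from (i, j-1)
      best = M[row + j - 1] - gap_open - gap_ext; tb = 0;
      if (IY[row + j - 1] - gap_open - gap_ext > best) {
        best = IY[row + j - 1] - gap_open - gap_ext; tb = 1;
      }
      if (IX[row + j - 1] - gap_ext > best) { best = IX[row + j - 1] - gap_ext; tb = 2; }
      IX[row + j] = best;
      tbX[row + j] = tb;
    }
  }

  // terminal cell: free trailing template skip; rightmost best column wins,
  // within a column prefer M > IY > IX
  int bscore = NEG_INF, bj = 0, bst = 0;
  size_t lastrow = (size_t)n * W;
  for (int j = 0; j <= m; ++j) {
    int v = M[lastrow + j], st = 0;
    if (IY[lastrow + j] > v) { v = IY[lastrow + j]; st = 1; }
    if (IX[lastrow + j] > v) { v = IX[lastrow + j]; st = 2; }
    if (v >= bscore) { bscore = v; bj = j; bst = st; }
  }

  std::string ra, ta;
  ra.reserve(n + 8);
  ta.reserve(n + 8);
  int i = n, j = bj, st = bst;
  while (i > 0) {
    size_t row = (size_t)i * W;
    if (st == 0) {
      ra.push_back(read[i - 1]);
      ta.push_back(tmpl[j - 1]);
      st = tbM[row + j];
      --i; --j;
    } else if (st == 1) {
      ra.push_back(read[i - 1]);
      ta.push_back('-');
      st = tbY[row + j];
      --i;
    } else {
      ra.push_back('-');
      ta.push_back(tmpl[j - 1]);
      st = tbX[row + j];
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(ta.begin(), ta.end());

  AlnResult res;
  res.score = bscore;
  res.start = j;
  res.end = bj;
  res.read_aln = ra;
  res.tmpl_aln = ta;
  return res;
}

// [[Rcpp::export]]
List cpp_bis_align(std::string read, std::string tmpl, int match, int mismatch,
                   int gap_open, int gap_ext) {
  AlnResult r = align_one(read, tmpl, match, mismatch, gap_open, gap_ext);
  return List::create(_["read_aln"] = r.read_aln, _["template_aln"] = r.tmpl_aln,
                      _["score"] = r.score, _["start"] = r.start, _["end"] = r.end);
}

// Batch alignment against one template with an optional anchor shortcut: when
// the read is bisulfite-compatible with the template at its expected offset
// without any mismatch, the gap-free identity alignment attains the maximal
// possible score (match * length) and is returned without running the DP.
// anchors are 0-based expected start offsets; NA or negative disables the
// shortcut for that read.
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string tmpl, IntegerVector anchors,
                     int match, int mismatch, int gap_open, int gap_ext) {
  const int nr = reads.size();
  const int m = (int)tmpl.size();
  IntegerVector start(nr), end(nr), score(nr);
  LogicalVector fast(nr);
  CharacterVector read_aln(nr), tmpl_aln(nr);
  for (int k = 0; k < nr; ++k) {
    std::string r = as<std::string>(reads[k]);
    const int len = (int)r.size();
    int a = (k < anchors.size()) ? anchors[k] : NA_INTEGER;
    bool done = false;
    if (a != NA_INTEGER && a >= 0 && a + len <= m && len > 0) {
      bool ok = true;
      for (int i = 0; i < len; ++i) {
        if (!bis_eq(r[i], tmpl[a + i])) { ok = false; break; }
      }
      if (ok) {
        start[k] = a;
        end[k] = a + len;
        score[k] = match * len;
        fast[k] = true;
        read_aln[k] = NA_STRING;
        tmpl_aln[k] = NA_STRING;
        done = true;
      }
    }
    if (!done) {
      AlnResult res = align_one(r, tmpl, match, mismatch, gap_open, gap_ext);
      start[k] = res.start;
      end[k] = res.end;
      score[k] = res.score;
      fast[k] = false;
      read_aln[k] = res.read_aln;
      tmpl_aln[k] = res.tmpl_aln;
    }
  }
  return List::create(_["start"] = start, _["end"] = end, _["score"] = score,
                      _["fast"] = fast, _["read_aln"] = read_aln,
                      _["template_aln"] = tmpl_aln);
}
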