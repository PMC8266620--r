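// Global pairwise alignment with affine gaps (Gotoh) for read-vs-reference
// error profiling. Deterministic tie-breaking: diagonal over deletion over
// insertion. Indels are left-normalised within homopolymers after
// traceback; optionally the leading deletion run is then reclassified as a
// soft-clip (truncated molecule). Gap cost convention: a gap of length L
// costs gap_open + L * gap_extend.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

namespace {

const double NEG = -1e18;

struct AlnResult {
  std::vector<int> events;      // per ref position: 0 match, 1..4 sub (obs
                                // base A,C,G,T), 5 deletion, 6 clipped
  std::vector<int> ins_pos;     // ref bases consumed before the insertion
  std::vector<std::string> ins_seq;
  double score;
  int clip5;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2;
    case 'G': return 3; case 'T': return 4;
  }
  return 0;
}

// One alignment; work matrices passed in and resized as needed.
AlnResult align_one(const std::string& read, const std::string& ref,
                    double s_match, double s_mis, double g_open,
                    double g_ext, bool free_lead_del) {
  const int n = (int)read.size();   // rows: read
  const int m = (int)ref.size();    // cols: reference
  const int W = m + 1;
  // state matrices: M diagonal, X deletion (gap in read, consumes ref),
  // Y insertion (gap in ref, consumes read)
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: predecessor state per cell/state (0=M,1=X,2=Y,3=start)
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
      pY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[j] = g_open + g_ext * j;
    pX[j] = (j == 1) ? 3 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Y[i * W] = g_open + g_ext * i;
    pY[i * W] = (i == 1) ? 3 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      const double sub = (read[i - 1] == ref[j - 1]) ? s_match : s_mis;
      // M: from any state at (i-1, j-1); prefer M > X > Y on ties
      {
        const int d = (i - 1) * W + (j - 1);
        double best = M[d]; signed char p = 0;
        if (X[d] > best) { best = X[d]; p = 1; }
        if (Y[d] > best) { best = Y[d]; p = 2; }
        if (i == 1 && j == 1 && 0.0 >= best) { best = 0.0; p = 3; }
        M[c] = best + sub; pM[c] = p;
      }
      // X: gap in read (deletion), from (i, j-1)
      {
        const int l = i * W + (j - 1);
        double open_sc = M[l] + g_open + g_ext;
        double ext_sc = X[l] + g_ext;
        double open_y = Y[l] + g_open + g_ext;
        double best = open_sc; signed char p = 0;
        if (ext_sc > best) { best = ext_sc; p = 1; }
        if (open_y > best) { best = open_y; p = 2; }
        X[c] = best; pX[c] = p;
      }
      // Y: gap in ref (insertion), from (i-1, j)
      {
        const int u = (i - 1) * W + j;
        double open_sc = M[u] + g_open + g_ext;
        double ext_sc = Y[u] + g_ext;
        double open_x = X[u] + g_open + g_ext;
        double best = open_sc; signed char p = 0;
        if (ext_sc > best) { best = ext_sc; p = 2; }
        if (open_x > best) { best = open_x; p = 1; }
        Y[c] = best; pY[c] = p;
      }
    }
  }

  AlnResult res;
  res.events.assign(m, 6);
  res.clip5 = 0;

  // end state: prefer M > X > Y on ties
  const int e = n * W + m;
  int state;
  double best = M[e]; state = 0;
  if (X[e] > best) { best = X[e]; state = 1; }
  if (Y[e] > best) { best = Y[e]; state = 2; }
  if (n == 0 && m == 0) { res.score = 0; return res; }
  res.score = best;

  int i = n, j = m;
  std::string cur_ins;
  std::vector<int> tmp_ins_pos;
  std::vector<std::string> tmp_ins_seq;
  while (i > 0 || j > 0) {
    if (state == 0) {  // M consumed (i-1, j-1)
      signed char p = pM[i * W + j];
      res.events[j - 1] =
          (read[i - 1] == ref[j - 1]) ? 0 : base_code(read[i - 1]);
      if (!cur_ins.empty()) { // insertion recorded to the right of j-1 .. no:
        // insertions are recorded when leaving Y state (below)
      }
      --i; --j;
      if (p == 3) break;
      state = p;
    } else if (state == 1) {  // X: deletion at ref j-1
      signed char p = pX[i * W + j];
      res.events[j - 1] = 5;
      --j;
      if (p == 3) break;
      state = p;
    } else {  // Y: insertion of read[i-1] before ref position j
      signed char p = pY[i * W + j];
      cur_ins.insert(cur_ins.begin(), read[i - 1]);
      --i;
      if (p != 2) {  // insertion run ends (towards the front)
        tmp_ins_pos.push_back(j);
        tmp_ins_seq.push_back(cur_ins);
        cur_ins.clear();
      }
      if (p == 3) break;
      state = p;
    }
  }
  if (!cur_ins.empty()) {
    tmp_ins_pos.push_back(j);
    tmp_ins_seq.push_back(cur_ins);
  }
  // traceback visited right-to-left; restore left-to-right order
  for (int t = (int)tmp_ins_pos.size() - 1; t >= 0; --t) {
    res.ins_pos.push_back(tmp_ins_pos[t]);
    res.ins_seq.push_back(tmp_ins_seq[t]);
  }

  // left-normalise deletion runs within homopolymers: while the matched
  // base just left of a run equals the run's rightmost ref base, slide
  int start = 0;  // first ref index eligible for normalisation (0-based)
  for (int b2 = start; b2 < m; ++b2) {
    if (res.events[b2] != 5) continue;
    int a = b2;
    while (a > start && res.events[a - 1] == 5) --a;  // run [a, b]
    int b = b2;
    while (b + 1 < m && res.events[b + 1] == 5) ++b;
    while (a > start && res.events[a - 1] == 0 && ref[a - 1] == ref[b]) {
      res.events[a - 1] = 5;
      res.events[b] = 0;
      --a; --b;
    }
    b2 = b;  // skip past this run
  }
  // left-normalise insertions: rotate while the ref base before the
  // insertion point equals the insertion's last base
  for (size_t t = 0; t < res.ins_pos.size(); ++t) {
    int p = res.ins_pos[t];
    std::string& s = res.ins_seq[t];
    while (p > start && res.events[p - 1] == 0 &&
           ref[p - 1] == s[s.size() - 1]) {
      s.insert(s.begin(), ref[p - 1]);
      s.erase(s.end() - 1);
      --p;
    }
    res.ins_pos[t] = p;
  }
  // truncation handling: the leading contiguous deletion run is the
  // signature of a capped/blocked molecule (missing reference 5' prefix,
  // since synthesis runs 3'->5'); reclassify it as soft-clip so it is
  // excluded from deletion accounting
  if (free_lead_del) {
    int k2 = 0;
    while (k2 < m && res.events[k2] == 5) {
      res.events[k2] = 6;
      ++k2;
    }
    res.clip5 = k2;
  }
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".align_batch_cpp")]]
List align_batch_cpp(CharacterVector reads, CharacterVector refs,
                     double s_match, double s_mis, double g_open,
                     double g_ext, bool free_lead_del) {
  const int N = reads.size();
  if (refs.size() != N) stop("reads and refs must have equal length");
  std::vector<int> ev_all, ev_off(N + 1, 0);
  std::vector<int> ins_read, ins_pos;
  std::vector<std::string> ins_seq;
  NumericVector score(N);
  IntegerVector clip5(N);
  for (int r = 0; r < N; ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::string rf = as<std::string>(refs[r]);
    AlnResult a = align_one(rd, rf, s_match, s_mis, g_open, g_ext,
                            free_lead_del);
    ev_off[r + 1] = ev_off[r] + (int)a.events.size();
    ev_all.insert(ev_all.end(), a.events.begin(), a.events.end());
    for (size_t t = 0; t < a.ins_pos.size(); ++t) {
      ins_read.push_back(r + 1);
      ins_pos.push_back(a.ins_pos[t]);
      ins_seq.push_back(a.ins_seq[t]);
    }
    score[r] = a.score;
    clip5[r] = a.clip5;
  }
  return List::create(_["events"] = wrap(ev_all),
                      _["offsets"] = wrap(ev_off),
                      _["ins_read"] = wrap(ins_read),
                      _["ins_pos"] = wrap(ins_pos),
                      _["ins_seq"] = wrap(ins_seq),
                      _["score"] = score,
                      _["clip5"] = clip5);
}
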