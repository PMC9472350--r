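#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Anchored approximate single-probe mapper.
//
// A window of the text is a raw hit when
//   (a) its Levenshtein distance to the pattern is <= delta,
//   (b) its length lies in [max(1, k - delta), k + delta], and
//   (c) it contains an exact occurrence of at least one `anchor`-mer of the
//       pattern (the k-mer-index sensitivity model of short-read mappers;
//       with the default anchor of 12 and 50-mer patterns, condition (c) is
//       implied by (a) whenever delta <= 3, by the pigeonhole principle, so
//       the mapper is exhaustive in that regime).
//
// Clusters of mutually overlapping raw hits are collapsed to one seed:
// minimum distance, ties to the leftmost start, then the smallest end.

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N or anything else: matches nothing
  }
}

// 1-based start positions of exact text matches of any pattern anchor-mer
static std::vector<int> anchor_positions(const std::string& text,
                                         const std::string& pat, int anchor) {
  const int k = (int) pat.size();
  const int n = (int) text.size();
  std::vector<int> out;
  if (k < anchor || n < anchor) return out;
  const uint64_t mask = (uint64_t(1) << (2 * anchor)) - 1;
  std::unordered_set<uint64_t> index;
  uint64_t code = 0;
  int run = 0;
  for (int i = 0; i < k; ++i) {
    int e = enc(pat[i]);
    code = ((code << 2) | (uint64_t)(e & 3)) & mask;
    run = (e < 4) ? run + 1 : 0;
    if (run >= anchor) index.insert(code);
  }
  code = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int e = enc(text[i]);
    code = ((code << 2) | (uint64_t)(e & 3)) & mask;
    run = (e < 4) ? run + 1 : 0;
    if (run >= anchor && index.count(code))
      out.push_back(i - anchor + 2); // 1-based start of the anchor-mer
  }
  return out;
}

// per-position minimum semi-global edit distance (free start in text) via
// Myers' bit-vector algorithm; requires k <= 64
static void myers_scan(const std::string& text, const std::string& pat,
                       std::vector<int>& score_out) {
  const int k = (int) pat.size();
  const int n = (int) text.size();
  score_out.assign(n + 1, 0);
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < k; ++i) {
    int e = enc(pat[i]);
    if (e < 4) Peq[e] |= (uint64_t(1) << i);
  }
  const uint64_t mask = (k == 64) ? ~uint64_t(0) : ((uint64_t(1) << k) - 1);
  const uint64_t hb = uint64_t(1) << (k - 1);
  uint64_t Pv = mask, Mv = 0;
  int score = k;
  for (int j = 0; j < n; ++j) {
    int e = enc(text[j]);
    uint64_t Eq = (e < 4) ? Peq[e] : 0;
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | (~(Xh | Pv) & mask);
    uint64_t Mh = Pv & Xh;
    if (Ph & hb) ++score; else if (Mh & hb) --score;
    Ph = (Ph << 1) & mask;
    Mh = (Mh << 1) & mask;
    Pv = (Mh | (~(Xv | Ph) & mask)) & mask;
    Mv = Ph & Xv;
    score_out[j + 1] = score;
  }
}

// [[Rcpp::export(name = ".cpp_map_probe")]]
DataFrame cpp_map_probe(std::string text, std::string pattern, int delta,
                        int anchor = 12) {
  const int k = (int) pattern.size();
  if (k < 1) stop("empty probe");
  if (delta < 0) stop("delta must be >= 0");
  if (anchor < 1) stop("anchor must be >= 1");
  if (k < anchor) stop("probe shorter than the anchor length");
  const int n = (int) text.size();
  const int BIG = 1 << 28;

  std::vector<int> anchors = anchor_positions(text, pattern, anchor);

  // candidate end positions: a window containing the anchor-mer at g ends in
  // [g + anchor - 1, g + k + delta - 1]
  std::vector<char> isEnd(n + 1, 0);
  for (size_t ai = 0; ai < anchors.size(); ++ai) {
    int g = anchors[ai];
    int from = g + anchor - 1;
    int to = std::min(n, g + k + delta - 1);
    for (int e = from; e <= to; ++e) isEnd[e] = 1;
  }

  // prefilter: a raw hit ending at e requires the best semi-global distance
  // at e to be <= delta already
  if (k <= 64 && n > 0) {
    std::vector<int> sc;
    myers_scan(text, pattern, sc);
    for (int e = 1; e <= n; ++e)
      if (isEnd[e] && sc[e] > delta) isEnd[e] = 0;
  }

  const int maxLen = k + delta;
  const int minLen = std::max(1, k - delta);
  std::map<int, std::pair<int, int>> best; // start -> (dist, end)
  std::vector<int> prev(maxLen + 1), cur(maxLen + 1);
  for (int e = 1; e <= n; ++e) {
    if (!isEnd[e]) continue;
    const int lo = std::max(1, e - maxLen + 1);
    const int Lt = e - lo + 1;
    // banded DP over reversed pattern vs reversed text: after row k, prev[x]
    // is ed(pattern, window of length x ending at e); cells with |x - i| >
    // delta exceed delta and are left at BIG
    for (int x = 0; x <= Lt; ++x) prev[x] = (x <= delta) ? x : BIG;
    for (int i = 1; i <= k; ++i) {
      int xlo = std::max(1, i - delta), xhi = std::min(Lt, i + delta);
      if (xlo > 1) cur[xlo - 1] = BIG;
      else cur[0] = (i <= delta) ? i : BIG;
      if (xhi < Lt && xhi + 1 <= maxLen) cur[xhi + 1] = BIG;
      int pe = enc(pattern[k - i]);
      for (int x = xlo; x <= xhi; ++x) {
        int te = enc(text[e - x]);
        int cost = (pe == te && pe < 4) ? 0 : 1;
        int v = prev[x - 1] + cost;
        if (prev[x] + 1 < v) v = prev[x] + 1;
        if (cur[x - 1] + 1 < v) v = cur[x - 1] + 1;
        cur[x] = v;
      }
      std::swap(prev, cur);
    }
    for (int x = minLen; x <= std::min(Lt, maxLen); ++x) {
      if (prev[x] > delta) continue;
      int s = e - x + 1;
      // anchor containment: some anchor g with s <= g and g+anchor-1 <= e
      std::vector<int>::const_iterator it =
        std::lower_bound(anchors.begin(), anchors.end(), s);
      if (it == anchors.end() || *it + anchor - 1 > e) continue;
      std::map<int, std::pair<int, int>>::iterator bit = best.find(s);
      if (bit == best.end())
        best[s] = std::make_pair(prev[x], e);
      else if (prev[x] < bit->second.first)
        bit->second = std::make_pair(prev[x], e);
      // equal distance keeps the stored end (ends are visited increasing,
      // so the stored one is the smallest)
    }
  }

  // collapse transitively overlapping hits to one seed per cluster
  std::vector<int> outS, outE, outD;
  bool open = false;
  int clS = 0, clE = 0, clD = 0, maxEnd = 0;
  for (std::map<int, std::pair<int, int>>::iterator kv = best.begin();
       kv != best.end(); ++kv) {
    int s = kv->first, d = kv->second.first, e2 = kv->second.second;
    if (open && s > maxEnd) {
      outS.push_back(clS); outE.push_back(clE); outD.push_back(clD);
      open = false;
    }
    if (!open) {
      open = true;
      clS = s; clE = e2; clD = d; maxEnd = e2;
    } else {
      if (d < clD) { clS = s; clE = e2; clD = d; }
      if (e2 > maxEnd) maxEnd = e2;
    }
  }
  if (open) { outS.push_back(clS); outE.push_back(clE); outD.push_back(clD); }

  return DataFrame::create(_["start"] = outS, _["end"] = outE,
                           _["dist"] = outD);
}
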