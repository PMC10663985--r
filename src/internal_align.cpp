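// Seed-and-extend pairwise nucleotide aligner used by the internal backend.
// Exact k-mer seeds are collapsed into maximal exact-match anchors, anchors
// are chained by sparse DP, inter-anchor gaps are closed with affine-gap
// (Gotoh) alignment, and chain ends are extended ungapped with an x-drop.
// Intended for test-scale inputs; production runs go through the external
// aligner adapter.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Anchor { int q, s, len; };

inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Affine-gap global alignment of a[0..n) vs b[0..m), returns cigar runs.
// Gap of length L costs go + ge*L.
void gotoh_align(const std::string& a, const std::string& b,
                 double match, double mismatch, double go, double ge,
                 std::vector<std::pair<int,char> >& runs) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0) return;
  if (n == 0) { runs.push_back(std::make_pair(m, 'D')); return; }
  if (m == 0) { runs.push_back(std::make_pair(n, 'I')); return; }
  const double NEG = -1e18;
  // M[i][j]: best ending in match/mismatch; E: gap in subject (I, consumes a);
  // F: gap in query (D, consumes b)
  std::vector<double> M((n+1)*(m+1), NEG), E((n+1)*(m+1), NEG), F((n+1)*(m+1), NEG);
  std::vector<unsigned char> tbM((n+1)*(m+1), 0), tbE((n+1)*(m+1), 0), tbF((n+1)*(m+1), 0);
  auto idx = [m](int i, int j) { return i*(m+1) + j; };
  M[idx(0,0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    E[idx(i,0)] = go + ge*i;
    tbE[idx(i,0)] = (i == 1) ? 0 : 1; // from E above
  }
  for (int j = 1; j <= m; ++j) {
    F[idx(0,j)] = go + ge*j;
    tbF[idx(0,j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: consume a[i-1] with gap in b
      double fromM = M[idx(i-1,j)] + go + ge;
      double fromE = E[idx(i-1,j)] + ge;
      if (fromM >= fromE) { E[idx(i,j)] = fromM; tbE[idx(i,j)] = 0; }
      else { E[idx(i,j)] = fromE; tbE[idx(i,j)] = 1; }
      double fromF_M = M[idx(i,j-1)] + go + ge;
      double fromF_F = F[idx(i,j-1)] + ge;
      if (fromF_M >= fromF_F) { F[idx(i,j)] = fromF_M; tbF[idx(i,j)] = 0; }
      else { F[idx(i,j)] = fromF_F; tbF[idx(i,j)] = 1; }
      double sub = (a[i-1] == b[j-1] && encode_base(a[i-1]) >= 0) ? match : mismatch;
      double dM = M[idx(i-1,j-1)], dE = E[idx(i-1,j-1)], dF = F[idx(i-1,j-1)];
      double best = dM; unsigned char t = 0;
      if (dE > best) { best = dE; t = 1; }
      if (dF > best) { best = dF; t = 2; }
      M[idx(i,j)] = best + sub; tbM[idx(i,j)] = t;
    }
  }
  // traceback from best of three at (n,m)
  int i = n, j = m;
  int state; // 0=M, 1=E, 2=F
  {
    double bM = M[idx(n,m)], bE = E[idx(n,m)], bF = F[idx(n,m)];
    state = 0; double best = bM;
    if (bE > best) { best = bE; state = 1; }
    if (bF > best) { best = bF; state = 2; }
  }
  std::vector<char> ops;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back('M');
      unsigned char t = tbM[idx(i,j)];
      --i; --j;
      state = t;
    } else if (state == 1) {
      ops.push_back('I');
      unsigned char t = tbE[idx(i,j)];
      --i;
      state = (t == 0) ? 0 : 1;
    } else {
      ops.push_back('D');
      unsigned char t = tbF[idx(i,j)];
      --j;
      state = (t == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  for (size_t k2 = 0; k2 < ops.size(); ++k2) {
    if (!runs.empty() && runs.back().second == ops[k2]) runs.back().first++;
    else runs.push_back(std::make_pair(1, ops[k2]));
  }
}

std::string runs_to_cigar(const std::vector<std::pair<int,char> >& runs) {
  std::string out;
  for (size_t i = 0; i < runs.size(); ++i) {
    if (runs[i].first <= 0) continue;
    out += std::to_string(runs[i].first);
    out += runs[i].second;
  }
  return out;
}

void push_run(std::vector<std::pair<int,char> >& runs, int len, char op) {
  if (len <= 0) return;
  if (!runs.empty() && runs.back().second == op) runs.back().first += len;
  else runs.push_back(std::make_pair(len, op));
}

} // namespace

// [[Rcpp::export(name = ".internal_align_cpp")]]
DataFrame internal_align_cpp(std::string qseq, std::string sseq,
                             int k, int band, int max_gap,
                             double min_score,
                             double match, double mismatch,
                             double gap_open, double gap_ext,
                             double xdrop) {
  const int nq = (int)qseq.size(), ns = (int)sseq.size();
  std::vector<int> q_starts, q_ends, s_starts, s_ends;
  std::vector<double> scores, idents;
  std::vector<std::string> cigars;

  if (nq >= k && ns >= k) {
    // --- subject k-mer index (2-bit encoding, skip ambiguous) ---
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2*k)) - 1);
    std::unordered_map<uint64_t, std::vector<int> > index;
    index.reserve((size_t)ns);
    {
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < ns; ++i) {
        int c = encode_base(sseq[i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= k) index[h].push_back(i - k + 1);
      }
    }
    const size_t max_occ = 256;

    // --- query scan: collect matches ---
    std::vector<std::pair<int,int> > matches; // (q, s)
    {
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < nq; ++i) {
        int c = encode_base(qseq[i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            index.find(h);
          if (it != index.end() && it->second.size() <= max_occ) {
            for (size_t j = 0; j < it->second.size(); ++j)
              matches.push_back(std::make_pair(i - k + 1, it->second[j]));
          }
        }
      }
    }

    // --- collapse matches into maximal anchors along diagonals ---
    std::sort(matches.begin(), matches.end(),
              [](const std::pair<int,int>& a, const std::pair<int,int>& b) {
                long da = (long)a.first - a.second, db = (long)b.first - b.second;
                if (da != db) return da < db;
                return a.first < b.first;
              });
    std::vector<Anchor> anchors;
    for (size_t i = 0; i < matches.size(); ++i) {
      int q = matches[i].first, s = matches[i].second;
      if (!anchors.empty()) {
        Anchor& a = anchors.back();
        if ((long)a.q - a.s == (long)q - s && q <= a.q + a.len) {
          int new_end = q + k;
          if (new_end > a.q + a.len) a.len = new_end - a.q;
          continue;
        }
      }
      Anchor a; a.q = q; a.s = s; a.len = k;
      anchors.push_back(a);
    }
    // guard against seed explosion on repetitive/random input
    if (anchors.size() > 200000) {
      std::vector<Anchor> keep;
      for (size_t i = 0; i < anchors.size(); ++i)
        if (anchors[i].len >= k + 4) keep.push_back(anchors[i]);
      anchors.swap(keep);
    }

    // --- sparse DP chaining ---
    std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
      if (a.q != b.q) return a.q < b.q;
      return a.s < b.s;
    });
    const int n = (int)anchors.size();
    std::vector<double> f(n);
    std::vector<int> prev(n, -1);
    const int lookback = 256;
    for (int i = 0; i < n; ++i) {
      f[i] = anchors[i].len;
      long di = (long)anchors[i].q - anchors[i].s;
      for (int j = i - 1; j >= 0 && j >= i - lookback; --j) {
        if (anchors[j].q >= anchors[i].q) continue;
        if (anchors[j].s >= anchors[i].s) continue;
        int qgap = anchors[i].q - (anchors[j].q + anchors[j].len);
        int sgap = anchors[i].s - (anchors[j].s + anchors[j].len);
        if (qgap > max_gap || sgap > max_gap) continue;
        long dj = (long)anchors[j].q - anchors[j].s;
        long dd = di > dj ? di - dj : dj - di;
        if (dd > band) continue;
        int added = std::min(anchors[i].len,
                             anchors[i].q + anchors[i].len -
                             (anchors[j].q + anchors[j].len));
        if (added <= 0) continue;
        double cand = f[j] + added - 0.3 * (double)dd
                      - 0.01 * (double)std::max(std::max(qgap, sgap), 0);
        if (cand > f[i]) { f[i] = cand; prev[i] = j; }
      }
    }

    // --- extract chains best-first ---
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::sort(order.begin(), order.end(), [&f, &anchors](int a, int b) {
      if (f[a] != f[b]) return f[a] > f[b];
      if (anchors[a].q != anchors[b].q) return anchors[a].q < anchors[b].q;
      return anchors[a].s < anchors[b].s;
    });
    std::vector<bool> used(n, false);
    for (int oi = 0; oi < n; ++oi) {
      int tail = order[oi];
      if (used[tail]) continue;
      if (f[tail] < (double)k) break; // nothing substantial left
      std::vector<int> chain;
      bool clash = false;
      for (int c = tail; c != -1; c = prev[c]) {
        if (used[c]) { clash = true; break; }
        chain.push_back(c);
      }
      if (clash) continue; // shares a prefix with a better chain
      std::reverse(chain.begin(), chain.end());
      for (size_t ci = 0; ci < chain.size(); ++ci) used[chain[ci]] = true;

      // --- build cigar along the chain ---
      std::vector<std::pair<int,char> > runs;
      const Anchor& a0 = anchors[chain[0]];
      int cur_q = a0.q, cur_s = a0.s;
      int beg_q = a0.q, beg_s = a0.s;
      push_run(runs, a0.len, 'M');
      cur_q += a0.len; cur_s += a0.len;
      for (size_t ci = 1; ci < chain.size(); ++ci) {
        Anchor a = anchors[chain[ci]];
        int t = std::max(std::max(cur_q - a.q, cur_s - a.s), 0);
        if (t >= a.len) continue;
        a.q += t; a.s += t; a.len -= t;
        int qgap = a.q - cur_q, sgap = a.s - cur_s;
        if (qgap > 0 || sgap > 0) {
          gotoh_align(qseq.substr(cur_q, qgap), sseq.substr(cur_s, sgap),
                      match, mismatch, gap_open, gap_ext, runs);
        }
        push_run(runs, a.len, 'M');
        cur_q = a.q + a.len; cur_s = a.s + a.len;
      }

      // --- ungapped x-drop end extension ---
      {
        double sc = 0, best = 0; int best_ext = 0;
        int e = 0;
        while (beg_q - e - 1 >= 0 && beg_s - e - 1 >= 0) {
          char qa = qseq[beg_q - e - 1], sb = sseq[beg_s - e - 1];
          sc += (qa == sb && encode_base(qa) >= 0) ? match : mismatch;
          ++e;
          if (sc > best) { best = sc; best_ext = e; }
          if (sc < best - xdrop) break;
        }
        if (best_ext > 0) {
          std::vector<std::pair<int,char> > pre;
          push_run(pre, best_ext, 'M');
          if (!runs.empty() && runs.front().second == 'M')
            pre.back().first += runs.front().first;
          for (size_t ri = (runs.empty() || runs.front().second != 'M') ? 0 : 1;
               ri < runs.size(); ++ri) pre.push_back(runs[ri]);
          runs.swap(pre);
          beg_q -= best_ext; beg_s -= best_ext;
        }
      }
      {
        double sc = 0, best = 0; int best_ext = 0;
        int e = 0;
        while (cur_q + e < nq && cur_s + e < ns) {
          char qa = qseq[cur_q + e], sb = sseq[cur_s + e];
          sc += (qa == sb && encode_base(qa) >= 0) ? match : mismatch;
          ++e;
          if (sc > best) { best = sc; best_ext = e; }
          if (sc < best - xdrop) break;
        }
        if (best_ext > 0) {
          push_run(runs, best_ext, 'M');
          cur_q += best_ext; cur_s += best_ext;
        }
      }

      // --- score/identity by walking the cigar against the sequences ---
      double score = 0; long ncol = 0, nmat = 0;
      {
        int qi = beg_q, si = beg_s;
        for (size_t ri = 0; ri < runs.size(); ++ri) {
          int L = runs[ri].first; char op = runs[ri].second;
          ncol += L;
          if (op == 'M') {
            for (int x = 0; x < L; ++x) {
              char qa = qseq[qi + x], sb = sseq[si + x];
              if (qa == sb && encode_base(qa) >= 0) { score += match; ++nmat; }
              else score += mismatch;
            }
            qi += L; si += L;
          } else if (op == 'I') {
            score += gap_open + gap_ext * L; qi += L;
          } else {
            score += gap_open + gap_ext * L; si += L;
          }
        }
      }
      if (score < min_score) continue;
      q_starts.push_back(beg_q); q_ends.push_back(cur_q);
      s_starts.push_back(beg_s); s_ends.push_back(cur_s);
      scores.push_back(score);
      idents.push_back(ncol > 0 ? (double)nmat / (double)ncol : 0.0);
      cigars.push_back(runs_to_cigar(runs));
    }
  }

  return DataFrame::create(
    Named("q_start") = q_starts, Named("q_end") = q_ends,
    Named("s_start") = s_starts, Named("s_end") = s_ends,
    Named("score") = scores, Named("identity") = idents,
    Named("cigar") = cigars,
    Named("stringsAsFactors") = false);
}
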