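// Minimum-intron splice-chain alignment of a CDS onto a genomic region.
//
// The alignment consumes the entire CDS left to right.  Within an exon every
// CDS base is paired with one genomic base (substitutions allowed, no
// indels); between exons the genome may be skipped by an intron of length
// >= min_intron that starts with GT and ends with AG (or by an arbitrary gap
// when gt_ag is false, used to diagnose splice violations).  The optimal
// chain minimises mismatches + INTRON_COST * introns, which at low
// divergence is the fewest-intron chain with fewest mismatches; among
// equally optimal chains the one whose donor positions are lexicographically
// smallest (leftmost donors, then leftmost acceptors) is returned.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// An intron costs the equivalent of INTRON_COST mismatches.  Skipping a
// true intron forces ~75% mismatches across >= min_intron genomic bases
// (>= 30 mismatches), while a spurious GT..AG jump can rescue at most a
// handful, so 20 separates the two regimes cleanly.
static const int INTRON_COST = 20;
static const int INF = INT_MAX / 4;

// [[Rcpp::export(name = ".splice_chain_cpp")]]
List splice_chain_cpp(std::string cds, std::string region,
                      int min_intron, bool gt_ag) {
  const int n = (int)cds.size();
  const int m = (int)region.size();
  if (n == 0 || m == 0 || n > m)
    return List::create(Named("ok") = false);

  // ctg[c][g]: minimal cost to align cds[c..n) starting at genome position g
  // (the state may begin with an intron jump unless c == 0 or c == n).
  // ctgm[c][g]: same but the state must begin with a match step.
  std::vector<int> ctg((size_t)(n + 1) * (m + 1), INF);
  std::vector<int> ctgm_row((size_t)m + 1, INF);
  std::vector<unsigned char> donor(m, 0), acceptor(m + 1, 0);
  for (int g = 0; g + 1 < m; ++g)
    donor[g] = (!gt_ag) || (region[g] == 'G' && region[g + 1] == 'T');
  // acceptor[a]: an intron may end just before genome position a.
  for (int a = 2; a <= m; ++a)
    acceptor[a] = (!gt_ag) || (region[a - 2] == 'A' && region[a - 1] == 'G');

  std::vector<int> sufacc((size_t)m + 2, INF);  // suffix min of ctgm over acceptors

  for (int g = 0; g <= m; ++g) ctg[(size_t)n * (m + 1) + g] = 0;

  // We keep the full ctg matrix for traceback; ctgm is recomputable from ctg.
  for (int c = n - 1; c >= 0; --c) {
    // ctgm for this row
    for (int g = 0; g <= m; ++g) {
      if (g < m) {
        int mm = (cds[c] != region[g]) ? 1 : 0;
        int v = ctg[(size_t)(c + 1) * (m + 1) + (g + 1)];
        ctgm_row[g] = (v >= INF) ? INF : v + mm;
      } else ctgm_row[g] = INF;
    }
    // suffix minima of ctgm over acceptor positions
    sufacc[m + 1] = INF;
    for (int a = m; a >= 0; --a) {
      int v = (a >= 2 && a <= m && acceptor[a]) ? ctgm_row[a] : INF;
      int nxt = sufacc[a + 1];
      sufacc[a] = v < nxt ? v : nxt;
    }
    bool intron_ok = (c >= 1 && c <= n - 1);
    for (int g = 0; g <= m; ++g) {
      int best = ctgm_row[g];
      if (intron_ok && g < m && donor[g]) {
        int lo = g + min_intron;
        if (lo <= m) {
          int v = sufacc[lo];
          if (v < INF) {
            int cand = v + INTRON_COST;
            if (cand < best) best = cand;
          }
        }
      }
      ctg[(size_t)c * (m + 1) + g] = best;
    }
  }

  // choose leftmost optimal start
  int best = INF, g0 = -1;
  for (int g = 0; g <= m; ++g) {
    int v = ctg[g];  // c == 0 row
    if (v < best) { best = v; g0 = g; }
  }
  if (best >= INF) return List::create(Named("ok") = false);

  // forward traceback, preferring intron jumps (leftmost donor) on ties
  std::vector<int> ex_start, ex_end;
  int c = 0, g = g0, exon_start = g0, mismatches = 0;
  while (c < n) {
    int cur = ctg[(size_t)c * (m + 1) + g];
    bool jumped = false;
    if (c >= 1 && c <= n - 1 && g < m && donor[g]) {
      // find smallest acceptor a >= g + min_intron with
      // INTRON_COST + ctgm[c][a] == cur; the jump is followed by a forced
      // match step so exons are never empty
      for (int a = g + min_intron; a < m; ++a) {
        if (!acceptor[a]) continue;
        int mm = (cds[c] != region[a]) ? 1 : 0;
        int v = ctg[(size_t)(c + 1) * (m + 1) + (a + 1)];
        if (v < INF && v + mm + INTRON_COST == cur) {
          ex_start.push_back(exon_start);
          ex_end.push_back(g);
          exon_start = a;
          mismatches += mm;
          ++c;
          g = a + 1;
          jumped = true;
          break;
        }
      }
    }
    if (!jumped) {
      mismatches += (cds[c] != region[g]) ? 1 : 0;
      ++c; ++g;
    }
  }
  ex_start.push_back(exon_start);
  ex_end.push_back(g);

  int introns = (int)ex_start.size() - 1;
  return List::create(Named("ok") = true,
                      Named("exon_start") = wrap(ex_start),
                      Named("exon_end") = wrap(ex_end),
                      Named("introns") = introns,
                      Named("mismatches") = mismatches);
}
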