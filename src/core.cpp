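#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Radius-limited BFS from every cell through passable edges (permeability > 0).
// nbr:  ncell x 6 matrix of 1-based neighbour cell ids (0 = matrix / off-map).
// perm: ncell x 6 matrix of edge transmission probabilities.
// Returns CSR: off (ncell + 1, 0-based), cells (1-based ids), dist; each cell's
// neighbourhood sorted by (distance, cell id) so nearest-first scans are cheap.
// [[Rcpp::export]]
List reach_cpp(IntegerMatrix nbr, NumericMatrix perm, int radius) {
  const int n = nbr.nrow();
  std::vector<int> off(n + 1, 0);
  std::vector<int> cells, dists;
  cells.reserve(n * 16);
  dists.reserve(n * 16);
  std::vector<int> seen(n, -1);
  std::vector<std::pair<int, int> > found; // (dist, cell0)

  for (int s = 0; s < n; ++s) {
    found.clear();
    std::queue<std::pair<int, int> > q;
    q.push(std::make_pair(s, 0));
    seen[s] = s;
    found.push_back(std::make_pair(0, s));
    while (!q.empty()) {
      int c = q.front().first, d = q.front().second;
      q.pop();
      if (d == radius) continue;
      for (int k = 0; k < 6; ++k) {
        int t = nbr(c, k);
        if (t == 0) continue;
        if (perm(c, k) <= 0.0) continue;
        int t0 = t - 1;
        if (seen[t0] == s) continue;
        seen[t0] = s;
        found.push_back(std::make_pair(d + 1, t0));
        q.push(std::make_pair(t0, d + 1));
      }
    }
    std::sort(found.begin(), found.end());
    for (size_t i = 0; i < found.size(); ++i) {
      dists.push_back(found[i].first);
      cells.push_back(found[i].second + 1);
    }
    off[s + 1] = (int)cells.size();
  }
  return List::create(_["off"] = wrap(off), _["cell"] = wrap(cells),
                      _["dist"] = wrap(dists));
}

// Monogamous nearest-male matching. Females are processed in input (id) order;
// each takes the nearest available adult male within her reachable
// neighbourhood, ties broken by smallest male id. Males and females are given
// in ascending id order, so "first in list" = "smallest id".
// f_cell, m_cell: 1-based cell ids. off/rcell/rdist: reach CSR from reach_cpp.
// Returns, per female, the 1-based index into the male vectors (0 = unpaired).
// [[Rcpp::export]]
IntegerVector pairs_cpp(IntegerVector f_cell, IntegerVector m_cell,
                        IntegerVector off, IntegerVector rcell,
                        IntegerVector rdist, int ncell) {
  const int nf = f_cell.size(), nm = m_cell.size();
  // counting sort of males by cell (stable: preserves id order within cell)
  std::vector<int> mcount(ncell + 1, 0);
  for (int j = 0; j < nm; ++j) mcount[m_cell[j]]++;
  std::vector<int> moff(ncell + 2, 0);
  for (int c = 1; c <= ncell; ++c) moff[c + 1] = moff[c] + mcount[c];
  std::vector<int> mlist(nm);
  std::vector<int> fill(ncell + 2, 0);
  for (int j = 0; j < nm; ++j) {
    int c = m_cell[j];
    mlist[moff[c] + fill[c]++] = j;
  }
  std::vector<bool> taken(nm, false);
  IntegerVector out(nf);

  for (int i = 0; i < nf; ++i) {
    int c0 = f_cell[i] - 1;
    int best = -1, bestDist = -1;
    for (int k = off[c0]; k < off[c0 + 1]; ++k) {
      int d = rdist[k];
      if (bestDist >= 0 && d > bestDist) break;
      int cc = rcell[k];
      for (int p = moff[cc]; p < moff[cc + 1]; ++p) {
        int j = mlist[p];
        if (taken[j]) continue;
        if (best < 0 || j < best) { best = j; bestDist = d; }
        break; // first available in this cell has the smallest id
      }
    }
    if (best >= 0) {
      taken[best] = true;
      out[i] = best + 1;
    } else {
      out[i] = 0;
    }
  }
  return out;
}

// Correlated random-walk natal dispersal. One walker per input element.
// len[i] steps are consumed; at each step the previous direction is kept with
// probability acorr/100 (first step, and after a blocked/failed crossing, the
// direction is uniform among the currently passable edges). A proposed move
// across an edge with permeability p succeeds with probability p per
// encounter; failures consume the step at the barrier. Successful crossings
// of an edge with 0 < p < 1 set the gap-crossing flag.
// Uses R's RNG (caller manages set.seed()).
// [[Rcpp::export]]
List disperse_cpp(IntegerVector start, IntegerVector len, IntegerMatrix nbr,
                  NumericMatrix perm, double acorr) {
  const int n = start.size();
  IntegerVector cell(n);
  LogicalVector crossed(n);
  const double keep = acorr / 100.0;
  int pass[6];

  for (int i = 0; i < n; ++i) {
    int c = start[i] - 1;
    int prev = -1;
    bool flag = false;
    const int L = len[i];
    for (int stp = 0; stp < L; ++stp) {
      int d;
      if (prev >= 0 && unif_rand() < keep) {
        d = prev;
      } else {
        d = (int)(unif_rand() * 6.0);
        if (d > 5) d = 5;
      }
      double p = perm(c, d);
      bool ok = false;
      if (p > 0.0) ok = (p >= 1.0) || (unif_rand() < p);
      if (ok) {
        if (p < 1.0) flag = true;
        c = nbr(c, d) - 1;
        prev = d;
      } else {
        // blocked: movement effort spent at the barrier; redirect uniformly
        // among passable edges for the next step
        int np = 0;
        for (int k = 0; k < 6; ++k)
          if (perm(c, k) > 0.0) pass[np++] = k;
        if (np == 0) break; // isolated single cell: stay put
        int pick = (int)(unif_rand() * np);
        if (pick >= np) pick = np - 1;
        prev = pass[pick];
      }
    }
    cell[i] = c + 1;
    crossed[i] = flag;
  }
  return List::create(_["cell"] = cell, _["crossed"] = crossed);
}
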