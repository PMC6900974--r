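#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Neighbor offsets: first 4 are the 4-connected (edge) neighbors, the last 4
// the diagonals, so connectivity 4 uses the first half and 8 uses all.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Connected-component labeling of a binary mask. Components are numbered
// consecutively from 1 in order of first encounter scanning columns
// (column-major, matching R's storage order), which makes label order
// deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  int nnb = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(c * nr + r);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(c2 * nr + r2);
          }
        }
      }
    }
  }
  return lab;
}

// Geodesic (mask-constrained) multi-label expansion. All label fronts advance
// one pixel per iteration; a pixel contested by several fronts in the same
// iteration goes to the lowest label (fixed tie-break). Labels never merge;
// expansion stops when no pixel changes. Seeds must lie inside the mask.
// [[Rcpp::export]]
IntegerMatrix geodesic_expand_cpp(IntegerMatrix seeds, IntegerMatrix mask,
                                  int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("seed and mask dimensions differ");
  int nnb = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab = clone(seeds);

  // current frontier: all labeled pixels (only those with unlabeled mask
  // neighbors matter; the first sweep prunes the rest)
  std::vector<int> frontier;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) != 0) frontier.push_back(c * nr + r);

  while (!frontier.empty()) {
    // synchronized step: collect candidate assignments from the current
    // state, then apply them all at once
    std::vector<int> cand_idx;
    std::vector<int> cand_lab;
    for (size_t i = 0; i < frontier.size(); ++i) {
      int idx = frontier[i];
      int cr = idx % nr, cc = idx / nr;
      int l = lab(cr, cc);
      for (int k = 0; k < nnb; ++k) {
        int r2 = cr + DR[k], c2 = cc + DC[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
          cand_idx.push_back(c2 * nr + r2);
          cand_lab.push_back(l);
        }
      }
    }
    std::vector<int> next_frontier;
    // lowest label wins on contested pixels
    for (size_t i = 0; i < cand_idx.size(); ++i) {
      int idx = cand_idx[i];
      int cr = idx % nr, cc = idx / nr;
      int cur = lab(cr, cc);
      if (cur == 0) {
        lab(cr, cc) = cand_lab[i];
        next_frontier.push_back(idx);
      } else if (cand_lab[i] < cur) {
        lab(cr, cc) = cand_lab[i];  // contested within this same iteration
      }
    }
    frontier.swap(next_frontier);
  }
  return lab;
}
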