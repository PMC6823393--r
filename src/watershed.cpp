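#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Marker-controlled watershed (Meyer's flooding algorithm, 8-connected).
//
// `im` is the landscape (higher = barrier), `markers` an integer matrix with
// 0 for unlabeled pixels and positive labels for seeds. Pixels are flooded
// in order of increasing height starting from the markers; each pixel takes
// the label of the front that reaches it first, so fronts meet on ridge
// crests. Ties in height are broken by insertion order (FIFO), which makes
// the result deterministic.

struct Entry {
  double h;
  unsigned long order;
  int idx;
  int label;
};

struct Cmp {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.h != b.h) return a.h > b.h;   // min-heap on height
    return a.order > b.order;           // FIFO among equal heights
  }
};

// [[Rcpp::export]]
IntegerMatrix meyer_watershed(NumericMatrix im, IntegerMatrix markers) {
  const int nr = im.nrow(), nc = im.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("markers must match image dimensions");

  IntegerMatrix lab(nr, nc);
  std::priority_queue<Entry, std::vector<Entry>, Cmp> pq;
  unsigned long order = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      lab(i, j) = markers(i, j);

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int r = i + dr[k], c = j + dc[k];
        if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
        if (lab(r, c) == 0)
          pq.push({im(r, c), order++, r + c * nr, lab(i, j)});
      }
    }

  while (!pq.empty()) {
    Entry e = pq.top();
    pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    if (lab(r, c) != 0) continue;
    lab(r, c) = e.label;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) == 0)
        pq.push({im(rr, cc), order++, rr + cc * nr, e.label});
    }
  }
  return lab;
}
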