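#include "sim_common.h"
using namespace Rcpp;

// Sequential random dart-throwing ("random sequential adsorption") of equal
// circles until `max_failures` consecutive rejections, which operationally
// defines a saturated ("densely packed") configuration. A uniform bucket
// grid with cell side 2r makes each overlap test O(1).
// [[Rcpp::export]]
NumericMatrix cpp_pack_circles(double width, double height, double radius,
                               int max_failures) {
  double lo = radius;
  double hix = width - radius, hiy = height - radius;
  double spanx = hix - lo, spany = hiy - lo;
  double d2min = 4.0 * radius * radius;
  double bucket = 2.0 * radius;
  int nbx = std::max(1, (int)std::ceil(width / bucket));
  int nby = std::max(1, (int)std::ceil(height / bucket));
  std::vector<std::vector<int> > grid(nbx * nby);
  std::vector<double> xs, ys;

  int failures = 0;
  while (failures < max_failures) {
    double x = lo + unif_rand() * spanx;
    double y = lo + unif_rand() * spany;
    int bx = std::min(nbx - 1, (int)(x / bucket));
    int by = std::min(nby - 1, (int)(y / bucket));
    bool ok = true;
    for (int ix = std::max(0, bx - 1); ix <= std::min(nbx - 1, bx + 1) && ok; ++ix)
      for (int iy = std::max(0, by - 1); iy <= std::min(nby - 1, by + 1) && ok; ++iy) {
        const std::vector<int>& cell = grid[ix + nbx * iy];
        for (size_t j = 0; j < cell.size(); ++j)
          if (sqdist(x, y, xs[cell[j]], ys[cell[j]]) < d2min) { ok = false; break; }
      }
    if (ok) {
      grid[bx + nbx * by].push_back((int)xs.size());
      xs.push_back(x);
      ys.push_back(y);
      failures = 0;
    } else {
      ++failures;
    }
  }
  NumericMatrix out((int)xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Per-site sorted neighbour lists: for each site the `m` nearest other
// sites by centre distance, ties by ascending index. Returned 0-based;
// padded with -1 when fewer than m sites exist.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_lists(NumericMatrix xy, int m) {
  int n = xy.nrow();
  int mm = std::min(m, n - 1);
  if (mm < 0) mm = 0;
  IntegerMatrix out(n, std::max(1, mm));
  std::fill(out.begin(), out.end(), -1);
  std::vector<std::pair<double, int> > cand(n > 0 ? n - 1 : 0);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand[c++] = std::make_pair(sqdist(xy(i, 0), xy(i, 1), xy(j, 0), xy(j, 1)), j);
    }
    std::partial_sort(cand.begin(), cand.begin() + mm, cand.end());
    for (int j = 0; j < mm; ++j) out(i, j) = cand[j].second;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_knn(NumericMatrix xy, IntegerMatrix nbor,
                      LogicalVector mask, int site, int k) {
  std::vector<char> msk(mask.size());
  for (int i = 0; i < mask.size(); ++i) msk[i] = mask[i] ? 1 : 0;
  std::vector<int> res = knn_masked(xy, nbor, msk, site, k);
  return wrap(res);
}

// [[Rcpp::export]]
int cpp_nearest_masked(NumericMatrix xy, LogicalVector mask, int site) {
  std::vector<char> msk(mask.size());
  for (int i = 0; i < mask.size(); ++i) msk[i] = mask[i] ? 1 : 0;
  return nearest_masked(xy, msk, site);
}

// [[Rcpp::export]]
IntegerVector cpp_path_to_empty(NumericMatrix xy, IntegerMatrix nbor,
                                LogicalVector occupied, int start) {
  std::vector<char> occ(occupied.size()), empty(occupied.size());
  for (int i = 0; i < occupied.size(); ++i) {
    occ[i] = occupied[i] ? 1 : 0;
    empty[i] = occupied[i] ? 0 : 1;
  }
  int target = nearest_masked(xy, empty, start);
  if (target < 0) return IntegerVector(0);
  std::vector<int> path = path_via_occupied(xy, nbor, occ, start, target);
  return wrap(path);
}

// [[Rcpp::export]]
int cpp_deposit_target(NumericMatrix xy, LogicalVector occupied,
                       LogicalVector producer, double tx, double ty,
                       double radius, double tol) {
  std::vector<char> occ(occupied.size()), prod(producer.size());
  for (int i = 0; i < occupied.size(); ++i) {
    occ[i] = occupied[i] ? 1 : 0;
    prod[i] = producer[i] ? 1 : 0;
  }
  return deposit_target(xy, occ, prod, tx, ty, radius, tol);
}
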