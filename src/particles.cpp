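#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a binary mask by flood fill.
// Labels are assigned in raster-scan order (column-major, matching R's
// matrix layout), so labeling is deterministic.
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nnb = connectivity;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && labels(r2, c2) == 0) {
            labels(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return labels;
}

// Moore-neighbour boundary trace of one labeled object; returns the
// chain-code perimeter with axial steps weighted 1 and diagonal steps
// weighted sqrt(2). start = (r0, c0) must be the boundary pixel of the
// object with the smallest row in its smallest column (raster first hit).
static double trace_perimeter(const IntegerMatrix& labels, int lab,
                              int r0, int c0) {
  const int nr = labels.nrow(), nc = labels.ncol();
  // clockwise Moore neighbourhood starting East
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const double w[8] = {1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2};

  // check for isolated pixel
  bool isolated = true;
  for (int k = 0; k < 8; ++k) {
    int r2 = r0 + dr[k], c2 = c0 + dc[k];
    if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && labels(r2, c2) == lab) {
      isolated = false;
      break;
    }
  }
  if (isolated) return 0.0;

  double perim = 0.0;
  int r = r0, c = c0;
  // we entered the start pixel "from the West": begin the clockwise scan
  // just after the backtrack direction
  int back = 4; // West
  int first_move = -1;
  long guard = 0, guard_max = 8L * (long)nr * (long)nc + 16;

  while (true) {
    int move = -1;
    for (int k = 1; k <= 8; ++k) {
      int dir = (back + k) % 8;
      int r2 = r + dr[dir], c2 = c + dc[dir];
      if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && labels(r2, c2) == lab) {
        move = dir;
        break;
      }
    }
    if (move < 0) break; // cannot happen for non-isolated pixels
    r += dr[move];
    c += dc[move];
    perim += w[move];
    // backtrack direction: pointing from the new pixel to the previous one
    back = (move + 4) % 8;
    if (first_move < 0) first_move = move;
    else if (r == r0 && c == c0) {
      // Jacob's stopping criterion: closed when we leave the start pixel
      // the same way we first did
      int nxt = -1;
      for (int k = 1; k <= 8; ++k) {
        int dir = (back + k) % 8;
        int r2 = r + dr[dir], c2 = c + dc[dir];
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && labels(r2, c2) == lab) {
          nxt = dir;
          break;
        }
      }
      if (nxt == first_move) break;
    }
    if (++guard > guard_max) break; // safety net
  }
  return perim;
}

// Per-label region statistics: pixel area, centroid (0-based), bounding box
// (0-based, inclusive) and chain-code perimeter.
// [[Rcpp::export]]
List cc_stats(const IntegerMatrix& labels, int nlab) {
  const int nr = labels.nrow(), nc = labels.ncol();
  IntegerVector area(nlab), bb_r0(nlab, nr), bb_r1(nlab, -1),
      bb_c0(nlab, nc), bb_c1(nlab, -1), start_r(nlab, -1), start_c(nlab, -1);
  NumericVector sum_r(nlab), sum_c(nlab), perim(nlab);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int lab = labels(r, c);
      if (lab <= 0) continue;
      int i = lab - 1;
      area[i] += 1;
      sum_r[i] += r;
      sum_c[i] += c;
      if (r < bb_r0[i]) bb_r0[i] = r;
      if (r > bb_r1[i]) bb_r1[i] = r;
      if (c < bb_c0[i]) bb_c0[i] = c;
      if (c > bb_c1[i]) bb_c1[i] = c;
      if (start_r[i] < 0) { start_r[i] = r; start_c[i] = c; }
    }
  }
  for (int i = 0; i < nlab; ++i) {
    if (area[i] == 0) continue;
    perim[i] = trace_perimeter(labels, i + 1, start_r[i], start_c[i]);
    sum_r[i] /= area[i];
    sum_c[i] /= area[i];
  }
  return List::create(
      _["area_px"] = area, _["centroid_y"] = sum_r, _["centroid_x"] = sum_c,
      _["perimeter_px"] = perim, _["bbox_y0"] = bb_r0, _["bbox_x0"] = bb_c0,
      _["bbox_y1"] = bb_r1, _["bbox_x1"] = bb_c1);
}
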