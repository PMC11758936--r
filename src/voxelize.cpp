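#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Amanatides & Woo traversal of one segment in continuous voxel space.
// Convention: voxel of a point is floor(p) (0-based); a point exactly on a
// voxel boundary belongs to the higher-index voxel.
static void traverse_segment(const double *p, const double *q, const int *dim,
                             std::vector<int> &out,
                             std::unordered_set<int> &seen) {
  int cur[3], end[3], step[3];
  double tmax[3], tdelta[3], dirv[3];
  for (int i = 0; i < 3; ++i) {
    cur[i] = (int)std::floor(p[i]);
    end[i] = (int)std::floor(q[i]);
    dirv[i] = q[i] - p[i];
    if (dirv[i] > 0) {
      step[i] = 1;
      tmax[i] = ((double)cur[i] + 1.0 - p[i]) / dirv[i];
      tdelta[i] = 1.0 / dirv[i];
    } else if (dirv[i] < 0) {
      step[i] = -1;
      tmax[i] = ((double)cur[i] - p[i]) / dirv[i];
      tdelta[i] = -1.0 / dirv[i];
    } else {
      step[i] = 0;
      tmax[i] = R_PosInf;
      tdelta[i] = R_PosInf;
    }
  }
  int guard = 3 * (dim[0] + dim[1] + dim[2]) + 6;
  while (guard-- > 0) {
    int lin = cur[0] + dim[0] * (cur[1] + dim[1] * cur[2]);
    if (seen.insert(lin).second) out.push_back(lin);
    if (cur[0] == end[0] && cur[1] == end[1] && cur[2] == end[2]) break;
    int ax = 0;
    if (tmax[1] < tmax[ax]) ax = 1;
    if (tmax[2] < tmax[ax]) ax = 2;
    if (tmax[ax] > 1.0) break;
    cur[ax] += step[ax];
    tmax[ax] += tdelta[ax];
  }
}

// [[Rcpp::export]]
IntegerVector voxelize_polyline_cpp(NumericMatrix pts, IntegerVector dim) {
  int m = pts.nrow();
  if (m < 1) stop("polyline needs at least one point");
  int d[3] = {dim[0], dim[1], dim[2]};
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 3; ++j)
      if (pts(i, j) < 0.0 || pts(i, j) >= (double)d[j])
        stop("polyline point outside grid bounds");
  std::vector<int> out;
  std::unordered_set<int> seen;
  if (m == 1) {
    double p[3] = {pts(0, 0), pts(0, 1), pts(0, 2)};
    traverse_segment(p, p, d, out, seen);
  } else {
    for (int s = 0; s + 1 < m; ++s) {
      double p[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
      double q[3] = {pts(s + 1, 0), pts(s + 1, 1), pts(s + 1, 2)};
      traverse_segment(p, q, d, out, seen);
    }
  }
  return wrap(out); // 0-based linear indices, first-traversal order
}

// [[Rcpp::export]]
List voxelize_polylines_cpp(List polylines, IntegerVector dim) {
  int n = polylines.size();
  List res(n);
  for (int i = 0; i < n; ++i)
    res[i] = voxelize_polyline_cpp(as<NumericMatrix>(polylines[i]), dim);
  return res;
}
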