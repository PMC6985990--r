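// Voxel-grid primitives: 26-connectivity labelling, point-set distances and
// a marching-tetrahedra isosurface (Kuhn decomposition, 6 tets per cube).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// Minimum distance from each row of A to the set B (both in mm).
// [[Rcpp::export(name = ".set_distance_cpp")]]
NumericVector set_distance_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

namespace {
// Kuhn triangulation: 6 tetrahedra sharing the main diagonal (corner 0 -> 6).
// Corner numbering: 0:(0,0,0) 1:(1,0,0) 2:(1,1,0) 3:(0,1,0) 4:(0,0,1) 5:(1,0,1) 6:(1,1,1) 7:(0,1,1)
const int CORN[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
const int TETS[6][4] = {{0,1,2,6},{0,1,5,6},{0,3,2,6},{0,3,7,6},{0,4,5,6},{0,4,7,6}};
}

// [[Rcpp::export(name = ".marching_tetra_cpp")]]
NumericMatrix marching_tetra_cpp(NumericVector field, IntegerVector dims,
                                 double iso, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<double> tri;  // 9 doubles per triangle
  double pos[8][3], val[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CORN[c][0], jj = j + CORN[c][1], kk = k + CORN[c][2];
          val[c] = field[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          pos[c][0] = ii * sx; pos[c][1] = jj * sy; pos[c][2] = kk * sz;
          if (val[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            if (val[idx[v]] >= iso) ins[ni++] = idx[v]; else outs[no++] = idx[v];
          }
          if (ni == 0 || ni == 4) continue;
          double q[4][3];
          int nq = 0;
          // interpolated crossing on each in/out edge
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            int others[3];
            int c = 0;
            for (int v = 0; v < 4; ++v) if (idx[v] != apex) others[c++] = idx[v];
            for (int e = 0; e < 3; ++e) {
              double tfrac = (iso - val[apex]) / (val[others[e]] - val[apex]);
              for (int d = 0; d < 3; ++d)
                q[e][d] = pos[apex][d] + tfrac * (pos[others[e]][d] - pos[apex][d]);
            }
            nq = 3;
          } else {  // 2 in, 2 out: quad split into two triangles
            int pair[4][2] = {{ins[0], outs[0]}, {ins[0], outs[1]}, {ins[1], outs[0]}, {ins[1], outs[1]}};
            for (int e = 0; e < 4; ++e) {
              int a = pair[e][0], b = pair[e][1];
              double tfrac = (iso - val[a]) / (val[b] - val[a]);
              for (int d = 0; d < 3; ++d)
                q[e][d] = pos[a][d] + tfrac * (pos[b][d] - pos[a][d]);
            }
            nq = 4;
          }
          if (nq == 3) {
            for (int e = 0; e < 3; ++e)
              for (int d = 0; d < 3; ++d) tri.push_back(q[e][d]);
          } else {
            // q0,q1 share ins[0]; q2,q3 share ins[1]; fan 0-1-2 and 2-1-3
            int f1[3] = {0, 1, 2}, f2[3] = {2, 1, 3};
            for (int e = 0; e < 3; ++e)
              for (int d = 0; d < 3; ++d) tri.push_back(q[f1[e]][d]);
            for (int e = 0; e < 3; ++e)
              for (int d = 0; d < 3; ++d) tri.push_back(q[f2[e]][d]);
          }
        }
      }

  int ntri = (int)(tri.size() / 9);
  NumericMatrix out(ntri, 9);
  for (int r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = tri[(R_xlen_t)r * 9 + c];
  return out;
}
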