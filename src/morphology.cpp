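#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 26-neighbourhood offsets are generated on the fly from (dx,dy,dz) loops.
// Volumes are 3D arrays in R order: x fastest, then y, then z.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Conflict-barrier label dilation: a background voxel adopts the unique
// nonzero label present in its 26-neighbourhood; voxels seeing two or more
// distinct labels stay background (they form the separating layer).
// [[Rcpp::export]]
IntegerVector cpp_dilate_labels_barrier(IntegerVector ids, IntegerVector dim,
                                        int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector cur = clone(ids);
  for (int it = 0; it < iters; ++it) {
    IntegerVector nxt = clone(cur);
    bool changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = lin(x, y, z, nx, ny);
          if (cur[i] != 0) continue;
          int lab = 0;
          bool conflict = false;
          for (int dz = -1; dz <= 1 && !conflict; ++dz)
            for (int dy = -1; dy <= 1 && !conflict; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                  continue;
                int v = cur[lin(xx, yy, zz, nx, ny)];
                if (v != 0) {
                  if (lab == 0) lab = v;
                  else if (lab != v) { conflict = true; break; }
                }
              }
          if (!conflict && lab != 0) { nxt[i] = lab; changed = true; }
        }
    cur = nxt;
    if (!changed) break;
  }
  return cur;
}

// One-sided carving: clear a labelled voxel iff its 26-neighbourhood holds a
// smaller nonzero label. Guarantees exactly one separating voxel layer
// between touching labels in a single deterministic pass.
// [[Rcpp::export]]
IntegerVector cpp_carve_touching(IntegerVector ids, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out = clone(ids);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        int v = ids[i];
        if (v == 0) continue;
        bool clearme = false;
        for (int dz = -1; dz <= 1 && !clearme; ++dz)
          for (int dy = -1; dy <= 1 && !clearme; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              int w = ids[lin(xx, yy, zz, nx, ny)];
              if (w != 0 && w < v) { clearme = true; break; }
            }
        if (clearme) out[i] = 0;
      }
  return out;
}

// Outer shell: background voxels with at least one labelled 26-neighbour.
// [[Rcpp::export]]
LogicalVector cpp_boundary_shell(IntegerVector ids, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(ids.size(), false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (ids[i] != 0) continue;
        bool hit = false;
        for (int dz = -1; dz <= 1 && !hit; ++dz)
          for (int dy = -1; dy <= 1 && !hit; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              if (ids[lin(xx, yy, zz, nx, ny)] != 0) { hit = true; break; }
            }
        out[i] = hit;
      }
  return out;
}

// For each queried voxel (1-based linear indices) return the two smallest
// distinct nonzero labels found in its 26-neighbourhood (0 if fewer).
// [[Rcpp::export]]
IntegerMatrix cpp_adjacent_pair(IntegerVector ids, IntegerVector dim,
                                IntegerVector voxels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = voxels.size();
  IntegerMatrix out(n, 2);
  for (int q = 0; q < n; ++q) {
    int i = voxels[q] - 1;
    int z = i / (nx * ny), rem = i % (nx * ny);
    int y = rem / nx, x = rem % nx;
    int a = 0, b = 0;  // two smallest distinct labels
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int v = ids[lin(xx, yy, zz, nx, ny)];
          if (v == 0 || v == a || v == b) continue;
          if (a == 0 || v < a) { b = a; a = v; }
          else if (b == 0 || v < b) { b = v; }
        }
    out(q, 0) = a;
    out(q, 1) = b;
  }
  return out;
}

// Connected-component labelling of a logical mask (connectivity 6 or 26).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < (int)mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      int j = q.front(); q.pop();
      int z = j / (nx * ny), rem = j % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int k = lin(xx, yy, zz, nx, ny);
            if (mask[k] && lab[k] == 0) { lab[k] = next; q.push(k); }
          }
    }
  }
  return lab;
}

// Nearest boundary voxel (Euclidean, isotropic voxels) within max_dist_vox
// for each query voxel; ties broken by smallest linear index. Returns
// 1-based linear index of the target boundary voxel, or NA if none in range.
// [[Rcpp::export]]
IntegerVector cpp_project_to_boundary(IntegerVector queries, LogicalVector boundary,
                                      IntegerVector dim, double max_dist_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = queries.size();
  int r = (int)std::floor(max_dist_vox);
  double d2max = max_dist_vox * max_dist_vox;
  IntegerVector out(n, NA_INTEGER);
  for (int q = 0; q < n; ++q) {
    int i = queries[q] - 1;
    int z = i / (nx * ny), rem = i % (nx * ny);
    int y = rem / nx, x = rem % nx;
    double best = d2max + 0.5;
    int besti = -1;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int k = lin(xx, yy, zz, nx, ny);
          if (!boundary[k]) continue;
          double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
          if (d2 > d2max) continue;
          if (d2 < best || (d2 == best && k < besti)) { best = d2; besti = k; }
        }
    if (besti >= 0) out[q] = besti + 1;
  }
  return out;
}
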