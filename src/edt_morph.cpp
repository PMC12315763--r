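// Low-level image numerics: exact anisotropic Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm with nearest-feature
// tracking), connected-component labelling, marching tetrahedra, trilinear
// sampling, separable convolution and priority-ordered region growing.
// All volumes are passed as flat vectors in R's column-major order
// (x fastest), dims = (nx, ny, nz), spacing in mm.

#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform along a line of n samples at spacing h.
// f: input squared distances; id: linear index of the current nearest
// feature (-1 if none). Results written to fo / ido.
static void dt1d(const std::vector<double>& f, const std::vector<int>& id,
                 int n, double h,
                 std::vector<double>& fo, std::vector<int>& ido) {
  // restrict the lower envelope to sites with finite values
  std::vector<int> site;
  site.reserve(n);
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) site.push_back(q);
  if (site.empty()) {
    for (int q = 0; q < n; ++q) { fo[q] = INF; ido[q] = -1; }
    return;
  }
  const int m = (int)site.size();
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int j = 1; j < m; ++j) {
    const double pq = h * site[j], fq = f[site[j]];
    double pr = h * site[v[k]], fr = f[site[v[k]]];
    double s = ((fq + pq * pq) - (fr + pr * pr)) / (2.0 * (pq - pr));
    while (s <= z[k]) { // z[0] = -inf guarantees k >= 0
      --k;
      pr = h * site[v[k]]; fr = f[site[v[k]]];
      s = ((fq + pq * pq) - (fr + pr * pr)) / (2.0 * (pq - pr));
    }
    ++k;
    v[k] = j;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double p = h * q;
    while (z[k + 1] < p) ++k;
    const int sidx = site[v[k]];
    const double d = p - h * sidx;
    fo[q] = d * d + f[sidx];
    ido[q] = id[sidx];
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest
// target voxel center; also returns the 1-based linear index of that voxel.
// [[Rcpp::export]]
List cpp_edt(LogicalVector target, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  std::vector<int> id(n);
  bool any = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (target[i]) { d[i] = 0.0; id[i] = (int)i; any = true; }
    else { d[i] = INF; id[i] = -1; }
  }
  if (!any) stop("distance transform: target mask is empty");

  // pass along x
  {
    std::vector<double> f(nx), fo(nx);
    std::vector<int> fi(nx), fio(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) { f[x] = d[base + x]; fi[x] = id[base + x]; }
        dt1d(f, fi, nx, spacing[0], fo, fio);
        for (int x = 0; x < nx; ++x) { d[base + x] = fo[x]; id[base + x] = fio[x]; }
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), fo(ny);
    std::vector<int> fi(ny), fio(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) {
          f[y] = d[base + (R_xlen_t)y * nx]; fi[y] = id[base + (R_xlen_t)y * nx];
        }
        dt1d(f, fi, ny, spacing[1], fo, fio);
        for (int y = 0; y < ny; ++y) {
          d[base + (R_xlen_t)y * nx] = fo[y]; id[base + (R_xlen_t)y * nx] = fio[y];
        }
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), fo(nz);
    std::vector<int> fi(nz), fio(nz);
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) {
          f[z] = d[base + (R_xlen_t)z * stride]; fi[z] = id[base + (R_xlen_t)z * stride];
        }
        dt1d(f, fi, nz, spacing[2], fo, fio);
        for (int z = 0; z < nz; ++z) {
          d[base + (R_xlen_t)z * stride] = fo[z]; id[base + (R_xlen_t)z * stride] = fio[z];
        }
      }
  }

  NumericVector dist(n);
  IntegerVector nearest(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dist[i] = std::sqrt(d[i]);
    nearest[i] = id[i] + 1; // 1-based for R
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

static void neighbor_offsets(int connectivity, int nx, int ny,
                             std::vector<int>& dx, std::vector<int>& dy,
                             std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  if (connectivity == 6) {
    int ox[6] = {1,-1,0,0,0,0}, oy[6] = {0,0,1,-1,0,0}, oz[6] = {0,0,0,0,1,-1};
    for (int i = 0; i < 6; ++i) { dx.push_back(ox[i]); dy.push_back(oy[i]); dz.push_back(oz[i]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a); dy.push_back(b); dz.push_back(c);
        }
  }
}

// Connected components of a binary mask; labels 1..K in decreasing
// discovery order, component sizes attached.
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, nx, ny, dx, dy, dz);
  const int nb = (int)dx.size();
  std::vector<R_xlen_t> stack;
  std::vector<double> sizes;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    double sz = 0;
    stack.clear();
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++sz;
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nb; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) { labels[w] = cur; stack.push_back(w); }
      }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// Marching tetrahedra on a scalar field: triangulated level set at `level`.
// Vertices in 0-based voxel coordinates; faces 1-based. Triangles are
// oriented so their normals point toward increasing field values.
// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dims,
                             double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // Kuhn 6-tetrahedra decomposition of the unit cube (corner indices 0..7,
  // corner c = (c&1, (c>>1)&1, (c>>2)&1)); all tets share the 0-7 diagonal,
  // which makes the triangulation conforming across neighboring cubes.
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };
  std::vector<double> vx, vy, vzc;
  std::vector<int> fa, fb, fc;
  std::map<std::pair<R_xlen_t, R_xlen_t>, int> edge_vertex;

  double cx[8], cy[8], cz8[8], cv[8];
  R_xlen_t ci[8];

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        for (int c = 0; c < 8; ++c) {
          int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
          cx[c] = x + ox; cy[c] = y + oy; cz8[c] = z + oz;
          ci[c] = (R_xlen_t)(z + oz) * sz + (R_xlen_t)(y + oy) * sy + (x + ox) * sx;
          cv[c] = field[ci[c]];
        }
        for (int t = 0; t < 6; ++t) {
          int above[4], nab = 0, below[4], nbe = 0;
          for (int j = 0; j < 4; ++j) {
            int c = tets[t][j];
            if (cv[c] >= level) above[nab++] = c; else below[nbe++] = c;
          }
          if (nab == 0 || nab == 4) continue;
          // collect crossing edges (each between an above and a below corner)
          int ea[4], eb[4], ne = 0;
          for (int a = 0; a < nab; ++a)
            for (int b = 0; b < nbe; ++b) { ea[ne] = above[a]; eb[ne] = below[b]; ++ne; }
          int vid[4];
          for (int e = 0; e < ne; ++e) {
            R_xlen_t i1 = ci[ea[e]], i2 = ci[eb[e]];
            std::pair<R_xlen_t, R_xlen_t> key = i1 < i2 ?
              std::make_pair(i1, i2) : std::make_pair(i2, i1);
            std::map<std::pair<R_xlen_t, R_xlen_t>, int>::iterator it =
              edge_vertex.find(key);
            if (it != edge_vertex.end()) { vid[e] = it->second; continue; }
            double v1 = cv[ea[e]], v2 = cv[eb[e]];
            double tt = (v1 == v2) ? 0.5 : (level - v1) / (v2 - v1);
            if (tt < 0) tt = 0; if (tt > 1) tt = 1;
            vx.push_back(cx[ea[e]] + tt * (cx[eb[e]] - cx[ea[e]]));
            vy.push_back(cy[ea[e]] + tt * (cy[eb[e]] - cy[ea[e]]));
            vzc.push_back(cz8[ea[e]] + tt * (cz8[eb[e]] - cz8[ea[e]]));
            vid[e] = (int)vx.size() - 1;
            edge_vertex[key] = vid[e];
          }
          // reference direction: from below-centroid toward above-centroid
          double bx = 0, by = 0, bz = 0, ax = 0, ay = 0, az = 0;
          for (int b = 0; b < nbe; ++b) { bx += cx[below[b]]; by += cy[below[b]]; bz += cz8[below[b]]; }
          for (int a = 0; a < nab; ++a) { ax += cx[above[a]]; ay += cy[above[a]]; az += cz8[above[a]]; }
          double rx = ax / nab - bx / nbe, ry = ay / nab - by / nbe,
                 rz = az / nab - bz / nbe;
          int ntri = (ne == 3) ? 1 : 2;
          int tris[2][3];
          if (ne == 3) { tris[0][0] = vid[0]; tris[0][1] = vid[1]; tris[0][2] = vid[2]; }
          else {
            // ne == 4 with pairs (a0b0, a0b1, a1b0, a1b1): quad order 0,1,3,2
            tris[0][0] = vid[0]; tris[0][1] = vid[1]; tris[0][2] = vid[3];
            tris[1][0] = vid[0]; tris[1][1] = vid[3]; tris[1][2] = vid[2];
          }
          for (int q = 0; q < ntri; ++q) {
            int i0 = tris[q][0], i1 = tris[q][1], i2 = tris[q][2];
            double ux = vx[i1] - vx[i0], uy = vy[i1] - vy[i0], uz = vzc[i1] - vzc[i0];
            double wx = vx[i2] - vx[i0], wy = vy[i2] - vy[i0], wz = vzc[i2] - vzc[i0];
            double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
                   nzv = ux * wy - uy * wx;
            if (nxv * rx + nyv * ry + nzv * rz < 0) { int tmp = i1; i1 = i2; i2 = tmp; }
            fa.push_back(i0 + 1); fb.push_back(i1 + 1); fc.push_back(i2 + 1);
          }
        }
      }
  const int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) { verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vzc[i]; }
  const int nf = (int)fa.size();
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) { faces(i, 0) = fa[i]; faces(i, 1) = fb[i]; faces(i, 2) = fc[i]; }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Trilinear interpolation at 0-based voxel coordinates; NA outside the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 && z <= nz - 1)) {
      out[i] = NA_REAL; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    R_xlen_t b = (R_xlen_t)z0 * sz + (R_xlen_t)y0 * sy + x0;
    int ddx = (nx > 1) ? 1 : 0, ddy = (ny > 1) ? (int)sy : 0,
        ddz = (nz > 1) ? (int)sz : 0;
    double c000 = vol[b], c100 = vol[b + ddx], c010 = vol[b + ddy],
           c110 = vol[b + ddx + ddy], c001 = vol[b + ddz],
           c101 = vol[b + ddx + ddz], c011 = vol[b + ddy + ddz],
           c111 = vol[b + ddx + ddy + ddz];
    double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable convolution along one axis (0, 1 or 2) with replicate padding.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int kl = kernel.size(), half = kl / 2;
  NumericVector out(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  const int len = nd[axis];
  const R_xlen_t st = strides[axis];
  int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
  const int n1 = nd[o1], n2 = nd[o2];
  const R_xlen_t s1 = strides[o1], s2 = strides[o2];
  std::vector<double> line(len);
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      R_xlen_t base = (R_xlen_t)j2 * s2 + (R_xlen_t)j1 * s1;
      for (int i = 0; i < len; ++i) line[i] = vol[base + (R_xlen_t)i * st];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int k = 0; k < kl; ++k) {
          int p = i + k - half;
          if (p < 0) p = 0;
          if (p >= len) p = len - 1;
          acc += line[p] * kernel[k];
        }
        out[base + (R_xlen_t)i * st] = acc;
      }
    }
  return out;
}

// Priority-ordered region growing: starting from `start` (1-based linear
// index), repeatedly absorb the frontier voxel (26-connected, inside mask)
// with the smallest priority until `target` voxels are collected.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(LogicalVector mask, IntegerVector dims,
                              NumericVector priority, int start, int target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector grown(n, false);
  if (target <= 0) return grown;
  std::vector<int> dx, dy, dz;
  neighbor_offsets(26, nx, ny, dx, dy, dz);
  typedef std::pair<double, R_xlen_t> qel;
  std::priority_queue<qel, std::vector<qel>, std::greater<qel> > pq;
  std::vector<char> queued(n, 0);
  R_xlen_t s = start - 1;
  pq.push(std::make_pair(priority[s], s));
  queued[s] = 1;
  int got = 0;
  while (!pq.empty() && got < target) {
    qel top = pq.top(); pq.pop();
    R_xlen_t v = top.second;
    if (grown[v]) continue;
    grown[v] = true;
    ++got;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < dx.size(); ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (mask[w] && !queued[w]) { queued[w] = 1; pq.push(std::make_pair(priority[w], w)); }
    }
  }
  return grown;
}
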