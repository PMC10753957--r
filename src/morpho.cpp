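// Low-level 3D grid operations: connected components, topological thinning,
// marker-controlled watershed, per-slice median filtering.
//
// All arrays are R 3D arrays with dim = c(nz, ny, nx), i.e. column-major with
// z the fastest axis: linear index = z + nz*(y + ny*x), 0-based here.

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <tuple>
#include <vector>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// neighborhood offsets (dz, dy, dx) for 6-, 18- or 26-connectivity
static std::vector<std::array<int, 3>> nb_offsets(int connectivity) {
  std::vector<std::array<int, 3>> d;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        d.push_back({dz, dy, dx});
      }
  return d;
}

// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb = nb_offsets(connectivity);
  std::vector<int> stack;
  int next = 0;
  // scan in linear (z-fastest) order so labels are deterministic
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      int z = c % nz, y = (c / nz) % ny, x = c / (nz * ny);
      for (const auto &o : nb) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// number of foreground 26-neighbors
static int n_nb26(const char *img, int z, int y, int x, int nz, int ny,
                  int nx) {
  int cnt = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        if (img[idx3(zz, yy, xx, nz, ny)]) ++cnt;
      }
  return cnt;
}

// Topological simple-point test (Bertrand & Malandain characterization):
// a foreground voxel is simple iff the foreground restricted to its 26
// neighbors has exactly one 26-component, and the background restricted to
// its 18-neighborhood has exactly one 6-component that is 6-adjacent to it.
static bool is_simple(const char *img, int z, int y, int x, int nz, int ny,
                      int nx) {
  char cube[27];  // local index l = (dz+1) + 3*(dy+1) + 9*(dx+1)
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        char v = 0;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = img[idx3(zz, yy, xx, nz, ny)];
        cube[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = v;
      }
  const int center = 13;

  // T26: 26-components of the foreground neighbors
  bool seen[27] = {false};
  int t26 = 0;
  std::vector<int> st;
  for (int l = 0; l < 27; ++l) {
    if (l == center || !cube[l] || seen[l]) continue;
    ++t26;
    if (t26 > 1) return false;
    st.clear();
    st.push_back(l);
    seen[l] = true;
    while (!st.empty()) {
      int c = st.back();
      st.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
              continue;
            int j = zz + 3 * yy + 9 * xx;
            if (j == center || seen[j] || !cube[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  if (t26 != 1) return false;

  // T6: 6-components of background within the 18-neighborhood, counted only
  // when they contain a face neighbor (i.e. are 6-adjacent to the center)
  bool seenb[27] = {false};
  int t6 = 0;
  const int face[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  for (int l = 0; l < 27; ++l) {
    int cz = l % 3, cy = (l / 3) % 3, cx = l / 9;
    int d = std::abs(cz - 1) + std::abs(cy - 1) + std::abs(cx - 1);
    if (d != 1) continue;  // seed from face neighbors only
    if (cube[l] || seenb[l]) continue;
    ++t6;
    st.clear();
    st.push_back(l);
    seenb[l] = true;
    while (!st.empty()) {
      int c = st.back();
      st.pop_back();
      int zz = c % 3, yy = (c / 3) % 3, xx = c / 9;
      for (const auto &o : face) {
        int z2 = zz + o[0], y2 = yy + o[1], x2 = xx + o[2];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        int j = z2 + 3 * y2 + 9 * x2;
        int dj = std::abs(z2 - 1) + std::abs(y2 - 1) + std::abs(x2 - 1);
        if (dj == 0 || dj == 3) continue;  // stay within the 18-neighborhood
        if (cube[j] || seenb[j]) continue;
        seenb[j] = true;
        st.push_back(j);
      }
    }
  }
  return t6 == 1;
}

// Sequential 6-subiteration thinning to a curve skeleton: repeatedly delete
// simple, non-endpoint border voxels, cycling through the six face
// directions; deletions are re-validated at removal time so topology is
// preserved exactly. Endpoints (<= 1 foreground 26-neighbor) are kept, which
// preserves curve extremities.
// [[Rcpp::export]]
LogicalVector skeletonize_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  std::vector<char> img(n);
  for (int i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int i = 0; i < n; ++i) {
        if (!img[i]) continue;
        int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
        int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
        bool border = true;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          border = !img[idx3(zz, yy, xx, nz, ny)];
        if (!border) continue;
        if (n_nb26(img.data(), z, y, x, nz, ny, nx) <= 1) continue;
        if (!is_simple(img.data(), z, y, x, nz, ny, nx)) continue;
        cand.push_back(i);
      }
      for (int i : cand) {
        int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
        if (n_nb26(img.data(), z, y, x, nz, ny, nx) <= 1) continue;
        if (!is_simple(img.data(), z, y, x, nz, ny, nx)) continue;
        img[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}

// Marker-controlled watershed by priority flooding: grow seed labels over
// the mask in increasing topography order; plateau ties are broken by
// insertion order (deterministic for identical inputs).
// [[Rcpp::export]]
IntegerVector watershed_3d(NumericVector topo, IntegerVector seeds,
                           LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  typedef std::tuple<double, long long, int> Item;  // priority, order, index
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> pq;
  long long counter = 0;
  for (int i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(Item(topo[i], counter++, i));
    }
  std::vector<std::array<int, 3>> nb = nb_offsets(connectivity);
  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    int c = std::get<2>(it);
    double pr = std::get<0>(it);
    int z = c % nz, y = (c / nz) % ny, x = c / (nz * ny);
    for (const auto &o : nb) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] || lab[j]) continue;
      lab[j] = lab[c];
      pq.push(Item(std::max(topo[j], pr), counter++, j));
    }
  }
  return lab;
}

// 2D median filter applied independently to every x-slice over the (z, y)
// plane; windows are truncated at the borders.
// [[Rcpp::export]]
NumericVector median_filter_yz_cpp(NumericVector vol, IntegerVector dims,
                                   int radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out(nz * ny * nx);
  std::vector<double> w;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        w.clear();
        for (int dy = -radius; dy <= radius; ++dy)
          for (int dz = -radius; dz <= radius; ++dz) {
            int zz = z + dz, yy = y + dy;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny) continue;
            w.push_back(vol[idx3(zz, yy, x, nz, ny)]);
          }
        std::sort(w.begin(), w.end());
        size_t m = w.size();
        out[idx3(z, y, x, nz, ny)] =
            (m % 2) ? w[m / 2] : 0.5 * (w[m / 2 - 1] + w[m / 2]);
      }
  return out;
}
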