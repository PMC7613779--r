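#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Volumes are R arrays dim = (ny, nx, nz), column-major: i = y + ny*(x + nx*z).

static inline void neighbours6(int idx, int ny, int nx, int nz, int* out, int& n) {
  int y = idx % ny;
  int t = idx / ny;
  int x = t % nx;
  int z = t / nx;
  n = 0;
  if (y > 0)      out[n++] = idx - 1;
  if (y < ny - 1) out[n++] = idx + 1;
  if (x > 0)      out[n++] = idx - ny;
  if (x < nx - 1) out[n++] = idx + ny;
  if (z > 0)      out[n++] = idx - ny * nx;
  if (z < nz - 1) out[n++] = idx + ny * nx;
}

// 3x3x3 median filter; windows truncated at the borders.
// [[Rcpp::export(name = ".median3_cpp")]]
NumericVector median3_cpp(NumericVector vol, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  std::vector<double> w;
  w.reserve(27);
  for (int z = 0; z < nz; z++) {
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) {
        w.clear();
        for (int dz = -1; dz <= 1; dz++) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dx = -1; dx <= 1; dx++) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            for (int dy = -1; dy <= 1; dy++) {
              int yy = y + dy; if (yy < 0 || yy >= ny) continue;
              w.push_back(vol[yy + ny * (xx + nx * zz)]);
            }
          }
        }
        size_t m = w.size() / 2;
        std::nth_element(w.begin(), w.begin() + m, w.end());
        double med = w[m];
        if (w.size() % 2 == 0) {
          std::nth_element(w.begin(), w.begin() + m - 1, w.begin() + m);
          med = 0.5 * (med + w[m - 1]);
        }
        out[y + ny * (x + nx * z)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

struct QEntry {
  double value;
  int push_order;
  int idx;
  int label;
};
struct QCompare {
  // max-heap on value; ties: smaller linear index, then earlier push
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.value != b.value) return a.value < b.value;
    if (a.idx != b.idx) return a.idx > b.idx;
    return a.push_order > b.push_order;
  }
};

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Hierarchical watershed: seeds are regional maxima with dynamics >= h and
// intensity > bg; watershed-by-flooding assigns every voxel with intensity > bg
// to a seed's catchment basin; each basin is then restricted to voxels with
// I >= p_s - flood_frac * (p_s - bg) where p_s is the seed peak intensity.
// [[Rcpp::export(name = ".hwatershed_cpp")]]
IntegerVector hwatershed_cpp(NumericVector land, IntegerVector dim,
                             double h, double bg, double flood_frac) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int n = ny * nx * nz;
  int nb[6], nn;

  // order voxels by decreasing intensity (ties: increasing index)
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (land[a] != land[b]) return land[a] > land[b];
    return a < b;
  });

  // union-find pass for component peaks and their dynamics
  std::vector<int> parent(n, -1);          // -1 = unprocessed
  std::vector<double> peak_val(n, 0.0);    // defined on roots (peak voxel index)
  std::vector<double> dynamics;            // per discovered peak
  std::vector<int> peak_idx;               // voxel index of each peak
  std::vector<int> peak_id_of(n, -1);      // root voxel -> entry in peak vectors

  for (int k = 0; k < n; k++) {
    int v = ord[k];
    neighbours6(v, ny, nx, nz, nb, nn);
    int best_root = -1;
    double best_peak = -1.0;
    int roots[6]; int nroots = 0;
    for (int j = 0; j < nn; j++) {
      int u = nb[j];
      if (parent[u] < 0) continue;
      int r = uf_find(parent, u);
      bool seen = false;
      for (int q = 0; q < nroots; q++) if (roots[q] == r) { seen = true; break; }
      if (!seen) roots[nroots++] = r;
    }
    if (nroots == 0) {
      parent[v] = v;
      peak_val[v] = land[v];
      peak_id_of[v] = (int) peak_idx.size();
      peak_idx.push_back(v);
      dynamics.push_back(R_PosInf);        // overwritten on merge
      continue;
    }
    for (int q = 0; q < nroots; q++) {
      int r = roots[q];
      if (peak_val[r] > best_peak ||
          (peak_val[r] == best_peak && (best_root < 0 || r < best_root))) {
        best_peak = peak_val[r];
        best_root = r;
      }
    }
    parent[v] = best_root;
    for (int q = 0; q < nroots; q++) {
      int r = roots[q];
      if (r == best_root) continue;
      dynamics[peak_id_of[r]] = peak_val[r] - land[v];
      parent[r] = best_root;
    }
  }

  // seeds: peaks with dynamics >= h and intensity > bg, labelled by
  // decreasing peak intensity (ties: voxel index) -> 1..n_seeds
  std::vector<int> seed_vox;
  for (size_t p = 0; p < peak_idx.size(); p++) {
    int v = peak_idx[p];
    if (land[v] > bg && dynamics[p] >= h) seed_vox.push_back(v);
  }
  std::stable_sort(seed_vox.begin(), seed_vox.end(), [&](int a, int b) {
    if (land[a] != land[b]) return land[a] > land[b];
    return a < b;
  });

  IntegerVector labels(n, 0);
  int nseed = (int) seed_vox.size();
  if (nseed > 0) {
    std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
    int push_order = 0;
    for (int s = 0; s < nseed; s++)
      pq.push(QEntry{(double) land[seed_vox[s]], push_order++, seed_vox[s], s + 1});
    while (!pq.empty()) {
      QEntry e = pq.top(); pq.pop();
      if (labels[e.idx] != 0) continue;
      labels[e.idx] = e.label;
      neighbours6(e.idx, ny, nx, nz, nb, nn);
      for (int j = 0; j < nn; j++) {
        int u = nb[j];
        if (labels[u] == 0 && land[u] > bg)
          pq.push(QEntry{(double) land[u], push_order++, u, e.label});
      }
    }
    // flooding restriction per basin
    std::vector<double> level(nseed + 1, 0.0);
    for (int s = 0; s < nseed; s++) {
      double p = land[seed_vox[s]];
      level[s + 1] = p - flood_frac * (p - bg);
    }
    for (int i = 0; i < n; i++) {
      int l = labels[i];
      if (l > 0 && land[i] < level[l]) labels[i] = 0;
    }
  }

  labels.attr("dim") = dim;
  IntegerVector seeds(seed_vox.begin(), seed_vox.end());
  for (int s = 0; s < nseed; s++) seeds[s] += 1;  // 1-based for R
  labels.attr("seeds") = seeds;
  return labels;
}

// Connected components of the non-zero pixels of a 2D matrix; only pixels
// holding the SAME value are joined, so distinct touching labels stay
// separate components. conn = 4 or 8.
// [[Rcpp::export(name = ".label2d_cpp")]]
IntegerMatrix label2d_cpp(IntegerMatrix mask, int conn) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (conn == 8) ? 8 : 4;
  for (int x = 0; x < nx; x++) {
    for (int y = 0; y < ny; y++) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      next++;
      int val = mask(y, x);
      stack.push_back(std::make_pair(y, x));
      lab(y, x) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int d = 0; d < ndir; d++) {
          int yy = p.first + dy8[d], xx = p.second + dx8[d];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) == val && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            stack.push_back(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return lab;
}

// Largest axis-aligned all-true rectangle in a logical matrix.
// Returns c(row0, col0, nrow, ncol), 1-based; zeros if no true cell.
// [[Rcpp::export(name = ".largest_rect_cpp")]]
IntegerVector largest_rect_cpp(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  std::vector<int> height(nx, 0);
  int best = 0, br0 = 0, bc0 = 0, bnr = 0, bnc = 0;
  for (int y = 0; y < ny; y++) {
    for (int x = 0; x < nx; x++)
      height[x] = mask(y, x) ? height[x] + 1 : 0;
    // largest rectangle in histogram
    std::vector<int> st;
    for (int x = 0; x <= nx; x++) {
      int hcur = (x == nx) ? 0 : height[x];
      while (!st.empty() && height[st.back()] >= hcur) {
        int hh = height[st.back()];
        st.pop_back();
        int left = st.empty() ? 0 : st.back() + 1;
        int width = x - left;
        if (hh * width > best) {
          best = hh * width;
          br0 = y - hh + 1;
          bc0 = left;
          bnr = hh;
          bnc = width;
        }
      }
      st.push_back(x);
    }
  }
  return IntegerVector::create(br0 + 1, bc0 + 1, bnr, bnc);
}
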