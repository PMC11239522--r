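// 3D connected-component labeling with 6/18/26 connectivity (union-find,
// two passes). Components are numbered by order of first appearance in the
// linear scan (z fastest, then y, then x), which makes labeling
// deterministic for a given mask.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <climits>
using namespace Rcpp;

namespace {

struct DSU {
  std::vector<int> parent;
  int add() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

}  // namespace

// [[Rcpp::export]]
List cc3d_label_cpp(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  int Z = dim[0], Y = dim[1], X = dim[2];
  long N = (long)Z * Y * X;
  long ZY = (long)Z * Y;

  // negative-direction neighbour offsets (already scanned voxels)
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        // keep only offsets that precede the voxel in scan order
        if (dx < 0 || (dx == 0 && dy < 0) || (dx == 0 && dy == 0 && dz < 0))
          offs.push_back({dz, dy, dx});
      }

  std::vector<int> prov(N, -1);
  DSU dsu;
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long v = z + (long)Z * y + ZY * x;
        if (!mask[v]) continue;
        int lab = -1;
        for (auto& o : offs) {
          int zn = z + o[0], yn = y + o[1], xn = x + o[2];
          if (zn < 0 || zn >= Z || yn < 0 || yn >= Y || xn < 0 || xn >= X)
            continue;
          long vn = zn + (long)Z * yn + ZY * xn;
          if (prov[vn] >= 0) {
            if (lab < 0) lab = prov[vn];
            else dsu.unite(lab, prov[vn]);
          }
        }
        if (lab < 0) lab = dsu.add();
        prov[v] = lab;
      }

  // map roots to final labels in order of first occurrence
  std::vector<int> final_of_root(dsu.parent.size(), 0);
  int next = 0;
  IntegerVector labels(N);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long v = z + (long)Z * y + ZY * x;
        if (prov[v] < 0) continue;
        int r = dsu.find(prov[v]);
        if (final_of_root[r] == 0) final_of_root[r] = ++next;
        labels[v] = final_of_root[r];
      }

  // per-component stats: count, centroid sums, bbox (1-based inclusive)
  int K = next;
  std::vector<double> cnt(K, 0), sz(K, 0), sy(K, 0), sx(K, 0);
  std::vector<int> zmin(K, INT_MAX), zmax(K, -1), ymin(K, INT_MAX),
      ymax(K, -1), xmin(K, INT_MAX), xmax(K, -1);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long v = z + (long)Z * y + ZY * x;
        int l = labels[v];
        if (l == 0) continue;
        int k = l - 1;
        cnt[k] += 1; sz[k] += z + 1; sy[k] += y + 1; sx[k] += x + 1;
        zmin[k] = std::min(zmin[k], z + 1); zmax[k] = std::max(zmax[k], z + 1);
        ymin[k] = std::min(ymin[k], y + 1); ymax[k] = std::max(ymax[k], y + 1);
        xmin[k] = std::min(xmin[k], x + 1); xmax[k] = std::max(xmax[k], x + 1);
      }
  NumericMatrix stats(K, 10);
  colnames(stats) = CharacterVector::create(
      "volume_vox", "cz", "cy", "cx", "z0", "z1", "y0", "y1", "x0", "x1");
  for (int k = 0; k < K; ++k) {
    stats(k, 0) = cnt[k];
    stats(k, 1) = sz[k] / cnt[k];
    stats(k, 2) = sy[k] / cnt[k];
    stats(k, 3) = sx[k] / cnt[k];
    stats(k, 4) = zmin[k]; stats(k, 5) = zmax[k];
    stats(k, 6) = ymin[k]; stats(k, 7) = ymax[k];
    stats(k, 8) = xmin[k]; stats(k, 9) = xmax[k];
  }
  labels.attr("dim") = dim;
  return List::create(_["labels"] = labels, _["stats"] = stats);
}

// Relabel a labeled grid through a lookup: map[old label] = new label
// (0 drops the voxel). map is an integer vector indexed by old label.
// [[Rcpp::export]]
IntegerVector relabel_cpp(IntegerVector labels, IntegerVector map) {
  IntegerVector out(labels.size());
  for (long i = 0; i < (long)labels.size(); ++i) {
    int l = labels[i];
    out[i] = (l > 0 && l <= map.size()) ? map[l - 1] : 0;
  }
  out.attr("dim") = labels.attr("dim");
  return out;
}

// Pair overlap table between two labeled grids: returns unique
// (label_a, label_b) pairs over voxels where both are nonzero.
// [[Rcpp::export]]
IntegerMatrix label_overlap_pairs_cpp(IntegerVector a, IntegerVector b) {
  std::map<std::pair<int, int>, int> seen;
  for (long i = 0; i < (long)a.size(); ++i) {
    if (a[i] > 0 && b[i] > 0) seen[{a[i], b[i]}] += 1;
  }
  IntegerMatrix out(seen.size(), 3);
  colnames(out) = CharacterVector::create("label_a", "label_b", "n_vox");
  int r = 0;
  for (auto& kv : seen) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
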