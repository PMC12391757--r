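#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

// Threshold-free cluster enhancement by incremental union-find.
//
// TFCE(v) = sum over h = dh, 2dh, ..., <= max(t) of e_h(v)^E * h^H * dh,
// with e_h(v) the voxel count of the connected component containing v in
// the supra-threshold set {t >= h}. Thresholds are processed in descending
// order; voxels activate as h drops to their value and components merge in
// a weighted union-find whose per-node offsets let each step's increment
// be credited to a component root in O(1) instead of per member.

namespace {

struct UF {
  std::vector<int> parent;   // -1 = inactive
  std::vector<double> off;   // node value offset relative to parent
  std::vector<double> acc;   // accumulated value, valid at roots
  std::vector<int> sz;       // component size, valid at roots

  explicit UF(int n) : parent(n, -1), off(n, 0.0), acc(n, 0.0), sz(n, 0) {}

  // path-compressing find; afterwards off[v] is v's offset to the root
  int find(int v) {
    int root = v;
    while (parent[root] != root) root = parent[root];
    std::vector<int> path;
    int cur = v;
    while (parent[cur] != cur) { path.push_back(cur); cur = parent[cur]; }
    double dist = 0.0;
    for (int i = static_cast<int>(path.size()) - 1; i >= 0; --i) {
      dist += off[path[i]];
      off[path[i]] = dist;
      parent[path[i]] = root;
    }
    return root;
  }

  // unite roots ra, rb, preserving every member's current value
  void unite(int ra, int rb) {
    if (sz[ra] < sz[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    off[rb] = acc[rb] - acc[ra];
    sz[ra] += sz[rb];
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector tfce_cpp(Rcpp::NumericVector t, Rcpp::IntegerVector dims,
                             double E, double H, double dh,
                             int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  Rcpp::NumericVector out(V);

  std::vector<int> pos;
  pos.reserve(256);
  double tmax = 0.0;
  for (int v = 0; v < V; ++v) {
    if (t[v] > 0.0) {
      pos.push_back(v);
      if (t[v] > tmax) tmax = t[v];
    }
  }
  if (pos.empty() || dh <= 0.0) return out;
  const long nsteps = static_cast<long>(std::floor(tmax / dh + 1e-6));
  if (nsteps < 1) return out;
  // tolerance so a voxel mathematically equal to a threshold is included
  // even when s * dh rounds a last-bit above it
  const double htol = dh * 1e-6;

  std::sort(pos.begin(), pos.end(),
            [&](int a, int b) { return t[a] > t[b]; });

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int noff = static_cast<int>(dxs.size());

  UF uf(V);
  std::vector<double> pow_sz(static_cast<std::size_t>(V) + 1, -1.0);
  std::vector<int> roots;
  std::size_t ptr = 0;
  for (long s = nsteps; s >= 1; --s) {
    const double h = s * dh;
    while (ptr < pos.size() && t[pos[ptr]] >= h - htol) {
      const int v = pos[ptr++];
      uf.parent[v] = v;
      uf.off[v] = 0.0;
      uf.acc[v] = 0.0;
      uf.sz[v] = 1;
      roots.push_back(v);
      const int x = v % nx;
      const int y = (v / nx) % ny;
      const int z = v / (nx * ny);
      for (int o = 0; o < noff; ++o) {
        const int xx = x + dxs[o], yy = y + dys[o], zz = z + dzs[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int u = xx + nx * (yy + ny * zz);
        if (uf.parent[u] == -1) continue;
        const int ru = uf.find(u);
        const int rv = uf.find(v);
        if (ru != rv) uf.unite(ru, rv);
      }
    }
    // drop stale roots, then credit this step's increment per component
    std::size_t w = 0;
    for (std::size_t i = 0; i < roots.size(); ++i)
      if (uf.parent[roots[i]] == roots[i]) roots[w++] = roots[i];
    roots.resize(w);
    const double hterm = std::pow(h, H) * dh;
    for (std::size_t i = 0; i < roots.size(); ++i) {
      const int r = roots[i];
      double& p = pow_sz[uf.sz[r]];
      if (p < 0.0) p = std::pow(static_cast<double>(uf.sz[r]), E);
      uf.acc[r] += p * hterm;
    }
  }
  for (std::size_t i = 0; i < pos.size(); ++i) {
    const int v = pos[i];
    if (uf.parent[v] == -1) continue;  // strictly below the lowest threshold
    const int r = uf.find(v);
    out[v] = uf.off[v] + uf.acc[r];
  }
  return out;
}
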