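#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Neighbour offsets for 6- or 26-connectivity on a 3D lattice.
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int,3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (connectivity == 6 && manh > 1) continue;
                if (connectivity == 18 && manh > 2) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

// Label connected components of `keep` (flattened 3D, column-major).
// Returns labels 1..K, 0 where !keep.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector keep, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = nx * ny * nz;
    IntegerVector labels(n, 0);
    auto off = neighbour_offsets(connectivity);
    int next_label = 0;
    std::queue<int> q;
    for (int i = 0; i < n; ++i) {
        if (!keep[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        q.push(i);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
            for (auto &d : off) {
                int xx = x + d[0], yy = y + d[1], zz = z + d[2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                int w = xx + nx * (yy + ny * zz);
                if (keep[w] && labels[w] == 0) {
                    labels[w] = next_label;
                    q.push(w);
                }
            }
        }
    }
    return labels;
}

// Threshold-free cluster enhancement of a (flattened, column-major) 3D map.
// For each voxel: sum over h = dh, 2dh, ... <= value of e(h)^E * h^H * dh,
// where e(h) is the extent of the supra-threshold (value >= h) connected
// component containing the voxel. Negative map values are never enhanced.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       LogicalVector mask, double E, double H, double dh,
                       int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = nx * ny * nz;
    NumericVector out(n, 0.0);
    double hmax = 0.0;
    for (int i = 0; i < n; ++i)
        if (mask[i] && map[i] > hmax) hmax = map[i];
    if (hmax <= 0.0 || dh <= 0.0) return out;

    auto off = neighbour_offsets(connectivity);
    std::vector<int> labels(n);
    std::vector<int> stack;
    for (double h = dh; h <= hmax + 1e-12; h += dh) {
        std::fill(labels.begin(), labels.end(), 0);
        int next_label = 0;
        std::vector<double> cluster_size;
        cluster_size.push_back(0.0); // label 0 unused
        for (int i = 0; i < n; ++i) {
            if (!mask[i] || map[i] < h || labels[i] != 0) continue;
            ++next_label;
            cluster_size.push_back(0.0);
            labels[i] = next_label;
            stack.clear();
            stack.push_back(i);
            while (!stack.empty()) {
                int v = stack.back(); stack.pop_back();
                cluster_size[next_label] += 1.0;
                int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
                for (auto &d : off) {
                    int xx = x + d[0], yy = y + d[1], zz = z + d[2];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                        zz < 0 || zz >= nz) continue;
                    int w = xx + nx * (yy + ny * zz);
                    if (mask[w] && map[w] >= h && labels[w] == 0) {
                        labels[w] = next_label;
                        stack.push_back(w);
                    }
                }
            }
        }
        double hH = std::pow(h, H);
        for (int i = 0; i < n; ++i) {
            if (labels[i] == 0) continue;
            out[i] += std::pow(cluster_size[labels[i]], E) * hH * dh;
        }
    }
    return out;
}
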