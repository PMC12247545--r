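#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Neighbourhood offsets for 6 (face), 18 (face+edge) or 26 (full cube)
// connectivity on a 3D lattice.
static std::vector<std::array<int, 3> > neighbour_offsets(int connectivity) {
    std::vector<std::array<int, 3> > off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

// Label connected components of a binary foreground on a 3D grid.
// Returns labels 1..k (0 = background). Used by the TFCE integrator and
// exposed for cluster summaries.
// [[Rcpp::export(name = ".labelComponentsCpp")]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (fg.size() != n) stop("foreground length does not match grid dims");
    std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);
    IntegerVector lab(n, 0);
    std::vector<int> stack;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!fg[s] || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back((int)s);
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
            for (size_t k = 0; k < off.size(); ++k) {
                int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                int w = xx + nx * (yy + ny * zz);
                if (fg[w] && lab[w] == 0) {
                    lab[w] = next;
                    stack.push_back(w);
                }
            }
        }
    }
    return lab;
}

// Threshold-free cluster enhancement of the positive part of a statistic
// volume: TFCE(v) = sum over thresholds h = dh, 2dh, ... <= stat(v) of
// e(h, v)^E * h^H * dh, where e(h, v) is the voxel count of the connected
// supra-threshold component containing v at height h. Voxels outside the
// mask, or with stat <= 0, get 0.
// [[Rcpp::export(name = ".tfceCpp")]]
NumericVector tfce_cpp(NumericVector stat, LogicalVector mask,
                       IntegerVector dims, double E, double H, double dh,
                       int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (stat.size() != n || mask.size() != n)
        stop("stat/mask length does not match grid dims");
    if (dh <= 0) stop("dh must be positive");
    std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);

    NumericVector out(n, 0.0);
    double hmax = 0.0;
    for (R_xlen_t i = 0; i < n; ++i)
        if (mask[i] && stat[i] > hmax) hmax = stat[i];
    if (hmax <= 0.0) return out;

    std::vector<char> fg(n);
    std::vector<int> lab(n);
    std::vector<int> stack;
    std::vector<double> csize;

    int nsteps = (int)std::floor(hmax / dh + 1e-12);
    for (int s = 1; s <= nsteps; ++s) {
        double h = s * dh;
        for (R_xlen_t i = 0; i < n; ++i)
            fg[i] = (mask[i] && stat[i] >= h) ? 1 : 0;
        std::fill(lab.begin(), lab.end(), 0);
        csize.clear();
        csize.push_back(0.0); // background
        int next = 0;
        for (R_xlen_t v0 = 0; v0 < n; ++v0) {
            if (!fg[v0] || lab[v0] != 0) continue;
            ++next;
            csize.push_back(0.0);
            lab[v0] = next;
            stack.clear();
            stack.push_back((int)v0);
            double cnt = 0.0;
            while (!stack.empty()) {
                int v = stack.back();
                stack.pop_back();
                cnt += 1.0;
                int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
                for (size_t k = 0; k < off.size(); ++k) {
                    int xx = x + off[k][0], yy = y + off[k][1],
                        zz = z + off[k][2];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                        zz >= nz)
                        continue;
                    int w = xx + nx * (yy + ny * zz);
                    if (fg[w] && lab[w] == 0) {
                        lab[w] = next;
                        stack.push_back(w);
                    }
                }
            }
            csize[next] = cnt;
        }
        double hH = std::pow(h, H);
        // size^E once per component, not per voxel
        std::vector<double> sizePow(csize.size());
        for (size_t k = 1; k < csize.size(); ++k)
            sizePow[k] = std::pow(csize[k], E) * hH * dh;
        for (R_xlen_t i = 0; i < n; ++i)
            if (fg[i]) out[i] += sizePow[lab[i]];
    }
    return out;
}
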