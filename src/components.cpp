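#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Neighborhood offsets for a given 3D connectivity.
//   6: face neighbors; 18: face + edge; 26: face + edge + corner.
static std::vector<std::array<int,3>> neighbor_offsets(int connectivity) {
    std::vector<std::array<int,3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
                int m = std::abs(dr) + std::abs(dc) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                off.push_back({dr, dc, dz});
            }
    return off;
}

// Label 3D connected components of a logical mask (dim = rows, cols, slices).
// Returns an integer array: 0 background, 1..k component ids in first-voxel
// (column-major) discovery order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    const int nr = dims[0], nc = dims[1], ns = dims[2];
    const R_xlen_t n = (R_xlen_t)nr * nc * ns;
    if (mask.size() != n) stop("mask length does not match dims");
    IntegerVector labels(n, 0);
    std::vector<std::array<int,3>> off = neighbor_offsets(connectivity);
    int next = 0;
    std::queue<R_xlen_t> q;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        labels[i] = ++next;
        q.push(i);
        while (!q.empty()) {
            R_xlen_t v = q.front(); q.pop();
            int r = (int)(v % nr);
            int c = (int)((v / nr) % nc);
            int z = (int)(v / ((R_xlen_t)nr * nc));
            for (size_t k = 0; k < off.size(); ++k) {
                int rr = r + off[k][0], cc = c + off[k][1], zz = z + off[k][2];
                if (rr < 0 || rr >= nr || cc < 0 || cc >= nc ||
                    zz < 0 || zz >= ns) continue;
                R_xlen_t w = (R_xlen_t)zz * nr * nc + (R_xlen_t)cc * nr + rr;
                if (mask[w] && labels[w] == 0) {
                    labels[w] = next;
                    q.push(w);
                }
            }
        }
    }
    labels.attr("dim") = dims;
    labels.attr("n_components") = next;
    return labels;
}

// Fill internal holes of a binary mask independently on each axial slice:
// background 4-connected flood fill from the slice border; unreached
// background becomes foreground.
// [[Rcpp::export(name = ".fill_holes_slicewise_cpp")]]
LogicalVector fill_holes_slicewise_cpp(LogicalVector mask, IntegerVector dims) {
    const int nr = dims[0], nc = dims[1], ns = dims[2];
    const R_xlen_t npl = (R_xlen_t)nr * nc;
    if (mask.size() != npl * ns) stop("mask length does not match dims");
    LogicalVector out = clone(mask);
    std::vector<char> reach(npl);
    std::queue<int> q;
    const int dr4[4] = {1, -1, 0, 0};
    const int dc4[4] = {0, 0, 1, -1};
    for (int z = 0; z < ns; ++z) {
        const R_xlen_t base = (R_xlen_t)z * npl;
        std::memset(reach.data(), 0, npl);
        for (int c = 0; c < nc; ++c)
            for (int r = 0; r < nr; ++r) {
                if (r != 0 && r != nr - 1 && c != 0 && c != nc - 1) continue;
                int i = c * nr + r;
                if (!mask[base + i] && !reach[i]) { reach[i] = 1; q.push(i); }
            }
        while (!q.empty()) {
            int v = q.front(); q.pop();
            int r = v % nr, c = v / nr;
            for (int k = 0; k < 4; ++k) {
                int rr = r + dr4[k], cc = c + dc4[k];
                if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
                int w = cc * nr + rr;
                if (!mask[base + w] && !reach[w]) { reach[w] = 1; q.push(w); }
            }
        }
        for (R_xlen_t i = 0; i < npl; ++i)
            if (!mask[base + i] && !reach[i]) out[base + i] = true;
    }
    out.attr("dim") = dims;
    return out;
}

// Chebyshev (26-connectivity ball) binary dilation by integer radius.
// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dims, int radius) {
    const int nr = dims[0], nc = dims[1], ns = dims[2];
    const R_xlen_t n = (R_xlen_t)nr * nc * ns;
    if (radius <= 0) return clone(mask);
    LogicalVector out(n, false);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int r = (int)(i % nr);
        int c = (int)((i / nr) % nc);
        int z = (int)(i / ((R_xlen_t)nr * nc));
        for (int dz = -radius; dz <= radius; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= ns) continue;
            for (int dc = -radius; dc <= radius; ++dc) {
                int cc = c + dc;
                if (cc < 0 || cc >= nc) continue;
                R_xlen_t col = (R_xlen_t)zz * nr * nc + (R_xlen_t)cc * nr;
                int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
                for (int rr = r0; rr <= r1; ++rr) out[col + rr] = true;
            }
        }
    }
    out.attr("dim") = dims;
    return out;
}

// Chebyshev binary erosion by integer radius (voxels outside the volume count
// as background, so the mask also erodes at the volume boundary).
// [[Rcpp::export(name = ".erode_cpp")]]
LogicalVector erode_cpp(LogicalVector mask, IntegerVector dims, int radius) {
    const int nr = dims[0], nc = dims[1], ns = dims[2];
    const R_xlen_t n = (R_xlen_t)nr * nc * ns;
    if (radius <= 0) return clone(mask);
    LogicalVector out(n, false);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int r = (int)(i % nr);
        int c = (int)((i / nr) % nc);
        int z = (int)(i / ((R_xlen_t)nr * nc));
        bool keep = true;
        for (int dz = -radius; keep && dz <= radius; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= ns) { keep = false; break; }
            for (int dc = -radius; keep && dc <= radius; ++dc) {
                int cc = c + dc;
                if (cc < 0 || cc >= nc) { keep = false; break; }
                R_xlen_t col = (R_xlen_t)zz * nr * nc + (R_xlen_t)cc * nr;
                for (int rr = r - radius; rr <= r + radius; ++rr) {
                    if (rr < 0 || rr >= nr || !mask[col + rr]) { keep = false; break; }
                }
            }
        }
        if (keep) out[i] = true;
    }
    out.attr("dim") = dims;
    return out;
}
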