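#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Truncated (4 sigma) discrete Gaussian, normalized to sum 1.
static std::vector<double> gauss_kernel(double sigma) {
    if (sigma <= 0.0) return std::vector<double>(1, 1.0);
    int r = (int)std::ceil(4.0 * sigma);
    std::vector<double> k(2 * r + 1);
    double s = 0.0;
    for (int i = -r; i <= r; ++i) {
        k[i + r] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
        s += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
    return k;
}

// Convolve a 3-D volume along one axis, zero value assumed outside the grid.
static void conv_axis(const double *src, double *dst, int nx, int ny, int nz,
                      int axis, const std::vector<double> &k) {
    int r = ((int)k.size() - 1) / 2;
    int n[3] = {nx, ny, nz};
    long stride[3] = {1, (long)nx, (long)nx * ny};
    long sa = stride[axis];
    int na = n[axis];
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) {
                long idx = x + (long)nx * y + (long)nx * ny * z;
                int pos = (axis == 0) ? x : (axis == 1 ? y : z);
                double acc = 0.0;
                int lo = std::max(-r, -pos), hi = std::min(r, na - 1 - pos);
                for (int d = lo; d <= hi; ++d)
                    acc += k[d + r] * src[idx + (long)d * sa];
                dst[idx] = acc;
            }
        }
    }
}

// [[Rcpp::export(name = ".cpp_smooth_gaussian")]]
NumericVector cpp_smooth_gaussian(NumericVector data, IntegerVector dim3,
                                  NumericVector sigma_vox) {
    int nx = dim3[0], ny = dim3[1], nz = dim3[2];
    long nvox = (long)nx * ny * nz;
    if (nvox <= 0) stop("empty grid");
    if (data.size() % nvox != 0) stop("data length is not a multiple of the grid size");
    int nt = (int)(data.size() / nvox);
    std::vector<double> kx = gauss_kernel(sigma_vox[0]);
    std::vector<double> ky = gauss_kernel(sigma_vox[1]);
    std::vector<double> kz = gauss_kernel(sigma_vox[2]);
    NumericVector out(data.size());
    std::vector<double> buf_a(nvox), buf_b(nvox);
    for (int t = 0; t < nt; ++t) {
        const double *frame = REAL(data) + (long)t * nvox;
        std::copy(frame, frame + nvox, buf_a.begin());
        conv_axis(buf_a.data(), buf_b.data(), nx, ny, nz, 0, kx);
        conv_axis(buf_b.data(), buf_a.data(), nx, ny, nz, 1, ky);
        conv_axis(buf_a.data(), buf_b.data(), nx, ny, nz, 2, kz);
        std::copy(buf_b.begin(), buf_b.end(), REAL(out) + (long)t * nvox);
    }
    out.attr("dim") = data.attr("dim");
    return out;
}

// Connected components of a 3-D binary map. Labels are assigned in order of
// each component's first voxel in column-major (x fastest) scan order, so the
// labeling is deterministic.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim3,
                                   int connectivity) {
    int nx = dim3[0], ny = dim3[1], nz = dim3[2];
    long nvox = (long)nx * ny * nz;
    if ((long)mask.size() != nvox) stop("mask length does not match grid");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    std::vector<int> ndx, ndy, ndz;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                ndx.push_back(dx); ndy.push_back(dy); ndz.push_back(dz);
            }

    IntegerVector labels(mask.size(), 0);
    std::vector<long> queue;
    int next_label = 0;
    for (long i = 0; i < nvox; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        queue.clear();
        queue.push_back(i);
        while (!queue.empty()) {
            long cur = queue.back();
            queue.pop_back();
            int x = (int)(cur % nx);
            int y = (int)((cur / nx) % ny);
            int z = (int)(cur / ((long)nx * ny));
            for (size_t j = 0; j < ndx.size(); ++j) {
                int xx = x + ndx[j], yy = y + ndy[j], zz = z + ndz[j];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                long nb = xx + (long)nx * yy + (long)nx * ny * zz;
                if (mask[nb] && labels[nb] == 0) {
                    labels[nb] = next_label;
                    queue.push_back(nb);
                }
            }
        }
    }
    labels.attr("dim") = dim3;
    return labels;
}
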