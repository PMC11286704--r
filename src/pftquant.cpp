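#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel index helpers for column-major (slice, row, col) arrays.
static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

//' 26-connected component labelling of a 3D logical array.
//'
//' Labels are assigned in raster (column-major) order of each component's
//' first voxel, so labelling is deterministic for a given mask.
//'
//' @param mask logical vector (3D array contents, column-major)
//' @param dims integer vector (nz, ny, nx)
//' @return integer vector of labels, 0 = background
//' @keywords internal
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int z = i % nz;
      int rest = i / nz;
      int y = rest % ny;
      int x = rest / ny;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("n_clusters") = next;
  return lab;
}

//' Exposed 6-neighbour face count per label.
//'
//' A face is exposed when the 6-neighbour across it carries a different
//' label (or lies outside the array). A single voxel scores 6.
//'
//' @keywords internal
// [[Rcpp::export(name = ".cc_exposed_faces")]]
IntegerVector cc_exposed_faces(IntegerVector lab, IntegerVector dims, int K) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector faces(K, 0);
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int l = lab[idx3(z, y, x, nz, ny)];
        if (!l) continue;
        for (int k = 0; k < 6; ++k) {
          int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
          int nb = 0;
          if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
            nb = lab[idx3(zz, yy, xx, nz, ny)];
          if (nb != l) ++faces[l - 1];
        }
      }
  return faces;
}

// Discrete two-phase piecewise-constant (Chan-Vese) energy:
//   E = mu * perimeter + l1 * sum_in (u - c1)^2 + l2 * sum_out (u - c2)^2
// with perimeter counted as 4-neighbour label-discordant pixel edges.
static double cv_energy(const NumericMatrix &img, const std::vector<char> &in,
                        double mu, double l1, double l2, double c1, double c2) {
  const int nr = img.nrow(), nc = img.ncol();
  double e = 0.0;
  long per = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int k = i + nr * j;
      double u = img(i, j);
      e += in[k] ? l1 * (u - c1) * (u - c1) : l2 * (u - c2) * (u - c2);
      if (i + 1 < nr && in[k] != in[k + 1]) ++per;
      if (j + 1 < nc && in[k] != in[k + nr]) ++per;
    }
  return e + mu * (double)per;
}

//' Two-phase piecewise-constant active contour by monotone label sweeps.
//'
//' Each outer iteration (i) re-estimates the region means c1/c2 and (ii)
//' performs one Gauss-Seidel raster sweep flipping any pixel whose flip
//' strictly lowers the energy at the current means. Both steps lower the
//' energy, so the per-iteration energy trace is non-increasing. Stops when
//' a sweep flips nothing or the relative energy decrease falls below tol.
//'
//' @keywords internal
// [[Rcpp::export(name = ".cv_evolve")]]
List cv_evolve(NumericMatrix img, LogicalMatrix init, double mu, double l1,
               double l2, int max_iter, double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  std::vector<char> in(n);
  long n_in = 0;
  for (int k = 0; k < n; ++k) {
    in[k] = init[k] ? 1 : 0;
    if (in[k]) ++n_in;
  }
  std::vector<double> energy;
  energy.reserve(max_iter);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    if (n_in == 0 || n_in == n) break;
    double s1 = 0, s2 = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (in[i + nr * j]) s1 += img(i, j); else s2 += img(i, j);
      }
    double c1 = s1 / (double)n_in;
    double c2 = s2 / (double)(n - n_in);
    long flips = 0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int k = i + nr * j;
        double u = img(i, j);
        // data-term change if this pixel switches phase
        double d_data = in[k]
          ? l2 * (u - c2) * (u - c2) - l1 * (u - c1) * (u - c1)
          : l1 * (u - c1) * (u - c1) - l2 * (u - c2) * (u - c2);
        // perimeter change: edges to same-phase neighbours become boundary,
        // edges to opposite-phase neighbours stop being boundary
        int same = 0, diff = 0;
        if (i > 0)      { if (in[k - 1]  == in[k]) ++same; else ++diff; }
        if (i + 1 < nr) { if (in[k + 1]  == in[k]) ++same; else ++diff; }
        if (j > 0)      { if (in[k - nr] == in[k]) ++same; else ++diff; }
        if (j + 1 < nc) { if (in[k + nr] == in[k]) ++same; else ++diff; }
        double d_e = d_data + mu * (double)(same - diff);
        if (d_e < 0) {
          in[k] = !in[k];
          n_in += in[k] ? 1 : -1;
          ++flips;
          if (n_in == 0 || n_in == n) break;
        }
      }
    // energy is evaluated at the optimal means of the current labelling,
    // which never raises it relative to the sweep's working means
    double e;
    if (n_in > 0 && n_in < n) {
      double t1 = 0, t2 = 0;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (in[i + nr * j]) t1 += img(i, j); else t2 += img(i, j);
        }
      e = cv_energy(img, in, mu, l1, l2, t1 / (double)n_in,
                    t2 / (double)(n - n_in));
    } else {
      double tall = 0;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) tall += img(i, j);
      double c = tall / (double)n;
      e = cv_energy(img, in, mu, l1, l2, c, c);
    }
    energy.push_back(e);
    bool settled = (flips == 0);
    size_t m = energy.size();
    if (m >= 2) {
      double prev = energy[m - 2];
      double rel = std::fabs(prev - e) / std::max(std::fabs(prev), 1.0);
      if (rel < tol) settled = true;
    }
    if (settled) { ++iter; break; }
  }
  LogicalMatrix out(nr, nc);
  for (int k = 0; k < n; ++k) out[k] = in[k] != 0;
  return List::create(_["mask"] = out,
                      _["energy"] = NumericVector(energy.begin(), energy.end()),
                      _["iterations"] = iter);
}
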