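#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Receive-only delay-and-sum. Distances in mm, sound speed in mm/us,
// sampling frequency in MHz, so r / c * fs is a (0-based) fractional
// sample index directly. Fractional delays use linear interpolation;
// the aperture grows with depth at a fixed F-number and is weighted by
// a Hann window (apodization == 1) or left uniform (== 0). Pixels sum
// only elements inside the aperture and divide by the weight sum so
// image amplitude tracks the channel amplitude, not the element count.
// [[Rcpp::export]]
NumericMatrix das_core(const NumericMatrix& channel,
                       const NumericVector& elem_x,
                       const NumericVector& pix_x,
                       const NumericVector& pix_z,
                       double sound_speed_mm_us,
                       double fs_mhz,
                       double f_number,
                       int apodization) {
  const int ns = channel.nrow(), ne = channel.ncol();
  const int nz = pix_z.size(), nx = pix_x.size();
  NumericMatrix out(nz, nx);
  for (int ix = 0; ix < nx; ++ix) {
    const double x = pix_x[ix];
    for (int iz = 0; iz < nz; ++iz) {
      const double z = pix_z[iz];
      const bool finite_ap = f_number > 0.0;
      const double half_ap = finite_ap ? z / (2.0 * f_number) : 0.0;
      double acc = 0.0, wsum = 0.0;
      for (int ie = 0; ie < ne; ++ie) {
        const double dx = elem_x[ie] - x;
        double w = 1.0;
        if (finite_ap) {
          if (std::fabs(dx) > half_ap) continue;
          if (apodization == 1)
            w = 0.5 * (1.0 + std::cos(M_PI * dx / half_ap));
        }
        const double r = std::sqrt(dx * dx + z * z);
        const double s = r / sound_speed_mm_us * fs_mhz;
        const int s0 = static_cast<int>(std::floor(s));
        if (s0 < 0 || s0 + 1 >= ns) continue;
        const double frac = s - s0;
        acc += w * ((1.0 - frac) * channel(s0, ie) + frac * channel(s0 + 1, ie));
        wsum += w;
      }
      out(iz, ix) = (wsum > 0.0) ? acc / wsum : 0.0;
    }
  }
  return out;
}

// Connected-component labeling of a binary mask with selectable 4- or
// 8-connectivity (stack-based flood fill). Labels are assigned in
// raster order starting from 1.
// [[Rcpp::export]]
IntegerMatrix label_core(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          const int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}
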