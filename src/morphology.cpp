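#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel grids are R arrays with dim = c(nrow, ncol, nslice); the first index
// varies fastest, so voxel (r, c, s) lives at r + nr * (c + nc * s), 0-based.

static inline int idx3(int r, int c, int s, int nr, int nc) {
  return r + nr * (c + (long long)nc * s);
}

// Label connected foreground components by flood fill. With three_d = FALSE
// slices are labelled independently with 8-connectivity in-plane (labels
// are unique across slices); with three_d = TRUE a single pass with
// 26-connectivity is used.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, bool three_d) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);

  const int zlo = three_d ? -1 : 0;
  const int zhi = three_d ? 1 : 0;

  for (int s = 0; s < ns; ++s) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int i0 = idx3(r, c, s, nr, nc);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          const int i = stack.back();
          stack.pop_back();
          const int rs = i % nr;
          const int cs = (i / nr) % nc;
          const int ss = i / (nr * nc);
          for (int dz = zlo; dz <= zhi; ++dz) {
            const int z2 = ss + dz;
            if (z2 < 0 || z2 >= ns) continue;
            for (int dc = -1; dc <= 1; ++dc) {
              const int c2 = cs + dc;
              if (c2 < 0 || c2 >= nc) continue;
              for (int dr = -1; dr <= 1; ++dr) {
                const int r2 = rs + dr;
                if (r2 < 0 || r2 >= nr) continue;
                if (dr == 0 && dc == 0 && dz == 0) continue;
                const int j = idx3(r2, c2, z2, nr, nc);
                if (mask[j] && !lab[j]) {
                  lab[j] = next;
                  stack.push_back(j);
                }
              }
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// Disc offsets for an in-plane structuring element of radius `radius`.
static std::vector<std::pair<int, int> > disc_offsets(double radius) {
  std::vector<std::pair<int, int> > off;
  const int ri = (int)std::floor(radius);
  for (int dr = -ri; dr <= ri; ++dr)
    for (int dc = -ri; dc <= ri; ++dc)
      if ((double)dr * dr + (double)dc * dc <= radius * radius + 1e-9)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

static LogicalVector morph(const LogicalVector& mask, const IntegerVector& dims,
                           double radius, bool dilate) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  LogicalVector out(mask.size());
  std::vector<std::pair<int, int> > off = disc_offsets(radius);
  for (int s = 0; s < ns; ++s) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        bool hit = dilate ? false : true;
        for (size_t k = 0; k < off.size(); ++k) {
          const int r2 = r + off[k].first, c2 = c + off[k].second;
          bool v;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc)
            v = false;  // outside the grid counts as background
          else
            v = mask[idx3(r2, c2, s, nr, nc)];
          if (dilate && v)  { hit = true;  break; }
          if (!dilate && !v){ hit = false; break; }
        }
        out[idx3(r, c, s, nr, nc)] = hit;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Per-slice binary closing (dilation then erosion) with a disc of the
// given radius in voxels. radius <= 0 returns the input unchanged.
// [[Rcpp::export(name = ".cc_close")]]
LogicalVector cc_close(LogicalVector mask, IntegerVector dims, double radius) {
  if (radius <= 0) {
    LogicalVector out = clone(mask);
    out.attr("dim") = dims;
    return out;
  }
  LogicalVector d = morph(mask, dims, radius, true);
  return morph(d, dims, radius, false);
}
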