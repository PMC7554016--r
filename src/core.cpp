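#include <Rcpp.h>
using namespace Rcpp;

// 2-D convolution with an odd-sized kernel, out(r,c) = sum_{u,v} x(r-u,c-v) k(u,v).
// boundary: 0 = zero padding, 1 = periodic wrap (used for seamless textures).
// Accumulates one shifted copy of x per kernel tap; column-major contiguous.
// [[Rcpp::export(name = ".cpp_conv2")]]
NumericMatrix cpp_conv2(const NumericMatrix& x, const NumericMatrix& k,
                        const int boundary = 0) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = k.nrow(), kc = k.ncol();
  const int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int v = -hc; v <= hc; ++v) {
    for (int u = -hr; u <= hr; ++u) {
      const double kv = k(u + hr, v + hc);
      if (kv == 0.0) continue;
      if (boundary == 1) {
        for (int c = 0; c < nc; ++c) {
          int cc = (c - v) % nc; if (cc < 0) cc += nc;
          double* oc = op + (size_t)c * nr;
          const double* xc = xp + (size_t)cc * nr;
          for (int r = 0; r < nr; ++r) {
            int rr = (r - u) % nr; if (rr < 0) rr += nr;
            oc[r] += kv * xc[rr];
          }
        }
      } else {
        const int c0 = std::max(0, v), c1 = std::min(nc, nc + v);
        const int r0 = std::max(0, u), r1 = std::min(nr, nr + u);
        for (int c = c0; c < c1; ++c) {
          double* oc = op + (size_t)c * nr + r0;
          const double* xc = xp + (size_t)(c - v) * nr + (r0 - u);
          const int n = r1 - r0;
          for (int r = 0; r < n; ++r) oc[r] += kv * xc[r];
        }
      }
    }
  }
  return out;
}

// Direction-selective correlator ensemble: for each sampling distance
// distances[j], the delayed map Mhat[[j]] at the reference cell is multiplied
// with the instantaneous map M at the displaced partner cell.  Partners
// falling outside the field contribute nothing.  Rows index y (top = row 1,
// "down" = increasing row), columns index x ("right" = increasing column).
// [[Rcpp::export(name = ".cpp_ds_maps")]]
List cpp_ds_maps(const NumericMatrix& M, const List& Mhat,
                 const IntegerVector& distances) {
  const int nr = M.nrow(), nc = M.ncol();
  NumericMatrix right(nr, nc), left(nr, nc), down(nr, nc), up(nr, nc);
  const double* mp = M.begin();
  double* rp = right.begin(); double* lp = left.begin();
  double* dp = down.begin();  double* up_ = up.begin();
  for (int j = 0; j < distances.size(); ++j) {
    const int d = distances[j];
    const NumericMatrix Mh = Mhat[j];
    const double* hp = Mh.begin();
    for (int c = 0; c + d < nc; ++c) {
      const size_t o = (size_t)c * nr, od = (size_t)(c + d) * nr;
      for (int r = 0; r < nr; ++r) {
        rp[o + r] += hp[o + r] * mp[od + r];
        lp[o + r] += hp[od + r] * mp[o + r];
      }
    }
    for (int c = 0; c < nc; ++c) {
      const size_t o = (size_t)c * nr;
      for (int r = 0; r + d < nr; ++r) {
        dp[o + r] += hp[o + r] * mp[o + r + d];
        up_[o + r] += hp[o + r + d] * mp[o + r];
      }
    }
  }
  return List::create(_["r"] = right, _["l"] = left,
                      _["d"] = down, _["u"] = up);
}
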