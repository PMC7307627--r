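#include <Rcpp.h>
using namespace Rcpp;

// Grayscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask elementwise), 8-connected. Used by the H-maxima
// transform. Forward/backward raster sweeps until stable.
//
// [[Rcpp::export(name = ".grayrec_dilate")]]
NumericMatrix grayrec_dilate(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  bool changed = true;
  int guard = 0;
  while (changed && ++guard < 10000) {
    changed = false;
    // forward sweep
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double m = J(i, j);
        if (i > 0)            m = std::max(m, J(i - 1, j));
        if (j > 0)            m = std::max(m, J(i, j - 1));
        if (i > 0 && j > 0)   m = std::max(m, J(i - 1, j - 1));
        if (i < nr - 1 && j > 0) m = std::max(m, J(i + 1, j - 1));
        m = std::min(m, mask(i, j));
        if (m > J(i, j)) { J(i, j) = m; changed = true; }
      }
    // backward sweep
    for (int j = nc - 1; j >= 0; --j)
      for (int i = nr - 1; i >= 0; --i) {
        double m = J(i, j);
        if (i < nr - 1)             m = std::max(m, J(i + 1, j));
        if (j < nc - 1)             m = std::max(m, J(i, j + 1));
        if (i < nr - 1 && j < nc - 1) m = std::max(m, J(i + 1, j + 1));
        if (i > 0 && j < nc - 1)    m = std::max(m, J(i - 1, j + 1));
        m = std::min(m, mask(i, j));
        if (m > J(i, j)) { J(i, j) = m; changed = true; }
      }
  }
  return J;
}
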