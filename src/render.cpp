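#include <Rcpp.h>
using namespace Rcpp;

// Render a scene cube in one pass:
//   out[y, x, b] = E(label(y, x), b) * illum(x) * gain + dark(y, b) + N(0, sd)
// Noise is drawn from the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector render_cube_native(IntegerMatrix labels, NumericMatrix E,
                                 NumericVector illum, NumericMatrix dark,
                                 double noise_sd, double gain, bool has_dark) {
  const int h = labels.nrow(), w = labels.ncol(), nb = E.ncol();
  NumericVector out(static_cast<R_xlen_t>(h) * w * nb);
  RNGScope scope;
  R_xlen_t idx = 0;
  for (int b = 0; b < nb; ++b) {
    for (int x = 0; x < w; ++x) {
      const double il = illum[x] * gain;
      for (int y = 0; y < h; ++y, ++idx) {
        double v = E(labels(y, x) - 1, b) * il;
        if (has_dark) v += dark(y, b);
        if (noise_sd > 0) v += norm_rand() * noise_sd;
        out[idx] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, nb);
  return out;
}
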