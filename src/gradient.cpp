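#include <Rcpp.h>
using namespace Rcpp;

// Means-of-gradients pupil-center objective.
//
// For each candidate center c, computes
//   w(c) * mean_i max(0, d_i . g_i)^2
// over the supplied strong-gradient pixels, where d_i is the unit
// displacement from c to pixel i and g_i the unit image gradient there.
// Positive dot products only: for a dark pupil on a bright iris the
// intensity gradient points radially away from the center.
//
// cx, cy      candidate centers (pixel coordinates)
// px, py      strong-gradient pixel coordinates
// gx, gy      unit gradient components at those pixels
// wc          per-candidate darkness weight (inverted smoothed intensity)
// [[Rcpp::export(name = ".grad_objective")]]
NumericVector grad_objective(NumericVector cx, NumericVector cy,
                             NumericVector px, NumericVector py,
                             NumericVector gx, NumericVector gy,
                             NumericVector wc) {
  int nc = cx.size(), np = px.size();
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c) {
    double acc = 0.0;
    double x0 = cx[c], y0 = cy[c];
    for (int i = 0; i < np; ++i) {
      double dx = px[i] - x0, dy = py[i] - y0;
      double nrm = std::sqrt(dx * dx + dy * dy);
      if (nrm < 1e-9) continue;
      double dot = (dx * gx[i] + dy * gy[i]) / nrm;
      if (dot > 0) acc += dot * dot;
    }
    out[c] = np > 0 ? wc[c] * acc / np : 0.0;
  }
  return out;
}
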