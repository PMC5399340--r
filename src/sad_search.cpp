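#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive SAD search of a template over a grid of integer displacements.
//
// frame : target frame (rows x cols)
// tmpl  : template pixels
// ty,tx : 0-based top-left of the template's source position in frame coords
// dys,dxs : candidate displacements (0-based offsets added to ty/tx)
//
// Returns a length(dys) x length(dxs) matrix of mean absolute differences;
// candidates whose footprint leaves the frame get NA.
// [[Rcpp::export]]
NumericMatrix sad_search_cpp(NumericMatrix frame, NumericMatrix tmpl,
                             int ty, int tx,
                             IntegerVector dys, IntegerVector dxs) {
  const int fh = frame.nrow(), fw = frame.ncol();
  const int th = tmpl.nrow(), tw = tmpl.ncol();
  const int ny = dys.size(), nx = dxs.size();
  NumericMatrix out(ny, nx);
  const double inv = 1.0 / (double)(th * tw);
  for (int j = 0; j < nx; ++j) {
    const int cx = tx + dxs[j];
    for (int i = 0; i < ny; ++i) {
      const int cy = ty + dys[i];
      if (cy < 0 || cx < 0 || cy + th > fh || cx + tw > fw) {
        out(i, j) = NA_REAL;
        continue;
      }
      double acc = 0.0;
      for (int c = 0; c < tw; ++c) {
        const double *fp = &frame(cy, cx + c);
        const double *tp = &tmpl(0, c);
        for (int r = 0; r < th; ++r) {
          const double d = fp[r] - tp[r];
          acc += d < 0 ? -d : d;
        }
      }
      out(i, j) = acc * inv;
    }
  }
  return out;
}
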