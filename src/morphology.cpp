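#include <Rcpp.h>
#include <deque>
#include <vector>

// Grayscale erosion/dilation with a (2r+1) x (2r+1) square structuring
// element, separable van Herk / monotonic-wedge running min/max: O(n) per
// pass independent of the radius. Borders replicate the edge values.
static void runningExtreme(const double* in, double* out, int n, int r,
                           bool maximum) {
  std::deque<int> q;
  for (int i = 0; i < n + r; ++i) {
    if (i < n) {
      while (!q.empty() &&
             (maximum ? in[q.back()] <= in[i] : in[q.back()] >= in[i]))
        q.pop_back();
      q.push_back(i);
    }
    int center = i - r;
    if (center >= 0) {
      while (q.front() < center - r) q.pop_front();
      out[center] = in[q.front()];
    }
  }
}

static Rcpp::NumericMatrix boxFilter(Rcpp::NumericMatrix x, int r,
                                     bool maximum) {
  const int nr = x.nrow(), nc = x.ncol();
  Rcpp::NumericMatrix tmp(nr, nc), out(nr, nc);
  std::vector<double> buf(std::max(nr, nc)), res(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {           // columns: along rows
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    runningExtreme(buf.data(), res.data(), nr, r, maximum);
    for (int i = 0; i < nr; ++i) tmp(i, j) = res[i];
  }
  for (int i = 0; i < nr; ++i) {           // rows: along columns
    for (int j = 0; j < nc; ++j) buf[j] = tmp(i, j);
    runningExtreme(buf.data(), res.data(), nc, r, maximum);
    for (int j = 0; j < nc; ++j) out(i, j) = res[j];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix box_open(Rcpp::NumericMatrix x, int radius) {
  if (radius < 1) Rcpp::stop("radius must be >= 1");
  return boxFilter(boxFilter(x, radius, false), radius, true);
}
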