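#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Window median and maximum absolute centre-neighbour difference for the
// fuzzy switching median filter. Border handled by edge replication.
// Returns a list with 'median' and 'maxdiff' matrices.
// [[Rcpp::export]]
List cpp_window_stats(NumericMatrix img, int window) {
  int h = img.nrow(), w = img.ncol();
  int half = window / 2;
  NumericMatrix med(h, w), mdiff(h, w);
  std::vector<double> buf(window * window);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double centre = img(i, j);
      double dmax = 0.0;
      int n = 0;
      for (int dj = -half; dj <= half; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
        for (int di = -half; di <= half; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
          double v = img(ii, jj);
          buf[n++] = v;
          if (di != 0 || dj != 0) {
            double d = std::fabs(centre - v);
            if (d > dmax) dmax = d;
          }
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      double m = buf[n / 2];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
        m = (m + lo) / 2.0;
      }
      med(i, j) = m;
      mdiff(i, j) = dmax;
    }
  }
  return List::create(_["median"] = med, _["maxdiff"] = mdiff);
}

// Circular Hough accumulator for one radius: each edge pixel votes for all
// candidate centres lying on the circle of radius r around it.
// Edge coordinates are 1-based (R row/col indices).
// [[Rcpp::export]]
NumericMatrix cpp_hough_vote(IntegerVector rows, IntegerVector cols,
                             int h, int w, double r) {
  NumericMatrix acc(h, w);
  int nsteps = std::max(16, (int)std::ceil(2.0 * M_PI * r));
  std::vector<int> dr(nsteps), dc(nsteps);
  for (int k = 0; k < nsteps; ++k) {
    double a = 2.0 * M_PI * k / nsteps;
    dr[k] = (int)std::lround(r * std::sin(a));
    dc[k] = (int)std::lround(r * std::cos(a));
  }
  int n = rows.size();
  for (int e = 0; e < n; ++e) {
    int ri = rows[e] - 1, ci = cols[e] - 1;
    int pr = INT_MIN, pc = INT_MIN;
    for (int k = 0; k < nsteps; ++k) {
      int rr = ri + dr[k], cc = ci + dc[k];
      if (rr == pr && cc == pc) continue;  // skip duplicate rounded point
      pr = rr; pc = cc;
      if (rr >= 0 && rr < h && cc >= 0 && cc < w) acc(rr, cc) += 1.0;
    }
  }
  return acc;
}

// 8-connected component labelling of a logical mask by iterative flood fill.
// Labels are 1..n in scan order of the first pixel encountered.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * h);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % h, pj = p / h;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * h);
            }
          }
        }
      }
    }
  }
  return lab;
}
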