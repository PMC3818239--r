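#include <Rcpp.h>
using namespace Rcpp;

// Disc-shaped neighbourhood offsets (dx*dx + dy*dy <= r*r), matching the
// circular kernels of ImageJ-style rank/mean filters.
static std::vector<std::pair<int, int> > disc_offsets(int radius) {
  std::vector<std::pair<int, int> > off;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dx * dx + dy * dy <= radius * radius)
        off.push_back(std::make_pair(dy, dx));
  return off;
}

// [[Rcpp::export(name = ".disc_median_cpp")]]
NumericMatrix disc_median_cpp(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int, int> > off = disc_offsets(radius);
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(off.size());
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
          buf.push_back(img(ii, jj));  // neighbourhood clipped at borders
      }
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// reflect index into [0, n): symmetric padding a b c | c b a
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".disc_mean_cpp")]]
NumericMatrix disc_mean_cpp(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int, int> > off = disc_offsets(radius);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (size_t k = 0; k < off.size(); ++k) {
        int ii = reflect(i + off[k].first, nr);
        int jj = reflect(j + off[k].second, nc);
        s += img(ii, jj);
      }
      out(i, j) = s / off.size();
    }
  }
  return out;
}
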