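#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Helpers for column-major n-D arrays (2D or 3D), dims in R order.

// Sliding min/max along one axis. Window at index i covers
// [i - left, i - left + k - 1]; out-of-range samples are ignored
// (equivalent to padding with -Inf for max / +Inf for min).
static void slide_axis(std::vector<double>& a, const IntegerVector& dim,
                       int axis, int k, int left, bool ismax) {
  int nd = dim.size();
  long long N = 1;
  for (int d = 0; d < nd; ++d) N *= dim[d];
  long long s = 1;
  for (int d = 0; d < axis; ++d) s *= dim[d];
  int n = dim[axis];
  long long nouter = N / (s * n);
  std::vector<double> line(n), out(n);
  for (long long o = 0; o < nouter; ++o) {
    for (long long in = 0; in < s; ++in) {
      long long base = o * s * n + in;
      for (int j = 0; j < n; ++j) line[j] = a[base + (long long)j * s];
      for (int j = 0; j < n; ++j) {
        int lo = j - left, hi = j - left + k - 1;
        if (lo < 0) lo = 0;
        if (hi > n - 1) hi = n - 1;
        double v = line[lo];
        for (int t = lo + 1; t <= hi; ++t) {
          if (ismax) { if (line[t] > v) v = line[t]; }
          else       { if (line[t] < v) v = line[t]; }
        }
        out[j] = v;
      }
      for (int j = 0; j < n; ++j) a[base + (long long)j * s] = out[j];
    }
  }
}

// Box (rectangular structuring element) min/max filter; `left[d]` gives the
// SE anchor offset along axis d so that the window is [i-left, i-left+k-1].
// [[Rcpp::export]]
NumericVector cpp_box_filter(NumericVector arr, IntegerVector dim,
                             IntegerVector ksize, IntegerVector left,
                             bool ismax) {
  std::vector<double> a(arr.begin(), arr.end());
  for (int d = 0; d < dim.size(); ++d)
    if (ksize[d] > 1) slide_axis(a, dim, d, ksize[d], left[d], ismax);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), weight w =
// spacing^2 along this axis.
static void dt1d(std::vector<double>& f, std::vector<double>& d, double w) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w * q * q) - (f[p] + w * p * p)) / (2.0 * w * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q] = w * (q - p) * (q - p) + f[p];
  }
}

// Exact anisotropic squared Euclidean distance transform: distance from every
// voxel to the nearest voxel with mask != 0, in physical units (spacing per
// axis). Returns +Inf everywhere if the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nd = dim.size();
  long long N = 1;
  for (int d = 0; d < nd; ++d) N *= dim[d];
  std::vector<double> a(N);
  // large finite sentinel: Inf would produce NaN in the envelope update
  const double INF = 1e30;
  for (long long i = 0; i < N; ++i) a[i] = (mask[i] != 0) ? 0.0 : INF;
  for (int axis = 0; axis < nd; ++axis) {
    double w = spacing[axis] * spacing[axis];
    long long s = 1;
    for (int d = 0; d < axis; ++d) s *= dim[d];
    int n = dim[axis];
    long long nouter = N / (s * n);
    std::vector<double> f(n), dd(n);
    for (long long o = 0; o < nouter; ++o) {
      for (long long in = 0; in < s; ++in) {
        long long base = o * s * n + in;
        bool allinf = true;
        for (int j = 0; j < n; ++j) {
          f[j] = a[base + (long long)j * s];
          if (f[j] < INF) allinf = false;
        }
        if (allinf) continue;
        for (int j = 0; j < n; ++j) if (f[j] > INF) f[j] = INF;
        dt1d(f, dd, w);
        for (int j = 0; j < n; ++j) a[base + (long long)j * s] = dd[j];
      }
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling of a binary mask. connectivity: for 2D use
// 4 or 8; for 3D use 6 or 26. Labels assigned in raster-scan order.
// [[Rcpp::export]]
IntegerVector cpp_label(IntegerVector mask, IntegerVector dim,
                        int connectivity) {
  int nd = dim.size();
  long long N = 1;
  for (int d = 0; d < nd; ++d) N *= dim[d];
  IntegerVector lab(N, 0);
  lab.attr("dim") = dim;
  // neighbor offsets
  std::vector<std::vector<int>> offs;
  int lo = -1, hi = 1;
  if (nd == 2) {
    for (int dx = lo; dx <= hi; ++dx) for (int dy = lo; dy <= hi; ++dy) {
      if (dx == 0 && dy == 0) continue;
      int man = std::abs(dx) + std::abs(dy);
      if (connectivity == 4 && man != 1) continue;
      offs.push_back({dx, dy});
    }
  } else {
    for (int dx = lo; dx <= hi; ++dx) for (int dy = lo; dy <= hi; ++dy)
      for (int dz = lo; dz <= hi; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  }
  std::vector<long long> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];
  std::vector<int> co(nd);
  int next = 0;
  std::queue<long long> q;
  for (long long i = 0; i < N; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      long long cur = q.front(); q.pop();
      long long rem = cur;
      for (int d = 0; d < nd; ++d) { co[d] = rem % dim[d]; rem /= dim[d]; }
      for (size_t k = 0; k < offs.size(); ++k) {
        long long nb = 0;
        bool ok = true;
        for (int d = 0; d < nd; ++d) {
          int c = co[d] + offs[k][d];
          if (c < 0 || c >= dim[d]) { ok = false; break; }
          nb += (long long)c * stride[d];
        }
        if (!ok) continue;
        if (mask[nb] != 0 && lab[nb] == 0) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  return lab;
}

// Separable Gaussian smoothing with reflect boundary; sigma per axis in
// voxel units (sigma <= 0 skips the axis).
// [[Rcpp::export]]
NumericVector cpp_gauss(NumericVector arr, IntegerVector dim,
                        NumericVector sigma) {
  int nd = dim.size();
  long long N = 1;
  for (int d = 0; d < nd; ++d) N *= dim[d];
  std::vector<double> a(arr.begin(), arr.end());
  for (int axis = 0; axis < nd; ++axis) {
    double sg = sigma[axis];
    if (sg <= 0) continue;
    int r = std::max(1, (int)std::ceil(4.0 * sg));
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      tot += ker[t + r];
    }
    for (int t = 0; t < 2 * r + 1; ++t) ker[t] /= tot;
    long long s = 1;
    for (int d = 0; d < axis; ++d) s *= dim[d];
    int n = dim[axis];
    long long nouter = N / (s * n);
    std::vector<double> line(n), out(n);
    for (long long o = 0; o < nouter; ++o) {
      for (long long in = 0; in < s; ++in) {
        long long base = o * s * n + in;
        for (int j = 0; j < n; ++j) line[j] = a[base + (long long)j * s];
        for (int j = 0; j < n; ++j) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int p = j + t;
            if (p < 0) p = -p - 1;            // reflect
            if (p > n - 1) p = 2 * n - 1 - p;
            if (p < 0) p = 0;
            if (p > n - 1) p = n - 1;
            acc += ker[t + r] * line[p];
          }
          out[j] = acc;
        }
        for (int j = 0; j < n; ++j) a[base + (long long)j * s] = out[j];
      }
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Local maxima: voxel value > thresh and >= every neighbor in the full
// (3^d - 1) neighborhood. Plateaus yield multiple flags; merge downstream.
// [[Rcpp::export]]
LogicalVector cpp_local_max(NumericVector arr, IntegerVector dim,
                            double thresh) {
  int nd = dim.size();
  long long N = 1;
  for (int d = 0; d < nd; ++d) N *= dim[d];
  LogicalVector out(N, false);
  out.attr("dim") = dim;
  std::vector<long long> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];
  std::vector<int> co(nd), off(nd);
  for (long long i = 0; i < N; ++i) {
    double v = arr[i];
    if (!(v > thresh)) continue;
    long long rem = i;
    for (int d = 0; d < nd; ++d) { co[d] = rem % dim[d]; rem /= dim[d]; }
    bool ismax = true;
    int total = 1;
    for (int d = 0; d < nd; ++d) total *= 3;
    for (int k = 0; k < total && ismax; ++k) {
      int kk = k;
      bool self = true;
      long long nb = 0;
      bool ok = true;
      for (int d = 0; d < nd; ++d) {
        off[d] = (kk % 3) - 1;
        kk /= 3;
        if (off[d] != 0) self = false;
        int c = co[d] + off[d];
        if (c < 0 || c >= dim[d]) { ok = false; }
        else nb += (long long)c * stride[d];
      }
      if (self || !ok) continue;
      if (arr[nb] > v) ismax = false;
    }
    if (ismax) out[i] = true;
  }
  return out;
}
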