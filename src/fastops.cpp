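#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// Column gather: out(, j) = X(, idx[j]). idx is 1-based.
// The hot path of im2col convolution; plain memcpy per column.
// [[Rcpp::export]]
NumericMatrix gather_cols(const NumericMatrix& X, const IntegerVector& idx) {
  const R_xlen_t B = X.nrow();
  const R_xlen_t n = idx.size();
  NumericMatrix out(B, n);
  const double* src = X.begin();
  double* dst = out.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    std::memcpy(dst + j * B, src + (R_xlen_t)(idx[j] - 1) * B,
                B * sizeof(double));
  }
  return out;
}

// Run-based column gather: for r-th run, copy `len[r]` consecutive source
// columns starting at src_start[r] to consecutive destination columns
// starting at dst_start[r] (all 1-based). Exploits the contiguity of
// im2col indices along the output-height axis for large memcpys.
// [[Rcpp::export]]
NumericMatrix gather_runs(const NumericMatrix& X, const IntegerVector& src_start,
                          const IntegerVector& dst_start,
                          const IntegerVector& len, int n_out) {
  const R_xlen_t B = X.nrow();
  NumericMatrix out(B, n_out);
  const double* src = X.begin();
  double* dst = out.begin();
  for (R_xlen_t r = 0; r < src_start.size(); ++r) {
    std::memcpy(dst + (R_xlen_t)(dst_start[r] - 1) * B,
                src + (R_xlen_t)(src_start[r] - 1) * B,
                (R_xlen_t)len[r] * B * sizeof(double));
  }
  return out;
}

// Column scatter-add: target(, idx[j]) += src(, j), sequential so repeated
// indices accumulate. Modifies `target` in place (caller owns a fresh copy).
// [[Rcpp::export]]
void scatter_add_cols(NumericMatrix target, const IntegerVector& idx,
                      const NumericMatrix& src) {
  const R_xlen_t B = target.nrow();
  const R_xlen_t n = idx.size();
  if (src.nrow() != B || src.ncol() != n)
    stop("scatter_add_cols: shape mismatch");
  double* dst = target.begin();
  const double* s = src.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    double* col = dst + (R_xlen_t)(idx[j] - 1) * B;
    const double* sc = s + j * B;
    for (R_xlen_t b = 0; b < B; ++b) col[b] += sc[b];
  }
}

// Ceil-mode 2x2 max pooling over all (position, channel) gather tables.
// idx1..idx4 are 1-based candidate columns, valid2..valid4 mark real
// (non-padded) candidates for the partial edge windows; offset 1 is always
// valid. Returns the max and, for backward, which candidate won.
// [[Rcpp::export]]
List pool_forward(const NumericMatrix& X, const IntegerVector& idx1,
                  const IntegerVector& idx2, const LogicalVector& valid2,
                  const IntegerVector& idx3, const LogicalVector& valid3,
                  const IntegerVector& idx4, const LogicalVector& valid4) {
  const R_xlen_t B = X.nrow();
  const R_xlen_t n = idx1.size();
  NumericMatrix best(B, n);
  IntegerMatrix arg(B, n);
  const double* src = X.begin();
  double* bp = best.begin();
  int* ap = arg.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* c1 = src + (R_xlen_t)(idx1[j] - 1) * B;
    const double* c2 = valid2[j] ? src + (R_xlen_t)(idx2[j] - 1) * B : 0;
    const double* c3 = valid3[j] ? src + (R_xlen_t)(idx3[j] - 1) * B : 0;
    const double* c4 = valid4[j] ? src + (R_xlen_t)(idx4[j] - 1) * B : 0;
    double* bo = bp + j * B;
    int* ao = ap + j * B;
    for (R_xlen_t b = 0; b < B; ++b) {
      double v = c1[b];
      int a = 1;
      if (c2 && c2[b] > v) { v = c2[b]; a = 2; }
      if (c3 && c3[b] > v) { v = c3[b]; a = 3; }
      if (c4 && c4[b] > v) { v = c4[b]; a = 4; }
      bo[b] = v;
      ao[b] = a;
    }
  }
  return List::create(Named("best") = best, Named("arg") = arg);
}

// Backward of pool_forward: route each gradient to the winning candidate.
// [[Rcpp::export]]
NumericMatrix pool_backward(const NumericMatrix& dY, const IntegerMatrix& arg,
                            const IntegerVector& idx1,
                            const IntegerVector& idx2,
                            const IntegerVector& idx3,
                            const IntegerVector& idx4, int in_cols) {
  const R_xlen_t B = dY.nrow();
  const R_xlen_t n = dY.ncol();
  NumericMatrix dX(B, in_cols);
  double* dst = dX.begin();
  const double* g = dY.begin();
  const int* ap = arg.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* gc = g + j * B;
    const int* ac = ap + j * B;
    for (R_xlen_t b = 0; b < B; ++b) {
      R_xlen_t tgt;
      switch (ac[b]) {
      case 1: tgt = idx1[j] - 1; break;
      case 2: tgt = idx2[j] - 1; break;
      case 3: tgt = idx3[j] - 1; break;
      default: tgt = idx4[j] - 1; break;
      }
      dst[tgt * B + b] += gc[b];
    }
  }
  return dX;
}
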