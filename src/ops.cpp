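#include <Rcpp.h>
using namespace Rcpp;

// Low-level numeric kernels for the sequential CNN. All image batches are
// column-major R arrays with dim (H, W, C, N); convolution weights have dim
// (3, 3, C_in, C_out). Valid padding only: output is (H-2, W-2, C_out, N).

static void dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// [[Rcpp::export]]
NumericVector conv3x3_fw(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3 || wd[2] != C)
    stop("weight array must have dim (3, 3, C_in, C_out)");
  const int F = wd[3];
  const int Ho = H - 2, Wo = W - 2;
  if (Ho < 1 || Wo < 1) stop("input too small for a valid 3x3 convolution");
  NumericVector out((R_xlen_t)Ho * Wo * F * N);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double s = pb[f];
          for (int c = 0; c < C; ++c)
            for (int kj = 0; kj < 3; ++kj) {
              const double *col = px + (R_xlen_t)(io) + (R_xlen_t)H * ((jo + kj) + (R_xlen_t)W * (c + (R_xlen_t)C * n));
              const double *ker = pw + (R_xlen_t)3 * (kj + 3 * (c + (R_xlen_t)C * f));
              s += col[0] * ker[0] + col[1] * ker[1] + col[2] * ker[2];
            }
          po[(R_xlen_t)io + (R_xlen_t)Ho * (jo + (R_xlen_t)Wo * (f + (R_xlen_t)F * n))] = s;
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return out;
}

// [[Rcpp::export]]
List conv3x3_bw(NumericVector x, NumericVector w, NumericVector gout) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int F = wd[3];
  const int Ho = H - 2, Wo = W - 2;
  NumericVector gx((R_xlen_t)x.size()), gw((R_xlen_t)w.size()), gb(F);
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          const double g = pg[(R_xlen_t)io + (R_xlen_t)Ho * (jo + (R_xlen_t)Wo * (f + (R_xlen_t)F * n))];
          if (g == 0.0) continue;
          pgb[f] += g;
          for (int c = 0; c < C; ++c)
            for (int kj = 0; kj < 3; ++kj) {
              R_xlen_t xoff = (R_xlen_t)(io) + (R_xlen_t)H * ((jo + kj) + (R_xlen_t)W * (c + (R_xlen_t)C * n));
              R_xlen_t woff = (R_xlen_t)3 * (kj + 3 * (c + (R_xlen_t)C * f));
              for (int ki = 0; ki < 3; ++ki) {
                pgx[xoff + ki] += pw[woff + ki] * g;
                pgw[woff + ki] += px[xoff + ki] * g;
              }
            }
        }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(3, 3, C, F);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2 (floor); trailing odd row/column dropped.
// Returns the pooled array and the 1-based linear index of each winner in
// the input, used both for backprop and winner-takes-all relevance routing.
// Ties go to the earliest element in column-major order.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small for 2x2 max pooling");
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  NumericVector idx((R_xlen_t)Ho * Wo * C * N);  // double: may exceed int range
  const double *px = x.begin();
  double *po = out.begin(), *pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          R_xlen_t base = (R_xlen_t)(2 * io) + (R_xlen_t)H * ((2 * jo) + (R_xlen_t)W * (c + (R_xlen_t)C * n));
          R_xlen_t best = base;
          double bv = px[base];
          R_xlen_t cand[3] = {base + 1, base + H, base + H + 1};
          for (int k = 0; k < 3; ++k)
            if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
          R_xlen_t o = (R_xlen_t)io + (R_xlen_t)Ho * (jo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          po[o] = bv;
          pi[o] = (double)(best + 1);
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector idx, NumericVector gout, IntegerVector xdim) {
  R_xlen_t len = 1;
  for (int k = 0; k < xdim.size(); ++k) len *= xdim[k];
  NumericVector gx(len);
  const double *pi = idx.begin(), *pg = gout.begin();
  double *pgx = gx.begin();
  for (R_xlen_t k = 0; k < gout.size(); ++k)
    pgx[(R_xlen_t)pi[k] - 1] += pg[k];
  gx.attr("dim") = xdim;
  return gx;
}
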