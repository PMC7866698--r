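// Diploid haplotype-copying Viterbi (Li-Stephens style).
//
// Hidden state at site j = ordered pair (x, y) of panel haplotypes being
// copied. Per-interval transition for each chromosome independently:
//   t(x' -> x) = (1 - r) * I[x' = x] + r / H,   r = 1 - exp(-rho * d)
// Emission compares the implied dosage h[x]+h[y] with the observed genotype
// dosage with a per-allele mismatch probability lambda.
//
// The maximization over H^2 predecessors factorizes through the stay/jump
// structure, giving O(S * H^2) time. Ties everywhere resolve toward the
// smaller haplotype index (strict improvement required to switch), so the
// decoded path is deterministic.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List diploid_viterbi_cpp(IntegerMatrix haps, IntegerVector gt,
                         NumericVector pos, double rho, double lambda) {
  const int H = haps.nrow();
  const int S = haps.ncol();
  if (S == 0 || H < 2) stop("need at least one site and two panel haplotypes");
  if (gt.size() != S || pos.size() != S) stop("gt/pos length mismatch");

  const double ll = std::log(lambda);
  const double l1 = std::log1p(-lambda);
  const double NEG_INF = -std::numeric_limits<double>::infinity();

  std::vector<double> V(static_cast<size_t>(H) * H);
  std::vector<double> A(static_cast<size_t>(H) * H);
  std::vector<double> cm(H), rm(H);
  std::vector<int> argcm_all(static_cast<size_t>(S) * H);
  std::vector<int> argrm_all(static_cast<size_t>(S) * H);
  // bit0 = caseM (1 = jump on chromosome 2), bit1 = caseA (1 = jump on chr 1)
  std::vector<uint8_t> cases(static_cast<size_t>(S) * H * H, 0);

  // per-site allele column and emission lookup by implied dosage
  std::vector<int> hs(H);
  double elut[3];
  auto load_site = [&](int j) {
    for (int x = 0; x < H; ++x) hs[x] = haps(x, j);
    const int g = gt[j];
    for (int d = 0; d <= 2; ++d) {
      if (g == NA_INTEGER || g < 0) {
        elut[d] = 0.0;
      } else {
        const int m = std::abs(d - g);
        elut[d] = m * ll + (2 - m) * l1;
      }
    }
  };

  load_site(0);
  for (int x = 0; x < H; ++x)
    for (int y = 0; y < H; ++y)
      V[static_cast<size_t>(x) * H + y] = elut[hs[x] + hs[y]];

  for (int j = 1; j < S; ++j) {
    const double d = pos[j] - pos[j - 1];
    const double r = -std::expm1(-rho * (d > 0 ? d : 0.0));
    const double lq = (r > 0) ? std::log(r / H) : NEG_INF;
    const double ls = std::log(1.0 - r + r / H);
    uint8_t* cs = &cases[static_cast<size_t>(j) * H * H];
    int* argcm = &argcm_all[static_cast<size_t>(j) * H];
    int* argrm = &argrm_all[static_cast<size_t>(j) * H];

    // column maxima over the first copied haplotype (sequential sweep:
    // x outer / y inner keeps every access unit-stride)
    for (int y = 0; y < H; ++y) { cm[y] = NEG_INF; argcm[y] = 0; }
    for (int x = 0; x < H; ++x) {
      const size_t off = static_cast<size_t>(x) * H;
      for (int y = 0; y < H; ++y) {
        const double v = V[off + y];
        if (v > cm[y]) { cm[y] = v; argcm[y] = x; }
      }
    }
    // A(x, y') = max over x' ; then row maxima over y'
    for (int x = 0; x < H; ++x) {
      double best = NEG_INF;
      int arg = 0;
      const size_t off = static_cast<size_t>(x) * H;
      for (int y = 0; y < H; ++y) {
        const double stay = ls + V[off + y];
        const double jump = lq + cm[y];
        double a;
        if (jump > stay) { a = jump; cs[off + y] |= 2; } else { a = stay; }
        A[off + y] = a;
        if (a > best) { best = a; arg = y; }
      }
      rm[x] = best;
      argrm[x] = arg;
    }
    // M(x, y) and the new scores
    load_site(j);
    for (int x = 0; x < H; ++x) {
      const size_t off = static_cast<size_t>(x) * H;
      const double* ex = elut;
      const int hx = hs[x];
      for (int y = 0; y < H; ++y) {
        const double stay = ls + A[off + y];
        const double jump = lq + rm[x];
        double m;
        if (jump > stay) { m = jump; cs[off + y] |= 1; } else { m = stay; }
        V[off + y] = ex[hx + hs[y]] + m;
      }
    }
  }

  // terminal argmax, smallest index pair on ties
  double best = NEG_INF;
  int bx = 0, by = 0;
  for (int x = 0; x < H; ++x)
    for (int y = 0; y < H; ++y) {
      const double v = V[static_cast<size_t>(x) * H + y];
      if (v > best) { best = v; bx = x; by = y; }
    }

  IntegerMatrix path(S, 2);
  int x = bx, y = by;
  path(S - 1, 0) = x + 1;
  path(S - 1, 1) = y + 1;
  for (int j = S - 1; j >= 1; --j) {
    const uint8_t* cs = &cases[static_cast<size_t>(j) * H * H];
    const int* argcm = &argcm_all[static_cast<size_t>(j) * H];
    const int* argrm = &argrm_all[static_cast<size_t>(j) * H];
    const int yp = (cs[static_cast<size_t>(x) * H + y] & 1)
                       ? argrm[x] : y;
    const int xp = (cs[static_cast<size_t>(x) * H + yp] & 2)
                       ? argcm[yp] : x;
    x = xp;
    y = yp;
    path(j - 1, 0) = x + 1;
    path(j - 1, 1) = y + 1;
  }

  return List::create(Named("path") = path, Named("logLik") = best);
}
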