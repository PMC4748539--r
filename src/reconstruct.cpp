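#include <Rcpp.h>
#include <queue>
#include <algorithm>

using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, hybrid algorithm
// (two raster sweeps followed by FIFO propagation). The marker is clamped
// below the mask on entry; connectivity is 4 or 8. Flat-array indexing
// (p = i + j*nr, column-major) keeps the inner loops cheap — cohort
// simulations call this thousands of times per run.

// [[Rcpp::export]]
NumericMatrix reconstruct_dilation_cpp(NumericMatrix marker, NumericMatrix mask,
                                       int connectivity = 8) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const bool eight = connectivity == 8;

  NumericMatrix Jm(nr, nc);
  double *J = Jm.begin();
  const double *M = mask.begin();
  {
    const double *mk = marker.begin();
    const int n = nr * nc;
    for (int p = 0; p < n; ++p) J[p] = std::min(mk[p], M[p]);
  }

  // forward sweep: N+ = up, left column (3 pixels for 8-connectivity)
  for (int j = 0; j < nc; ++j) {
    const int col = j * nr;
    for (int i = 0; i < nr; ++i) {
      const int p = col + i;
      double v = J[p];
      if (i > 0 && J[p - 1] > v) v = J[p - 1];
      if (j > 0) {
        const int q = p - nr;
        if (J[q] > v) v = J[q];
        if (eight) {
          if (i > 0 && J[q - 1] > v) v = J[q - 1];
          if (i < nr - 1 && J[q + 1] > v) v = J[q + 1];
        }
      }
      J[p] = std::min(v, M[p]);
    }
  }

  // backward sweep + queue seeding
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j) {
    const int col = j * nr;
    for (int i = nr - 1; i >= 0; --i) {
      const int p = col + i;
      double v = J[p];
      if (i < nr - 1 && J[p + 1] > v) v = J[p + 1];
      if (j < nc - 1) {
        const int q = p + nr;
        if (J[q] > v) v = J[q];
        if (eight) {
          if (i < nr - 1 && J[q + 1] > v) v = J[q + 1];
          if (i > 0 && J[q - 1] > v) v = J[q - 1];
        }
      }
      const double jp = std::min(v, M[p]);
      J[p] = jp;

      bool seed = false;
      if (i < nr - 1 && J[p + 1] < jp && J[p + 1] < M[p + 1]) seed = true;
      if (!seed && j < nc - 1) {
        const int q = p + nr;
        if (J[q] < jp && J[q] < M[q]) seed = true;
        if (!seed && eight) {
          if (i < nr - 1 && J[q + 1] < jp && J[q + 1] < M[q + 1]) seed = true;
          if (!seed && i > 0 && J[q - 1] < jp && J[q - 1] < M[q - 1])
            seed = true;
        }
      }
      if (seed) fifo.push(p);
    }
  }

  // FIFO propagation
  while (!fifo.empty()) {
    const int p = fifo.front();
    fifo.pop();
    const int i = p % nr, j = p / nr;
    const double jp = J[p];
    const int lo = (i > 0) ? -1 : 0, hi = (i < nr - 1) ? 1 : 0;
    for (int dj = -1; dj <= 1; ++dj) {
      const int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      for (int di = lo; di <= hi; ++di) {
        if (di == 0 && dj == 0) continue;
        if (!eight && di != 0 && dj != 0) continue;
        const int q = p + di + dj * nr;
        if (J[q] < jp && J[q] < M[q]) {
          J[q] = std::min(jp, M[q]);
          fifo.push(q);
        }
      }
    }
  }
  return Jm;
}
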