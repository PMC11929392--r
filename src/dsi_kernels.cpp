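#include <Rcpp.h>
using namespace Rcpp;

// Random walk over a free-cell graph under the default policy (uniform over
// available actions). Uses the R RNG so set.seed() / withr::with_seed()
// control reproducibility.
//
// neighbors: per-state integer vector of reachable state indices (1-based)
// actions:   per-state integer vector of the action ids taken to reach them
// [[Rcpp::export]]
List cpp_random_walk(List neighbors, List actions, int length, int start) {
  IntegerVector states(length);
  IntegerVector acts(length > 1 ? length - 1 : 0);
  int cur = start;
  states[0] = cur;
  for (int t = 1; t < length; ++t) {
    IntegerVector nb = neighbors[cur - 1];
    IntegerVector ac = actions[cur - 1];
    int k = nb.size();
    int pick = (int)(unif_rand() * k);
    if (pick >= k) pick = k - 1;  // guard unif_rand() == 1.0
    cur = nb[pick];
    states[t] = cur;
    acts[t - 1] = ac[pick];
  }
  return List::create(_["states"] = states, _["actions"] = acts);
}

// Empirical successor representation by discounted forward counting.
// For every visit of s the discounted future indicator sum (truncated at the
// end of the containing segment) is accumulated into row s; rows are later
// divided by visit counts in R. seg_starts are 1-based positions where a new
// segment (document) begins; the discount window never crosses a boundary.
// Accumulation is into the transpose (column s contiguous) for cache
// friendliness; the caller transposes once.
// [[Rcpp::export]]
List cpp_sr_accumulate(IntegerVector states, IntegerVector seg_starts,
                       int n_states, double gamma) {
  int T = states.size();
  NumericMatrix Mt(n_states, n_states);
  IntegerVector visits(n_states);
  std::vector<double> e(n_states);
  int nseg = seg_starts.size();
  for (int seg = 0; seg < nseg; ++seg) {
    int a = seg_starts[seg] - 1;
    int b = (seg + 1 < nseg ? seg_starts[seg + 1] - 1 : T) - 1;
    std::fill(e.begin(), e.end(), 0.0);
    for (int t = b; t >= a; --t) {
      int s = states[t] - 1;
      if (s < 0 || s >= n_states) stop("state index out of range");
      for (int j = 0; j < n_states; ++j) e[j] *= gamma;
      e[s] += 1.0;
      visits[s] += 1;
      double* col = &Mt(0, s);
      for (int j = 0; j < n_states; ++j) col[j] += e[j];
    }
  }
  return List::create(_["sum_t"] = Mt, _["visits"] = visits);
}

// Masked spatial autocorrelogram: Pearson correlation of a map with itself
// at every 2-D offset, over overlapping unmasked (non-NA) cells. Offsets
// with fewer than min_overlap overlapping cells, or with degenerate
// variance, are NA.
// [[Rcpp::export]]
NumericMatrix cpp_autocorrelogram(NumericMatrix map, int min_overlap) {
  int h = map.nrow(), w = map.ncol();
  int H = 2 * h - 1, W = 2 * w - 1;
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), NA_REAL);
  bool has_na = false;
  for (int i = 0; i < h * w; ++i) {
    if (ISNAN(map[i])) { has_na = true; break; }
  }
  for (int dr = -(h - 1); dr <= h - 1; ++dr) {
    for (int dc = -(w - 1); dc <= w - 1; ++dc) {
      double n = 0, sx = 0, sy = 0, sxy = 0, sxx = 0, syy = 0;
      int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
      int c0 = std::max(0, -dc), c1 = std::min(w, w - dc);
      if (!has_na) {
        n = (double)(r1 - r0) * (c1 - c0);
        for (int c = c0; c < c1; ++c) {
          const double* x = &map(r0, c);
          const double* y = &map(r0 + dr, c + dc);
          int len = r1 - r0;
          for (int r = 0; r < len; ++r) {
            sx += x[r]; sy += y[r];
            sxy += x[r] * y[r]; sxx += x[r] * x[r]; syy += y[r] * y[r];
          }
        }
      } else {
        for (int r = r0; r < r1; ++r) {
          for (int c = c0; c < c1; ++c) {
            double x = map(r, c);
            double y = map(r + dr, c + dc);
            if (ISNAN(x) || ISNAN(y)) continue;
            n += 1; sx += x; sy += y;
            sxy += x * y; sxx += x * x; syy += y * y;
          }
        }
      }
      if (n >= min_overlap) {
        double vx = n * sxx - sx * sx;
        double vy = n * syy - sy * sy;
        if (vx > 1e-12 && vy > 1e-12) {
          out(dr + h - 1, dc + w - 1) = (n * sxy - sx * sy) / std::sqrt(vx * vy);
        }
      }
    }
  }
  return out;
}
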