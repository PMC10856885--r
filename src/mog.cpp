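#include <Rcpp.h>
using namespace Rcpp;

// Online per-pixel Gaussian-mixture background update and classification.
//
// State layout: for pixel i and component k, index i*K + k. The state
// vectors are owned by the model environment on the R side and are updated
// in place; a copy of the frame classification is returned as the mask.
//
// A pixel is background when it matches (squared Mahalanobis distance below
// var_thresh) one of its highest-weight components whose cumulative weight
// does not exceed bg_thresh (the first component is always eligible).
// Matched components are updated with learning rate alpha; an unmatched
// pixel spawns a new component (weight alpha) replacing the weakest one
// when all slots are taken. Weights are renormalized to sum to one.

// [[Rcpp::export]]
IntegerVector mog_step_cpp(NumericVector means, NumericVector vars,
                           NumericVector weights, IntegerVector ncomp,
                           NumericVector frame, int K,
                           double alpha, double var_thresh, double bg_thresh,
                           double var_floor, double init_var) {
  const int n = frame.size();
  IntegerVector mask(n);
  int ord[16];

  for (int i = 0; i < n; ++i) {
    const int base = i * K;
    const double x = frame[i];
    int m = ncomp[i];

    if (m == 0) {  // uninitialized pixel: seed with the observation
      means[base] = x; vars[base] = init_var; weights[base] = 1.0;
      ncomp[i] = 1; mask[i] = 0;
      continue;
    }

    // order live components by weight, descending (insertion sort, m <= K)
    for (int k = 0; k < m; ++k) ord[k] = k;
    for (int k = 1; k < m; ++k) {
      int o = ord[k]; int j = k;
      while (j > 0 && weights[base + ord[j - 1]] < weights[base + o]) {
        ord[j] = ord[j - 1]; --j;
      }
      ord[j] = o;
    }

    // background set: the largest leading run whose cumulative weight stays
    // within bg_thresh; the top component is always eligible
    int n_bg = 1; double cum = 0.0;
    for (int k = 0; k < m; ++k) {
      cum += weights[base + ord[k]];
      if (k == 0 || cum <= bg_thresh) n_bg = k + 1;
      if (cum > bg_thresh) break;
    }

    // first matching component in weight order
    int match = -1; int match_rank = -1;
    for (int k = 0; k < m; ++k) {
      const int c = base + ord[k];
      const double d = x - means[c];
      if (d * d < var_thresh * vars[c]) { match = c; match_rank = k; break; }
    }

    mask[i] = (match >= 0 && match_rank < n_bg) ? 0 : 1;

    // recursive update
    for (int k = 0; k < m; ++k) weights[base + k] *= (1.0 - alpha);
    if (match >= 0) {
      weights[match] += alpha;
      const double d = x - means[match];
      means[match] += alpha * d;
      const double d2 = x - means[match];
      vars[match] += alpha * (d2 * d2 - vars[match]);
      if (vars[match] < var_floor) vars[match] = var_floor;
    } else {
      int slot;
      if (m < K) { slot = base + m; ncomp[i] = ++m; }
      else {
        slot = base;  // replace weakest
        for (int k = 1; k < m; ++k)
          if (weights[base + k] < weights[slot]) slot = base + k;
      }
      weights[slot] = alpha; means[slot] = x; vars[slot] = init_var;
    }

    double s = 0.0;
    for (int k = 0; k < m; ++k) s += weights[base + k];
    if (s > 0) for (int k = 0; k < m; ++k) weights[base + k] /= s;
  }
  return mask;
}
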