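#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive linear-band trajectory search on a circular posterior.
//
// P:      nt x nb posterior (rows = time bins, cols = circular position bins)
// trel:   time of each bin centre relative to the first (s)
// slopes: signed candidate slopes (cm/s), ordered by the caller so that the
//         first maximum encountered wins ties (|slope| ascending)
// bin_cm: spatial bin size; half_band_bins: band half-width in bins
//
// For every (start bin, slope) the band score is the summed probability in
// the bins whose centres lie within the band around pos(t) = start +
// slope * trel, wrapped circularly. Returns best score, slope and start.
// [[Rcpp::export(name = ".band_best_fit")]]
List band_best_fit(NumericMatrix P, NumericVector trel, NumericVector slopes,
                   double bin_cm, int half_band_bins) {
  const int nt = P.nrow(), nb = P.ncol(), ns = slopes.size();
  // band sums B[t][c] = sum of P[t, c-h .. c+h] (wrapped)
  NumericMatrix B(nt, nb);
  for (int t = 0; t < nt; ++t) {
    for (int c = 0; c < nb; ++c) {
      double s = 0.0;
      for (int o = -half_band_bins; o <= half_band_bins; ++o) {
        int j = (c + o) % nb; if (j < 0) j += nb;
        s += P(t, j);
      }
      B(t, c) = s;
    }
  }
  double best = -1.0; int best_slope = 0, best_start = 0;
  std::vector<int> off(nt);
  for (int si = 0; si < ns; ++si) {
    const double sl = slopes[si];
    for (int t = 0; t < nt; ++t) {
      int o = (int)std::lround(sl * trel[t] / bin_cm) % nb;
      if (o < 0) o += nb;
      off[t] = o;
    }
    for (int c = 0; c < nb; ++c) {
      double s = 0.0;
      for (int t = 0; t < nt; ++t) {
        int j = c + off[t]; if (j >= nb) j -= nb;
        s += B(t, j);
      }
      if (s > best + 1e-12) { best = s; best_slope = si; best_start = c; }
    }
  }
  return List::create(_["score"] = best,
                      _["slope"] = slopes[best_slope],
                      _["start_bin"] = best_start + 1);
}

static double fit_best_score(const std::vector<double>& P, int nt, int nb,
                             const NumericVector& trel,
                             const NumericVector& slopes, double bin_cm,
                             int hb) {
  std::vector<double> B(nt * nb);
  for (int t = 0; t < nt; ++t) {
    for (int c = 0; c < nb; ++c) {
      double s = 0.0;
      for (int o = -hb; o <= hb; ++o) {
        int j = (c + o) % nb; if (j < 0) j += nb;
        s += P[t + nt * j];
      }
      B[t + nt * c] = s;
    }
  }
  double best = -1.0;
  std::vector<int> off(nt);
  const int ns = slopes.size();
  for (int si = 0; si < ns; ++si) {
    const double sl = slopes[si];
    for (int t = 0; t < nt; ++t) {
      int o = (int)std::lround(sl * trel[t] / bin_cm) % nb;
      if (o < 0) o += nb;
      off[t] = o;
    }
    for (int c = 0; c < nb; ++c) {
      double s = 0.0;
      for (int t = 0; t < nt; ++t) {
        int j = c + off[t]; if (j >= nb) j -= nb;
        s += B[t + nt * j];
      }
      if (s > best) best = s;
    }
  }
  return best;
}

// Decode one shuffled event against one direction's maps and return the
// best band-fit score. cell-identity shuffle: spike train c is decoded
// with the map of cell perm[c] (1-based); map shuffle: each cell's map is
// circularly offset by offsets[c] bins. Exactly one of perm / offsets is
// used, selected by use_map.
// [[Rcpp::export(name = ".shuffle_fit_score")]]
double shuffle_fit_score(NumericMatrix logF, NumericMatrix F,
                         NumericMatrix counts, double tau,
                         NumericVector trel, NumericVector slopes,
                         double bin_cm, int half_band_bins,
                         IntegerVector perm, IntegerVector offsets,
                         bool use_map) {
  const int nb = logF.nrow(), nc = logF.ncol(), nt = counts.ncol();
  // log-likelihood LP[i,t] then softmax over i
  std::vector<double> LP(nb * nt, 0.0);
  std::vector<double> cons(nb, 0.0);
  if (!use_map) {
    for (int i = 0; i < nb; ++i) {
      double s = 0.0;
      for (int c = 0; c < nc; ++c) s += F(i, c);
      cons[i] = tau * s;
    }
    for (int t = 0; t < nt; ++t)
      for (int c = 0; c < nc; ++c) {
        const double n = counts(c, t);
        if (n == 0.0) continue;
        const int m = perm[c] - 1;
        for (int i = 0; i < nb; ++i) LP[i + nb * t] += n * logF(i, m);
      }
  } else {
    for (int c = 0; c < nc; ++c) {
      int o = offsets[c] % nb; if (o < 0) o += nb;
      for (int i = 0; i < nb; ++i) {
        int j = (i - o) % nb; if (j < 0) j += nb;
        cons[i] += tau * F(j, c);
      }
    }
    for (int t = 0; t < nt; ++t)
      for (int c = 0; c < nc; ++c) {
        const double n = counts(c, t);
        if (n == 0.0) continue;
        int o = offsets[c] % nb; if (o < 0) o += nb;
        for (int i = 0; i < nb; ++i) {
          int j = (i - o) % nb; if (j < 0) j += nb;
          LP[i + nb * t] += n * logF(j, c);
        }
      }
  }
  // posterior, stored time-major for the fitter: P[t + nt*i]
  std::vector<double> P(nt * nb);
  for (int t = 0; t < nt; ++t) {
    double mx = -1e300;
    for (int i = 0; i < nb; ++i) {
      LP[i + nb * t] -= cons[i];
      if (LP[i + nb * t] > mx) mx = LP[i + nb * t];
    }
    double z = 0.0;
    for (int i = 0; i < nb; ++i) z += std::exp(LP[i + nb * t] - mx);
    for (int i = 0; i < nb; ++i)
      P[t + nt * i] = std::exp(LP[i + nb * t] - mx) / z;
  }
  return fit_best_score(P, nt, nb, trel, slopes, bin_cm, half_band_bins);
}
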