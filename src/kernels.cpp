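#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement component for an orthorhombic box edge L.
static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// Coordinates are passed as the flat data of an (n_atoms, 3, n_frames) array.
static inline double pair_dist2(const double *xyz, int na, int f,
                                int i, int j, const double *box) {
  double s = 0.0;
  for (int c = 0; c < 3; ++c) {
    const double *col = xyz + (std::size_t)na * (c + 3 * (std::size_t)f);
    double d = min_image(col[i] - col[j], box[c]);
    s += d * d;
  }
  return s;
}

// Pair-distance histogram for an RDF, accumulated over all frames.
// Bins are half-open [k*bw, (k+1)*bw); distances >= n_bins*bw are dropped.
// Pairs sharing an atom index are skipped.
// [[Rcpp::export]]
NumericVector cpp_rdf_counts(NumericVector coords, IntegerVector idx_a,
                             IntegerVector idx_b, NumericMatrix boxes,
                             double bin_width, int n_bins) {
  IntegerVector dim = coords.attr("dim");
  const int na = dim[0], nf = dim[2];
  const double *xyz = coords.begin();
  NumericVector counts(n_bins);
  const double r_max = bin_width * n_bins;
  for (int f = 0; f < nf; ++f) {
    double box[3] = {boxes(f, 0), boxes(f, 1), boxes(f, 2)};
    for (int a = 0; a < idx_a.size(); ++a) {
      const int i = idx_a[a] - 1;
      for (int b = 0; b < idx_b.size(); ++b) {
        const int j = idx_b[b] - 1;
        if (i == j) continue;
        double r = std::sqrt(pair_dist2(xyz, na, f, i, j, box));
        if (r < r_max) counts[(int)(r / bin_width)] += 1.0;
      }
    }
  }
  return counts;
}

// Bond indicator matrix (pairs x frames); pair p = (a-1)*n_b + b is bonded
// at frame f iff the minimum-image distance is <= cutoff.
// [[Rcpp::export]]
IntegerMatrix cpp_pair_indicator(NumericVector coords, IntegerVector idx_a,
                                 IntegerVector idx_b, NumericMatrix boxes,
                                 double cutoff) {
  IntegerVector dim = coords.attr("dim");
  const int na = dim[0], nf = dim[2];
  const double *xyz = coords.begin();
  const int npair = idx_a.size() * idx_b.size();
  const double cut2 = cutoff * cutoff;
  IntegerMatrix ind(npair, nf);
  for (int f = 0; f < nf; ++f) {
    double box[3] = {boxes(f, 0), boxes(f, 1), boxes(f, 2)};
    int p = 0;
    for (int a = 0; a < idx_a.size(); ++a) {
      const int i = idx_a[a] - 1;
      for (int b = 0; b < idx_b.size(); ++b, ++p) {
        const int j = idx_b[b] - 1;
        ind(p, f) = pair_dist2(xyz, na, f, i, j, box) <= cut2 ? 1 : 0;
      }
    }
  }
  return ind;
}

// Per-frame count of species atoms inside a sphere of radius `radius`
// centred at the midpoint of the minimum-image segment site_a -> site_b.
// [[Rcpp::export]]
IntegerVector cpp_region_counts(NumericVector coords, int site_a, int site_b,
                                IntegerVector idx_species, NumericMatrix boxes,
                                double radius) {
  IntegerVector dim = coords.attr("dim");
  const int na = dim[0], nf = dim[2];
  const double *xyz = coords.begin();
  const double r2 = radius * radius;
  IntegerVector counts(nf);
  const int ia = site_a - 1, ib = site_b - 1;
  for (int f = 0; f < nf; ++f) {
    double box[3] = {boxes(f, 0), boxes(f, 1), boxes(f, 2)};
    double mid[3];
    for (int c = 0; c < 3; ++c) {
      const double *col = xyz + (std::size_t)na * (c + 3 * (std::size_t)f);
      mid[c] = col[ia] + 0.5 * min_image(col[ib] - col[ia], box[c]);
    }
    int n = 0;
    for (int s = 0; s < idx_species.size(); ++s) {
      const int j = idx_species[s] - 1;
      double d2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        const double *col = xyz + (std::size_t)na * (c + 3 * (std::size_t)f);
        double d = min_image(col[j] - mid[c], box[c]);
        d2 += d * d;
      }
      if (d2 <= r2) ++n;
    }
    counts[f] = n;
  }
  return counts;
}

// Overdamped Langevin dynamics of a single coordinate in pmf(x) plus a
// harmonic restraint whose minimum moves at constant speed:
//   dx = -(V'(x) + k (x - x0(t))) dt / zeta + sqrt(2 kBT dt / zeta) eta.
// The Gaussian noise is pre-drawn in R so the R RNG seed governs everything.
// pmf_type: 0 zero, 1 harmonic (a, c), 2 double well (h, c, w),
//           3 screened Coulomb (prefactor q: V = q / x).
// Records (t, x, restraint force k (x0 - x)) at t = 0, dt, ..., (n-1) dt.
// [[Rcpp::export]]
List cpp_langevin_pull(int pmf_type, NumericVector pp, double k_spring,
                       double pull_speed, double x_start, double zeta,
                       double kT, double dt, int n_steps,
                       NumericVector noise) {
  NumericVector times(n_steps), xs(n_steps), fr(n_steps);
  double x = x_start;
  const double mob = dt / zeta;
  const double amp = std::sqrt(2.0 * kT * dt / zeta);
  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    const double x0 = x_start + pull_speed * t;
    times[i] = t;
    xs[i] = x;
    fr[i] = k_spring * (x0 - x);
    double grad;  // V'(x)
    switch (pmf_type) {
      case 1: grad = pp[0] * (x - pp[1]); break;
      case 2: {
        const double u = (x - pp[1]) / pp[2];
        grad = 4.0 * pp[0] * u * (u * u - 1.0) / pp[2];
        break;
      }
      case 3: grad = -pp[0] / (x * x); break;
      default: grad = 0.0;
    }
    x += (-grad + k_spring * (x0 - x)) * mob + amp * noise[i];
  }
  return List::create(_["times"] = times, _["x"] = xs, _["force"] = fr);
}
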