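#include <Rcpp.h>
using namespace Rcpp;

// Great-circle distance (haversine, atan2 form) on a sphere of radius
// 6,371,000 m. Must stay numerically identical to the R-side haversine so
// that crossing-point interpolation agrees across language boundaries.
static const double EARTH_R = 6371000.0;
static const double DEG_TO_RAD = M_PI / 180.0;

static inline double haversine(double lon1, double lat1,
                               double lon2, double lat2) {
  double p1 = lat1 * DEG_TO_RAD, p2 = lat2 * DEG_TO_RAD;
  double dp = (lat2 - lat1) * DEG_TO_RAD, dl = (lon2 - lon1) * DEG_TO_RAD;
  double sdp = sin(dp / 2.0), sdl = sin(dl / 2.0);
  double a = sdp * sdp + cos(p1) * cos(p2) * sdl * sdl;
  return 2.0 * EARTH_R * atan2(sqrt(a), sqrt(std::max(0.0, 1.0 - a)));
}

// One-sided passage times for fix i over an ascending radius grid.
// Walks away from the focal fix (dir = +1 forward, -1 backward) within the
// focal fix's segment; the first fix whose distance to the centre exceeds
// radii[k] closes radius k, with the exit instant linearly interpolated on
// distance along the chord between the last inside fix and the first
// outside fix. Radii never exited before the segment end stay NA.
static void one_sided(const NumericVector& lon, const NumericVector& lat,
                      const NumericVector& tim, const IntegerVector& seg,
                      const NumericVector& radii, int i, int dir,
                      std::vector<double>& out) {
  const int n = lon.size(), nr = radii.size();
  std::fill(out.begin(), out.end(), NA_REAL);
  int k = 0;
  double prev_d = 0.0, prev_t = tim[i];
  for (int j = i + dir; j >= 0 && j < n && k < nr; j += dir) {
    if (seg[j] != seg[i]) break;  // gap: passage undefined in this direction
    double d = haversine(lon[i], lat[i], lon[j], lat[j]);
    while (k < nr && d > radii[k]) {
      double f = (radii[k] - prev_d) / (d - prev_d);
      double t_exit = prev_t + f * (tim[j] - prev_t);
      out[k] = std::fabs(t_exit - tim[i]);
      ++k;
    }
    prev_d = d;
    prev_t = tim[j];
  }
}

// [[Rcpp::export]]
NumericMatrix fpt_matrix_cpp(NumericVector lon, NumericVector lat,
                             NumericVector tim, IntegerVector seg,
                             NumericVector radii) {
  const int n = lon.size(), nr = radii.size();
  NumericMatrix fpt(n, nr);
  std::vector<double> fwd(nr), bwd(nr);
  for (int i = 0; i < n; ++i) {
    one_sided(lon, lat, tim, seg, radii, i, +1, fwd);
    one_sided(lon, lat, tim, seg, radii, i, -1, bwd);
    for (int k = 0; k < nr; ++k)
      fpt(i, k) = (ISNAN(fwd[k]) || ISNAN(bwd[k])) ? NA_REAL : fwd[k] + bwd[k];
  }
  return fpt;
}
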