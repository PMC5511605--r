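#include <Rcpp.h>
using namespace Rcpp;

// Three-phase wheat phenology: sowing -> emergence (fixed thermal time),
// emergence -> flag leaf (vernalization + photoperiod set the final leaf
// number, leaves appear at one phyllochron of thermal time each), ligule ->
// heading (a fixed tail of phyllochrons). Continuous time within a day by
// linear interpolation of the thermal-time accumulator; day d covers
// [d, d+1) with day 0 the sowing day.
//
// Return codes when heading is not reached within the horizon:
//   -1 emergence not reached, -2 vernalization never saturates,
//   -3 leaf phase not completed.
static double heading_one(double vai, double sldl, double phyl,
                          const double *tm, const double *dl, int n,
                          double tt_em, double vbee,
                          double vern_t_min, double vern_t_max,
                          double l_base, double dl_sat, double n_tail,
                          double vern_leaf_frac) {
  double cum_tt = 0.0, cum_v = 0.0;
  double t_em = -1.0, t_sat = -1.0, c_sat = -1.0;
  int d_em = -1, d_sat = -1;

  // Pass 1: emergence, then vernalization (which starts at emergence and
  // runs at a day-fraction rate from the emergence instant onward).
  for (int d = 0; d < n; ++d) {
    double tt = tm[d] > 0.0 ? tm[d] : 0.0;
    double day_start = (double)d;
    if (t_em < 0.0 && cum_tt + tt >= tt_em && tt > 0.0) {
      t_em = d + (tt_em - cum_tt) / tt;
      d_em = d;
    }
    if (t_em >= 0.0) {
      // fraction of day d during which the crop is emerged
      double frac = 1.0;
      if (t_em > day_start) frac = day_start + 1.0 - t_em;
      double tc = tm[d];
      if (tc < vern_t_min) tc = vern_t_min;
      if (tc > vern_t_max) tc = vern_t_max;
      double v = vbee + vai * tc;
      if (t_sat < 0.0 && cum_v + v * frac >= 1.0 && v > 0.0) {
        double from = (t_em > day_start) ? t_em : day_start;
        t_sat = from + (1.0 - cum_v) / v;
        d_sat = d;
        // thermal time accumulated at the (interpolated) saturation instant
        c_sat = cum_tt + (t_sat - day_start) * tt;
      }
      cum_v += v * frac;
    }
    cum_tt += tt;
    if (t_em >= 0.0 && t_sat >= 0.0) break;
  }
  if (t_em < 0.0) return -1.0;
  if (t_sat < 0.0) return -2.0;

  // Day length read on the day vernalization saturates (or the emergence
  // day if saturation happened before emergence).
  int d_dl = d_sat > d_em ? d_sat : d_em;
  // Leaves emerged before vernalization saturation delay the flag leaf:
  // a fraction of the emergence-to-saturation thermal time is added to
  // the leaf-phase target (zero when saturation precedes emergence).
  double vern_delay = vern_leaf_frac * std::max(0.0, c_sat - tt_em);
  double fln = l_base + vern_delay / phyl +
    sldl * std::max(0.0, dl_sat - dl[d_dl]);
  double target = tt_em + (fln + n_tail) * phyl;

  // Pass 2: invert the thermal-time accumulator at the heading target.
  cum_tt = 0.0;
  double t_head = -1.0;
  for (int d = 0; d < n; ++d) {
    double tt = tm[d] > 0.0 ? tm[d] : 0.0;
    if (cum_tt + tt >= target && tt > 0.0) {
      t_head = d + (target - cum_tt) / tt;
      break;
    }
    cum_tt += tt;
  }
  if (t_head < 0.0) return -3.0;
  // Heading cannot precede vernalization saturation.
  return t_head > t_sat ? t_head : t_sat;
}

// theta: n_var x 3 matrix (VAI, SLDL, Phyl). tmean/daylen: per-environment
// numeric vectors of equal length. Returns n_var x n_env matrix of heading
// times in days after sowing (negative codes where heading is not reached).
// [[Rcpp::export]]
NumericMatrix cpp_heading_matrix(NumericMatrix theta, List tmean, List daylen,
                                 List constants) {
  const double tt_em = constants["tt_em"];
  const double vbee = constants["vbee"];
  const double vern_t_min = constants["vern_t_min"];
  const double vern_t_max = constants["vern_t_max"];
  const double l_base = constants["l_base"];
  const double dl_sat = constants["dl_sat"];
  const double n_tail = constants["n_tail"];
  const double vern_leaf_frac = constants["vern_leaf_frac"];
  const int nv = theta.nrow();
  const int ne = tmean.size();
  NumericMatrix out(nv, ne);
  for (int j = 0; j < ne; ++j) {
    NumericVector tm = tmean[j];
    NumericVector dl = daylen[j];
    if (dl.size() < tm.size()) stop("day-length series shorter than temperature series");
    const int n = tm.size();
    for (int i = 0; i < nv; ++i) {
      out(i, j) = heading_one(theta(i, 0), theta(i, 1), theta(i, 2),
                              tm.begin(), dl.begin(), n,
                              tt_em, vbee, vern_t_min, vern_t_max,
                              l_base, dl_sat, n_tail, vern_leaf_frac);
    }
  }
  return out;
}

// Fused criterion evaluation: outputs restricted to the design's columns
// (m x Z), pairwise squared output distances scaled by K replications,
// column-wise softmax normalization of the log-likelihoods (the n_y
// prefactor cancels), then the weight-averaged parameter distance.
// [[Rcpp::export]]
double cpp_optimet_value(NumericMatrix out_sub, NumericMatrix dist,
                         double K, double sigma2) {
  const int m = out_sub.nrow();
  const int Z = out_sub.ncol();
  std::vector<double> logl(m);
  double total = 0.0;
  for (int v = 0; v < m; ++v) {
    double mx = -1e300;
    for (int u = 0; u < m; ++u) {
      double d2 = 0.0;
      for (int j = 0; j < Z; ++j) {
        double diff = out_sub(u, j) - out_sub(v, j);
        d2 += diff * diff;
      }
      double l = -K * d2 / (4.0 * sigma2);
      logl[u] = l;
      if (l > mx) mx = l;
    }
    double denom = 0.0;
    for (int u = 0; u < m; ++u) {
      logl[u] = std::exp(logl[u] - mx);
      denom += logl[u];
    }
    double acc = 0.0;
    for (int u = 0; u < m; ++u) acc += dist(u, v) * logl[u];
    total += acc / denom;
  }
  return total;
}
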