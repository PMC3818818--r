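#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout (kept in sync with .param_order in R/model_params.R)
enum Par {
  TAU1, TAU2, IKK_ACT, IKK_INACT,
  TXN_IKBA, TXN_TRAF1, TXN_P100, TXN_CANON, TXN_TNIP1,
  HILL_K_RELA, HILL_K_P52, HILL_H,
  TLN_IKBA, TLN_TRAF1, TLN_P100,
  DEG_MRNA, DEG_IKBA, DEG_TRAF1, DEG_P100, DEG_P52,
  NIK_SYNTH, NIK_FAST_DEG, NIK_STABLE_DEG, TRAF1_NIK_BIND,
  PROC_RATE, PROC_K, IKBA_RELA_ASSOC, IKBA_DEG_BY_IKK, RELA_TOTAL, BASAL_TXN,
  NPAR
};

// State vector layout (kept in sync with .species_names in R/model_params.R)
enum St {
  IKK, IKBA_M, IKBA_P, RELA_CPLX, RELA_N, CANON_M,
  TRAF1_M, TRAF1_P, NIK, CPLX, P100_M, P100_P, P52, TNIP1_M,
  NSP
};

static inline double hill(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double r = std::pow(K / x, h);   // overflow-safe for large x
  return 1.0 / (1.0 + r);
}

struct History {
  // ring-free append buffer of the two delayed mRNA species at step points
  std::vector<double> traf1m, p100m;
  double h;           // step size, min
  double y0_traf1m, y0_p100m;

  double look(const std::vector<double> &buf, double y0v, double s) const {
    if (s <= 0.0) return y0v;          // constant pre-stimulus history
    double idx = s / h;
    size_t k = (size_t)std::floor(idx);
    if (k + 1 >= buf.size()) return buf.back();
    double w = idx - (double)k;
    return (1.0 - w) * buf[k] + w * buf[k + 1];
  }
  double traf1(double s) const { return look(traf1m, y0_traf1m, s); }
  double p100(double s) const { return look(p100m, y0_p100m, s); }
};

static void deriv(double t, const double *y, double *dy,
                  const double *p, const History &hist,
                  double amplitude, double onset) {
  double stim = (t >= onset) ? amplitude : 0.0;
  double Hr = hill(y[RELA_N], p[HILL_K_RELA], p[HILL_H]);
  double Hp = hill(y[P52], p[HILL_K_P52], p[HILL_H]);

  double traf1m_lag = (p[TAU1] > 0.0) ? hist.traf1(t - p[TAU1]) : y[TRAF1_M];
  double p100m_lag  = (p[TAU2] > 0.0) ? hist.p100(t - p[TAU2])  : y[P100_M];

  double assoc   = p[IKBA_RELA_ASSOC] * y[IKBA_P] * y[RELA_N];
  double release = p[IKBA_DEG_BY_IKK] * y[IKK] * y[RELA_CPLX];
  double capture = p[TRAF1_NIK_BIND] * y[TRAF1_P] * y[NIK];
  // cooperative p100 processing: second order in p100 at low abundance,
  // first order at saturation (processive NIK-IKKa multisite phosphorylation)
  double proc    = p[PROC_RATE] * y[CPLX] * y[P100_P] * y[P100_P] / (p[PROC_K] + y[P100_P]);

  dy[IKK]      = p[IKK_ACT] * stim * (1.0 - y[IKK]) - p[IKK_INACT] * y[IKK];
  dy[IKBA_M]   = p[BASAL_TXN] + p[TXN_IKBA] * Hr - p[DEG_MRNA] * y[IKBA_M];
  dy[IKBA_P]   = p[TLN_IKBA] * y[IKBA_M] - assoc - p[DEG_IKBA] * y[IKBA_P];
  dy[RELA_CPLX]= assoc - release;
  dy[RELA_N]   = release - assoc;
  dy[CANON_M]  = p[BASAL_TXN] + p[TXN_CANON] * Hr - p[DEG_MRNA] * y[CANON_M];
  dy[TRAF1_M]  = p[BASAL_TXN] + p[TXN_TRAF1] * Hr - p[DEG_MRNA] * y[TRAF1_M];
  dy[TRAF1_P]  = p[TLN_TRAF1] * traf1m_lag - p[DEG_TRAF1] * y[TRAF1_P] - capture;
  dy[NIK]      = p[NIK_SYNTH] - p[NIK_FAST_DEG] * y[NIK] - capture;
  dy[CPLX]     = capture - p[NIK_STABLE_DEG] * y[CPLX];
  dy[P100_M]   = p[BASAL_TXN] + p[TXN_P100] * Hr - p[DEG_MRNA] * y[P100_M];
  dy[P100_P]   = p[TLN_P100] * p100m_lag - proc - p[DEG_P100] * y[P100_P];
  dy[P52]      = proc - p[DEG_P52] * y[P52];
  dy[TNIP1_M]  = p[BASAL_TXN] + p[TXN_TNIP1] * Hp - p[DEG_MRNA] * y[TNIP1_M];
}

// Fixed-step RK4 with linear interpolation of the stored history buffer for
// the two lagged mRNA reads.  Returns a (n_out x NSP) matrix sampled on the
// dt_out grid; attribute "max_clamp" reports the largest negative excursion
// that was clamped to zero.
// [[Rcpp::export]]
NumericMatrix dde_rk4_cpp(NumericVector params, NumericVector y0,
                          double t_end, double dt_out, double h,
                          double amplitude, double onset) {
  if (params.size() != NPAR) stop("parameter vector has wrong length");
  if (y0.size() != NSP) stop("state vector has wrong length");

  // make h divide dt_out exactly so output lands on step points
  int sub = (int)std::ceil(dt_out / h - 1e-12);
  h = dt_out / sub;
  int n_out = (int)std::round(t_end / dt_out);
  int n_steps = n_out * sub;

  const double *p = REAL(params);
  std::vector<double> y(y0.begin(), y0.end());
  History hist;
  hist.h = h;
  hist.y0_traf1m = y[TRAF1_M];
  hist.y0_p100m = y[P100_M];
  hist.traf1m.reserve(n_steps + 1);
  hist.p100m.reserve(n_steps + 1);
  hist.traf1m.push_back(y[TRAF1_M]);
  hist.p100m.push_back(y[P100_M]);

  NumericMatrix out(n_out + 1, NSP);
  for (int j = 0; j < NSP; ++j) out(0, j) = y[j];

  double k1[NSP], k2[NSP], k3[NSP], k4[NSP], yt[NSP];
  double max_clamp = 0.0;

  for (int i = 0; i < n_steps; ++i) {
    double t = i * h;
    deriv(t, y.data(), k1, p, hist, amplitude, onset);
    for (int j = 0; j < NSP; ++j) yt[j] = y[j] + 0.5 * h * k1[j];
    deriv(t + 0.5 * h, yt, k2, p, hist, amplitude, onset);
    for (int j = 0; j < NSP; ++j) yt[j] = y[j] + 0.5 * h * k2[j];
    deriv(t + 0.5 * h, yt, k3, p, hist, amplitude, onset);
    for (int j = 0; j < NSP; ++j) yt[j] = y[j] + h * k3[j];
    deriv(t + h, yt, k4, p, hist, amplitude, onset);
    for (int j = 0; j < NSP; ++j) {
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (y[j] < 0.0) {
        if (-y[j] > max_clamp) max_clamp = -y[j];
        y[j] = 0.0;
      }
      if (!std::isfinite(y[j]))
        stop("non-finite state at t = %f min (species %d)", t + h, j + 1);
    }
    hist.traf1m.push_back(y[TRAF1_M]);
    hist.p100m.push_back(y[P100_M]);
    if ((i + 1) % sub == 0) {
      int r = (i + 1) / sub;
      for (int j = 0; j < NSP; ++j) out(r, j) = y[j];
    }
  }
  out.attr("max_clamp") = max_clamp;
  return out;
}
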