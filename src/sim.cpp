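// Fixed-step RK4 integrator for the eight-variable energy-balance model with
// daily food-deposition events and a ring buffer holding per-step consumed
// energy for the two trailing-average memory windows. The formulas mirror the
// pure R evaluators in R/model_core.R (cross-checked in the test suite).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parameter vector layout (keep in sync with PARAM_NAMES in R/parameters.R)
enum {
  P_THETA = 0, P_RHOF, P_RHOFFM, P_K, P_A, P_B, P_C, P_LAMBDA0,
  P_GHR_PROD, P_GHR_CLEAR, P_GLU_YIELD, P_GLU_CLEAR,
  P_LEP_PROD, P_LEP_CLEAR,
  P_H_GHR, P_H_LEP, P_H_GLU, P_H_RELAX,
  P_MEM_GAIN, P_TAU1, P_TAU2
};

// state layout
enum { S_F = 0, S_FFM, S_FAV, S_H, S_L, S_G, S_GHR, S_LAM, NSTATE };

static const double MIN_PER_DAY = 1440.0;

static inline double alpha_partition_c(double F, const double* p) {
  return p[P_A] / (1.0 + p[P_C] * F) +
         p[P_B] * p[P_K] / (p[P_K] + p[P_RHOF] * F);
}

// full-model right-hand side; m1/m2 are the window means (kJ/day), frozen
// over the step; memory_on toggles the lambda equation
static void rhs_full(const double* s, double* ds, const double* p,
                     double m1, double m2, bool memory_on) {
  const double F = s[S_F] > 0 ? s[S_F] : 0.0;
  const double FFM = s[S_FFM] > 0 ? s[S_FFM] : 0.0;
  const double Fav = s[S_FAV] > 0 ? s[S_FAV] : 0.0;
  const double H = s[S_H] > 0 ? s[S_H] : 0.0;
  const double L = s[S_L] > 0 ? s[S_L] : 0.0;
  const double G = s[S_G] > 0 ? s[S_G] : 0.0;
  const double Ghr = s[S_GHR] > 0 ? s[S_GHR] : 0.0;
  const double lam = s[S_LAM];

  const double q = std::min(H, Fav) / p[P_THETA];
  const double ee = lam * (p[P_RHOF] * F + p[P_RHOFFM] * FFM);
  const double E = q - ee;

  const double a = alpha_partition_c(F, p);
  double dF = E / (p[P_RHOF] + p[P_RHOFFM] * a);
  double dFFM = a * dF;
  // starvation guard: never draw an empty compartment below zero
  if (s[S_F] <= 0.0 && dF < 0.0) { dFFM += dF * p[P_RHOF] / p[P_RHOFFM]; dF = 0.0; }
  if (s[S_FFM] <= 0.0 && dFFM < 0.0) { dFFM = 0.0; }

  ds[S_F] = dF;
  ds[S_FFM] = dFFM;
  ds[S_FAV] = -q;
  ds[S_H] = p[P_H_GHR] * Ghr * std::exp(-G / p[P_H_GLU]) /
              (1.0 + p[P_H_LEP] * L) -
            p[P_H_RELAX] * G * H;
  ds[S_L] = p[P_LEP_PROD] * F - p[P_LEP_CLEAR] * L;
  ds[S_G] = p[P_GLU_YIELD] * q - p[P_GLU_CLEAR] * G;
  ds[S_GHR] = p[P_GHR_PROD] / (1.0 + p[P_THETA] * q) - p[P_GHR_CLEAR] * Ghr;
  ds[S_LAM] = memory_on
    ? (p[P_MEM_GAIN] / MIN_PER_DAY) * lam * (m1 - m2)
    : 0.0;
}

// [[Rcpp::export(name = ".sim_full_cpp")]]
List sim_full_cpp(NumericVector init, NumericVector params,
                  NumericVector sched_kj, LogicalVector unlimited,
                  double dt, int stride, bool memory_on,
                  double q_prehist, Nullable<NumericVector> prehist_buffer,
                  double unlimited_kj = 1.0e6) {
  if (init.size() != NSTATE) stop("init must have 8 entries");
  if (params.size() != 21) stop("params must have 21 entries");
  const int n_days = sched_kj.size();
  if (n_days < 1) stop("schedule must cover at least one day");
  if (dt <= 0 || std::fabs(MIN_PER_DAY / dt - std::round(MIN_PER_DAY / dt)) > 1e-9)
    stop("dt must divide 1440 minutes");
  const int steps_per_day = (int)std::round(MIN_PER_DAY / dt);
  if (stride < 1) stop("stride must be at least 1");

  const double* p = params.begin();
  const int n1 = (int)std::round(p[P_TAU1] * MIN_PER_DAY / dt);
  const int n2 = (int)std::round(p[P_TAU2] * MIN_PER_DAY / dt);
  if (n1 < 1 || n2 <= n1) stop("memory windows must satisfy 0 < tau1 < tau2");

  // ring buffer of per-step consumed energy covering the last tau2 days
  std::vector<double> buf(n2);
  if (prehist_buffer.isNotNull()) {
    NumericVector pb(prehist_buffer);
    if (pb.size() != n2) stop("prehist_buffer must have tau2*1440/dt entries");
    std::copy(pb.begin(), pb.end(), buf.begin());
  } else {
    std::fill(buf.begin(), buf.end(), q_prehist * dt);
  }
  double sum1 = 0.0, sum2 = 0.0;
  for (int i = 0; i < n2; ++i) sum2 += buf[i];
  for (int i = n2 - n1; i < n2; ++i) sum1 += buf[i];
  int pos = 0; // slot holding the oldest entry (next to overwrite)

  const long total_steps = (long)n_days * steps_per_day;
  const int n_rec = (int)(total_steps / stride) + 1;
  NumericMatrix rec(n_rec, NSTATE);
  NumericVector rec_t(n_rec), rec_consumed(n_rec);
  double cum_consumed = 0.0;
  NumericVector daily_consumed(n_days), daily_delivered(n_days),
      daily_removed(n_days);

  double s[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
      tmp[NSTATE];
  for (int i = 0; i < NSTATE; ++i) s[i] = init[i];

  int irec = 0;
  rec_t[irec] = 0.0;
  for (int i = 0; i < NSTATE; ++i) rec(irec, i) = s[i];
  ++irec;

  long step = 0;
  for (int d = 0; d < n_days; ++d) {
    // daily servicing: remove leftovers, then deposit the day's ration
    daily_removed[d] = s[S_FAV];
    s[S_FAV] = 0.0;
    const double deposit = unlimited[d] ? unlimited_kj : sched_kj[d];
    s[S_FAV] = deposit;
    daily_delivered[d] = deposit;

    double consumed_today = 0.0;
    for (int k = 0; k < steps_per_day; ++k, ++step) {
      const double m1 = sum1 * MIN_PER_DAY / (n1 * dt);
      const double m2 = sum2 * MIN_PER_DAY / (n2 * dt);
      const double fav_before = s[S_FAV];

      rhs_full(s, k1, p, m1, m2, memory_on);
      for (int i = 0; i < NSTATE; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
      rhs_full(tmp, k2, p, m1, m2, memory_on);
      for (int i = 0; i < NSTATE; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
      rhs_full(tmp, k3, p, m1, m2, memory_on);
      for (int i = 0; i < NSTATE; ++i) tmp[i] = s[i] + dt * k3[i];
      rhs_full(tmp, k4, p, m1, m2, memory_on);
      for (int i = 0; i < NSTATE; ++i)
        s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

      // non-negativity clamps (hunger floor; availability cannot undershoot)
      if (s[S_FAV] < 0.0) s[S_FAV] = 0.0;
      if (s[S_H] < 0.0) s[S_H] = 0.0;
      if (s[S_F] < 0.0) s[S_F] = 0.0;
      if (s[S_FFM] < 0.0) s[S_FFM] = 0.0;
      if (s[S_L] < 0.0) s[S_L] = 0.0;
      if (s[S_G] < 0.0) s[S_G] = 0.0;
      if (s[S_GHR] < 0.0) s[S_GHR] = 0.0;

      for (int i = 0; i < NSTATE; ++i)
        if (!std::isfinite(s[i]))
          stop("state blow-up (non-finite) at t = %.1f min", (step + 1) * dt);

      // exact availability bookkeeping: consumed = what left the trough
      const double consumed = fav_before - s[S_FAV];
      consumed_today += consumed;
      cum_consumed += consumed;

      // ring-buffer update for the memory windows
      const int leave1 = (pos - n1 + n2) % n2;
      sum1 += consumed - buf[leave1];
      sum2 += consumed - buf[pos];
      buf[pos] = consumed;
      pos = (pos + 1) % n2;

      if ((step + 1) % stride == 0) {
        rec_t[irec] = (step + 1) * dt;
        for (int i = 0; i < NSTATE; ++i) rec(irec, i) = s[i];
        rec_consumed[irec] = cum_consumed;
        ++irec;
      }
    }
    daily_consumed[d] = consumed_today;
  }

  // final buffer in chronological order (oldest first), for continuations
  NumericVector final_buf(n2);
  for (int i = 0; i < n2; ++i) final_buf[i] = buf[(pos + i) % n2];
  NumericVector final_state(NSTATE);
  for (int i = 0; i < NSTATE; ++i) final_state[i] = s[i];

  return List::create(
      _["time_min"] = rec_t, _["states"] = rec,
      _["cum_consumed"] = rec_consumed,
      _["daily_consumed"] = daily_consumed,
      _["daily_delivered"] = daily_delivered,
      _["daily_removed"] = daily_removed,
      _["final_state"] = final_state, _["final_buffer"] = final_buf);
}

// body-composition subsystem driven by a known daily intake series (kJ/day),
// with a constant rate of energy expenditure; used by estimation step 1
// [[Rcpp::export(name = ".sim_bodycomp_cpp")]]
NumericMatrix sim_bodycomp_cpp(double F0, double FFM0, NumericVector params,
                               double lambda, NumericVector q_daily,
                               double dt) {
  if (params.size() != 21) stop("params must have 21 entries");
  const double* p = params.begin();
  const int n_days = q_daily.size();
  if (dt <= 0 || std::fabs(MIN_PER_DAY / dt - std::round(MIN_PER_DAY / dt)) > 1e-9)
    stop("dt must divide 1440 minutes");
  const int steps_per_day = (int)std::round(MIN_PER_DAY / dt);

  NumericMatrix out(n_days + 1, 2);
  double F = F0, FFM = FFM0;
  out(0, 0) = F; out(0, 1) = FFM;

  for (int d = 0; d < n_days; ++d) {
    const double q = q_daily[d] / MIN_PER_DAY; // kJ/min, constant over the day
    for (int k = 0; k < steps_per_day; ++k) {
      double kF[4], kM[4];
      double Fi = F, Mi = FFM;
      for (int stage = 0; stage < 4; ++stage) {
        const double Fc = Fi > 0 ? Fi : 0.0, Mc = Mi > 0 ? Mi : 0.0;
        const double E = q - lambda * (p[P_RHOF] * Fc + p[P_RHOFFM] * Mc);
        const double a = alpha_partition_c(Fc, p);
        kF[stage] = E / (p[P_RHOF] + p[P_RHOFFM] * a);
        kM[stage] = a * kF[stage];
        const double w = (stage < 2) ? 0.5 : 1.0;
        if (stage < 3) { Fi = F + w * dt * kF[stage]; Mi = FFM + w * dt * kM[stage]; }
      }
      F += dt / 6.0 * (kF[0] + 2 * kF[1] + 2 * kF[2] + kF[3]);
      FFM += dt / 6.0 * (kM[0] + 2 * kM[1] + 2 * kM[2] + kM[3]);
      if (F < 0) F = 0;
      if (FFM < 0) FFM = 0;
      if (!std::isfinite(F) || !std::isfinite(FFM))
        stop("state blow-up in body-composition subsystem (day %d)", d + 1);
    }
    out(d + 1, 0) = F; out(d + 1, 1) = FFM;
  }
  return out;
}
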