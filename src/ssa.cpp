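#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of the four-reaction network
//   mRNA birth   : rate c * tau(t)   (tau(t) piecewise constant, one switch)
//   mRNA death   : rate delta_M * M
//   protein birth: rate alpha * M
//   protein death: rate delta_P * P
// The time dependence of tau is handled exactly: if a proposed waiting time
// crosses the changepoint s, the clock is advanced to s and the waiting time
// re-drawn with on-phase propensities (valid by memorylessness for a
// piecewise-constant rate).  Initial state M = P = 0 at t = 0 (transfection).

struct SsaState {
  double t; long M, P;
};

static inline double cur_tau(double t, double s, double tau_off, double tau_on) {
  return (t >= s) ? tau_on : tau_off;
}

// Advance one reaction event (or to the switch, or to t_end).  Returns false
// when no further event can occur before t_end.
static inline bool ssa_step(SsaState &st, double t_end,
                            double tau_off, double tau_on, double s,
                            double alpha, double dM, double dP, double c) {
  for (;;) {
    double tau = cur_tau(st.t, s, tau_off, tau_on);
    double a1 = c * tau, a2 = dM * st.M, a3 = alpha * st.M, a4 = dP * st.P;
    double a0 = a1 + a2 + a3 + a4;
    if (a0 <= 0.0) {
      if (st.t < s && s < t_end) { st.t = s; continue; }
      st.t = t_end;
      return false;
    }
    double dt = R::exp_rand() / a0;
    if (st.t < s && st.t + dt >= s) { st.t = s; continue; }
    double tn = st.t + dt;
    if (tn > t_end) { st.t = t_end; return false; }
    st.t = tn;
    double u = R::unif_rand() * a0;
    if (u < a1) st.M++;
    else if (u < a1 + a2) st.M--;
    else if (u < a1 + a2 + a3) st.P++;
    else st.P--;
    return true;
  }
}

// [[Rcpp::export]]
NumericMatrix ssa_sample_cpp(NumericVector sample_times,
                             double tau_off, double tau_on, double s,
                             double alpha, double delta_M, double delta_P,
                             double copy_number, double event_cap) {
  int n = sample_times.size();
  NumericMatrix out(n, 2);
  SsaState st = {0.0, 0, 0};
  double t_end = sample_times[n - 1];
  int idx = 0;
  double events = 0.0;
  for (;;) {
    double t_prev = st.t;
    long Mp = st.M, Pp = st.P;
    bool more = ssa_step(st, t_end, tau_off, tau_on, s,
                         alpha, delta_M, delta_P, copy_number);
    // state over [t_prev, st.t) was (Mp, Pp)
    while (idx < n && sample_times[idx] < st.t) {
      out(idx, 0) = (double)Mp; out(idx, 1) = (double)Pp; idx++;
    }
    if (!more) break;
    if (++events > event_cap)
      stop("Gillespie event cap exceeded (runaway trajectory?)");
  }
  while (idx < n) { out(idx, 0) = (double)st.M; out(idx, 1) = (double)st.P; idx++; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ssa_events_cpp(double t_end,
                             double tau_off, double tau_on, double s,
                             double alpha, double delta_M, double delta_P,
                             double copy_number, double event_cap) {
  std::vector<double> ts, Ms, Ps;
  SsaState st = {0.0, 0, 0};
  ts.push_back(0.0); Ms.push_back(0); Ps.push_back(0);
  double events = 0.0;
  for (;;) {
    bool more = ssa_step(st, t_end, tau_off, tau_on, s,
                         alpha, delta_M, delta_P, copy_number);
    if (!more) break;
    ts.push_back(st.t); Ms.push_back((double)st.M); Ps.push_back((double)st.P);
    if (++events > event_cap)
      stop("Gillespie event cap exceeded (runaway trajectory?)");
  }
  int n = ts.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) { out(i, 0) = ts[i]; out(i, 1) = Ms[i]; out(i, 2) = Ps[i]; }
  colnames(out) = CharacterVector::create("time", "M", "P");
  return out;
}
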