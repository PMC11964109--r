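#include <Rcpp.h>
using namespace Rcpp;

// Rate-coding functions. Drive I and thresholds are force-like [N], rates in Hz.
// Linear: r rises from 0 at delta to rmax over the recruitment bandwidth Delta.
static inline double rate_linear(double I, double delta, double Delta,
                                 double rmax) {
  if (I <= delta) return 0.0;
  if (I >= delta + Delta) return rmax;
  return rmax * (I - delta) / Delta;
}

// Logarithmic: steady-state rate of a leaky integrate-and-fire motor neuron,
// r = (1/rmax - kr * ln(1 - delta/I))^-1 with kr = d1 * Rr^((i/N)^d2) / delta.
// The ln term is negative for I > delta, so 1/r > 1/rmax and r < rmax always.
static inline double rate_log(double I, double delta, double kr, double rmax) {
  if (I <= delta * (1.0 + 1e-12)) return 0.0;
  double inv = 1.0 / rmax - kr * std::log(1.0 - delta / I);
  if (inv <= 0.0) return rmax; // unreachable under admissible parameters
  double r = 1.0 / inv;
  return (r > rmax) ? rmax : r;
}

// Per-MU impulse-train generator state. Impulses fire on grid points; the
// carried correction C compensates the discretization of the inter-impulse
// interval via linear interpolation of the continuous firing time.
struct TrainState {
  bool fired;
  double phi_prev; // last firing time
  double C_prev;   // carried timing correction
  double r_prev;   // rate at the previous grid step
  TrainState() : fired(false), phi_prev(0.0), C_prev(0.0), r_prev(0.0) {}
};

// Advance one grid step; returns true if an impulse fires at time t.
static inline bool train_step(TrainState &st, double t, double r, double dt) {
  bool fire = false;
  if (r > 0.0) {
    if (!st.fired) {
      // first impulse at the first instant with positive rate
      fire = true;
      st.fired = true;
      st.phi_prev = t;
      st.C_prev = 0.0;
    } else if (t >= st.phi_prev + 1.0 / r - st.C_prev - 1e-9) {
      // 1 ns slack absorbs rounding of t = k*dt when the target interval
      // is an exact multiple of the grid step
      fire = true;
      double C = 0.0;
      if (st.r_prev > 0.0) {
        double den = 1.0 / st.r_prev - 1.0 / r + dt;
        if (den > 1e-12) {
          double num = 1.0 / st.r_prev + st.phi_prev - t + dt;
          C = dt * (1.0 - num / den);
          if (C > dt) C = dt;
          if (C < -dt) C = -dt;
        }
      }
      st.phi_prev = t;
      st.C_prev = C;
    }
  }
  st.r_prev = r;
  return fire;
}

//' @noRd
// [[Rcpp::export]]
NumericVector build_train_cpp(NumericVector rates, double dt) {
  int n = rates.size();
  TrainState st;
  std::vector<double> phi;
  for (int k = 0; k < n; ++k) {
    if (train_step(st, k * dt, rates[k], dt)) phi.push_back(k * dt);
  }
  return wrap(phi);
}

// Linear third-order twitch cascade advanced by the exact one-step transition
// matrix Ad; an impulse enters as a unit jump on the first state at its grid
// time, the (unit-peak-scaled) third state is the unnormalized activation.
// [[Rcpp::export]]
NumericVector twitch_filter_cpp(IntegerVector impulse_steps, int n_steps,
                                NumericMatrix Ad, double gain) {
  NumericVector a(n_steps);
  std::vector<char> imp(n_steps, 0);
  for (int j = 0; j < impulse_steps.size(); ++j) {
    int k = impulse_steps[j];
    if (k >= 0 && k < n_steps) imp[k] = 1;
  }
  double x1 = 0.0, x2 = 0.0, x3 = 0.0;
  for (int k = 0; k < n_steps; ++k) {
    double n1 = Ad(0, 0) * x1;
    double n2 = Ad(1, 0) * x1 + Ad(1, 1) * x2;
    double n3 = Ad(2, 0) * x1 + Ad(2, 1) * x2 + Ad(2, 2) * x3;
    x1 = n1; x2 = n2; x3 = n3;
    if (imp[k]) x1 += 1.0;
    a[k] = gain * x3;
  }
  return a;
}

// Full pool simulation: neural drive -> rates -> impulse trains -> activation
// -> forces, one pass over the grid. With gamma != 0 the drive receives the
// idealized feedback error Fd(t_k) - FM(t_{k-1}) (one-step delay breaks the
// algebraic loop); with gamma == 0 the result is identical to the open-loop
// pipeline.
// [[Rcpp::export]]
List sim_pool_cpp(NumericVector Iff, NumericVector Fd, NumericVector g,
                  double gamma, NumericVector delta, NumericVector Delta,
                  NumericVector fmax, NumericVector rmax, int rate_family,
                  NumericVector kr, NumericMatrix Ad, double gain,
                  NumericVector amax, double dt, bool full_output) {
  int nT = Iff.size();
  int N = delta.size();
  if (Fd.size() != nT || g.size() != nT)
    stop("Iff, Fd and g must share one time grid");

  std::vector<TrainState> st(N);
  std::vector<double> x1(N, 0.0), x2(N, 0.0), x3(N, 0.0);
  std::vector<std::vector<double> > phi;
  if (full_output) phi.resize(N);

  NumericVector FM(nT), Ivec(nT), Ifb(nT);
  IntegerVector n_imp(N);
  NumericMatrix rates_m, abar_m;
  if (full_output) {
    rates_m = NumericMatrix(nT, N);
    abar_m = NumericMatrix(nT, N);
  }

  const double a11 = Ad(0, 0), a21 = Ad(1, 0), a22 = Ad(1, 1);
  const double a31 = Ad(2, 0), a32 = Ad(2, 1), a33 = Ad(2, 2);

  double FM_prev = 0.0;
  for (int k = 0; k < nT; ++k) {
    double t = k * dt;
    double e = Fd[k] - FM_prev;
    double I = Iff[k] + gamma * e;
    double F = 0.0;
    for (int i = 0; i < N; ++i) {
      double r = (rate_family == 0)
                     ? rate_linear(I, delta[i], Delta[i], rmax[i])
                     : rate_log(I, delta[i], kr[i], rmax[i]);
      bool fire = train_step(st[i], t, r, dt);
      double n1 = a11 * x1[i];
      double n2 = a21 * x1[i] + a22 * x2[i];
      double n3 = a31 * x1[i] + a32 * x2[i] + a33 * x3[i];
      x1[i] = n1; x2[i] = n2; x3[i] = n3;
      if (fire) {
        x1[i] += 1.0;
        n_imp[i]++;
        if (full_output) phi[i].push_back(t);
      }
      double abar = gain * x3[i] / amax[i];
      if (abar > 1.0) abar = 1.0;
      if (abar < 0.0) abar = 0.0;
      F += fmax[i] * g[k] * abar;
      if (full_output) {
        rates_m(k, i) = r;
        abar_m(k, i) = abar;
      }
    }
    if (!R_finite(F)) stop("non-finite force at step %d", k + 1);
    FM[k] = F;
    Ivec[k] = I;
    Ifb[k] = e;
    FM_prev = F;
  }

  List out = List::create(_["FM"] = FM, _["I"] = Ivec, _["Ifb"] = Ifb,
                          _["n_impulses"] = n_imp);
  if (full_output) {
    List trains(N);
    for (int i = 0; i < N; ++i) trains[i] = wrap(phi[i]);
    out["rates"] = rates_m;
    out["abar"] = abar_m;
    out["trains"] = trains;
  }
  return out;
}
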