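#include <Rcpp.h>
using namespace Rcpp;

// Two-neuron robust mutual-inhibition decision network.
//
//   tau dT/dt = -T + S(P_T),  P_T = E_T - k * N * D
//   tau dD/dt = -D + S(P_D),  P_D = E_D - k * (N-1) * D - k * T
//   S(P) = M P^2 / (sigma^2 + P^2) for P >= 0, else 0
//
// Robust variant: while a neuron's information threshold P is negative
// (the neuron is disconnected) positive activity holds (derivative 0) and
// only non-positive activity decays. The original variant lets activity
// decay exponentially whenever S(P) = 0. Integrated with classical RK4;
// the external inputs are zero-order held within each input sample.

static inline double mm_gain_c(double P, double M, double sigma) {
  if (P < 0.0) return 0.0;
  return M * P * P / (sigma * sigma + P * P);
}

static inline double drift(double A, double P, double tau, double M,
                           double sigma, bool robust) {
  if (robust && P < 0.0) {
    return (A > 0.0) ? 0.0 : -A / tau;
  }
  return (-A + mm_gain_c(P, M, sigma)) / tau;
}

struct Deriv {
  double dT, dD;
};

static inline Deriv f_td(double T, double D, double ET, double ED, double k,
                         int N, double tau, double M, double sigma,
                         bool robust) {
  double PT = ET - k * N * D;
  double PD = ED - k * (N - 1) * D - k * T;
  Deriv d;
  d.dT = drift(T, PT, tau, M, sigma, robust);
  d.dD = drift(D, PD, tau, M, sigma, robust);
  return d;
}

// One RK4 step of size h with inputs held at (ET, ED).
static inline void rk4_step(double &T, double &D, double ET, double ED,
                            double k, int N, double tau, double M,
                            double sigma, bool robust, double h) {
  Deriv k1 = f_td(T, D, ET, ED, k, N, tau, M, sigma, robust);
  Deriv k2 = f_td(T + 0.5 * h * k1.dT, D + 0.5 * h * k1.dD, ET, ED, k, N,
                  tau, M, sigma, robust);
  Deriv k3 = f_td(T + 0.5 * h * k2.dT, D + 0.5 * h * k2.dD, ET, ED, k, N,
                  tau, M, sigma, robust);
  Deriv k4 = f_td(T + h * k3.dT, D + h * k3.dD, ET, ED, k, N, tau, M,
                  sigma, robust);
  T += h / 6.0 * (k1.dT + 2.0 * k2.dT + 2.0 * k3.dT + k4.dT);
  D += h / 6.0 * (k1.dD + 2.0 * k2.dD + 2.0 * k3.dD + k4.dD);
}

// Integrate many trials at once. ER / EL: n_samples x n_trials matrices of
// the summed right-bank / left-bank inputs sampled every dt_in seconds;
// n_sub RK4 substeps per sample. The T-label (which bank enters the
// T-equation) is the first bank whose input exceeds eps in that trial.
// Returns per-trial: winner side (1 = right, 2 = left, 0 = tie/undecided),
// final activities, peak activity times of each bank's neuron, and the
// T-label used.
// [[Rcpp::export]]
List solve_decision_block(NumericMatrix ER, NumericMatrix EL, double dt_in,
                          int n_sub, double tau, double k, double M,
                          double sigma, int N, bool robust,
                          double eps = 1e-9) {
  const int ns = ER.nrow();
  const int nt = ER.ncol();
  if (EL.nrow() != ns || EL.ncol() != nt)
    stop("input matrices must have identical dimensions");
  const double h = dt_in / n_sub;
  if (h >= tau)
    warning("RK4 step (%g s) >= tau (%g s): integration may be unstable",
            h, tau);

  IntegerVector winner(nt), t_label(nt);
  NumericVector actR(nt), actL(nt), peakR(nt), peakL(nt);

  for (int j = 0; j < nt; ++j) {
    // label T: first bank excited
    int lab = 0; // 1 = right bank is T, 2 = left bank is T
    for (int i = 0; i < ns && lab == 0; ++i) {
      bool r = ER(i, j) > eps, l = EL(i, j) > eps;
      if (r && l) lab = (ER(i, j) >= EL(i, j)) ? 1 : 2;
      else if (r) lab = 1;
      else if (l) lab = 2;
    }
    if (lab == 0) lab = 1;
    t_label[j] = lab;

    double T = 0.0, D = 0.0; // T = activity of the lab bank
    double pkT = 0.0, pkD = 0.0, tpT = NA_REAL, tpD = NA_REAL;
    for (int i = 0; i < ns; ++i) {
      double ET = (lab == 1) ? ER(i, j) : EL(i, j);
      double ED = (lab == 1) ? EL(i, j) : ER(i, j);
      if (!R_finite(ET) || !R_finite(ED)) stop("non-finite decision input");
      for (int s = 0; s < n_sub; ++s) {
        rk4_step(T, D, ET, ED, k, N, tau, M, sigma, robust, h);
        double t_now = i * dt_in + (s + 1) * h;
        if (T > pkT) { pkT = T; tpT = t_now; }
        if (D > pkD) { pkD = D; tpD = t_now; }
      }
    }
    double aR = (lab == 1) ? T : D;
    double aL = (lab == 1) ? D : T;
    actR[j] = aR; actL[j] = aL;
    peakR[j] = (lab == 1) ? tpT : tpD;
    peakL[j] = (lab == 1) ? tpD : tpT;
    if (aR < eps && aL < eps) winner[j] = 0;       // undecided
    else if (aR == aL) winner[j] = 0;              // exact tie
    else winner[j] = (aR > aL) ? 1 : 2;
  }
  return List::create(_["winner"] = winner, _["act_right"] = actR,
                      _["act_left"] = actL, _["peak_right"] = peakR,
                      _["peak_left"] = peakL, _["t_label"] = t_label);
}
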