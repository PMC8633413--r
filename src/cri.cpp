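#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled regulatory interaction system:
//   dH/dt = aH (1 - H/KH) H + aH bHD H D
//   dD/dt = aD (1 - D/KD) D + aD bDH D H
// theta = (aH, KH, bHD, aD, KD, bDH) on the natural scale.
static inline void cri_deriv(const double *th, double H, double D,
                             double &dH, double &dD) {
  dH = th[0] * (1.0 - H / th[1]) * H + th[0] * th[2] * H * D;
  dD = th[3] * (1.0 - D / th[4]) * D + th[3] * th[5] * D * H;
}

// One classic RK4 step of size h from (H, D); returns false on non-finite state.
static inline bool rk4_step(const double *th, double h, double &H, double &D) {
  double k1H, k1D, k2H, k2D, k3H, k3D, k4H, k4D;
  cri_deriv(th, H, D, k1H, k1D);
  cri_deriv(th, H + 0.5 * h * k1H, D + 0.5 * h * k1D, k2H, k2D);
  cri_deriv(th, H + 0.5 * h * k2H, D + 0.5 * h * k2D, k3H, k3D);
  cri_deriv(th, H + h * k3H, D + h * k3D, k4H, k4D);
  H += h / 6.0 * (k1H + 2.0 * k2H + 2.0 * k3H + k4H);
  D += h / 6.0 * (k1D + 2.0 * k2D + 2.0 * k3D + k4D);
  return R_finite(H) && R_finite(D);
}

// Integrate between consecutive requested times with a fixed internal step
// (the last sub-step of each interval is shortened to land exactly on the
// requested time). Writes H then D into out (length 2*T). Returns the index
// of the first time at which the state went non-finite, or -1 on success.
static int rk4_solve(const double *th, double H0, double D0,
                     const double *times, int T, double step, double *out) {
  double H = H0, D = D0;
  out[0] = H;
  out[T] = D;
  for (int i = 1; i < T; ++i) {
    double span = times[i] - times[i - 1];
    int nsub = (int)std::ceil(span / step - 1e-9);
    if (nsub < 1) nsub = 1;
    double h = span / nsub;
    for (int k = 0; k < nsub; ++k) {
      if (!rk4_step(th, h, H, D)) return i;
    }
    out[i] = H;
    out[T + i] = D;
  }
  return -1;
}

// [[Rcpp::export]]
NumericMatrix cri_rk4_cpp(NumericVector theta, double H0, double D0,
                          NumericVector times, double step) {
  int T = times.size();
  std::vector<double> out(2 * T);
  int bad = rk4_solve(REAL(theta), H0, D0, REAL(times), T, step, out.data());
  if (bad >= 0)
    stop("CRI integration produced a non-finite state near t = %f",
         times[bad]);
  NumericMatrix res(T, 2);
  for (int i = 0; i < T; ++i) {
    res(i, 0) = out[i];
    res(i, 1) = out[T + i];
  }
  return res;
}

// 0.5 * sum_i (y_i - mu)' Q (y_i - mu) for n individuals sharing mean mu,
// expanded as 0.5 * (s2 - 2 mu'Q s1 + n mu'Q mu) with s1 = colSums(Y) and
// s2 = sum_i y_i' Q y_i precomputed. mu is the stacked RK4 solution
// (trait 1 at all times, then trait 2). Returns a large penalty for invalid
// parameters or a diverging trajectory so that simplex search stays inside
// the feasible region.
// [[Rcpp::export]]
double cri_negq_cpp(NumericVector theta, double H0, double D0,
                    NumericVector times, double step, NumericMatrix Q,
                    NumericVector s1, double s2, double n) {
  const double BIG = 1e12;
  const double *th = REAL(theta);
  for (int j = 0; j < 6; ++j)
    if (!R_finite(th[j])) return BIG;
  if (th[0] <= 0 || th[1] <= 0 || th[3] <= 0 || th[4] <= 0) return BIG;
  int T = times.size();
  int m = 2 * T;
  std::vector<double> mu(m);
  if (rk4_solve(th, H0, D0, REAL(times), T, step, mu.data()) >= 0) return BIG;
  // q1 = mu'Q s1, q2 = mu'Q mu (Q symmetric)
  const double *q = REAL(Q);
  const double *s = REAL(s1);
  double q1 = 0.0, q2 = 0.0;
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    const double *col = q + (size_t)j * m;
    for (int i = 0; i < m; ++i) acc += col[i] * mu[i];
    q1 += acc * s[j];
    q2 += acc * mu[j];
  }
  double val = 0.5 * (s2 - 2.0 * q1 + n * q2);
  if (!R_finite(val)) return BIG;
  return val;
}
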