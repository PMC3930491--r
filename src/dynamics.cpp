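#include <Rcpp.h>
using namespace Rcpp;

// Quadratic Naka-Rushton signal with threshold gamma and shape beta.
static inline double sig(double x, double gamma, double beta2) {
  double h = x - gamma;
  if (h <= 0.0) return 0.0;
  double h2 = h * h;
  return h2 / (beta2 + h2);
}

// Integrates the MSTd shunting recurrent competitive field across a trial.
// S: match scores, n_units x n_frames (held constant within each frame
// interval). Units are grouped into CoM hypercolumns (com_index, 1-based)
// and orientation wings (orient: +1 CCW, -1 CW, 0 radial). Three
// inhibition pools: spiral_space (same CoM, same wing incl. radial,
// different unit), orientation (same CoM, opposite wing), spatial (other
// CoMs, weight W). pool_mean divides each pool by its size. Explicit Euler
// with `substeps` steps per frame and local step subdivision whenever a
// step would move any unit by more than a quarter of the ceiling U.
// Returns the activation history sampled at the end of each frame.
// [[Rcpp::export]]
NumericMatrix cpp_mstd_integrate(const NumericMatrix& S,
                                 const IntegerVector& com_index,
                                 const IntegerVector& orient,
                                 int n_com, int n_pattern,
                                 int n_pos, int n_neg, int n_zero,
                                 double A, double D, double U, double W,
                                 double gamma, double gamma_r, double beta,
                                 bool lesion_spiral, bool lesion_orient,
                                 bool lesion_spatial, bool pool_mean,
                                 double frame_dt, int substeps) {
  const int n_units = S.nrow();
  const int n_frames = S.ncol();
  const double beta2 = beta * beta;
  NumericMatrix zh(n_units, n_frames);
  std::vector<double> z(n_units, 0.0), f(n_units), fS(n_units), dz(n_units);
  std::vector<double> sum_pos(n_com), sum_neg(n_com), sum_zero(n_com);

  const double den_spatial = pool_mean ?
    std::max(1.0, double(n_com - 1) * n_pattern) : 1.0;
  const double den_sp_pos = pool_mean ?
    std::max(1, n_pos + n_zero - 1) : 1.0;
  const double den_sp_neg = pool_mean ?
    std::max(1, n_neg + n_zero - 1) : 1.0;
  const double den_sp_zero = pool_mean ? std::max(1, n_pattern - 1) : 1.0;
  const double den_or_pos = pool_mean ? std::max(1, n_neg) : 1.0;
  const double den_or_neg = pool_mean ? std::max(1, n_pos) : 1.0;

  const double h0 = frame_dt / substeps;
  const double max_move = 0.25 * U;

  for (int fr = 0; fr < n_frames; ++fr) {
    for (int c = 0; c < n_units; ++c) fS[c] = sig(S(c, fr), gamma, beta2);
    for (int k = 0; k < substeps; ++k) {
      double remaining = h0;
      int guard = 0;
      while (remaining > 1e-12 && guard++ < 64) {
        // pool bookkeeping at current state
        std::fill(sum_pos.begin(), sum_pos.end(), 0.0);
        std::fill(sum_neg.begin(), sum_neg.end(), 0.0);
        std::fill(sum_zero.begin(), sum_zero.end(), 0.0);
        double total = 0.0;
        for (int c = 0; c < n_units; ++c) {
          f[c] = sig(z[c], gamma_r, beta2);
          int j = com_index[c] - 1;
          if (orient[c] > 0) sum_pos[j] += f[c];
          else if (orient[c] < 0) sum_neg[j] += f[c];
          else sum_zero[j] += f[c];
          total += f[c];
        }
        double maxdz = 0.0;
        for (int c = 0; c < n_units; ++c) {
          int j = com_index[c] - 1;
          double G = sum_pos[j] + sum_neg[j] + sum_zero[j];
          double spiral, orientp, den_sp, den_or;
          if (orient[c] > 0) {
            spiral = sum_pos[j] + sum_zero[j] - f[c];
            orientp = sum_neg[j];
            den_sp = den_sp_pos; den_or = den_or_pos;
          } else if (orient[c] < 0) {
            spiral = sum_neg[j] + sum_zero[j] - f[c];
            orientp = sum_pos[j];
            den_sp = den_sp_neg; den_or = den_or_neg;
          } else {
            spiral = G - f[c];
            orientp = 0.0;
            den_sp = den_sp_zero; den_or = 1.0;
          }
          double spatial = total - G;
          double inhib = 0.0;
          if (!lesion_spiral) inhib += spiral / den_sp;
          if (!lesion_orient) inhib += orientp / den_or;
          if (!lesion_spatial) inhib += W * spatial / den_spatial;
          dz[c] = A * (-D * z[c] + (U - z[c]) * (f[c] + fS[c]) -
                       z[c] * inhib);
          double a = std::fabs(dz[c]);
          if (a > maxdz) maxdz = a;
        }
        double h = remaining;
        if (maxdz * h > max_move) h = max_move / maxdz;
        for (int c = 0; c < n_units; ++c) {
          double v = z[c] + h * dz[c];
          if (v < 0.0) v = 0.0;
          if (v > U) v = U;
          z[c] = v;
        }
        remaining -= h;
      }
    }
    for (int c = 0; c < n_units; ++c) zh(c, fr) = z[c];
  }
  return zh;
}
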