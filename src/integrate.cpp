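#include <Rcpp.h>
#include <cmath>

// Fixed-step integrators for the SAC bursting model.
//
// Parameter vector layout (see param_vector() on the R side):
//  0 C_m  1 g_L  2 g_C  3 g_K  4 g_sAHP
//  5 V_L  6 V_C  7 V_K  8 V_1  9 V_2  10 V_3  11 V_4
// 12 tau_N 13 tau_R 14 tau_S 15 tau_C
// 16 delta_C 17 alpha_S 18 alpha_C 19 alpha_R 20 H_X 21 C_0
//
// Units: ms, mV, pF, pA, nS, nM throughout (nS*mV = pA, pA/pF = mV/ms).

// [[Rcpp::export(name = ".sim_full_cpp")]]
Rcpp::List sim_full_cpp(Rcpp::NumericVector par,
                        Rcpp::NumericMatrix segments, // cols: t0, t1, I_ext
                        double T, double dt, double sigma,
                        Rcpp::NumericVector init, // V N C S R
                        int stride) {
  const double C_m = par[0], g_L = par[1], g_C = par[2], g_K = par[3],
               g_sAHP = par[4], V_L = par[5], V_C = par[6], V_K = par[7],
               V_1 = par[8], V_2 = par[9], V_3 = par[10], V_4 = par[11],
               tau_N = par[12], tau_R = par[13], tau_S = par[14],
               tau_C = par[15], delta_C = par[16], alpha_S = par[17],
               alpha_C = par[18], alpha_R = par[19], H_X = par[20],
               C_0 = par[21];

  const long nstep = (long)std::llround(T / dt);
  const long nout = nstep / stride + 1;
  Rcpp::NumericMatrix out(nout, 6); // t V N C S R

  double V = init[0], N = init[1], C = init[2], S = init[3], R = init[4];
  const double noise_amp = sigma * std::sqrt(dt) / C_m;
  const double kC = alpha_C / H_X;

  long nseg = segments.nrow();
  long seg = 0;
  long nclamp = 0;
  long row = 0;

  Rcpp::RNGScope rng; // draws flow from R's seeded generator

  out(0, 0) = 0.0; out(0, 1) = V; out(0, 2) = N;
  out(0, 3) = C;   out(0, 4) = S; out(0, 5) = R;
  ++row;

  for (long i = 0; i < nstep; ++i) {
    const double t = i * dt;
    while (seg + 1 < nseg && t >= segments(seg, 1)) ++seg;
    const double I_ext = segments(seg, 2);

    const double M_inf = 0.5 * (1.0 + std::tanh((V - V_1) / V_2));
    const double N_inf = 0.5 * (1.0 + std::tanh((V - V_3) / V_4));
    const double Lam   = std::cosh((V - V_3) / (2.0 * V_4));

    const double I_C = -g_C * M_inf * (V - V_C);
    const double Itot_V = -g_L * (V - V_L) + I_C - g_K * N * (V - V_K)
                          - g_sAHP * R * R * R * R * (V - V_K) + I_ext;

    const double dV = Itot_V / C_m * dt
                      + (sigma > 0.0 ? noise_amp * norm_rand() : 0.0);
    const double dN = Lam * (N_inf - N) / tau_N * dt;
    const double dC = (-kC * C + C_0 + delta_C * I_C) / tau_C * dt;
    const double C4 = C * C * C * C;
    const double dS = (alpha_S * C4 * (1.0 - S) - S) / tau_S * dt;
    const double dR = (alpha_R * S * (1.0 - R) - R) / tau_R * dt;

    V += dV; N += dN; C += dC; S += dS; R += dR;

    // Drift preserves [0,1] and C>=0 exactly; only discretization can
    // overshoot. Clamp and count.
    if (N < 0.0) { N = 0.0; ++nclamp; } else if (N > 1.0) { N = 1.0; ++nclamp; }
    if (S < 0.0) { S = 0.0; ++nclamp; } else if (S > 1.0) { S = 1.0; ++nclamp; }
    if (R < 0.0) { R = 0.0; ++nclamp; } else if (R > 1.0) { R = 1.0; ++nclamp; }
    if (C < 0.0) { C = 0.0; ++nclamp; }

    if (!std::isfinite(V) || !std::isfinite(C))
      Rcpp::stop("non-finite state at step %ld (t = %.3f ms): V = %g, C = %g",
                 i + 1, t + dt, V, C);

    if ((i + 1) % stride == 0 && row < nout) {
      out(row, 0) = (i + 1) * dt;
      out(row, 1) = V; out(row, 2) = N; out(row, 3) = C;
      out(row, 4) = S; out(row, 5) = R;
      ++row;
    }
  }

  return Rcpp::List::create(Rcpp::Named("samples") = out,
                            Rcpp::Named("n_clamped") = (double)nclamp,
                            Rcpp::Named("n_steps") = (double)nstep);
}

// Deterministic fast (V, N) subsystem at frozen I_tot.
// [[Rcpp::export(name = ".sim_fast_cpp")]]
Rcpp::NumericMatrix sim_fast_cpp(Rcpp::NumericVector par, double I_tot,
                                 double T, double dt,
                                 Rcpp::NumericVector init, int stride) {
  const double C_m = par[0], g_L = par[1], g_C = par[2], g_K = par[3],
               V_L = par[5], V_C = par[6], V_K = par[7],
               V_1 = par[8], V_2 = par[9], V_3 = par[10], V_4 = par[11],
               tau_N = par[12];

  const long nstep = (long)std::llround(T / dt);
  const long nout = nstep / stride + 1;
  Rcpp::NumericMatrix out(nout, 3); // t V N

  double V = init[0], N = init[1];
  long row = 0;
  out(0, 0) = 0.0; out(0, 1) = V; out(0, 2) = N;
  ++row;

  for (long i = 0; i < nstep; ++i) {
    const double M_inf = 0.5 * (1.0 + std::tanh((V - V_1) / V_2));
    const double N_inf = 0.5 * (1.0 + std::tanh((V - V_3) / V_4));
    const double Lam   = std::cosh((V - V_3) / (2.0 * V_4));

    const double dV = (-g_L * (V - V_L) - g_C * M_inf * (V - V_C)
                       - g_K * N * (V - V_K) + I_tot) / C_m * dt;
    const double dN = Lam * (N_inf - N) / tau_N * dt;

    V += dV; N += dN;
    if (N < 0.0) N = 0.0; else if (N > 1.0) N = 1.0;

    if (!std::isfinite(V))
      Rcpp::stop("non-finite V at step %ld of the fast subsystem", i + 1);

    if ((i + 1) % stride == 0 && row < nout) {
      out(row, 0) = (i + 1) * dt;
      out(row, 1) = V; out(row, 2) = N;
      ++row;
    }
  }
  return out;
}
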