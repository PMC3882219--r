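// Fixed-step solver for the coupled xenograft model:
//   - two 3-compartment PK blocks (carboplatin, ABT-737)
//   - mass-action Bcl-xL / Bax / ABT-737 network
//   - logistic proliferating pools (sensitive + resistant) and an
//     age-structured arrested compartment advanced along characteristics
//     (uniform age bins, delta_a = delta_t, escalator-boxcar style).
//
// The "fast" subsystem (PK + network) is integrated with classical RK4 using
// adaptive sub-stepping sized from a local stiffness estimate; populations
// advance with one RK4 step per macro step with PK/network inputs frozen at
// their step midpoint.  Drug input enters either as state jumps (bolus) or
// through the exact window-average of the analytic cumulative infusion
// profile, so delivered mass is exact for any step size.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pars {
  // carboplatin PK
  double ck_pc, ck_ct, ck_tc, ck_el, cV_p, cV_c, cV_t;
  // ABT-737 PK
  double ak_pc, ak_ci, ak_ic, ak_el, ak_loss, aV_p, aV_c, aV_i;
  // Bcl network
  double kon_b, koff_b, kon_a, koff_a, p_L, p_B, d_L, d_B, d_LB, d_LA;
  // growth / treatment response
  double g, K, dN_max, B_half, h_N, x_B0;
  double a_max, C_half, a_hill, dM0, lambda_s, psi, p_mut;
};

inline double getd(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

Pars read_pars(const List& p) {
  Pars q;
  q.ck_pc = getd(p, "carbo_k_pc"); q.ck_ct = getd(p, "carbo_k_ct");
  q.ck_tc = getd(p, "carbo_k_tc"); q.ck_el = getd(p, "carbo_k_el");
  q.cV_p = getd(p, "carbo_V_p"); q.cV_c = getd(p, "carbo_V_c");
  q.cV_t = getd(p, "carbo_V_t");
  q.ak_pc = getd(p, "abt_k_pc"); q.ak_ci = getd(p, "abt_k_ci");
  q.ak_ic = getd(p, "abt_k_ic"); q.ak_el = getd(p, "abt_k_el");
  q.ak_loss = getd(p, "abt_k_loss");
  q.aV_p = getd(p, "abt_V_p"); q.aV_c = getd(p, "abt_V_c");
  q.aV_i = getd(p, "abt_V_i");
  q.kon_b = getd(p, "bcl_kon_bax"); q.koff_b = getd(p, "bcl_koff_bax");
  q.kon_a = getd(p, "bcl_kon_abt"); q.koff_a = getd(p, "bcl_koff_abt");
  q.p_L = getd(p, "bcl_prod_bclxl"); q.p_B = getd(p, "bcl_prod_bax");
  q.d_L = getd(p, "bcl_deg_bclxl"); q.d_B = getd(p, "bcl_deg_bax");
  q.d_LB = getd(p, "bcl_deg_dimer"); q.d_LA = getd(p, "bcl_deg_drug_complex");
  q.g = getd(p, "growth_rate"); q.K = getd(p, "carrying_capacity");
  q.dN_max = getd(p, "death_max"); q.B_half = getd(p, "death_bax_half");
  q.h_N = getd(p, "death_hill"); q.x_B0 = getd(p, "bax_baseline");
  q.a_max = getd(p, "arrest_max"); q.C_half = getd(p, "arrest_carbo_half");
  q.a_hill = getd(p, "arrest_hill");
  q.dM0 = getd(p, "arrest_death_coef"); q.lambda_s = getd(p, "bax_sensitivity");
  q.psi = getd(p, "arrest_duration"); q.p_mut = getd(p, "p_mut");
  return q;
}

// y layout for the fast subsystem (12 states)
enum { iCp = 0, iCc, iCt, iEc, iAp, iAc, iAi, iEa, ixL, ixB, ixLB, ixLA,
       NFAST };

inline void fast_deriv(const double* y, double u_c, double u_a,
                       const Pars& p, double* dy) {
  const double bind = p.kon_a * y[ixL] * y[iAi] - p.koff_a * y[ixLA];
  dy[iCp] = u_c / p.cV_p - p.ck_pc * y[iCp];
  dy[iCc] = (p.ck_pc * y[iCp] * p.cV_p - p.ck_ct * y[iCc] * p.cV_c +
             p.ck_tc * y[iCt] * p.cV_t - p.ck_el * y[iCc] * p.cV_c) / p.cV_c;
  dy[iCt] = (p.ck_ct * y[iCc] * p.cV_c - p.ck_tc * y[iCt] * p.cV_t) / p.cV_t;
  dy[iEc] = p.ck_el * y[iCc] * p.cV_c;
  dy[iAp] = u_a / p.aV_p - p.ak_pc * y[iAp];
  dy[iAc] = (p.ak_pc * y[iAp] * p.aV_p - p.ak_ci * y[iAc] * p.aV_c +
             p.ak_ic * y[iAi] * p.aV_i - p.ak_el * y[iAc] * p.aV_c) / p.aV_c;
  dy[iAi] = (p.ak_ci * y[iAc] * p.aV_c - p.ak_ic * y[iAi] * p.aV_i) / p.aV_i -
            bind - p.ak_loss * y[iAi];
  dy[iEa] = p.ak_el * y[iAc] * p.aV_c;
  const double hetero = p.kon_b * y[ixL] * y[ixB] - p.koff_b * y[ixLB];
  dy[ixL] = p.p_L - p.d_L * y[ixL] - hetero - bind;
  dy[ixB] = p.p_B - p.d_B * y[ixB] - hetero;
  dy[ixLB] = hetero - p.d_LB * y[ixLB];
  dy[ixLA] = bind - p.d_LA * y[ixLA];
}

inline double alpha_fun(double c_t, const Pars& p) {
  if (c_t <= 0.0) return 0.0;
  const double ch = std::pow(c_t, p.a_hill);
  return p.a_max * ch / (ch + std::pow(p.C_half, p.a_hill));
}

inline double deltaN_fun(double x_b, const Pars& p) {
  const double u = x_b > p.x_B0 ? x_b - p.x_B0 : 0.0;
  if (u <= 0.0) return 0.0;
  const double uh = std::pow(u, p.h_N);
  return p.dN_max * uh / (uh + std::pow(p.B_half, p.h_N));
}

// cumulative drug amount delivered by one periodic infusion regimen up to t
inline double cum_infused(double t, double start, double period, double ti,
                          double rate, double n_doses) {
  if (t <= start) return 0.0;
  const double jmaxd = std::floor((t - start) / period);
  double nfull = jmaxd;                     // windows fully before current
  if (nfull > n_doses) nfull = n_doses;
  double w = 0.0;
  if (jmaxd < n_doses) {                    // partial/complete current window
    double frac = t - start - jmaxd * period;
    if (frac > ti) frac = ti;
    w += frac;
  }
  return rate * (w + ti * nfull);
}

struct Sched {
  std::vector<double> bolus_t, bolus_amt;
  std::vector<double> inf_start, inf_period, inf_ti, inf_rate, inf_n;
};

Sched read_sched(const List& s) {
  Sched out;
  out.bolus_t = as<std::vector<double>>(s["bolus_times"]);
  out.bolus_amt = as<std::vector<double>>(s["bolus_amounts"]);
  out.inf_start = as<std::vector<double>>(s["inf_start"]);
  out.inf_period = as<std::vector<double>>(s["inf_period"]);
  out.inf_ti = as<std::vector<double>>(s["inf_ti"]);
  out.inf_rate = as<std::vector<double>>(s["inf_rate"]);
  out.inf_n = as<std::vector<double>>(s["inf_n"]);
  return out;
}

inline double avg_rate(const Sched& s, double t, double dt) {
  double w = 0.0;
  for (size_t i = 0; i < s.inf_start.size(); ++i) {
    w += cum_infused(t + dt, s.inf_start[i], s.inf_period[i], s.inf_ti[i],
                     s.inf_rate[i], s.inf_n[i]) -
         cum_infused(t, s.inf_start[i], s.inf_period[i], s.inf_ti[i],
                     s.inf_rate[i], s.inf_n[i]);
  }
  return w / dt;
}

}  // namespace

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericVector y0, double N0, double Nr0,
                  NumericVector M0, NumericVector Carr0,
                  List pars, List carbo_sched, List abt_sched,
                  double t0, double t_end, double dt, int rec_every) {
  const Pars p = read_pars(pars);
  const Sched sc = read_sched(carbo_sched);
  const Sched sa = read_sched(abt_sched);

  if (y0.size() != NFAST) stop("internal: fast state must have 12 components");
  const int n_age = (int)std::floor(p.psi / dt + 0.5);
  if (n_age < 1 || std::fabs(n_age * dt - p.psi) > 1e-8 * p.psi)
    stop("dt must divide the arrest duration psi exactly");
  if ((int)M0.size() != n_age || (int)Carr0.size() != n_age)
    stop("age-grid state has wrong number of bins for this dt");

  const long nsteps = (long)std::floor((t_end - t0) / dt + 0.5);
  if (nsteps < 1) stop("horizon shorter than one time step");
  if (std::fabs(t0 + nsteps * dt - t_end) > 1e-7)
    stop("dt must divide the simulation horizon exactly");

  double y[NFAST], yw[NFAST], k1[NFAST], k2[NFAST], k3[NFAST], k4[NFAST];
  for (int i = 0; i < NFAST; ++i) y[i] = y0[i];
  double N = N0, Nr = Nr0;

  // circular age buffer; head = index of youngest cohort
  std::vector<double> M(M0.begin(), M0.end());
  std::vector<double> Carr(Carr0.begin(), Carr0.end());
  int head = 0;
  double M_tot = 0.0;
  for (int i = 0; i < n_age; ++i) M_tot += M[i];

  const long nrec = nsteps / rec_every + 1;
  NumericMatrix out(nrec, 1 + NFAST + 4);  // t, fast, N, Nr, M_tot, recov
  long irec = 0;
  size_t ibc = 0, iba = 0;

  auto record = [&](double t, double recov) {
    out(irec, 0) = t;
    for (int i = 0; i < NFAST; ++i) out(irec, 1 + i) = y[i];
    out(irec, 1 + NFAST) = N;
    out(irec, 2 + NFAST) = Nr;
    out(irec, 3 + NFAST) = M_tot;
    out(irec, 4 + NFAST) = recov;
    ++irec;
  };
  record(t0, 0.0);

  for (long k = 0; k < nsteps; ++k) {
    const double t = t0 + k * dt;

    // boluses scheduled within [t, t + dt) fire at the step start
    while (ibc < sc.bolus_t.size() && sc.bolus_t[ibc] < t + dt - 1e-12) {
      if (sc.bolus_t[ibc] >= t - 1e-12) y[iCp] += sc.bolus_amt[ibc] / p.cV_p;
      ++ibc;
    }
    while (iba < sa.bolus_t.size() && sa.bolus_t[iba] < t + dt - 1e-12) {
      if (sa.bolus_t[iba] >= t - 1e-12) y[iAp] += sa.bolus_amt[iba] / p.aV_p;
      ++iba;
    }

    const double u_c = avg_rate(sc, t, dt);
    const double u_a = avg_rate(sa, t, dt);
    const double Ct_start = y[iCt], xB_start = y[ixB];

    // local stiffness estimate -> number of RK4 sub-steps
    double L = p.ck_pc + p.ck_ct + p.ck_tc + p.ck_el;
    const double La = p.ak_pc + p.ak_ci + p.ak_ic + p.ak_el + p.ak_loss;
    if (La > L) L = La;
    double Ln = p.kon_b * (y[ixL] + y[ixB]) + p.koff_b +
                p.kon_a * (y[ixL] + y[iAi]) + p.koff_a +
                p.d_L + p.d_B + p.d_LB + p.d_LA;
    if (Ln > L) L = Ln;
    int m = (int)std::ceil(dt * L / 0.5);
    if (m < 1) m = 1;
    const double h = dt / m;

    for (int s = 0; s < m; ++s) {
      fast_deriv(y, u_c, u_a, p, k1);
      for (int i = 0; i < NFAST; ++i) yw[i] = y[i] + 0.5 * h * k1[i];
      fast_deriv(yw, u_c, u_a, p, k2);
      for (int i = 0; i < NFAST; ++i) yw[i] = y[i] + 0.5 * h * k2[i];
      fast_deriv(yw, u_c, u_a, p, k3);
      for (int i = 0; i < NFAST; ++i) yw[i] = y[i] + h * k3[i];
      fast_deriv(yw, u_c, u_a, p, k4);
      for (int i = 0; i < NFAST; ++i) {
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (y[i] < 0.0) {
          if (y[i] > -1e-9) y[i] = 0.0;
          else stop("negative concentration at t = %g (state %d)", t, i);
        }
      }
    }

    // populations: RK4 over dt with PK/network frozen at step midpoints
    const double a_mid = alpha_fun(0.5 * (Ct_start + y[iCt]), p);
    const double dN_mid = deltaN_fun(0.5 * (xB_start + y[ixB]), p);
    const double c_arr = 0.5 * (Ct_start + y[iCt]);
    double S = 0.0;
    {
      double kN[4], kR[4], kS[4];
      double Nn = N, Rr = Nr, Ss = S;
      for (int s = 0; s < 4; ++s) {
        const double w = (s == 0) ? 0.0 : (s == 3 ? 1.0 : 0.5);
        const double Ne = N + w * dt * (s ? kN[s - 1] : 0.0);
        const double Re = Nr + w * dt * (s ? kR[s - 1] : 0.0);
        const double crowd = 1.0 - (Ne + Re + M_tot) / p.K;
        kN[s] = p.g * Ne * crowd - dN_mid * Ne - a_mid * Ne;
        kR[s] = p.g * Re * crowd - dN_mid * Re;
        kS[s] = a_mid * Ne;
      }
      N = Nn + dt / 6.0 * (kN[0] + 2 * kN[1] + 2 * kN[2] + kN[3]);
      Nr = Rr + dt / 6.0 * (kR[0] + 2 * kR[1] + 2 * kR[2] + kR[3]);
      S = Ss + dt / 6.0 * (kS[0] + 2 * kS[1] + 2 * kS[2] + kS[3]);
      if (N < 0.0) N = 0.0;
      if (Nr < 0.0) Nr = 0.0;
      if (S < 0.0) S = 0.0;
    }

    // arrested compartment: pointwise survival, advect by one bin,
    // terminal cohort recovers, new cohort enters at age 0
    const double xB_mid = 0.5 * (xB_start + y[ixB]);
    const double xs = xB_mid > p.x_B0 ? xB_mid - p.x_B0 : 0.0;
    const double kill = p.dM0 + p.lambda_s * xs;
    for (int i = 0; i < n_age; ++i)
      if (M[i] > 0.0) M[i] *= std::exp(-Carr[i] * kill * dt);
    // oldest cohort = the one just behind head in the ring
    const int tail = (head - 1 + n_age) % n_age;
    const double recov = M[tail];
    N += (1.0 - p.p_mut) * recov;
    Nr += p.p_mut * recov;
    M[tail] = S;          // becomes the new youngest cohort
    Carr[tail] = c_arr;
    head = tail;
    M_tot = 0.0;
    for (int i = 0; i < n_age; ++i) M_tot += M[i];

    if ((k + 1) % rec_every == 0) record(t + dt, recov / dt);
  }

  // unwrap the ring so bin 1 = youngest cohort (age in (0, dt])
  NumericVector Mout(n_age), Cout(n_age);
  for (int i = 0; i < n_age; ++i) {
    const int j = (head + i) % n_age;
    Mout[i] = M[j];
    Cout[i] = Carr[j];
  }
  NumericVector yout(NFAST);
  for (int i = 0; i < NFAST; ++i) yout[i] = y[i];

  return List::create(_["traj"] = out, _["y"] = yout, _["N"] = N,
                      _["Nr"] = Nr, _["M"] = Mout, _["Carr"] = Cout);
}

// Derivatives of the fast (PK + network) subsystem at a point; used by the
// test-suite to cross-check the compiled kinetics against the R-level
// derivative functions.
// [[Rcpp::export(name = ".fast_deriv_cpp")]]
NumericVector fast_deriv_cpp(NumericVector y, double u_c, double u_a,
                             List pars) {
  const Pars p = read_pars(pars);
  if (y.size() != NFAST) stop("fast state must have 12 components");
  double dy[NFAST];
  fast_deriv(REAL(y), u_c, u_a, p, dy);
  return NumericVector(dy, dy + NFAST);
}
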