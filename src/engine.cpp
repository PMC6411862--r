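#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Detachment-profile variants share the constants of the measured law;
// codes: 0 = measured, 1 = symmetric_hindering, 2 = symmetric_assisting,
// 3 = reversed. Kept in lockstep with the R-level detachment_rate().
static inline double eps_measured(double F, double eps0, double Fdm,
                                  double Fdp, double bslope, double bpref) {
  if (F <= 0.0) return eps0 * std::exp(-F / Fdm);
  if (F <= 2.0) return eps0 * (1.0 + bslope * F);
  return eps0 * bpref * std::exp(F / Fdp);
}

static inline double eps_rate(double F, int variant, double eps0, double Fdm,
                              double Fdp, double bslope, double bpref) {
  switch (variant) {
  case 0: return eps_measured(F, eps0, Fdm, Fdp, bslope, bpref);
  case 1: return eps0 * std::exp(std::fabs(F) / Fdm);
  case 2: {
    double a = std::fabs(F);
    if (a <= 2.0) return eps0 * (1.0 + bslope * a);
    return eps0 * bpref * std::exp(a / Fdp);
  }
  case 3: return eps_measured(-F, eps0, Fdm, Fdp, bslope, bpref);
  default: stop("unknown detachment-profile variant code");
  }
  return NA_REAL; // not reached
}

static inline double kstep_rate(double F, double kmax, double Fs) {
  if (F <= -Fs) return 0.0;
  if (F <= 0.0) {
    double r = F / Fs;
    return kmax * (1.0 - r * r);
  }
  return kmax;
}

static inline double tether_load(double delta, double kappa, double L0) {
  if (delta > L0) return kappa * (delta - L0);
  if (delta < -L0) return kappa * (delta + L0);
  return 0.0;
}

// One transport run: per-step order is (1) load from displacement,
// (2) Bernoulli detachment at eps(F)*dt, (3) Bernoulli motor step at
// k_step(F)*dt, (4) cargo Euler-Maruyama update, (5) advance time.
// RNG draws per surviving step: detach uniform, step uniform, diffusion
// normal (the normal is drawn even when D = 0 to keep the stream layout
// independent of the fluid).
// [[Rcpp::export(.sim_transport_cpp)]]
List sim_transport_cpp(double dt, double max_steps, double v0, double dx,
                       double Fs, double kappa, double L0, double xi,
                       double D, int variant, double eps0, double Fdm,
                       double Fdp, double bslope, double bpref,
                       int stride, double init_delta) {
  const double kmax = v0 / dx;
  const double sdiff = std::sqrt(2.0 * D * dt);
  double motor = 0.0, cargo = init_delta, t = 0.0;
  double n_motor_steps = 0.0;
  bool detached = false;

  const bool rec = stride > 0;
  R_xlen_t cap = rec ? (R_xlen_t)(max_steps / stride) + 2 : 0;
  NumericVector rt(cap), rmotor(cap), rcargo(cap), rload(cap);
  R_xlen_t nrec = 0;

  const long long n_max = (long long)max_steps;
  int since_rec = 0; // records step 0, then every stride-th step
  for (long long n = 0; n < n_max; ++n) {
    double F = tether_load(cargo - motor, kappa, L0);
    if (rec && since_rec == 0) {
      rt[nrec] = t; rmotor[nrec] = motor; rcargo[nrec] = cargo;
      rload[nrec] = F; ++nrec;
    }
    if (rec && ++since_rec == stride) since_rec = 0;
    double eps = eps_rate(F, variant, eps0, Fdm, Fdp, bslope, bpref);
    if (unif_rand() < eps * dt) { detached = true; break; }
    if (unif_rand() < kstep_rate(F, kmax, Fs) * dt) {
      motor += dx;
      n_motor_steps += 1.0;
    }
    cargo += (-F / xi) * dt + sdiff * norm_rand();
    if (!std::isfinite(cargo) || !std::isfinite(motor))
      stop("simulation state became non-finite");
    t += dt;
  }

  List out = List::create(
    _["n_motor_steps"] = n_motor_steps,
    _["run_length"] = n_motor_steps * dx,
    _["duration"] = t,
    _["termination"] = detached ? "detached" : "max_steps",
    _["final_motor"] = motor,
    _["final_cargo"] = cargo);
  if (rec) {
    out["time"] = NumericVector(rt.begin(), rt.begin() + nrec);
    out["motor"] = NumericVector(rmotor.begin(), rmotor.begin() + nrec);
    out["cargo"] = NumericVector(rcargo.begin(), rcargo.begin() + nrec);
    out["load"] = NumericVector(rload.begin(), rload.begin() + nrec);
  }
  return out;
}

// Equilibrium mode: motor fixed at 0, detachment and stepping disabled;
// the cargo diffuses in the flat-bottomed harmonic tether potential.
// Samples the displacement after every `stride`-th update, after
// `burn_in` discarded updates. kappa = 0 gives free diffusion.
// One normal draw per update.
// [[Rcpp::export(.sim_equilibrium_cpp)]]
NumericVector sim_equilibrium_cpp(double dt, R_xlen_t n_samples,
                                  R_xlen_t burn_in, int stride,
                                  double kappa, double L0, double xi,
                                  double D, double init_delta) {
  const double sdiff = std::sqrt(2.0 * D * dt);
  double cargo = init_delta;
  NumericVector out(n_samples);
  for (R_xlen_t i = 0; i < burn_in; ++i) {
    double F = (kappa > 0.0) ? tether_load(cargo, kappa, L0) : 0.0;
    cargo += (-F / xi) * dt + sdiff * norm_rand();
  }
  for (R_xlen_t s = 0; s < n_samples; ++s) {
    for (int k = 0; k < stride; ++k) {
      double F = (kappa > 0.0) ? tether_load(cargo, kappa, L0) : 0.0;
      cargo += (-F / xi) * dt + sdiff * norm_rand();
    }
    if (!std::isfinite(cargo)) stop("simulation state became non-finite");
    out[s] = cargo;
  }
  return out;
}
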