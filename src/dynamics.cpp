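// Euler-Maruyama integrators for the two stochastic processes of the model
// (two-population mean-field race; double-well intention process) and the
// closed-loop episode/block simulator that couples them to strategy learning.
// All random draws go through R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct MfPars {
  double tau, sigma, delta_thr, w_plus, w_minus, f_max, theta, k_sig, dt, t_max;
};

struct IntPars {
  double tau_psi, sigma_psi, dt, eps, t_max;
};

MfPars mf_pars(const List& p) {
  MfPars q;
  q.tau       = as<double>(p["tau"]);
  q.sigma     = as<double>(p["sigma"]);
  q.delta_thr = as<double>(p["delta_thr"]);
  q.w_plus    = as<double>(p["w_plus"]);
  q.w_minus   = as<double>(p["w_minus"]);
  q.f_max     = as<double>(p["f_max"]);
  q.theta     = as<double>(p["theta"]);
  q.k_sig     = as<double>(p["k_sig"]);
  q.dt        = as<double>(p["dt"]);
  q.t_max     = as<double>(p["t_max"]);
  return q;
}

IntPars int_pars(const List& p) {
  IntPars q;
  q.tau_psi   = as<double>(p["tau_psi"]);
  q.sigma_psi = as<double>(p["sigma_psi"]);
  q.dt        = as<double>(p["dt"]);
  q.eps       = as<double>(p["eps"]);
  q.t_max     = as<double>(p["t_max"]);
  return q;
}

inline double transfer(double x, const MfPars& p) {
  return p.f_max / (1.0 + std::exp(-(x - p.theta) / p.k_sig));
}

// One mean-field race.  psi selects which stimulus drives which pool:
// pool L receives psi*lambda_L + (1-psi)*lambda_R, pool R the converse.
// Returns winner (0 none, 1 left, 2 right) and the crossing time.
inline void mf_run(double lambda_L, double lambda_R, double psi,
                   const MfPars& p, int& winner, double& when,
                   double* final_L = nullptr, double* final_R = nullptr,
                   std::vector<double>* tr_t = nullptr,
                   std::vector<double>* tr_l = nullptr,
                   std::vector<double>* tr_r = nullptr) {
  const double in_L = psi * lambda_L + (1.0 - psi) * lambda_R;
  const double in_R = psi * lambda_R + (1.0 - psi) * lambda_L;
  const double sdt  = std::sqrt(p.dt);
  double rL = 0.0, rR = 0.0, t = 0.0;
  winner = 0;
  when = NA_REAL;
  if (tr_t) { tr_t->push_back(0.0); tr_l->push_back(rL); tr_r->push_back(rR); }
  while (t < p.t_max) {
    double nL = 0.0, nR = 0.0;
    if (p.sigma > 0.0) {
      nL = p.sigma * sdt * norm_rand();
      nR = p.sigma * sdt * norm_rand();
    }
    const double fL = transfer(in_L + p.w_plus * rL - p.w_minus * rR, p);
    const double fR = transfer(in_R + p.w_plus * rR - p.w_minus * rL, p);
    rL += (p.dt * (-rL + fL) + nL) / p.tau;
    rR += (p.dt * (-rR + fR) + nR) / p.tau;
    t += p.dt;
    if (!std::isfinite(rL) || !std::isfinite(rR))
      stop("mean-field integration diverged at t = %f ms (r_L = %f, r_R = %f)",
           t, rL, rR);
    if (tr_t) { tr_t->push_back(t); tr_l->push_back(rL); tr_r->push_back(rR); }
    if (std::fabs(rL - rR) > p.delta_thr) {   // strict crossing
      winner = (rL > rR) ? 1 : 2;
      when = t;
      break;
    }
  }
  if (final_L) *final_L = rL;
  if (final_R) *final_R = rR;
}

// One realization of the double-well intention process
//   tau_psi dpsi = -4 psi (psi-1)(psi-1/2) dt + sigma_psi (1+t/tau_psi)^-2 dW.
// Returns 0/1 (basin reached) and the settling time.
inline void intention_run(double psi0, const IntPars& p,
                          int& out, double& when, bool& settled,
                          std::vector<double>* tr_t = nullptr,
                          std::vector<double>* tr_p = nullptr) {
  const double sdt = std::sqrt(p.dt);
  double psi = psi0, t = 0.0;
  out = NA_INTEGER;
  when = NA_REAL;
  settled = false;
  if (tr_t) { tr_t->push_back(0.0); tr_p->push_back(psi); }
  while (t < p.t_max) {
    const double drift = -4.0 * psi * (psi - 1.0) * (psi - 0.5);
    double noise = 0.0;
    if (p.sigma_psi > 0.0) {
      const double decay = 1.0 / std::pow(1.0 + t / p.tau_psi, 2.0);
      noise = p.sigma_psi * decay * sdt * norm_rand();
    }
    psi += (p.dt * drift + noise) / p.tau_psi;
    if (psi < -0.2) psi = -0.2;              // keep noise excursions bounded
    if (psi >  1.2) psi =  1.2;
    t += p.dt;
    if (tr_t) { tr_t->push_back(t); tr_p->push_back(psi); }
    if (psi <= p.eps)        { out = 0; when = t; settled = true; break; }
    if (psi >= 1.0 - p.eps)  { out = 1; when = t; settled = true; break; }
  }
  if (!settled) {                            // classify by nearest basin
    if (psi == 0.5) out = (unif_rand() < 0.5) ? 0 : 1;
    else out = (psi < 0.5) ? 0 : 1;
    when = t;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_mf_trial(double lambda_L, double lambda_R, double psi,
                  List pars, bool keep_trace) {
  MfPars p = mf_pars(pars);
  int winner;
  double when;
  if (keep_trace) {
    std::vector<double> tt, tl, trr;
    mf_run(lambda_L, lambda_R, psi, p, winner, when, nullptr, nullptr,
           &tt, &tl, &trr);
    return List::create(_["winner"] = winner, _["time"] = when,
                        _["trace"] = DataFrame::create(
                          _["t"] = tt, _["r_L"] = tl, _["r_R"] = trr));
  }
  mf_run(lambda_L, lambda_R, psi, p, winner, when);
  return List::create(_["winner"] = winner, _["time"] = when);
}

// [[Rcpp::export]]
List cpp_mf_batch(NumericVector lambda_L, NumericVector lambda_R,
                  NumericVector psi, List pars) {
  MfPars p = mf_pars(pars);
  const int n = lambda_L.size();
  IntegerVector winner(n);
  NumericVector when(n), rL(n), rR(n);
  for (int i = 0; i < n; ++i) {
    int w;
    double tm, fl, fr;
    mf_run(lambda_L[i], lambda_R[i], psi[i], p, w, tm, &fl, &fr);
    winner[i] = w;
    when[i] = tm;
    rL[i] = fl;
    rR[i] = fr;
  }
  return List::create(_["winner"] = winner, _["time"] = when,
                      _["r_L"] = rL, _["r_R"] = rR);
}

// [[Rcpp::export]]
List cpp_intention_trial(double psi0, List pars, bool keep_trace) {
  IntPars p = int_pars(pars);
  int out;
  double when;
  bool settled;
  if (keep_trace) {
    std::vector<double> tt, tp;
    intention_run(psi0, p, out, when, settled, &tt, &tp);
    return List::create(_["psi_tilde"] = out, _["settle_time"] = when,
                        _["settled"] = settled,
                        _["trace"] = DataFrame::create(_["t"] = tt,
                                                       _["psi"] = tp));
  }
  intention_run(psi0, p, out, when, settled);
  return List::create(_["psi_tilde"] = out, _["settle_time"] = when,
                      _["settled"] = settled);
}

// [[Rcpp::export]]
IntegerVector cpp_intention_batch(int n, double psi0, List pars) {
  IntPars p = int_pars(pars);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int o;
    double when;
    bool settled;
    intention_run(psi0, p, o, when, settled);
    out[i] = o;
  }
  return out;
}

// Closed-loop simulation of one block: episodes of (horizon + 1) dependent
// trials.  Stimulus means chain within an episode (+G after "small", -G
// after "big"); the strategy vector phi (one entry per within-episode
// position) seeds the intention process and is updated by the
// reinforcement-comparison rule after every decided trial.
//
// final_reward: 1 -> signed gain (+G if big chosen, -G if small chosen);
//               2 -> chosen value minus pair mean (+/- delta/2).
// force_psi: -1 -> run the intention process; 0/1 -> clamp the intention.
// [[Rcpp::export]]
List cpp_simulate_block(int horizon, double G,
                        NumericVector ep_delta, NumericVector ep_M1,
                        IntegerVector big_left,     // per trial, 1 yes 0 no
                        IntegerVector first_left,   // per trial, 1 yes 0 no
                        List neural, List intention,
                        double k, NumericVector phi0,
                        double alpha, double beta, double rt_shift,
                        int final_reward, int force_psi) {
  MfPars mp = mf_pars(neural);
  IntPars ip = int_pars(intention);
  const int n_ep = ep_delta.size();
  const int n_per = horizon + 1;
  const int n_tr = n_ep * n_per;
  if (big_left.size() != n_tr || first_left.size() != n_tr)
    stop("per-trial layout vectors must have length episodes * (horizon + 1)");
  if (phi0.size() != n_per)
    stop("phi0 must have one entry per within-episode position");

  std::vector<double> phi(phi0.begin(), phi0.end());
  NumericMatrix phi_path(n_ep + 1, n_per);
  for (int j = 0; j < n_per; ++j) phi_path(0, j) = phi[j];

  IntegerVector episode(n_tr), trial_in_ep(n_tr), psi_tilde(n_tr),
      chosen_big(n_tr), chosen_left(n_tr), no_decision(n_tr);
  NumericVector m_t(n_tr), s_left(n_tr), s_right(n_tr), psi_init(n_tr),
      dec_time(n_tr), rt(n_tr), chosen_value(n_tr), reward(n_tr);

  int i = 0;
  for (int e = 0; e < n_ep; ++e) {
    double M = ep_M1[e];
    const double d = ep_delta[e];
    for (int te = 0; te < n_per; ++te, ++i) {
      episode[i] = e + 1;
      trial_in_ep[i] = te + 1;
      m_t[i] = M;
      const double s_small = M - d / 2.0, s_big = M + d / 2.0;
      const bool bl = big_left[i] == 1;
      s_left[i]  = bl ? s_big : s_small;
      s_right[i] = bl ? s_small : s_big;

      const double p0 = phi[te];
      psi_init[i] = p0;
      int psi;
      if (force_psi >= 0) {
        psi = force_psi;
      } else {
        double when;
        bool settled;
        intention_run(p0, ip, psi, when, settled);
      }
      psi_tilde[i] = psi;

      const double lamL = alpha + beta * s_left[i];
      const double lamR = alpha + beta * s_right[i];
      int w;
      double tm;
      mf_run(lamL, lamR, (double)psi, mp, w, tm);

      if (w == 0) {                     // response window elapsed
        no_decision[i] = 1;
        chosen_big[i] = NA_INTEGER;
        chosen_left[i] = NA_INTEGER;
        chosen_value[i] = NA_REAL;
        dec_time[i] = NA_REAL;
        rt[i] = NA_REAL;
        reward[i] = NA_REAL;
        // mean chain advances without the gain/loss shift
        continue;
      }
      no_decision[i] = 0;
      const bool left = (w == 1);
      chosen_left[i] = left ? 1 : 0;
      chosen_value[i] = left ? s_left[i] : s_right[i];
      const bool big = (left == bl);
      chosen_big[i] = big ? 1 : 0;
      dec_time[i] = tm;
      rt[i] = tm + rt_shift;

      double R;
      if (te < n_per - 1) {
        R = big ? -G : G;               // mean shift caused by the choice
        M += big ? -G : G;
      } else if (final_reward == 2 || G <= 0.0) {
        R = big ? d / 2.0 : -d / 2.0;   // chosen value relative to the mean
      } else {
        R = big ? G : -G;               // signed gain-sized terminal reward
      }
      reward[i] = R;
      const double f = phi[te];
      phi[te] = f + k * R * (2.0 * psi - 1.0) * (f - 1.0) * (f - 1.0) * f * f;
    }
    for (int j = 0; j < n_per; ++j) phi_path(e + 1, j) = phi[j];
  }

  DataFrame trials = DataFrame::create(
      _["episode"] = episode, _["trial_in_episode"] = trial_in_ep,
      _["M"] = m_t, _["s_left"] = s_left, _["s_right"] = s_right,
      _["psi0"] = psi_init, _["psi_tilde"] = psi_tilde,
      _["chosen_left"] = chosen_left, _["chosen_big"] = chosen_big,
      _["chosen_value"] = chosen_value, _["reward"] = reward,
      _["decision_time"] = dec_time, _["rt"] = rt,
      _["no_decision"] = no_decision);
  return List::create(_["trials"] = trials, _["phi_path"] = phi_path);
}
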