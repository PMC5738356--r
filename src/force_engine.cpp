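// Core fixed-step integration loop for FORCE-trained reservoirs.
//
// The recurrent input is split into (i) the static chaotic component,
// propagated event-wise: each spike adds one column of the (pre-scaled)
// static matrix into an exponentially filtered postsynaptic current, and
// (ii) the learned rank-m feedback Q * eta * xhat, recomputed from the
// current approximant xhat = phi' r at every integration step.  RLS runs
// at its own (coarser) cadence on the decode filter r.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// model codes
static const int MODEL_THETA = 0, MODEL_LIF = 1, MODEL_IZH = 2, MODEL_RATE = 3;

// [[Rcpp::export(name = ".cpp_force_run")]]
List cpp_force_run(int model,
                   List npar,
                   const arma::sp_mat& omega_static, // N x N, already G-scaled
                   double Q,
                   const arma::mat& eta,             // N x m
                   int syn_kind,                     // 0 single-exp, 1 double-exp
                   double tau_s, double tau_r, double tau_d,
                   const arma::mat& X,               // m x nX supervisor samples (RLS cadence)
                   double dt,                        // ms
                   int nt,
                   int rls_start, int rls_stop, int rls_every,
                   double lambda_inv, bool denom_in_phi, bool rls_on,
                   arma::mat phi,                    // N x m (updated in place)
                   arma::mat P,                      // N x N, or 0x0 to init as lambda_inv*I
                   const arma::mat& Win,             // N x K, or 0x0
                   const arma::mat& U,               // K x nU input samples
                   int u_every,
                   int record_every,
                   int phi_record_every,
                   List state0,
                   int delete_neuron,                // 0-based, -1 disables
                   double del_t0, double del_t1,     // ms
                   bool delete_transmission_only,
                   double runaway_hz,
                   bool return_P,
                   int stat_start) {               // step index where rate stats begin
  const int N = omega_static.n_rows;
  const int m = eta.n_cols;
  const bool has_input = (Win.n_rows == (unsigned)N) && (Win.n_cols > 0) && (U.n_cols > 0);
  const int K = has_input ? Win.n_cols : 0;

  // neuron parameters
  double Ibias = as<double>(npar["I_bias"]);
  double tscale = npar.containsElementNamed("t_scale") ? as<double>(npar["t_scale"]) : 1.0;
  double tau_m = 0, v_t = 0, v_reset = 0, tau_ref = 0;
  double C = 0, k = 0, v_r = 0, v_peak = 0, a = 0, b = 0, d = 0;
  double Fr = 0, tau_unit = 0;
  if (model == MODEL_LIF) {
    tau_m = as<double>(npar["tau_m"]); v_t = as<double>(npar["v_t"]);
    v_reset = as<double>(npar["v_reset"]); tau_ref = as<double>(npar["tau_ref"]);
  } else if (model == MODEL_IZH) {
    C = as<double>(npar["C"]); k = as<double>(npar["k"]);
    v_r = as<double>(npar["v_r"]); v_t = as<double>(npar["v_t"]);
    v_peak = as<double>(npar["v_peak"]); v_reset = as<double>(npar["v_reset"]);
    a = as<double>(npar["a"]); b = as<double>(npar["b"]); d = as<double>(npar["d"]);
  } else if (model == MODEL_RATE) {
    Fr = as<double>(npar["F"]); tau_unit = as<double>(npar["tau_s"]);
  }

  // state
  arma::vec v = as<arma::vec>(state0["v"]);
  arma::vec uad = state0.containsElementNamed("u") ? as<arma::vec>(state0["u"]) : arma::zeros(N);
  arma::vec refr = state0.containsElementNamed("refr") ? as<arma::vec>(state0["refr"]) : arma::zeros(N);
  arma::vec r = state0.containsElementNamed("r") ? as<arma::vec>(state0["r"]) : arma::zeros(N);
  arma::vec hr = state0.containsElementNamed("hr") ? as<arma::vec>(state0["hr"]) : arma::zeros(N);
  arma::vec Ipsc = state0.containsElementNamed("Ipsc") ? as<arma::vec>(state0["Ipsc"]) : arma::zeros(N);
  arma::vec hI = state0.containsElementNamed("hI") ? as<arma::vec>(state0["hI"]) : arma::zeros(N);

  if (rls_on && P.n_rows != (unsigned)N) {
    P.eye(N, N);
    P *= lambda_inv;
  }

  // filter decay factors
  const double e_d = std::exp(-dt / tau_d);
  const double e_r = std::exp(-dt / tau_r);
  const double e_s = std::exp(-dt / tau_s);
  // exact cascade coupling: r(t+dt) = r e_d + h * c_de for the rise
  // variable decaying with tau_r (alpha limit: dt * e_d)
  const double c_de = (std::abs(tau_r - tau_d) < 1e-12)
    ? dt * e_d
    : (e_d - e_r) / (1.0 / tau_r - 1.0 / tau_d);
  const double jump_de = 1.0 / (tau_r * tau_d); // increment into h per spike
  const double jump_se = 1.0 / tau_s;

  // recording
  const int nrec = (record_every > 0) ? nt / record_every : 0;
  arma::mat xhat_rec(m, nrec, arma::fill::zeros);
  arma::vec t_rec(nrec, arma::fill::zeros);
  const int nphirec = (phi_record_every > 0) ? nt / phi_record_every : 0;
  const int ntrack = std::min(20, N);
  arma::mat phi_track(ntrack, nphirec, arma::fill::zeros);
  arma::mat phi_norm(m, nphirec, arma::fill::zeros);
  arma::vec t_phi(nphirec, arma::fill::zeros);
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  sp_t.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  // per-unit running stats (from stat_start onward)
  arma::vec sum_r(N, arma::fill::zeros);
  arma::vec max_r(N, arma::fill::zeros);
  long stat_n = 0;

  arma::vec I(N), xhat(m), rate_r(N), Iff(N, arma::fill::zeros);
  arma::vec Pr(N), e(m);
  bool deletion_done = (delete_neuron < 0);
  long rls_count = 0;
  long block_spikes = 0;
  const int block = 2000;
  std::vector<arma::uword> spikers;
  spikers.reserve(64);

  for (int s = 0; s < nt; ++s) {
    const double t_now = (s + 1) * dt;

    if (has_input && (s % u_every == 0)) {
      int ku = s / u_every;
      if (ku >= (int)U.n_cols) ku = U.n_cols - 1;
      Iff = Win * U.col(ku);
    }

    if (model == MODEL_RATE) {
      // type-I normal form rate unit: r = F sqrt(s)_+
      rate_r = Fr * arma::sqrt(arma::clamp(v, 0.0, arma::datum::inf));
      xhat = phi.t() * rate_r;
      arma::vec drive = omega_static * rate_r + Q * (eta * xhat) + Ibias;
      if (has_input) drive += Iff;
      v += dt * (-v + drive) / tau_unit;
      r = rate_r; // decode basis
      if (s >= stat_start) {
        sum_r += rate_r;
        max_r = arma::max(max_r, rate_r);
        ++stat_n;
      }
    } else {
      xhat = phi.t() * r;
      I = Ipsc + Q * (eta * xhat) + Ibias;
      if (has_input) I += Iff;

      spikers.clear();
      const bool del_window = !deletion_done && t_now >= del_t0 && t_now <= del_t1;
      if (model == MODEL_THETA) {
        for (int i = 0; i < N; ++i) {
          double th = v[i];
          const double cth = std::cos(th);
          th += dt * tscale * ((1.0 - cth) +
                               (arma::datum::pi * arma::datum::pi) * (1.0 + cth) * I[i]);
          if (th >= arma::datum::pi) {
            // phase passes the spike point; wrap back onto (-pi, pi]
            th -= 2.0 * arma::datum::pi;
            if (del_window && i == delete_neuron) {
              deletion_done = true; // phase continues round the circle; spike untransmitted
            } else {
              spikers.push_back(i);
            }
          }
          v[i] = th;
        }
      } else if (model == MODEL_LIF) {
        for (int i = 0; i < N; ++i) {
          if (refr[i] > 0.0) {
            refr[i] -= dt;
            v[i] = v_reset;
          } else {
            v[i] += dt * (-v[i] + I[i]) / tau_m;
            if (v[i] >= v_t) {
              if (del_window && i == delete_neuron) {
                deletion_done = true;
                if (delete_transmission_only) {
                  v[i] = v_reset;
                  refr[i] = tau_ref;
                } // else: reset skipped, membrane rides on
              } else {
                spikers.push_back(i);
                v[i] = v_reset;
                refr[i] = tau_ref;
              }
            }
          }
        }
      } else { // Izhikevich
        for (int i = 0; i < N; ++i) {
          const double vold = v[i];
          v[i] += dt * (k * (vold - v_r) * (vold - v_t) - uad[i] + I[i]) / C;
          uad[i] += dt * a * (b * (vold - v_r) - uad[i]);
          if (v[i] >= v_peak) {
            if (del_window && i == delete_neuron) {
              // the quadratic upstroke forces a reset either way; the spike
              // is simply never transmitted (and leaves no raster event)
              deletion_done = true;
              v[i] = v_reset;
              uad[i] += d;
            } else {
              spikers.push_back(i);
              v[i] = v_reset;
              uad[i] += d;
            }
          }
        }
      }

      // synaptic filters: exact exponential decay, impulse jumps on spikes
      if (syn_kind == 1) {
        r = r * e_d + hr * c_de;
        hr *= e_r;
        Ipsc = Ipsc * e_d + hI * c_de;
        hI *= e_r;
      } else {
        r *= e_s;
        Ipsc *= e_s;
      }

      for (arma::uword idx = 0; idx < spikers.size(); ++idx) {
        const arma::uword j = spikers[idx];
        sp_t.push_back(t_now);
        sp_id.push_back(j + 1);
        ++block_spikes;
        if (syn_kind == 1) {
          hr[j] += jump_de;
          // add the j-th static column into the rise variable
          for (arma::sp_mat::const_col_iterator it = omega_static.begin_col(j);
               it != omega_static.end_col(j); ++it) {
            hI[it.row()] += (*it) * jump_de;
          }
        } else {
          r[j] += jump_se;
          for (arma::sp_mat::const_col_iterator it = omega_static.begin_col(j);
               it != omega_static.end_col(j); ++it) {
            Ipsc[it.row()] += (*it) * jump_se;
          }
        }
      }

      if (s >= stat_start) ++stat_n; // spiking stats come from the raster in R
    }

    // RLS update
    if (rls_on && (s + 1) >= rls_start && (s + 1) <= rls_stop &&
        ((s + 1) % rls_every == 0)) {
      const int kx = (s + 1) / rls_every - 1;
      if (kx >= 0 && kx < (int)X.n_cols) {
        e = phi.t() * r - X.col(kx);
        // P is stored as its upper triangle (symmetric): dsymv/dsyr keep
        // it exactly symmetric with half the memory traffic
        const double d_one = 1.0, d_zero = 0.0;
        const int i_one = 1;
        F77_CALL(dsymv)("U", &N, &d_one, P.memptr(), &N, r.memptr(), &i_one,
                        &d_zero, Pr.memptr(), &i_one FCONE);
        const double denom = 1.0 + arma::dot(r, Pr);
        if (!std::isfinite(denom)) {
          stop("RLS correlation estimate lost conditioning (non-finite denominator) at t = %f ms",
               t_now);
        }
        phi -= Pr * e.t() / (denom_in_phi ? denom : 1.0);
        const double alpha = -1.0 / denom;
        F77_CALL(dsyr)("U", &N, &alpha, Pr.memptr(), &i_one, P.memptr(), &N FCONE);
        ++rls_count;
      }
    }

    if (record_every > 0 && ((s + 1) % record_every == 0)) {
      const int kr = (s + 1) / record_every - 1;
      if (kr < nrec) {
        xhat_rec.col(kr) = (model == MODEL_RATE) ? xhat : phi.t() * r;
        t_rec[kr] = t_now;
      }
    }
    if (phi_record_every > 0 && ((s + 1) % phi_record_every == 0)) {
      const int kp = (s + 1) / phi_record_every - 1;
      if (kp < nphirec) {
        phi_track.col(kp) = phi.submat(0, 0, ntrack - 1, 0);
        for (int cc = 0; cc < m; ++cc) phi_norm(cc, kp) = arma::norm(phi.col(cc));
        t_phi[kp] = t_now;
      }
    }

    // health checks
    if ((s + 1) % 200 == 0) {
      if (!v.is_finite()) {
        arma::uword bad = 0;
        for (arma::uword i = 0; i < v.n_elem; ++i)
          if (!std::isfinite(v[i])) { bad = i; break; }
        stop("integration instability: non-finite state for neuron %d at t = %f ms",
             (int)bad + 1, t_now);
      }
    }
    if (model != MODEL_RATE && ((s + 1) % block == 0)) {
      const double hz = 1000.0 * block_spikes / (N * block * dt);
      if (runaway_hz > 0 && hz > runaway_hz) {
        stop("runaway network activity: mean rate %.1f Hz exceeds bound %.1f Hz at t = %f ms",
             hz, runaway_hz, t_now);
      }
      block_spikes = 0;
    }
  }

  List out = List::create(
    _["spike_t"] = wrap(sp_t),
    _["spike_id"] = wrap(sp_id),
    _["xhat"] = xhat_rec,
    _["t_rec"] = t_rec,
    _["phi"] = phi,
    _["phi_track"] = phi_track,
    _["phi_norm"] = phi_norm,
    _["t_phi"] = t_phi,
    _["state"] = List::create(_["v"] = v, _["u"] = uad, _["refr"] = refr,
                              _["r"] = r, _["hr"] = hr, _["Ipsc"] = Ipsc,
                              _["hI"] = hI),
    _["sum_r"] = sum_r,
    _["max_r"] = max_r,
    _["stat_n"] = (double)stat_n);
  if (return_P) out["P"] = arma::mat(arma::symmatu(P));
  return out;
}
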