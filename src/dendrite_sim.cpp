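// Conductance-based membrane dynamics:
//  - single-compartment (point-dendrite) exponential-Euler integrator
//  - tree cable solver (backward Euler in V, Hines elimination)
// Channel kinetics follow a shared first-order Boltzmann gating scheme; the
// channel tables live on the R side.

#include <Rcpp.h>
using namespace Rcpp;

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

static inline double mgblock(double v, double mg) {
  return 1.0 / (1.0 + mg / 3.57 * std::exp(-0.062 * v));
}

// channel table columns (shared with R):
// 0 gbar, 1 erev, 2 is_k, 3 p, 4 act_vh, 5 act_k, 6 act_tau,
// 7 q, 8 inact_vh, 9 inact_k, 10 inact_tau

// [[Rcpp::export]]
List cpp_point_dendrite(NumericMatrix ch, double cm, double v0,
                        NumericVector ev_time, IntegerVector ev_type,
                        NumericVector ev_amp,
                        NumericMatrix syn, // rows: types; cols taur,taud,erev,is_nmda
                        NumericVector ek_time, NumericVector ek_value,
                        double dt, double t_total, int record_every,
                        double mg) {
  const int nch = ch.nrow(), nsyn = syn.nrow(), nev = ev_time.size();
  const int nt = (int)std::ceil(t_total / dt);
  const int nrec = (nt + record_every - 1) / record_every;

  std::vector<double> act(nch, 1.0), inact(nch, 1.0);
  std::vector<double> fact(nch, 0.0), finact(nch, 0.0);
  for (int c = 0; c < nch; ++c) {
    if (ch(c, 3) > 0) {
      act[c] = boltz(v0, ch(c, 4), ch(c, 5));
      fact[c] = 1.0 - std::exp(-dt / ch(c, 6));
    }
    if (ch(c, 7) > 0) {
      inact[c] = boltz(v0, ch(c, 8), ch(c, 9));
      finact[c] = 1.0 - std::exp(-dt / ch(c, 10));
    }
  }
  std::vector<double> synA(nsyn, 0.0), synB(nsyn, 0.0);
  std::vector<double> decA(nsyn), decB(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    decA[s] = std::exp(-dt / syn(s, 0));
    decB[s] = std::exp(-dt / syn(s, 1));
  }

  NumericVector t_out(nrec), v_out(nrec);
  NumericMatrix gates_out(nrec, 2 * nch);
  double v = v0;
  int iev = 0, iek = 0, irec = 0;
  double dek = 0.0;
  for (int i = 0; i < nt; ++i) {
    double t = i * dt;
    while (iek < ek_time.size() && ek_time[iek] <= t) {
      dek = ek_value[iek];
      ++iek;
    }
    while (iev < nev && ev_time[iev] <= t) {
      int s = ev_type[iev];
      synA[s] += ev_amp[iev];
      synB[s] += ev_amp[iev];
      ++iev;
    }
    // gating (exponential update, tau constant)
    for (int c = 0; c < nch; ++c) {
      if (ch(c, 3) > 0) act[c] += (boltz(v, ch(c, 4), ch(c, 5)) - act[c]) * fact[c];
      if (ch(c, 7) > 0) inact[c] += (boltz(v, ch(c, 8), ch(c, 9)) - inact[c]) * finact[c];
    }
    // total conductance and reversal-weighted sum
    double gsum = 0.0, gesum = 0.0;
    for (int c = 0; c < nch; ++c) {
      double g = ch(c, 0);
      int p = (int)ch(c, 3);
      for (int k = 0; k < p; ++k) g *= act[c];
      if ((int)ch(c, 7) > 0) g *= inact[c];
      double e = ch(c, 1) + (ch(c, 2) > 0 ? dek : 0.0);
      gsum += g;
      gesum += g * e;
    }
    for (int s = 0; s < nsyn; ++s) {
      double g = synB[s] - synA[s];
      if (g < 0) g = 0;
      if (syn(s, 3) > 0) g *= mgblock(v, mg);
      gsum += g;
      gesum += g * syn(s, 2);
      synA[s] *= decA[s];
      synB[s] *= decB[s];
    }
    double vinf = gesum / gsum;
    double tau = cm / gsum;
    v = vinf + (v - vinf) * std::exp(-dt / tau);
    if (!std::isfinite(v)) stop("integration failure: non-finite Vm at t=%f", t);
    if (i % record_every == 0) {
      t_out[irec] = t;
      v_out[irec] = v;
      for (int c = 0; c < nch; ++c) {
        gates_out(irec, c) = act[c];
        gates_out(irec, nch + c) = inact[c];
      }
      ++irec;
    }
  }
  return List::create(_["t_ms"] = t_out, _["v_mV"] = v_out,
                      _["gates"] = gates_out);
}

// [[Rcpp::export]]
List cpp_cable_sim(IntegerVector parent,       // 0-based, -1 for root; parent[i] < i
                   NumericVector cm_abs,       // uF per compartment
                   NumericVector g_axial,      // mS to parent (0 for root)
                   NumericMatrix ch,           // kinetics table as above (gbar unused)
                   NumericMatrix gdens,        // ncomp x nch absolute conductance, mS
                   NumericVector dek,          // per-compartment static E_K shift, mV
                   NumericVector ev_time, IntegerVector ev_comp,
                   IntegerVector ev_type, NumericVector ev_amp, // amp in mS
                   NumericMatrix syn,
                   double dt, double t_total,
                   IntegerVector record_comp,  // 0-based compartments to record
                   int record_every, double mg, double v0) {
  const int ncomp = parent.size(), nch = ch.nrow(), nsyn = syn.nrow();
  const int nev = ev_time.size();
  const int nt = (int)std::ceil(t_total / dt);
  const int nrec = (nt + record_every - 1) / record_every;
  const int nrc = record_comp.size();

  // cache kinetics in flat arrays (NumericMatrix access is slow in hot loops)
  std::vector<int> cp(nch), cq(nch), cisk(nch);
  std::vector<double> cerev(nch), cavh(nch), cak(nch), civh(nch), cik(nch);
  std::vector<double> fact(nch, 0.0), finact(nch, 0.0);
  for (int c = 0; c < nch; ++c) {
    cp[c] = (int)ch(c, 3);
    cq[c] = (int)ch(c, 7);
    cisk[c] = ch(c, 2) > 0 ? 1 : 0;
    cerev[c] = ch(c, 1);
    cavh[c] = ch(c, 4);
    cak[c] = ch(c, 5);
    civh[c] = ch(c, 8);
    cik[c] = ch(c, 9);
    if (cp[c] > 0) fact[c] = 1.0 - std::exp(-dt / ch(c, 6));
    if (cq[c] > 0) finact[c] = 1.0 - std::exp(-dt / ch(c, 10));
  }
  std::vector<double> act(ncomp * nch), inact(ncomp * nch);
  std::vector<double> gd(ncomp * nch);
  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < ncomp; ++i) {
      act[i * nch + c] = (cp[c] > 0) ? boltz(v0, cavh[c], cak[c]) : 1.0;
      inact[i * nch + c] = (cq[c] > 0) ? boltz(v0, civh[c], cik[c]) : 1.0;
      gd[i * nch + c] = gdens(i, c);
    }
  }
  NumericMatrix synA(ncomp, nsyn), synB(ncomp, nsyn);
  std::vector<double> decA(nsyn), decB(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    decA[s] = std::exp(-dt / syn(s, 0));
    decB[s] = std::exp(-dt / syn(s, 1));
  }

  std::vector<double> v(ncomp, v0), d(ncomp), rhs(ncomp);
  NumericMatrix v_out(nrec, nrc);
  NumericVector t_out(nrec);
  int iev = 0, irec = 0;

  for (int i = 0; i < nt; ++i) {
    double t = i * dt;
    while (iev < nev && ev_time[iev] <= t) {
      int cidx = ev_comp[iev], s = ev_type[iev];
      synA(cidx, s) += ev_amp[iev];
      synB(cidx, s) += ev_amp[iev];
      ++iev;
    }
    for (int n = 0; n < ncomp; ++n) {
      double vn = v[n];
      double gsum = 0.0, gesum = 0.0;
      double *an = &act[n * nch], *hn = &inact[n * nch], *gn = &gd[n * nch];
      for (int c = 0; c < nch; ++c) {
        double a = an[c], h = hn[c];
        if (cp[c] > 0) {
          a += (boltz(vn, cavh[c], cak[c]) - a) * fact[c];
          an[c] = a;
        }
        if (cq[c] > 0) {
          h += (boltz(vn, civh[c], cik[c]) - h) * finact[c];
          hn[c] = h;
        }
        double g = gn[c];
        if (g <= 0) continue;
        for (int k = 0; k < cp[c]; ++k) g *= a;
        if (cq[c] > 0) g *= h;
        double e = cerev[c] + (cisk[c] ? dek[n] : 0.0);
        gsum += g;
        gesum += g * e;
      }
      for (int s = 0; s < nsyn; ++s) {
        double g = synB(n, s) - synA(n, s);
        if (g < 0) g = 0;
        if (g > 0) {
          if (syn(s, 3) > 0) g *= mgblock(vn, mg);
          gsum += g;
          gesum += g * syn(s, 2);
        }
        synA(n, s) *= decA[s];
        synB(n, s) *= decB[s];
      }
      double cdt = cm_abs[n] / dt;
      d[n] = cdt + gsum;
      rhs[n] = cdt * vn + gesum;
    }
    // axial terms
    for (int n = 1; n < ncomp; ++n) {
      int p = parent[n];
      if (p >= 0 && g_axial[n] > 0) {
        d[n] += g_axial[n];
        d[p] += g_axial[n];
      }
    }
    // Hines elimination: children have larger indices than parents
    for (int n = ncomp - 1; n >= 1; --n) {
      int p = parent[n];
      if (p < 0) continue;
      double f = g_axial[n] / d[n];
      d[p] -= f * g_axial[n];
      rhs[p] += f * rhs[n];
    }
    v[0] = rhs[0] / d[0];
    for (int n = 1; n < ncomp; ++n) {
      int p = parent[n];
      v[n] = (rhs[n] + g_axial[n] * v[p]) / d[n];
      if (!std::isfinite(v[n])) stop("integration failure: non-finite Vm at t=%f", t);
    }
    if (i % record_every == 0) {
      t_out[irec] = t;
      for (int j = 0; j < nrc; ++j) v_out(irec, j) = v[record_comp[j]];
      ++irec;
    }
  }
  return List::create(_["t_ms"] = t_out, _["v_mV"] = v_out);
}
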