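#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the dual-source Rescorla-Wagner model.
//
// Two value traces run in parallel: V_primary tracks the probability that
// the primary-congruent option is rewarded (updated with the outcome r),
// V_secondary tracks the probability that the secondary source's advice is
// correct (updated with the inferred correctness s = advice XOR r).  On each
// trial the secondary belief is converted to a primary-congruent probability
// via |advice - V_secondary|, mixed with V_primary by zeta, and pushed
// through the unit-square sigmoid with inverse temperature beta.
//
// phase codes: 0 = stable, 1 = volatile.  y may contain NA (missing choice):
// such trials update beliefs (feedback was shown) but add nothing to the
// negative log-likelihood.
//
// alpha is length 4: (primary/stable, primary/volatile,
//                     secondary/stable, secondary/volatile).

static const double V_CLIP = 1e-6;  // clip combined value before the sigmoid
static const double LOG_P_MIN = -27.631021115928547;  // log(1e-12): per-trial
// log-loss floor, applied identically to both choice branches so that
// relabelling the two options leaves the likelihood invariant

// [[Rcpp::export]]
List rw_filter_cpp(NumericVector alpha, double zeta, double beta, double v0,
                   IntegerVector r, IntegerVector advice,
                   IntegerVector phase_primary, IntegerVector phase_secondary,
                   IntegerVector y) {
  int n = r.size();
  NumericVector Vp(n), Vs(n), Vaw(n), Vc(n), pc(n), pep(n), pes(n);
  double vp = v0, vs = v0, nll = 0.0;
  int n_used = 0;

  for (int t = 0; t < n; ++t) {
    Vp[t] = vp;
    Vs[t] = vs;
    double aw = std::fabs((double)advice[t] - vs);
    Vaw[t] = aw;
    double vc = zeta * aw + (1.0 - zeta) * vp;
    Vc[t] = vc;
    double vcl = std::min(1.0 - V_CLIP, std::max(V_CLIP, vc));
    double num = std::pow(vcl, beta);
    double den = num + std::pow(1.0 - vcl, beta);
    double p = num / den;
    pc[t] = std::min(1.0 - 1e-12, std::max(1e-12, p));

    if (y[t] != NA_INTEGER) {
      double term = (y[t] == 1) ? std::log(p) : std::log1p(-p);
      if (!(term > LOG_P_MIN)) term = LOG_P_MIN;
      nll -= term;
      ++n_used;
    }

    // secondary source correct iff its advice endorsed the rewarded option
    int s = (advice[t] != r[t]) ? 1 : 0;
    pep[t] = (double)r[t] - vp;
    pes[t] = (double)s - vs;
    double ap = (phase_primary[t] == 1) ? alpha[1] : alpha[0];
    double as = (phase_secondary[t] == 1) ? alpha[3] : alpha[2];
    vp += ap * ((double)r[t] - vp);
    vs += as * ((double)s - vs);
  }

  return List::create(_["v_primary"] = Vp, _["v_secondary"] = Vs,
                      _["v_advice_weighted"] = Vaw, _["v_combined"] = Vc,
                      _["p_choice"] = pc, _["pe_primary"] = pep,
                      _["pe_secondary"] = pes, _["nll"] = nll,
                      _["n_choices"] = n_used);
}

// Negative log-likelihood only (hot path for the optimiser).
// [[Rcpp::export]]
double rw_nll_cpp(NumericVector alpha, double zeta, double beta, double v0,
                  IntegerVector r, IntegerVector advice,
                  IntegerVector phase_primary, IntegerVector phase_secondary,
                  IntegerVector y) {
  int n = r.size();
  double vp = v0, vs = v0, nll = 0.0;
  for (int t = 0; t < n; ++t) {
    double aw = std::fabs((double)advice[t] - vs);
    double vc = zeta * aw + (1.0 - zeta) * vp;
    double vcl = std::min(1.0 - V_CLIP, std::max(V_CLIP, vc));
    if (y[t] != NA_INTEGER) {
      double num = std::pow(vcl, beta);
      double p = num / (num + std::pow(1.0 - vcl, beta));
      double term = (y[t] == 1) ? std::log(p) : std::log1p(-p);
      if (!(term > LOG_P_MIN)) term = LOG_P_MIN;
      nll -= term;
    }
    int s = (advice[t] != r[t]) ? 1 : 0;
    vp += ((phase_primary[t] == 1) ? alpha[1] : alpha[0]) * ((double)r[t] - vp);
    vs += ((phase_secondary[t] == 1) ? alpha[3] : alpha[2]) * ((double)s - vs);
  }
  return nll;
}
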