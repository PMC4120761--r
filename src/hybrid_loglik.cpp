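#include <Rcpp.h>
using namespace Rcpp;

// One forward pass of the hybrid learner over a session.
//
// par: beta1, beta2, alpha1, alpha2, lam, omega, rho
// a1, a2 in {0,1}; s2 in {0,1}; r in {0,1}
// common_map[a] = common second-stage state for first-stage action a
//
// Per trial: model-based first-stage values from the true transition
// probabilities and the current max second-stage value; net values mix
// MB and MF by omega; softmax with inverse temperature beta1 and a
// perseveration bonus rho toward the previous first-stage action;
// second stage is a plain softmax over its MF values. Prediction errors
// use the pre-update values; the second-stage error also updates the
// first-stage value through the stage-skipping weight lambda.
// Likelihood-only variant for the optimizer's hot loop: no per-trial
// output allocation.
// [[Rcpp::export]]
double hybrid_session_loglik(IntegerVector a1, IntegerVector s2,
                             IntegerVector a2, NumericVector r,
                             NumericVector par, double p_common,
                             IntegerVector common_map) {
  const int n = a1.size();
  const double beta1 = par[0], beta2 = par[1], alpha1 = par[2],
               alpha2 = par[3], lam = par[4], omega = par[5], rho = par[6];
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  double ll = 0.0;
  int prev = -1;
  for (int t = 0; t < n; ++t) {
    double qmb[2];
    for (int a = 0; a < 2; ++a) {
      int cs = common_map[a];
      double mc = std::max(q2[cs][0], q2[cs][1]);
      double mo = std::max(q2[1 - cs][0], q2[1 - cs][1]);
      qmb[a] = p_common * mc + (1.0 - p_common) * mo;
    }
    double v0 = omega * qmb[0] + (1.0 - omega) * q1[0];
    double v1 = omega * qmb[1] + (1.0 - omega) * q1[1];
    double x0 = beta1 * (v0 + rho * (prev == 0 ? 1.0 : 0.0));
    double x1 = beta1 * (v1 + rho * (prev == 1 ? 1.0 : 0.0));
    double mx = std::max(x0, x1);
    double e0 = std::exp(x0 - mx), e1 = std::exp(x1 - mx);
    double p1 = (a1[t] == 0 ? e0 : e1) / (e0 + e1);
    int s = s2[t];
    double y0 = beta2 * q2[s][0], y1 = beta2 * q2[s][1];
    double my = std::max(y0, y1);
    double f0 = std::exp(y0 - my), f1 = std::exp(y1 - my);
    double p2 = (a2[t] == 0 ? f0 : f1) / (f0 + f1);
    double d1 = q2[s][a2[t]] - q1[a1[t]];
    double d2 = r[t] - q2[s][a2[t]];
    q2[s][a2[t]] += alpha2 * d2;
    q1[a1[t]] += alpha1 * d1 + alpha1 * lam * d2;
    ll += std::log(std::max(p1, 1e-300)) + std::log(std::max(p2, 1e-300));
    prev = a1[t];
  }
  return ll;
}

// [[Rcpp::export]]
List hybrid_session_pass(IntegerVector a1, IntegerVector s2, IntegerVector a2,
                         NumericVector r, NumericVector par,
                         double p_common, IntegerVector common_map) {
  const int n = a1.size();
  const double beta1 = par[0], beta2 = par[1], alpha1 = par[2],
               alpha2 = par[3], lam = par[4], omega = par[5], rho = par[6];
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  NumericVector delta1(n), delta2(n), p_a1(n), p_a2(n);
  IntegerVector rep1(n);
  double ll = 0.0;
  int prev = -1;  // no previous first-stage action on trial 1

  for (int t = 0; t < n; ++t) {
    // model-based first-stage values (true transition probabilities)
    double qmb[2];
    for (int a = 0; a < 2; ++a) {
      int cs = common_map[a];
      double mc = std::max(q2[cs][0], q2[cs][1]);
      double mo = std::max(q2[1 - cs][0], q2[1 - cs][1]);
      qmb[a] = p_common * mc + (1.0 - p_common) * mo;
    }
    double v0 = omega * qmb[0] + (1.0 - omega) * q1[0];
    double v1 = omega * qmb[1] + (1.0 - omega) * q1[1];

    double x0 = beta1 * (v0 + rho * (prev == 0 ? 1.0 : 0.0));
    double x1 = beta1 * (v1 + rho * (prev == 1 ? 1.0 : 0.0));
    double mx = std::max(x0, x1);
    double e0 = std::exp(x0 - mx), e1 = std::exp(x1 - mx);
    double p1 = (a1[t] == 0 ? e0 : e1) / (e0 + e1);

    int s = s2[t];
    double y0 = beta2 * q2[s][0], y1 = beta2 * q2[s][1];
    double my = std::max(y0, y1);
    double f0 = std::exp(y0 - my), f1 = std::exp(y1 - my);
    double p2 = (a2[t] == 0 ? f0 : f1) / (f0 + f1);

    double d1 = q2[s][a2[t]] - q1[a1[t]];
    double d2 = r[t] - q2[s][a2[t]];
    q2[s][a2[t]] += alpha2 * d2;
    q1[a1[t]] += alpha1 * d1 + alpha1 * lam * d2;

    ll += std::log(std::max(p1, 1e-300)) + std::log(std::max(p2, 1e-300));
    delta1[t] = d1;
    delta2[t] = d2;
    p_a1[t] = p1;
    p_a2[t] = p2;
    rep1[t] = (prev >= 0 && a1[t] == prev) ? 1 : 0;
    prev = a1[t];
  }

  return List::create(_["loglik"] = ll, _["delta1"] = delta1,
                      _["delta2"] = delta2, _["rep1"] = rep1,
                      _["p_a1"] = p_a1, _["p_a2"] = p_a2,
                      _["q1_final"] = NumericVector::create(q1[0], q1[1]),
                      _["q2_final"] = NumericVector::create(
                          q2[0][0], q2[1][0], q2[0][1], q2[1][1]));
}
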