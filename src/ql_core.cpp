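#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise Rescorla-Wagner Q-learning pass over one session.
//
// Encoding contract (see R wrappers in R/rl_models.R):
//   choice : 1 = option A, 2 = option B, 0 = missed trial
//   outcome: 1 = win, -1 = loss, 0 = none (missed)
//
// Q-values are stored *before* the trial's update; the softmax has unit
// temperature (the sensitivities carry the reinforcement magnitude).
// Missed trials contribute no likelihood term and leave Q unchanged.
// [[Rcpp::export]]
List ql_trajectory_cpp(IntegerVector choice, IntegerVector outcome,
                       double alpha, double beta_rew, double beta_pun,
                       double q_init, bool double_update) {
  int n = choice.size();
  NumericVector qA(n), qB(n);
  NumericVector p_choice(n, NA_REAL), pe(n, NA_REAL);
  double qa = q_init, qb = 0.0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    qA[t] = qa;
    qB[t] = qb;
    int c = choice[t];
    if (c != 1 && c != 2) continue;  // missed: carry Q forward
    double pA = 1.0 / (1.0 + std::exp(-(qa - qb)));
    double pc = (c == 1) ? pA : 1.0 - pA;
    p_choice[t] = pc;
    ll += std::log(pc);
    double R = (outcome[t] == 1) ? beta_rew : beta_pun;
    double delta = R - ((c == 1) ? qa : qb);
    pe[t] = delta;
    if (c == 1) {
      qa += alpha * delta;
      if (double_update) qb += alpha * (-R - qb);
    } else {
      qb += alpha * delta;
      if (double_update) qa += alpha * (-R - qa);
    }
  }
  return List::create(_["qA"] = qA, _["qB"] = qB,
                      _["p_choice"] = p_choice, _["pe"] = pe,
                      _["loglik"] = ll);
}

// Log-likelihood only; hot path for MAP optimization.
// [[Rcpp::export]]
double ql_loglik_cpp(IntegerVector choice, IntegerVector outcome,
                     double alpha, double beta_rew, double beta_pun,
                     double q_init, bool double_update) {
  int n = choice.size();
  double qa = q_init, qb = 0.0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = choice[t];
    if (c != 1 && c != 2) continue;
    double pA = 1.0 / (1.0 + std::exp(-(qa - qb)));
    double pc = (c == 1) ? pA : 1.0 - pA;
    ll += std::log(pc);
    double R = (outcome[t] == 1) ? beta_rew : beta_pun;
    double delta = R - ((c == 1) ? qa : qb);
    if (c == 1) {
      qa += alpha * delta;
      if (double_update) qb += alpha * (-R - qb);
    } else {
      qb += alpha * delta;
      if (double_update) qa += alpha * (-R - qa);
    }
  }
  return ll;
}
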