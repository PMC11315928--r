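#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a valence-specific Q-learning model over one
// subject-visit trial sequence. cond: 0 = win, 1 = loss; choice: 1 = the
// high-probability symbol of the pair, 0 = the low-probability symbol;
// outcome in {-1, 0, +1}. block is used only when reset_per_block is true.
// Q state: [win-high, win-low, loss-high, loss-low], initialised to 0.
// [[Rcpp::export]]
double pilt_nll_core(IntegerVector cond, IntegerVector choice,
                     NumericVector outcome, IntegerVector block,
                     double alpha_win, double alpha_loss,
                     double rho_win, double rho_loss,
                     bool reset_per_block) {
  int n = cond.size();
  double Q[4] = {0.0, 0.0, 0.0, 0.0};
  double nll = 0.0;
  int cur_block = n > 0 ? block[0] : 0;
  for (int i = 0; i < n; ++i) {
    if (reset_per_block && block[i] != cur_block) {
      Q[0] = Q[1] = Q[2] = Q[3] = 0.0;
      cur_block = block[i];
    }
    int base = (cond[i] == 0) ? 0 : 2;
    int c = base + (choice[i] == 1 ? 0 : 1);
    int o = base + (choice[i] == 1 ? 1 : 0);
    double dq = Q[c] - Q[o];
    // softmax pair probability, unit temperature; stable for large |dq|
    double p = 1.0 / (1.0 + std::exp(-dq));
    if (p < 1e-300) p = 1e-300;
    nll -= std::log(p);
    double alpha = (cond[i] == 0) ? alpha_win : alpha_loss;
    double rho = (cond[i] == 0) ? rho_win : rho_loss;
    Q[c] += alpha * (rho * outcome[i] - Q[c]);
  }
  return nll;
}
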