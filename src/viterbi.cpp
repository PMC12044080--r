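#include <Rcpp.h>
using namespace Rcpp;

// Three-state (AA, AB, BB) Viterbi decoder for windowed allele counts.
//
// Emission: P(nA | state, n = nA + nB) = Binomial(n, pA_state); windows
// with n = 0 emit likelihood 1 for every state. All arithmetic is in log
// space. Tie-breaking prefers the predecessor equal to the current state,
// so exact score ties never introduce a spurious crossover.
//
// [[Rcpp::export(name = ".viterbi_core")]]
List viterbi_core(IntegerVector nA, IntegerVector nB,
                  NumericVector pA_state, NumericVector log_init,
                  NumericMatrix log_trans) {
  const int T = nA.size();
  const int S = 3;
  if (T < 1) stop("invalid-argument: empty observation sequence");

  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);

  auto emit = [&](int t, int s) -> double {
    int tot = nA[t] + nB[t];
    if (tot == 0) return 0.0;  // empty window: likelihood 1 for all states
    return R::dbinom((double)nA[t], (double)tot, pA_state[s], 1);
  };

  for (int s = 0; s < S; ++s) delta(s, 0) = log_init[s] + emit(0, s);

  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      // start from the same-state predecessor (preferred on ties)
      int best = s;
      double best_score = delta(s, t - 1) + log_trans(s, s);
      for (int j = 0; j < S; ++j) {
        if (j == s) continue;
        double sc = delta(j, t - 1) + log_trans(j, s);
        if (sc > best_score) { best_score = sc; best = j; }
      }
      delta(s, t) = best_score + emit(t, s);
      psi(s, t) = best;
    }
  }

  int last = 0;
  double best_final = delta(0, T - 1);
  for (int s = 1; s < S; ++s) {
    if (delta(s, T - 1) > best_final) { best_final = delta(s, T - 1); last = s; }
  }

  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based state codes

  return List::create(_["path"] = path, _["logp"] = best_final);
}
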