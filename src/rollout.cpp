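#include <Rcpp.h>
using namespace Rcpp;

// Greedy rollout through the planner's model without learning: follow the
// argmax of Q (ties broken uniformly via R's RNG) from `start` until the
// goal or until `cap` simulated actions. Saltatory agents count an option
// launch as one simulated action; others count its primitive steps.
// All indices are 1-based (as in the R tables).
// [[Rcpp::export]]
List cpp_greedy_rollout(NumericMatrix Q, List avail, IntegerMatrix next_state,
                        NumericMatrix term, NumericMatrix dur,
                        bool saltatory, int start, int goal, int cap) {
  int s = start;
  long sim = 0, steps = 0, decisions = 0;
  std::vector<int> cand;
  while (s != goal && sim < cap) {
    IntegerVector av = avail[s - 1];
    double best = R_NegInf;
    for (int i = 0; i < av.size(); ++i) {
      double q = Q(s - 1, av[i] - 1);
      if (q > best) best = q;
    }
    cand.clear();
    for (int i = 0; i < av.size(); ++i)
      if (Q(s - 1, av[i] - 1) == best) cand.push_back(av[i]);
    int a = cand.size() == 1 ? cand[0]
      : cand[(int)(unif_rand() * cand.size()) % cand.size()];
    ++decisions;
    if (a <= 4) {
      s = next_state(s - 1, a - 1);
      ++steps;
      ++sim;
    } else {
      int o = a - 5;                       // 0-based option column
      int k = (int)dur(s - 1, o);
      int s2 = (int)term(s - 1, o);
      steps += k;
      sim += saltatory ? 1 : k;
      s = s2;
    }
  }
  return List::create(_["sim"] = (double)sim, _["steps"] = (double)steps,
                      _["decisions"] = (double)decisions,
                      _["reached"] = s == goal);
}
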