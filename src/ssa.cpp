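#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method on a compiled mass-action network.
//
// x0:     initial copy numbers (length S)
// stoich: S x R net stoichiometry (products - reactants)
// r1,r2:  0-based reactant indices per reaction (-1 = none); r2 valid only
//         for order-2 reactions
// homo:   order-2 reaction is a self-interaction (propensity k*x*(x-1)/2)
// rate:   rate constants
// grid:   reporting times, strictly increasing, grid[0] == 0
//
// Uses R's RNG stream so a set.seed() in the caller makes the trajectory
// bit-reproducible. The state recorded at a grid time is the state holding
// at that instant (left-continuous between reaction events). When the total
// propensity reaches zero the state is absorbing and the remaining grid is
// filled with the frozen state.
// [[Rcpp::export]]
NumericMatrix ssa_run_cpp(NumericVector x0, IntegerMatrix stoich,
                          IntegerVector r1, IntegerVector r2,
                          LogicalVector homo, NumericVector rate,
                          NumericVector grid) {
  const int S = x0.size();
  const int R = rate.size();
  const int G = grid.size();
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(G, S);
  std::vector<double> a(R);
  RNGScope scope;

  double t = 0.0;
  int gi = 0;
  for (;;) {
    double atot = 0.0;
    for (int j = 0; j < R; ++j) {
      double aj;
      const int i1 = r1[j];
      if (i1 < 0) {
        aj = rate[j];
      } else if (r2[j] < 0) {
        aj = rate[j] * x[i1];
      } else if (homo[j]) {
        aj = rate[j] * x[i1] * (x[i1] - 1.0) * 0.5;
      } else {
        aj = rate[j] * x[i1] * x[r2[j]];
      }
      a[j] = aj;
      atot += aj;
    }
    if (!std::isfinite(atot))
      stop("propensity overflow: total propensity is not finite");

    double tnext = (atot > 0.0) ? t + R::exp_rand() / atot : R_PosInf;

    while (gi < G && grid[gi] < tnext) {
      for (int s = 0; s < S; ++s) out(gi, s) = x[s];
      ++gi;
    }
    if (gi >= G || !std::isfinite(tnext)) break;

    t = tnext;
    double u = R::unif_rand() * atot;
    int j = 0;
    double c = a[0];
    while (c < u && j < R - 1) {
      ++j;
      c += a[j];
    }
    for (int s = 0; s < S; ++s) x[s] += stoich(s, j);
  }
  return out;
}
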