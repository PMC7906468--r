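#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie direct-method) simulation of a jump process whose
// propensities are linear in the counts: a_j(n) = sum_k coef(j,k) * n_k.
// Uses R's RNG so runs are reproducible through set.seed().
//
// Records the state at each requested output time (the state holding just
// before that time), tracks absorption at total 0 and the first time the
// total strictly exceeds `threshold`. With `stop_at_threshold` the walk
// stops at that crossing (remaining output times repeat the crossing state).
// [[Rcpp::export(name = ".ssa_linear")]]
List ssa_linear(NumericMatrix coef, IntegerMatrix stoich,
                NumericVector init, double t_end,
                NumericVector times_out, double threshold,
                bool stop_at_threshold) {
  const int nr = coef.nrow();
  const int nk = coef.ncol();
  if (stoich.nrow() != nr || stoich.ncol() != nk)
    stop("propensity and stoichiometry dimensions disagree");
  if (init.size() != nk) stop("initial state has wrong length");

  std::vector<double> n(nk);
  double total = 0.0;
  for (int k = 0; k < nk; ++k) {
    if (init[k] < 0 || init[k] != std::floor(init[k]))
      stop("initial counts must be non-negative integers");
    n[k] = init[k];
    total += n[k];
  }

  const int nt = times_out.size();
  NumericMatrix states(nt, nk);
  int out_idx = 0;
  double t = 0.0;
  double ext_time = NA_REAL;
  double cross_time = NA_REAL;
  bool crossed = total > threshold;
  if (crossed) cross_time = 0.0;

  std::vector<double> a(nr);

  auto flush_outputs = [&](double upto) {
    while (out_idx < nt && times_out[out_idx] <= upto) {
      for (int k = 0; k < nk; ++k) states(out_idx, k) = n[k];
      ++out_idx;
    }
  };

  RNGScope scope;
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      double aj = 0.0;
      for (int k = 0; k < nk; ++k) aj += coef(j, k) * n[k];
      a[j] = aj > 0 ? aj : 0.0;
      a0 += a[j];
    }
    if (a0 <= 0.0) { flush_outputs(t_end); break; }

    double dt = exp_rand() / a0;
    double t_next = t + dt;
    if (t_next > t_end) { flush_outputs(t_end); break; }
    // outputs strictly before the jump see the pre-jump state
    while (out_idx < nt && times_out[out_idx] < t_next) {
      for (int k = 0; k < nk; ++k) states(out_idx, k) = n[k];
      ++out_idx;
    }

    double u = unif_rand() * a0;
    int j = 0;
    double cum = a[0];
    while (j < nr - 1 && u > cum) cum += a[++j];

    total = 0.0;
    for (int k = 0; k < nk; ++k) {
      n[k] += stoich(j, k);
      if (n[k] < 0) n[k] = 0;  // cannot happen with consistent propensities
      total += n[k];
    }
    t = t_next;

    if (total <= 0.0) { ext_time = t; flush_outputs(t_end); break; }
    if (!crossed && total > threshold) {
      crossed = true;
      cross_time = t;
      if (stop_at_threshold) { flush_outputs(t_end); break; }
    }
  }

  return List::create(_["states"] = states,
                      _["extinction_time"] = ext_time,
                      _["crossing_time"] = cross_time,
                      _["t_final"] = t);
}
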