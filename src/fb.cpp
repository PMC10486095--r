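#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for an HMM with product-Bernoulli emissions over
// binary observation columns.
//
// Forward variables are rescaled at each position by the sum of the forward
// variables; backward variables are rescaled independently by the sum of the
// backward variables at that position.  This independent backward scaling is
// what keeps long concatenated multi-gene sequences from overflowing when
// different mixture components dominate the forward and backward passes.
// After scaling, any variable below 1e-300 is floored to 1e-300 -- except a
// forward variable whose emission probability product is exactly zero, which
// is kept at zero so that structural impossibilities stay impossible.
//
// Returns the log-likelihood (sum of log forward scale factors), the
// per-position state posteriors gamma, the summed pairwise transition
// expectations xi, and the accumulated emission sufficient statistics.
// [[Rcpp::export(name = ".fb_scaled")]]
List fb_scaled(NumericVector init, NumericMatrix trans, NumericMatrix emit,
               IntegerMatrix obs, bool want_gamma = true,
               bool want_stats = true) {
  const int n = init.size();
  const int T = obs.nrow();
  const int K = obs.ncol();
  if (trans.nrow() != n || trans.ncol() != n)
    stop("transition matrix must be %d x %d", n, n);
  if (emit.nrow() != n || emit.ncol() != K)
    stop("emission matrix has %d columns but observations have %d",
         emit.ncol(), K);
  if (T < 1) stop("empty observation sequence");
  const double FLOOR = 1e-300;

  // per-position emission probability product b[t][s]
  NumericMatrix b(T, n);
  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < n; ++s) {
      double p = 1.0;
      for (int e = 0; e < K; ++e) {
        const double be = emit(s, e);
        p *= obs(t, e) ? be : 1.0 - be;
      }
      b(t, s) = p;
    }
  }

  NumericMatrix alpha(T, n);
  NumericMatrix beta(T, n);
  double loglik = 0.0;

  // forward pass
  {
    double tot = 0.0;
    for (int s = 0; s < n; ++s) {
      alpha(0, s) = init[s] * b(0, s);
      tot += alpha(0, s);
    }
    if (!(tot > 0.0))
      stop("observation sequence impossible under model at position 1");
    loglik += std::log(tot);
    for (int s = 0; s < n; ++s) {
      double v = alpha(0, s) / tot;
      if (b(0, s) <= 0.0) v = 0.0;
      else if (v < FLOOR) v = FLOOR;
      alpha(0, s) = v;
    }
  }
  for (int t = 1; t < T; ++t) {
    double tot = 0.0;
    for (int s = 0; s < n; ++s) {
      double a = 0.0;
      for (int r = 0; r < n; ++r) a += alpha(t - 1, r) * trans(r, s);
      a *= b(t, s);
      alpha(t, s) = a;
      tot += a;
    }
    if (!(tot > 0.0))
      stop("observation sequence impossible under model at position %d", t + 1);
    loglik += std::log(tot);
    for (int s = 0; s < n; ++s) {
      double v = alpha(t, s) / tot;
      if (b(t, s) <= 0.0) v = 0.0;
      else if (v < FLOOR) v = FLOOR;
      alpha(t, s) = v;
    }
  }

  // backward pass, scaled by its own per-position sum
  for (int s = 0; s < n; ++s) beta(T - 1, s) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double tot = 0.0;
    for (int s = 0; s < n; ++s) {
      double v = 0.0;
      for (int r = 0; r < n; ++r)
        v += trans(s, r) * b(t + 1, r) * beta(t + 1, r);
      beta(t, s) = v;
      tot += v;
    }
    if (!(tot > 0.0))
      stop("backward recursion vanished at position %d", t + 1);
    for (int s = 0; s < n; ++s) {
      double v = beta(t, s) / tot;
      if (v < FLOOR) v = FLOOR;
      beta(t, s) = v;
    }
  }

  // posteriors
  NumericMatrix gamma(T, n);
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int s = 0; s < n; ++s) {
      gamma(t, s) = alpha(t, s) * beta(t, s);
      tot += gamma(t, s);
    }
    if (!(tot > 0.0))
      stop("state posterior vanished at position %d", t + 1);
    for (int s = 0; s < n; ++s) gamma(t, s) /= tot;
  }

  List out = List::create(_["log_likelihood"] = loglik);
  if (want_gamma) out["gamma"] = gamma;

  if (want_stats) {
    NumericMatrix xi(n, n);
    NumericMatrix em_num(n, K);
    NumericVector em_den(n);
    for (int t = 0; t + 1 < T; ++t) {
      double tot = 0.0;
      for (int i = 0; i < n; ++i) {
        const double ai = alpha(t, i);
        if (ai <= 0.0) continue;
        for (int j = 0; j < n; ++j) {
          const double tij = trans(i, j);
          if (tij <= 0.0) continue;
          tot += ai * tij * b(t + 1, j) * beta(t + 1, j);
        }
      }
      if (!(tot > 0.0))
        stop("pairwise posterior vanished at position %d", t + 1);
      for (int i = 0; i < n; ++i) {
        const double ai = alpha(t, i);
        if (ai <= 0.0) continue;
        for (int j = 0; j < n; ++j) {
          const double tij = trans(i, j);
          if (tij <= 0.0) continue;
          xi(i, j) += ai * tij * b(t + 1, j) * beta(t + 1, j) / tot;
        }
      }
    }
    for (int t = 0; t < T; ++t) {
      for (int s = 0; s < n; ++s) {
        const double g = gamma(t, s);
        em_den[s] += g;
        if (g > 0.0)
          for (int e = 0; e < K; ++e)
            if (obs(t, e)) em_num(s, e) += g;
      }
    }
    out["xi"] = xi;
    out["emit_num"] = em_num;
    out["emit_den"] = em_den;
  }
  return out;
}
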