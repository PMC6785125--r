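#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form HKY transition probabilities (TN93 with equal transition
// rates), states in A,C,G,T order. The generator is normalized to one
// expected substitution per site per unit time, so t is in subst/site.
static void hky_pmat(double t, double kappa, const double* bf, double* P) {
  const double piA = bf[0], piC = bf[1], piG = bf[2], piT = bf[3];
  const double piR = piA + piG, piY = piC + piT;
  // mean rate under unnormalized generator with transversion rate 1,
  // transition rate kappa (each times pi_j)
  const double mu = 2.0 * kappa * (piA * piG + piC * piT) + 2.0 * piR * piY;
  const double beta = 1.0 / mu;          // transversion rate
  const double alpha = kappa / mu;       // transition rate
  const double e2 = std::exp(-beta * t);
  const double e3 = std::exp(-(piR * alpha + piY * beta) * t); // purine
  const double e4 = std::exp(-(piY * alpha + piR * beta) * t); // pyrimidine

  // rows: ancestral state i; columns: descendant j (A,C,G,T)
  // purines
  P[0*4+0] = piA + piA * piY / piR * e2 + piG / piR * e3; // A->A
  P[0*4+2] = piG + piG * piY / piR * e2 - piG / piR * e3; // A->G
  P[2*4+2] = piG + piG * piY / piR * e2 + piA / piR * e3; // G->G
  P[2*4+0] = piA + piA * piY / piR * e2 - piA / piR * e3; // G->A
  // pyrimidines
  P[1*4+1] = piC + piC * piR / piY * e2 + piT / piY * e4; // C->C
  P[1*4+3] = piT + piT * piR / piY * e2 - piT / piY * e4; // C->T
  P[3*4+3] = piT + piT * piR / piY * e2 + piC / piY * e4; // T->T
  P[3*4+1] = piC + piC * piR / piY * e2 - piC / piY * e4; // T->C
  // transversions
  P[0*4+1] = P[2*4+1] = piC * (1.0 - e2);
  P[0*4+3] = P[2*4+3] = piT * (1.0 - e2);
  P[1*4+0] = P[3*4+0] = piA * (1.0 - e2);
  P[1*4+2] = P[3*4+2] = piG * (1.0 - e2);
}

// [[Rcpp::export(name = ".hky_pmat_cpp")]]
NumericMatrix hky_pmat_cpp(double t, double kappa, NumericVector bf) {
  NumericMatrix P(4, 4);
  double buf[16];
  hky_pmat(t, kappa, bf.begin(), buf);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) P(i, j) = buf[i * 4 + j];
  return P;
}

// Felsenstein pruning log-likelihood for an HKY model with a discrete rate
// mixture. tip_states: ntips x npatterns, values 0..3 (A,C,G,T) or 4
// (missing/gap). edge: (child, parent) rows in postorder, 1-based ape node
// ids (tips 1..n, internals n+1..2n-1). brlen: expected substitutions per
// site for each edge (clock and rate multipliers already applied).
// [[Rcpp::export(name = ".hky_pruning_cpp")]]
double hky_pruning_cpp(IntegerMatrix tip_states, NumericVector weights,
                       IntegerMatrix edge, NumericVector brlen,
                       double kappa, NumericVector bf, NumericVector rates) {
  const int ntip = tip_states.nrow();
  const int npat = tip_states.ncol();
  const int nedge = edge.nrow();
  const int nnode = 2 * ntip - 1;
  const int ncat = rates.size();

  std::vector<double> sitelik(npat * ncat);   // log L per pattern per category

  std::vector<double> partial((size_t)nnode * 4 * npat);
  std::vector<double> logscale(nnode * 0 + npat);
  std::vector<char> seen(nnode);
  double P[16];

  for (int c = 0; c < ncat; ++c) {
    std::fill(partial.begin(), partial.end(), 1.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    std::fill(seen.begin(), seen.end(), 0);

    for (int e = 0; e < nedge; ++e) {
      const int child = edge(e, 0) - 1;
      const int parent = edge(e, 1) - 1;
      hky_pmat(brlen[e] * rates[c], kappa, bf.begin(), P);
      double* pp = &partial[(size_t)parent * 4 * npat];
      if (child < ntip) {
        for (int s = 0; s < npat; ++s) {
          const int st = tip_states(child, s);
          if (st >= 4) continue;  // missing: sum_j P[i][j] * 1 = 1
          for (int i = 0; i < 4; ++i) pp[i * npat + s] *= P[i * 4 + st];
        }
      } else {
        const double* cp = &partial[(size_t)child * 4 * npat];
        for (int s = 0; s < npat; ++s) {
          double v0 = 0, v1 = 0, v2 = 0, v3 = 0;
          const double c0 = cp[0 * npat + s], c1 = cp[1 * npat + s],
                       c2 = cp[2 * npat + s], c3 = cp[3 * npat + s];
          v0 = P[0]*c0 + P[1]*c1 + P[2]*c2 + P[3]*c3;
          v1 = P[4]*c0 + P[5]*c1 + P[6]*c2 + P[7]*c3;
          v2 = P[8]*c0 + P[9]*c1 + P[10]*c2 + P[11]*c3;
          v3 = P[12]*c0 + P[13]*c1 + P[14]*c2 + P[15]*c3;
          pp[0 * npat + s] *= v0; pp[1 * npat + s] *= v1;
          pp[2 * npat + s] *= v2; pp[3 * npat + s] *= v3;
        }
      }
      // rescale parent occasionally to avoid underflow
      if (!seen[parent]) seen[parent] = 1;
      double mx = 0;
      for (int s = 0; s < npat; ++s) {
        mx = pp[s];
        for (int i = 1; i < 4; ++i)
          if (pp[i * npat + s] > mx) mx = pp[i * npat + s];
        if (mx > 0 && mx < 1e-200) {
          for (int i = 0; i < 4; ++i) pp[i * npat + s] /= mx;
          logscale[s] += std::log(mx);
        }
      }
    }

    const int root = edge(nedge - 1, 1) - 1;  // postorder: last parent is root
    const double* rp = &partial[(size_t)root * 4 * npat];
    for (int s = 0; s < npat; ++s) {
      double lik = 0;
      for (int i = 0; i < 4; ++i) lik += bf[i] * rp[i * npat + s];
      sitelik[(size_t)c * npat + s] =
        (lik > 0 ? std::log(lik) : -1e300) + logscale[s];
    }
  }

  // mix categories with equal weights, then sum over patterns
  double total = 0;
  const double logncat = std::log((double)ncat);
  for (int s = 0; s < npat; ++s) {
    double m = sitelik[s];
    for (int c = 1; c < ncat; ++c)
      if (sitelik[(size_t)c * npat + s] > m) m = sitelik[(size_t)c * npat + s];
    double acc = 0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(sitelik[(size_t)c * npat + s] - m);
    total += weights[s] * (m + std::log(acc) - logncat);
  }
  return total;
}
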