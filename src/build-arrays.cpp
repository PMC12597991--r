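#include <Rcpp.h>
using namespace Rcpp;

// Assemble the per-age transition products M[, , a] = phi(a) %*% psi(a)
// directly from the structural parameter vectors (one value per age).
// State order: J SA NB- NB+ B- B+ FD D. Doing this in compiled code keeps
// the per-evaluation cost of the likelihood dominated by the forward pass
// rather than by matrix assembly.
// [[Rcpp::export]]
NumericVector build_M_cpp(NumericVector phiNBlo, NumericVector phiNBhi,
                          NumericVector phiBlo, NumericVector phiBhi,
                          NumericVector psiBlo, NumericVector psiBhi,
                          NumericVector psiNBlo, NumericVector psiNBhi,
                          NumericVector psiR) {
  const int na = psiR.size();
  NumericVector M(64 * na);
  auto at = [&](int a, int s, int j) -> double & { return M[64 * a + s + 8 * j]; };
  for (int a = 0; a < na; ++a) {
    const double r = psiR[a];
    // J row: survives surely, then 1-3r stay, r to SA, r to each breeder class
    at(a, 0, 0) = 1.0 - 3.0 * r;
    at(a, 0, 1) = r;
    at(a, 0, 4) = r;
    at(a, 0, 5) = r;
    // SA row: survives surely, 1-2r stay, r to each breeder class
    at(a, 1, 1) = 1.0 - 2.0 * r;
    at(a, 1, 4) = r;
    at(a, 1, 5) = r;
    // NB-: survive phiNBlo then arrive with psiBlo
    at(a, 2, 2) = phiNBlo[a] * (1.0 - psiBlo[a]);
    at(a, 2, 4) = phiNBlo[a] * psiBlo[a];
    at(a, 2, 6) = 1.0 - phiNBlo[a];
    // NB+
    at(a, 3, 3) = phiNBhi[a] * (1.0 - psiBhi[a]);
    at(a, 3, 5) = phiNBhi[a] * psiBhi[a];
    at(a, 3, 6) = 1.0 - phiNBhi[a];
    // B-: survive phiBlo then depart with psiNBlo
    at(a, 4, 2) = phiBlo[a] * psiNBlo[a];
    at(a, 4, 4) = phiBlo[a] * (1.0 - psiNBlo[a]);
    at(a, 4, 6) = 1.0 - phiBlo[a];
    // B+
    at(a, 5, 3) = phiBhi[a] * psiNBhi[a];
    at(a, 5, 5) = phiBhi[a] * (1.0 - psiNBhi[a]);
    at(a, 5, 6) = 1.0 - phiBhi[a];
    // FD -> D, D absorbing
    at(a, 6, 7) = 1.0;
    at(a, 7, 7) = 1.0;
  }
  M.attr("dim") = IntegerVector::create(8, 8, na);
  return M;
}
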