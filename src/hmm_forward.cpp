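#include <Rcpp.h>
using namespace Rcpp;

// Log-space forward (and optional backward) pass for the two-state hotspot
// chain. Emissions enter as the hotspot-state log correction factor relative
// to the background state (the shared background emission cancels), one
// column per quadrature node of the gene-effect posterior.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log1p(exp((a > b ? b : a) - m));
}

// logh: npos x nnodes matrix of hotspot log factors; q = entry prob,
// ex = exit prob. Returns log of the path-summed correction factor H per
// node, with the chain started at its stationary distribution.
// [[Rcpp::export]]
NumericVector hmmForwardLogH(NumericMatrix logh, double q, double ex) {
  int n = logh.nrow(), K = logh.ncol();
  double piH = q / (q + ex);
  double lPiH = piH > 0 ? log(piH) : R_NegInf;
  double lPiB = piH < 1 ? log1p(-piH) : R_NegInf;
  double lBB = q < 1 ? log1p(-q) : R_NegInf;
  double lBH = q > 0 ? log(q) : R_NegInf;
  double lHB = log(ex);
  double lHH = ex < 1 ? log1p(-ex) : R_NegInf;
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    if (n == 0) { out[k] = 0.0; continue; }
    double fB = lPiB;
    double fH = lPiH == R_NegInf ? R_NegInf : lPiH + logh(0, k);
    for (int i = 1; i < n; ++i) {
      double nB = lse2(fB + lBB, fH + lHB);
      double nH = lse2(fB + lBH, fH + lHH);
      nH = nH == R_NegInf ? R_NegInf : nH + logh(i, k);
      fB = nB; fH = nH;
    }
    out[k] = lse2(fB, fH);
  }
  return out;
}

// Forward-backward: returns the per-position posterior probability of the
// hotspot state for each node (npos x nnodes), plus per-node log H in the
// "logH" attribute.
// [[Rcpp::export]]
NumericMatrix hmmForwardBackward(NumericMatrix logh, double q, double ex) {
  int n = logh.nrow(), K = logh.ncol();
  double piH = q / (q + ex);
  double lPiH = piH > 0 ? log(piH) : R_NegInf;
  double lPiB = piH < 1 ? log1p(-piH) : R_NegInf;
  double lBB = q < 1 ? log1p(-q) : R_NegInf;
  double lBH = q > 0 ? log(q) : R_NegInf;
  double lHB = log(ex);
  double lHH = ex < 1 ? log1p(-ex) : R_NegInf;
  NumericMatrix post(n, K);
  NumericVector logH(K);
  NumericVector aB(n), aH(n), bB(n), bH(n);
  for (int k = 0; k < K; ++k) {
    if (n == 0) { logH[k] = 0.0; continue; }
    aB[0] = lPiB;
    aH[0] = lPiH == R_NegInf ? R_NegInf : lPiH + logh(0, k);
    for (int i = 1; i < n; ++i) {
      aB[i] = lse2(aB[i - 1] + lBB, aH[i - 1] + lHB);
      double nH = lse2(aB[i - 1] + lBH, aH[i - 1] + lHH);
      aH[i] = nH == R_NegInf ? R_NegInf : nH + logh(i, k);
    }
    logH[k] = lse2(aB[n - 1], aH[n - 1]);
    bB[n - 1] = 0.0;
    bH[n - 1] = 0.0;
    for (int i = n - 2; i >= 0; --i) {
      double eH = logh(i + 1, k);
      bB[i] = lse2(lBB + bB[i + 1], lBH + eH + bH[i + 1]);
      bH[i] = lse2(lHB + bB[i + 1], lHH + eH + bH[i + 1]);
    }
    for (int i = 0; i < n; ++i) {
      double num = aH[i] + bH[i];
      post(i, k) = num == R_NegInf ? 0.0 : exp(num - logH[k]);
    }
  }
  post.attr("logH") = logH;
  return post;
}
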