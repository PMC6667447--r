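# Independent numerical oracles, deliberately implemented without reusing
# the package's closed forms.

# Poisson-Gamma marginal by adaptive quadrature over the gene effect.
quadMarginalLoglik <- function(y, mu, a, b) {
  logf <- function(l) {
    vapply(l, function(li) {
      sum(stats::dpois(y, mu * li, log = TRUE)) +
        stats::dgamma(li, a, b, log = TRUE)
    }, numeric(1))
  }
  mode <- max((a + sum(y) - 1) / (b + sum(mu)), 1e-8)
  m <- logf(mode)
  val <- stats::integrate(function(l) exp(logf(l) - m), 0, Inf,
                          rel.tol = 1e-12, abs.tol = 0)$value
  m + log(val)
}

# Spatial marginal by exhaustive enumeration over hidden state paths: each
# path contributes its chain probability times the closed-form
# Poisson-Gamma marginal with hotspot-scaled rates, and the path integral
# over lambda is exact.
enumHmmLoglik <- function(counts, effRates, positions, a, b, q, meanLen,
                          rho) {
  upos <- unique(positions)
  n <- length(upos)
  stopifnot(n <= 14)
  ex <- 1 / meanLen
  piH <- q / (q + ex)
  trans <- matrix(c(1 - q, q, ex, 1 - ex), 2, 2, byrow = TRUE)
  init <- c(1 - piH, piH)
  posIdx <- match(positions, upos)
  total <- -Inf
  for (code in 0:(2^n - 1)) {
    path <- as.integer(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    lp <- log(init[path[1] + 1])
    if (n > 1) {
      for (i in 2:n)
        lp <- lp + log(trans[path[i - 1] + 1, path[i] + 1])
    }
    if (!is.finite(lp)) next
    r <- effRates * rho^path[posIdx]
    ll <- sum(counts * log(r)) - sum(lgamma(counts + 1)) +
      a * log(b) - lgamma(a) + lgamma(a + sum(counts)) -
      (a + sum(counts)) * log(b + sum(r))
    total <- driverBayes:::logSumExp(c(total, lp + ll))
  }
  total
}

# Small random HMM test instance generator.
randomHmmInstance <- function(nPos, seed) {
  set.seed(seed)
  positions <- rep(sort(sample(1:50, nPos)), each = 3)
  effRates <- stats::runif(3 * nPos, 1e-4, 5e-3)
  counts <- stats::rpois(3 * nPos, 0.3)
  list(counts = counts, effRates = effRates, positions = positions,
       a = stats::runif(1, 0.5, 12), b = stats::runif(1, 0.5, 12))
}
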