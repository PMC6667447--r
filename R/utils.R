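# Internal numeric helpers shared across modules.

## log(sum(exp(x))) without overflow; -Inf-safe.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise logSumExp for a matrix (used to combine quadrature nodes).
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

## Closed-form Poisson-Gamma marginal:
## log int prod_i Pois(y_i; mu_i * lambda) Gamma(lambda; a, b) dlambda
##   = sum_i [y_i log mu_i - lgamma(y_i + 1)]
##     + a log b - lgamma(a) + lgamma(a + Y) - (a + Y) log(b + M)
## with Y = sum(y), M = sum(mu).  Vectorized over groups via precomputed
## per-group sums; `sumYLogMu` must already exclude rows with y = 0 safely
## (0 * log(mu) with mu > 0 is fine).
pgLogMarginal <- function(sumYLogMu, sumLgammaY1, Y, M, a, b) {
  sumYLogMu - sumLgammaY1 + a * log(b) - lgamma(a) +
    lgamma(a + Y) - (a + Y) * log(b + M)
}

## Grouped sums aligned to factor levels; absent levels get NA.
groupSum <- function(x, group) {
  out <- rowsum(x, group)
  res <- stats::setNames(rep(NA_real_, nlevels(group)), levels(group))
  res[rownames(out)] <- out[, 1L]
  res
}

## Generalized Gauss-Laguerre quadrature adapted to a Gamma(a, b)
## probability measure: returns nodes lambda_k and weights w_k (sum 1) such
## that sum_k w_k f(lambda_k) ~ E[f(lambda)], lambda ~ Gamma(a, b).
## Golub-Welsch on the symmetric tridiagonal Jacobi matrix for the weight
## x^(a-1) e^(-x).
gammaQuadrature <- function(a, b, n = 16L) {
  stopifnot(a > 0, b > 0, n >= 1L)
  if (n == 1L) return(list(nodes = a / b, weights = 1))
  alpha0 <- a - 1
  d <- 2 * seq_len(n) - 1 + alpha0
  e <- sqrt(seq_len(n - 1L) * (seq_len(n - 1L) + alpha0))
  J <- diag(d)
  idx <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  J[idx] <- e
  J[idx[, 2:1, drop = FALSE]] <- e
  eg <- eigen(J, symmetric = TRUE)
  w <- eg$vectors[1L, ]^2
  ord <- order(eg$values)
  list(nodes = eg$values[ord] / b, weights = w[ord] / sum(w))
}

## Coefficient of determination against the slope-1 diagonal
## (residuals measured from the y = x line, total SS from the mean).
r2Diagonal <- function(observed, predicted) {
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ssTot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Bounded quasi-Newton minimization with a fallback: L-BFGS-B line
## searches can abort near flat plateaus at machine precision; in that
## case polish with Nelder-Mead from the best point and re-run L-BFGS-B.
## Errors only if no attempt reaches a convergent state.
robustMaximize <- function(fn, gr, init, lower, upper, maxit, factr,
                           context = "fit") {
  opt <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr))
  if (opt$convergence %in% c(0L, 1L)) return(opt)
  polish <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 500L, reltol = 1e-12))
  start <- pmin(pmax(polish$par, lower), upper)
  opt2 <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = maxit, factr = factr))
  if (opt2$convergence %in% c(0L, 1L)) return(opt2)
  ## accept the better point if the remaining gradient is negligible on
  ## the scale of the objective
  best <- if (opt2$value <= polish$value) opt2 else polish
  gnorm <- sqrt(sum(gr(best$par)^2))
  if (gnorm < 1e-4 * max(1, abs(best$value))) {
    best$convergence <- 0L
    return(best)
  }
  stop(context, " did not converge: ", best$message %||% "line search failed")
}
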