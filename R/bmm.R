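## Background mutation model: log-linear rates over mutation types and
## genomic covariates, with Gamma(alpha, alpha) gene-specific effects
## integrated out analytically (Poisson-Gamma marginal). Fit by marginal
## maximum likelihood on synonymous sites only.

## Apply a BMMParams' standardization to a raw background-feature matrix.
standardizeBg <- function(bg, params) {
  nm <- names(params@betaBg)
  if (length(nm)) {
    miss <- setdiff(nm, colnames(bg))
    if (length(miss))
      stop("site table lacks background feature(s): ",
           paste(miss, collapse = ", "))
    bg <- bg[, nm, drop = FALSE]
    for (j in seq_along(nm))
      bg[, j] <- (bg[, j] - params@center[j]) / params@scale[j]
  }
  bg
}

#' Background mutation rate per site row
#'
#' Evaluates the log-linear background model: the expected number of
#' mutations (per cohort) of each possible mutation is
#' \code{exp(beta0[type] + x_bg . betaBg)}, with continuous background
#' features standardized by the constants stored in the fitted model.
#'
#' @param sites a \code{\link{SiteTable}} (or subset).
#' @param params a \code{\link{BMMParams}}.
#' @return positive numeric vector of rates, one per site row.
#' @export
backgroundRate <- function(sites, params) {
  s <- siteData(sites)
  bg <- standardizeBg(bgFeatures(sites), params)
  if (any(!is.finite(bg))) {
    bad <- which(!is.finite(bg), arr.ind = TRUE)[1L, ]
    stop("missing background feature value: site row ", bad[1L],
         ", feature '", colnames(bg)[bad[2L]], "'")
  }
  eta <- params@beta0[s$mutation_type]
  if (length(params@betaBg))
    eta <- eta + drop(bg %*% params@betaBg)
  exp(eta)
}

#' Marginal log-likelihood of one gene's synonymous counts
#'
#' Closed-form Poisson-Gamma marginal: the gene effect lambda ~
#' Gamma(alpha, alpha) is integrated out of the product of
#' Poisson(y_i; mu_i * lambda) terms, giving a negative-multinomial
#' likelihood.
#'
#' @param counts nonnegative integer counts for the gene's synonymous rows.
#' @param rates aligned background rates mu_i.
#' @param alpha Gamma shape/rate of the gene effect (> 0).
#' @return log marginal likelihood (finite for finite inputs).
#' @export
synMarginalLoglik <- function(counts, rates, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  stopifnot(length(counts) == length(rates), all(rates > 0),
            all(counts >= 0))
  pgLogMarginal(sum(counts * log(rates)), sum(lgamma(counts + 1)),
                sum(counts), sum(rates), alpha, alpha)
}

## Shared optimizer bookkeeping: records accepted improvements so the
## convergence report carries a monotone likelihood trace.
makeTracer <- function() {
  env <- new.env()
  env$best <- -Inf
  env$trace <- numeric(0)
  env$evals <- 0L
  env
}

traceEval <- function(tracer, value) {
  tracer$evals <- tracer$evals + 1L
  if (value > tracer$best) {
    tracer$best <- value
    tracer$trace <- c(tracer$trace, value)
  }
}

#' Fit the background mutation model by marginal maximum likelihood
#'
#' Maximizes the product over genes of the closed-form Poisson-Gamma
#' synonymous marginal over the per-type intercepts, background-feature
#' coefficients and log alpha, using L-BFGS-B with analytic gradients.
#' Continuous background features are z-scored internally; the transform is
#' stored in the returned model. Intercepts of mutation types with no
#' observed synonymous mutation are clamped at a floor of -30 with a
#' warning.
#'
#' @param sites a \code{\link{SiteTable}}; only rows with impact "S" enter
#'   the fit.
#' @param counts integer count vector aligned with \code{sites} rows.
#' @param beta0Floor lower clamp for per-type log intercepts.
#' @param maxit,factr L-BFGS-B controls.
#' @return a \code{\link{BMMParams}} whose \code{convergence} slot records
#'   iterations, evaluation count, final gradient norm, log-likelihood and
#'   the monotone trace of accepted improvements.
#' @export
fitBMM <- function(sites, counts, beta0Floor = -30, maxit = 500L,
                   factr = 1e7) {
  s <- siteData(sites)
  stopifnot(length(counts) == nrow(s))
  isSyn <- s$impact == "S"
  if (sum(counts[isSyn]) == 0L)
    stop("no synonymous mutations observed; cannot fit background model")
  y <- counts[isSyn]
  typeIdx <- s$mutation_type[isSyn]
  gene <- factor(s$gene_id[isSyn])
  bg <- bgFeatures(sites)[isSyn, , drop = FALSE]
  p <- ncol(bg)

  ## z-score continuous features; leave binary (0/1) columns untouched
  center <- rep(0, p)
  scale <- rep(1, p)
  if (p) {
    for (j in seq_len(p)) {
      v <- bg[, j]
      if (!all(v %in% c(0, 1))) {
        center[j] <- mean(v)
        scale[j] <- stats::sd(v)
        if (scale[j] == 0) scale[j] <- 1
        bg[, j] <- (v - center[j]) / scale[j]
      }
    }
    names(center) <- names(scale) <- colnames(bg)
  }

  typeCount <- groupSum(y, factor(typeIdx, levels = 1:9))
  typeSites <- tabulate(typeIdx, nbins = 9L)
  if (any(typeSites == 0L))
    stop("every mutation type needs at least one possible synonymous site")
  unseen <- typeCount == 0
  if (any(unseen))
    warning("mutation type(s) with zero observed synonymous mutations: ",
            paste(which(unseen), collapse = ", "),
            "; intercept clamped at ", beta0Floor)

  Yg <- groupSum(y, gene)
  sumLgam <- sum(lgamma(y + 1))
  sumYX <- if (p) drop(crossprod(bg, y)) else numeric(0)
  sumYT <- typeCount

  unpack <- function(par) {
    list(beta0 = par[1:9],
         beta = if (p) par[10:(9 + p)] else numeric(0),
         alpha = exp(par[10 + p]))
  }

  evalModel <- function(par) {
    pr <- unpack(par)
    eta <- pr$beta0[typeIdx]
    if (p) eta <- eta + drop(bg %*% pr$beta)
    mu <- exp(eta)
    Mg <- groupSum(mu, gene)
    a <- pr$alpha
    ll <- sum(y * eta) +
      sum(a * log(a) - lgamma(a) + lgamma(a + Yg) -
            (a + Yg) * log(a + Mg))
    w <- (a + Yg) / (a + Mg)
    r <- y - w[gene] * mu
    gBeta0 <- groupSum(r, factor(typeIdx, levels = 1:9))
    gBeta <- if (p) drop(crossprod(bg, r)) else numeric(0)
    gLogA <- a * sum(log(a) + 1 - digamma(a) + digamma(a + Yg) -
                       log(a + Mg) - w)
    list(ll = ll, grad = c(gBeta0, gBeta, gLogA))
  }

  tracer <- makeTracer()
  fn <- function(par) {
    v <- evalModel(par)$ll
    traceEval(tracer, v)
    -v
  }
  gr <- function(par) -evalModel(par)$grad

  beta0Init <- log(pmax(typeCount, 0.5) / typeSites)
  beta0Init <- pmax(beta0Init, beta0Floor)
  parInit <- c(beta0Init, rep(0, p), 0)
  lower <- c(rep(beta0Floor, 9L), rep(-30, p), log(1e-8))
  upper <- c(rep(30, 9L), rep(30, p), log(1e8))
  opt <- robustMaximize(fn, gr, parInit, lower = lower, upper = upper,
                        maxit = maxit, factr = factr,
                        context = "background model fit")
  pr <- unpack(opt$par)
  finalGrad <- evalModel(opt$par)$grad
  ## zero out gradient components pinned at the clamp
  atFloor <- opt$par[1:9] <= beta0Floor + 1e-8
  finalGrad[1:9][atFloor] <- 0
  ## observed-information standard errors on the working scale
  ## (beta0, betaBg standardized, log alpha)
  se <- rep(NA_real_, length(opt$par))
  hess <- try(stats::optimHess(opt$par, fn, gr), silent = TRUE)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0))
      se <- sqrt(diag(vc))
  }
  names(se) <- c(paste0("beta0_", 1:9), colnames(bg), "logAlpha")
  report <- list(iterations = opt$counts[["function"]],
                 evaluations = tracer$evals,
                 loglik = -opt$value - sumLgam,
                 gradientNorm = sqrt(sum(finalGrad^2)),
                 trace = tracer$trace - sumLgam,
                 convergence = opt$convergence,
                 se = se,
                 message = opt$message %||% "")
  beta <- pr$beta
  names(beta) <- colnames(bg)
  BMMParams(beta0 = unname(pr$beta0), betaBg = beta,
            alpha = unname(pr$alpha),
            center = center, scale = scale, convergence = report)
}

#' Posterior distribution of gene-specific effects
#'
#' Given the fitted gene-effect shape \code{alphaHat}, the posterior of
#' lambda_g given a gene's synonymous data is Gamma(alphaHat + observed
#' synonymous count, alphaHat + expected synonymous count). A gene with no
#' synonymous opportunity gets the prior Gamma(alphaHat, alphaHat).
#'
#' @param alphaHat fitted alpha (> 0).
#' @param ySyn observed synonymous counts, one per gene.
#' @param muSyn expected synonymous counts (sum of background rates), one
#'   per gene.
#' @param geneId optional gene ids.
#' @return a \code{\link{GenePosterior}}.
#' @export
geneEffectPosterior <- function(alphaHat, ySyn, muSyn, geneId = NULL) {
  stopifnot(alphaHat > 0, length(ySyn) == length(muSyn))
  if (is.null(geneId)) geneId <- as.character(seq_along(ySyn))
  new("GenePosterior", geneId = as.character(geneId),
      a = alphaHat + ySyn, b = alphaHat + muSyn)
}

## Per-gene synonymous summaries -> GenePosterior, for a full site table.
genePosteriorFromData <- function(sites, counts, params,
                                  rates = NULL) {
  s <- siteData(sites)
  gene <- factor(s$gene_id, levels = unique(s$gene_id))
  if (is.null(rates)) rates <- backgroundRate(sites, params)
  isSyn <- s$impact == "S"
  gSyn <- factor(s$gene_id[isSyn], levels = levels(gene))
  ySyn <- groupSum(counts[isSyn], gSyn)
  muSyn <- groupSum(rates[isSyn], gSyn)
  ySyn[is.na(ySyn)] <- 0
  muSyn[is.na(muSyn)] <- 0
  geneEffectPosterior(params@alpha, ySyn, muSyn, levels(gene))
}

#' Observed versus expected non-synonymous counts per gene
#'
#' Cross-validation-style diagnostic of the gene-specific effect: for each
#' gene, compares the observed non-synonymous count against its expectation
#' under the background model, with and without multiplying by the
#' posterior mean of the gene effect (which was learned from synonymous
#' data only). R-squared values are computed against the slope-1 diagonal.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param counts aligned count vector.
#' @param params fitted \code{\link{BMMParams}}.
#' @return list with \code{table} (per-gene observed, expected, adjusted,
#'   posterior mean) and \code{r2} (named: unadjusted, adjusted; NA when
#'   fewer than two genes).
#' @export
validateGeneEffects <- function(sites, counts, params) {
  s <- siteData(sites)
  rates <- backgroundRate(sites, params)
  post <- genePosteriorFromData(sites, counts, params, rates)
  lev <- post@geneId
  isNS <- s$impact == "NS"
  gNS <- factor(s$gene_id[isNS], levels = lev)
  obs <- groupSum(counts[isNS], gNS)
  expd <- groupSum(rates[isNS], gNS)
  obs[is.na(obs)] <- 0
  expd[is.na(expd)] <- 0
  noNS <- expd == 0
  if (any(noNS))
    warning(sum(noNS), " gene(s) without non-synonymous sites excluded")
  lam <- posteriorMean(post)
  tab <- data.frame(gene_id = lev, observed_ns = obs, expected_ns = expd,
                    adjusted_ns = lam * expd, lambda_post_mean = lam,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[!noNS, , drop = FALSE]
  r2 <- c(unadjusted = NA_real_, adjusted = NA_real_)
  if (nrow(tab) >= 2L) {
    r2["unadjusted"] <- r2Diagonal(tab$observed_ns, tab$expected_ns)
    r2["adjusted"] <- r2Diagonal(tab$observed_ns, tab$adjusted_ns)
  }
  list(table = tab, r2 = r2)
}

#' Write / read a fitted background model as structured text
#'
#' Round-trips all parameters, the feature standardization constants and
#' the convergence report through a YAML file.
#'
#' @param params a \code{\link{BMMParams}}.
#' @param path file path.
#' @return \code{readBMM} returns a \code{\link{BMMParams}}.
#' @export
writeBMM <- function(params, path) {
  obj <- list(model = "bmm",
              beta0 = as.numeric(params@beta0),
              features = as.list(params@betaBg),
              center = as.list(params@center),
              scale = as.list(params@scale),
              alpha = params@alpha,
              convergence = params@convergence[
                c("iterations", "loglik", "gradientNorm", "convergence")])
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname writeBMM
#' @export
readBMM <- function(path) {
  obj <- yaml::read_yaml(path)
  stopifnot(identical(obj$model, "bmm"))
  BMMParams(beta0 = as.numeric(obj$beta0),
            betaBg = unlist(obj$features) %||% numeric(0),
            alpha = obj$alpha,
            center = unlist(obj$center) %||% numeric(0),
            scale = unlist(obj$scale) %||% numeric(0),
            convergence = obj$convergence %||% list())
}
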