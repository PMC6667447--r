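## Selection mutation model: hypothesis-specific log-linear multipliers on
## non-synonymous rates, fit by maximizing the conditional likelihood of
## non-synonymous counts given each training gene's synonymous data, plus
## empirical-Bayes shrinkage of coefficients across tumor types.

#' Selection effect per site row
#'
#' Evaluates gamma = exp(beta0F + x_fn . betaF) for every row. Under a null
#' model with all-zero parameters gamma is 1 everywhere.
#'
#' @param sites a \code{\link{SiteTable}} (or subset).
#' @param params an \code{\link{SMMParams}}.
#' @return positive numeric vector of selection multipliers.
#' @export
selectionEffect <- function(sites, params) {
  fn <- fnFeatures(sites)
  nm <- names(params@betaF)
  eta <- rep(params@beta0F, nSites(sites))
  if (length(nm)) {
    miss <- setdiff(nm, colnames(fn))
    if (length(miss))
      stop("site table lacks functional feature(s): ",
           paste(miss, collapse = ", "))
    eta <- eta + drop(fn[, nm, drop = FALSE] %*% params@betaF)
  }
  exp(eta)
}

#' Conditional log-likelihood of a gene's non-synonymous counts
#'
#' Poisson-Gamma marginal of the non-synonymous counts with effective rates
#' mu * gamma, integrating the gene effect against its synonymous-data
#' posterior Gamma(a, b). With gamma = 1 and the prior as posterior this
#' coincides with \code{\link{synMarginalLoglik}}.
#'
#' @param counts nonnegative counts of the gene's non-synonymous rows.
#' @param rates aligned background rates mu.
#' @param gamma aligned selection effects (> 0).
#' @param posterior a \code{\link{GenePosterior}} restricted to one gene,
#'   or a list with elements \code{a} and \code{b}.
#' @return log conditional likelihood.
#' @export
nsConditionalLoglik <- function(counts, rates, gamma, posterior) {
  if (any(gamma <= 0)) stop("selection effects must be > 0")
  ab <- extractAB(posterior)
  stopifnot(length(counts) == length(rates),
            length(gamma) == length(rates))
  eff <- rates * gamma
  pgLogMarginal(sum(counts * log(eff)), sum(lgamma(counts + 1)),
                sum(counts), sum(eff), ab$a, ab$b)
}

extractAB <- function(posterior) {
  if (is(posterior, "GenePosterior")) {
    stopifnot(length(posterior@a) == 1L)
    list(a = posterior@a, b = posterior@b)
  } else {
    stopifnot(is.list(posterior), !is.null(posterior$a),
              !is.null(posterior$b))
    posterior[c("a", "b")]
  }
}

#' Fit a selection mutation model on a set of training genes
#'
#' Maximizes the product over training genes of the conditional likelihood
#' of non-synonymous counts given synonymous data (background model frozen,
#' spatial model off), over the intercept and functional-feature
#' coefficients. Standard errors come from the inverse of the numerically
#' evaluated observed information at the maximum.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param counts aligned count vector.
#' @param bmm fitted \code{\link{BMMParams}} (frozen).
#' @param trainGenes character vector of training gene ids; for the null
#'   hypothesis pass all genes outside both driver training lists.
#' @param hypothesis "H0", "OG" or "TSG".
#' @param featureSubset optional character vector restricting which
#'   functional features enter the model.
#' @param maxit,factr L-BFGS-B controls.
#' @param rates optional precomputed background rates for all site rows
#'   (recomputed from \code{bmm} when NULL).
#' @return an \code{\link{SMMParams}} with standard errors and a
#'   convergence report.
#' @export
fitSMM <- function(sites, counts, bmm, trainGenes, hypothesis,
                   featureSubset = NULL, maxit = 500L, factr = 1e7,
                   rates = NULL) {
  stopifnot(length(trainGenes) >= 1L)
  s <- siteData(sites)
  if (is.null(rates)) rates <- backgroundRate(sites, bmm)
  idx <- which(!is.na(match(s$gene_id, trainGenes)))
  if (!length(idx)) stop("no training genes found in the site table")
  geneSub <- s$gene_id[idx]
  impactSub <- s$impact[idx]
  cnt <- counts[idx]
  rSub <- rates[idx]
  lev <- unique(geneSub)

  ## gene-effect posterior from the training genes' synonymous rows
  isSyn <- impactSub == "S"
  gS <- factor(geneSub[isSyn], levels = lev)
  ySyn <- groupSum(cnt[isSyn], gS)
  muSyn <- groupSum(rSub[isSyn], gS)
  ySyn[is.na(ySyn)] <- 0
  muSyn[is.na(muSyn)] <- 0
  post <- geneEffectPosterior(bmm@alpha, ySyn, muSyn, lev)

  isNS <- impactSub == "NS"
  gene <- factor(geneSub[isNS], levels = lev)
  y <- cnt[isNS]
  mu <- rSub[isNS]
  X <- fnFeatures(sites)[idx[isNS], , drop = FALSE]
  if (!is.null(featureSubset)) {
    miss <- setdiff(featureSubset, colnames(X))
    if (length(miss))
      stop("unknown functional feature(s): ", paste(miss, collapse = ", "))
    X <- X[, featureSubset, drop = FALSE]
  }
  p <- ncol(X)
  a <- post@a
  b <- post@b
  Yg <- groupSum(y, gene)
  Yg[is.na(Yg)] <- 0
  sumLgam <- sum(lgamma(y + 1))
  logMu <- log(mu)
  constAB <- sum(a * log(b) - lgamma(a) + lgamma(a + Yg))

  ## the likelihood depends on the binary features only through per-gene,
  ## per-feature-pattern sums of counts and rates: collapse the row-level
  ## data onto that coarse grid before optimizing
  pid <- if (p) as.integer(drop(X %*% 2^(seq_len(p) - 1L))) + 1L
         else rep(1L, length(y))
  U <- if (p) {
    codes <- seq_len(2^p) - 1L
    vapply(seq_len(p), function(j) as.numeric(bitwAnd(codes, 2^(j - 1L)) > 0),
           numeric(2^p))
  } else matrix(0, 1L, 0L)
  if (p) colnames(U) <- colnames(X)
  nPat <- nrow(U)
  gi <- (as.integer(gene) - 1L) * nPat + pid
  keep <- sort(unique(gi))
  sY <- as.numeric(rowsum(y, gi))
  sMu <- as.numeric(rowsum(mu, gi))
  gpGene <- factor(levels(gene)[(keep - 1L) %/% nPat + 1L],
                   levels = levels(gene))
  gpPid <- (keep - 1L) %% nPat + 1L

  ## additive constants (in par) stay out of the optimized objective to
  ## preserve line-search precision; restored in the reported loglik
  llConst <- sum(y * logMu) - sumLgam + constAB
  evalModel <- function(par) {
    etaU <- par[1L] + if (p) drop(U %*% par[-1L]) else 0
    eff <- sMu * exp(etaU)[gpPid]
    Mg <- groupSum(eff, gpGene)
    Mg[is.na(Mg)] <- 0
    ll <- sum(sY * etaU[gpPid]) - sum((a + Yg) * log(b + Mg))
    w <- (a + Yg) / (b + Mg)
    r <- sY - w[gpGene] * eff
    list(ll = ll,
         grad = c(sum(r),
                  if (p) drop(crossprod(U[gpPid, , drop = FALSE], r))))
  }

  tracer <- makeTracer()
  fn <- function(par) {
    v <- evalModel(par)$ll
    traceEval(tracer, v)
    -v
  }
  gr <- function(par) -evalModel(par)$grad
  parInit <- rep(0, 1L + p)
  opt <- robustMaximize(fn, gr, parInit, lower = rep(-20, 1L + p),
                        upper = rep(20, 1L + p), maxit = maxit,
                        factr = factr, context = "selection model fit")
  hess <- stats::optimHess(opt$par, fn, gr)
  se <- rep(NA_real_, 1L + p)
  vc <- try(solve(hess), silent = TRUE)
  if (inherits(vc, "try-error") || any(diag(vc) <= 0)) {
    warning("singular observed information; standard errors reported NA")
  } else {
    se <- sqrt(diag(vc))
  }
  report <- list(iterations = opt$counts[["function"]],
                 evaluations = tracer$evals,
                 loglik = -opt$value + llConst,
                 gradientNorm = sqrt(sum(evalModel(opt$par)$grad^2)),
                 trace = tracer$trace + llConst,
                 convergence = opt$convergence,
                 nTrainGenes = nlevels(gene))
  betaF <- if (p) stats::setNames(opt$par[-1L], colnames(X)) else numeric(0)
  names(se) <- c("intercept", colnames(X))
  SMMParams(hypothesis = hypothesis, beta0F = opt$par[1L], betaF = betaF,
            se = se, convergence = report)
}

#' Empirical-Bayes shrinkage of per-tumor coefficients toward their mean
#'
#' Normal-means model: each tumor type's raw estimate is Normal(truth,
#' se^2) and truths are Normal(m, tau^2) across tumor types; (m, tau^2) are
#' estimated by marginal maximum likelihood (profile over m, tau^2 >= 0)
#' and posterior means shrink each estimate toward m, most strongly for
#' tumors with large standard errors.
#'
#' @param estimates named numeric vector, one coefficient per tumor type.
#' @param ses aligned standard errors (>= 0).
#' @return list with \code{raw}, \code{se}, \code{m}, \code{tau2} and
#'   \code{shrunk} (posterior means per tumor).
#' @export
shrinkAcrossTumors <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses), all(ses >= 0, na.rm = TRUE))
  ok <- is.finite(estimates) & is.finite(ses)
  if (sum(ok) < 2L) {
    warning("fewer than two tumors with finite estimates; returned unshrunk")
    return(list(raw = estimates, se = ses, m = NA_real_, tau2 = NA_real_,
                shrunk = estimates))
  }
  x <- estimates[ok]
  se2 <- ses[ok]^2
  profM <- function(tau2) {
    w <- 1 / (se2 + tau2)
    sum(w * x) / sum(w)
  }
  nll <- function(logTau2) {
    tau2 <- exp(logTau2)
    m <- profM(tau2)
    -sum(stats::dnorm(x, m, sqrt(se2 + tau2), log = TRUE))
  }
  ## profile over log tau2, then compare against the tau2 = 0 boundary
  opt <- stats::optimize(nll, c(log(1e-12), log(1e6)), tol = 1e-10)
  tau2 <- exp(opt$minimum)
  m0 <- profM(0)
  nll0 <- -sum(stats::dnorm(x, m0, sqrt(pmax(se2, 1e-300)), log = TRUE))
  if (all(se2 > 0) && nll0 <= opt$objective) {
    tau2 <- 0
  }
  m <- profM(tau2)
  shrunk <- estimates
  if (tau2 == 0) {
    shrunk[ok] <- ifelse(se2 == 0, x, m)
  } else {
    wData <- tau2 / (se2 + tau2)
    shrunk[ok] <- wData * x + (1 - wData) * m
  }
  list(raw = estimates, se = ses, m = m, tau2 = tau2, shrunk = shrunk)
}

#' Shrink fitted selection models across tumor cohorts
#'
#' Applies \code{\link{shrinkAcrossTumors}} coefficient-by-coefficient
#' (intercept and every functional feature, within each hypothesis) to a
#' set of per-cohort fitted selection models, replacing each cohort's
#' estimates by their empirical-Bayes posterior means. Standard errors are
#' passed through unchanged.
#'
#' @param smmByTumor named list (one element per tumor cohort) of named
#'   lists of \code{\link{SMMParams}} as returned by the fitting workflow.
#' @return the same structure with shrunk coefficients.
#' @export
shrinkSMMAcrossTumors <- function(smmByTumor) {
  stopifnot(length(smmByTumor) >= 2L)
  tumors <- names(smmByTumor)
  hyps <- Reduce(intersect, lapply(smmByTumor, names))
  for (h in hyps) {
    coefs <- c("(intercept)",
               names(smmByTumor[[1L]][[h]]@betaF))
    for (cf in coefs) {
      est <- vapply(tumors, function(tm) {
        pm <- smmByTumor[[tm]][[h]]
        if (cf == "(intercept)") pm@beta0F else pm@betaF[[cf]]
      }, numeric(1))
      ses <- vapply(tumors, function(tm) {
        pm <- smmByTumor[[tm]][[h]]
        if (!length(pm@se)) return(NA_real_)
        if (cf == "(intercept)") pm@se[[1L]]
        else pm@se[[cf]]
      }, numeric(1))
      sh <- suppressWarnings(shrinkAcrossTumors(est, ses))
      for (tm in tumors) {
        pm <- smmByTumor[[tm]][[h]]
        if (cf == "(intercept)") pm@beta0F <- unname(sh$shrunk[[tm]])
        else pm@betaF[[cf]] <- unname(sh$shrunk[[tm]])
        smmByTumor[[tm]][[h]] <- pm
      }
    }
  }
  smmByTumor
}

#' Write / read fitted selection models as structured text
#'
#' One YAML document holding one block per hypothesis.
#'
#' @param smmList named list of \code{\link{SMMParams}} (names H0/OG/TSG).
#' @param path file path.
#' @return \code{readSMM} returns the named list back.
#' @export
writeSMM <- function(smmList, path) {
  blocks <- lapply(smmList, function(pm) {
    list(hypothesis = pm@hypothesis, beta0F = pm@beta0F,
         betaF = as.list(pm@betaF), se = as.list(pm@se))
  })
  yaml::write_yaml(list(model = "smm", hypotheses = blocks), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname writeSMM
#' @export
readSMM <- function(path) {
  obj <- yaml::read_yaml(path)
  stopifnot(identical(obj$model, "smm"))
  out <- lapply(obj$hypotheses, function(bl) {
    SMMParams(hypothesis = bl$hypothesis, beta0F = bl$beta0F,
              betaF = unlist(bl$betaF) %||% numeric(0),
              se = unlist(bl$se) %||% numeric(0))
  })
  names(out) <- vapply(out, function(x) x@hypothesis, character(1))
  out
}
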