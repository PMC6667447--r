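## Gene-level Bayes factors, driver-fraction estimation, posterior driver
## probabilities, Bayesian FDR and calling.

#' Score all genes: Bayes factors, posteriors and Bayesian FDR
#'
#' For each gene, computes the conditional marginal log-likelihood of its
#' non-synonymous counts given its synonymous data under the non-driver,
#' oncogene and tumor-suppressor models (the driver models optionally with
#' their hotspot HMM), and the Bayes factor
#' \deqn{BF = [0.5 P(Y|OG) + 0.5 P(Y|TSG)] / P(Y|H0),}
#' assembled in log space. The synonymous factor is common to all
#' hypotheses and cancels. Posterior driver probabilities use the
#' (estimated or supplied) driver-gene fraction, and genes are called at
#' the Bayesian FDR threshold.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param counts aligned count vector.
#' @param bmm fitted \code{\link{BMMParams}}.
#' @param smm named list of \code{\link{SMMParams}} with elements
#'   \code{H0}, \code{OG}, \code{TSG}.
#' @param hmm optional named list of \code{\link{HMMParams}} with elements
#'   \code{OG}, \code{TSG}; NULL disables the spatial model.
#' @param pi driver-gene fraction; estimated by maximum likelihood from the
#'   Bayes factors when NULL.
#' @param fdrThreshold Bayesian FDR calling cutoff.
#' @param nNodes quadrature nodes for the spatial likelihood.
#' @param rates optional precomputed background rates for all site rows.
#' @return data.frame with one row per gene: counts, per-hypothesis
#'   log-likelihoods, \code{log10_bf}, advisory \code{driver_class},
#'   \code{pp}, \code{qvalue} and \code{called}.
#' @export
scoreGenes <- function(sites, counts, bmm, smm, hmm = NULL, pi = NULL,
                       fdrThreshold = 0.1, nNodes = 16L, rates = NULL) {
  stopifnot(all(c("H0", "OG", "TSG") %in% names(smm)))
  s <- siteData(sites)
  if (is.null(rates)) rates <- backgroundRate(sites, bmm)
  post <- genePosteriorFromData(sites, counts, bmm, rates)
  lev <- post@geneId
  a <- post@a
  b <- post@b
  isNS <- s$impact == "NS"
  gNS <- factor(s$gene_id[isNS], levels = lev)
  y <- counts[isNS]
  mu <- rates[isNS]
  Yg <- groupSum(y, gNS)
  Yg[is.na(Yg)] <- 0
  lgamG <- groupSum(lgamma(y + 1), gNS)
  lgamG[is.na(lgamG)] <- 0
  nSyn <- groupSum(counts[!isNS], factor(s$gene_id[!isNS], levels = lev))
  nSyn[is.na(nSyn)] <- 0

  fnNS <- fnFeatures(sites)[isNS, , drop = FALSE]
  condLL <- function(pm) {
    nm <- names(pm@betaF)
    eta <- rep(pm@beta0F, length(y))
    if (length(nm)) {
      miss <- setdiff(nm, colnames(fnNS))
      if (length(miss))
        stop("site table lacks functional feature(s): ",
             paste(miss, collapse = ", "))
      eta <- eta + drop(fnNS[, nm, drop = FALSE] %*% pm@betaF)
    }
    gamma <- exp(eta)
    eff <- mu * gamma
    sumYLog <- groupSum(y * log(eff), gNS)
    sumYLog[is.na(sumYLog)] <- 0
    Mg <- groupSum(eff, gNS)
    Mg[is.na(Mg)] <- 0
    list(ll = pgLogMarginal(sumYLog, lgamG, Yg, Mg, a, b), M = Mg,
         gamma = gamma)
  }
  h0 <- condLL(smm$H0)
  og <- condLL(smm$OG)
  tsg <- condLL(smm$TSG)

  ## spatial correction for driver hypotheses (additive on the log scale)
  hmmCorrection <- function(base, gammaVec, pm) {
    corr <- numeric(length(lev))
    if (is.null(pm) || pm@noHotspot || pm@rho == 1 || pm@qEnter == 0)
      return(corr)
    eff <- mu * gammaVec
    posNS <- s$pos[isNS]
    ord <- order(gNS, posNS)
    idxByGene <- split(ord, gNS[ord])
    for (k in seq_along(lev)) {
      sel <- idxByGene[[k]]
      if (!length(sel)) next
      cp <- collapseByPosition(y[sel], eff[sel], posNS[sel])
      quad <- gammaQuadrature(a[k] + sum(y[sel]), b[k] + sum(eff[sel]),
                              nNodes)
      logh <- hotspotLogFactors(cp$y, cp$R, pm@rho, quad$nodes)
      logH <- hmmForwardLogH(logh, pm@qEnter, 1 / pm@meanLen)
      corr[k] <- logSumExp(log(quad$weights) + logH)
    }
    corr
  }
  llH0 <- h0$ll
  llOG <- og$ll + hmmCorrection(og$ll, og$gamma, hmm$OG)
  llTSG <- tsg$ll + hmmCorrection(tsg$ll, tsg$gamma, hmm$TSG)

  noNS <- h0$M == 0
  if (any(noNS))
    warning(sum(noNS), " gene(s) without non-synonymous opportunity; ",
            "Bayes factor set to 1")
  lbf <- apply(cbind(log(0.5) + llOG, log(0.5) + llTSG), 1L, logSumExp) -
    llH0
  lbf[noNS] <- 0
  log10bf <- lbf / log(10)

  if (is.null(pi)) pi <- estimateDriverFraction(log10bf)
  fdr <- posteriorAndFdr(log10bf, pi, fdrThreshold, geneIds = lev)
  res <- data.frame(gene_id = lev, n_syn = as.integer(nSyn),
                    n_nonsyn = as.integer(Yg),
                    loglik_H0 = llH0, loglik_OG = llOG, loglik_TSG = llTSG,
                    log10_bf = log10bf,
                    driver_class = ifelse(llOG >= llTSG, "OG", "TSG"),
                    pp = fdr$pp, qvalue = fdr$qvalue, called = fdr$called,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "pi") <- pi
  res
}

#' Estimate the proportion of driver genes by maximum likelihood
#'
#' Maximizes the two-group marginal log-likelihood in Bayes-factor form,
#' \eqn{\sum_g \log(\pi BF_g + 1 - \pi)}, over \eqn{\pi \in [0, 1]}.
#'
#' @param log10bf per-gene log10 Bayes factors.
#' @return estimated fraction; 0 with a warning when the likelihood is flat
#'   (all Bayes factors 1).
#' @export
estimateDriverFraction <- function(log10bf) {
  stopifnot(length(log10bf) >= 1L)
  lbf <- log10bf * log(10)
  if (all(abs(lbf) < 1e-12)) {
    warning("all Bayes factors equal 1: flat likelihood, returning pi = 0")
    return(0)
  }
  obj <- function(pi) {
    if (pi <= 0) return(0)
    if (pi >= 1) return(sum(lbf))
    sum(apply(cbind(log(pi) + lbf, log1p(-pi)), 1L, logSumExp))
  }
  opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-9)
  cand <- c(opt$maximum, 0, 1)
  vals <- vapply(cand, obj, numeric(1))
  cand[which.max(vals)]
}

#' Posterior driver probabilities and Bayesian FDR
#'
#' Posterior probability \eqn{pp_g = \pi BF_g / (\pi BF_g + 1 - \pi)};
#' genes are ranked by Bayes factor (ties broken by gene id) and the
#' q-value at rank k is the running mean of (1 - pp) over the top k (the
#' expected proportion of non-drivers among the called set). The called
#' set is the largest prefix with q-value at or below the threshold.
#'
#' @param log10bf per-gene log10 Bayes factors.
#' @param pi driver-gene fraction in [0, 1].
#' @param threshold Bayesian FDR cutoff.
#' @param geneIds optional ids used for deterministic tie-breaking.
#' @return list with \code{pp}, \code{qvalue}, \code{called} (logical), in
#'   the input order.
#' @export
posteriorAndFdr <- function(log10bf, pi, threshold = 0.1, geneIds = NULL) {
  stopifnot(pi >= 0, pi <= 1)
  n <- length(log10bf)
  if (is.null(geneIds)) geneIds <- as.character(seq_len(n))
  lbf <- log10bf * log(10)
  pp <- if (pi == 0) rep(0, n) else if (pi == 1) rep(1, n) else {
    num <- log(pi) + lbf
    den <- apply(cbind(num, log1p(-pi)), 1L, logSumExp)
    exp(num - den)
  }
  ord <- order(-log10bf, geneIds)
  qSorted <- cumsum(1 - pp[ord]) / seq_len(n)
  called <- rep(FALSE, n)
  ok <- which(qSorted <= threshold)
  if (length(ok)) called[ord[seq_len(max(ok))]] <- TRUE
  qvalue <- numeric(n)
  qvalue[ord] <- qSorted
  list(pp = pp, qvalue = qvalue, called = called)
}

#' Leave-one-gene-out evaluation of training genes
#'
#' Refits the selection (and spatial) model for the hypothesis whose
#' training list contains each target gene, with that gene omitted, then
#' rescores all genes and reports the target's result row. Guards against
#' the optimism of evaluating a training gene with models trained on
#' itself.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param counts aligned count vector.
#' @param bmm fitted \code{\link{BMMParams}}.
#' @param smm named list of fitted \code{\link{SMMParams}} (H0/OG/TSG).
#' @param hmm optional named list of fitted \code{\link{HMMParams}}.
#' @param ogList,tsgList training gene id vectors.
#' @param targetGenes genes to evaluate (each must be in a training list).
#' @param featureSubset,fdrThreshold,nNodes passed through to the fitting
#'   and scoring steps.
#' @param pi driver fraction passed to scoring (estimated when NULL).
#' @return data.frame with one result row per target gene.
#' @export
leaveOneGeneOut <- function(sites, counts, bmm, smm, hmm = NULL,
                            ogList, tsgList, targetGenes,
                            featureSubset = NULL, fdrThreshold = 0.1,
                            pi = NULL, nNodes = 16L) {
  rows <- vector("list", length(targetGenes))
  for (i in seq_along(targetGenes)) {
    g <- targetGenes[[i]]
    inOG <- g %in% ogList
    inTSG <- g %in% tsgList
    if (!inOG && !inTSG)
      stop("gene '", g, "' is not in any training list")
    smm2 <- smm
    hmm2 <- hmm
    for (hyp in c("OG", "TSG")[c(inOG, inTSG)]) {
      lst <- setdiff(if (hyp == "OG") ogList else tsgList, g)
      if (!length(lst))
        stop("training list for ", hyp, " would be empty without '", g, "'")
      smm2[[hyp]] <- fitSMM(sites, counts, bmm, lst, hyp,
                            featureSubset = featureSubset)
      if (!is.null(hmm))
        hmm2[[hyp]] <- fitHMM(sites, counts, bmm, smm2[[hyp]], lst, hyp,
                              nNodes = nNodes)
    }
    res <- scoreGenes(sites, counts, bmm, smm2, hmm2, pi = pi,
                      fdrThreshold = fdrThreshold, nNodes = nNodes)
    rows[[i]] <- res[res$gene_id == g, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write gene-level results as TSV
#'
#' @param results data.frame from \code{\link{scoreGenes}}.
#' @param path output path.
#' @export
writeResults <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
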