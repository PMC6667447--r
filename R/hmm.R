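## Two-state hotspot hidden Markov model over a gene's coding positions.
## The hidden chain (background / hotspot) runs along non-synonymous
## positions in genomic order; the hotspot state multiplies non-synonymous
## rates by rho. The gene effect lambda is integrated against its posterior
## on a fixed Gauss quadrature grid: writing the full likelihood as the
## non-spatial Poisson-Gamma marginal times a path-averaged correction
## factor, the reference measure is the full-data lambda posterior
## Gamma(a + Y, b + M) and the correction for a hotspot position is
## rho^y_i * exp(-(rho - 1) R_i lambda), so the spatial likelihood is exact
## (not merely quadrature-close) at rho = 1 and at qEnter = 0.

## Collapse per-(position, alt) rows of one gene into per-position sums.
collapseByPosition <- function(counts, effRates, positions) {
  if (is.unsorted(positions)) stop("positions must be sorted along the gene")
  f <- factor(positions, levels = unique(positions))
  list(y = as.numeric(groupSum(counts, f)),
       R = as.numeric(groupSum(effRates, f)),
       pos = unique(positions))
}

## Hotspot log correction factors: npos x nnodes matrix.
hotspotLogFactors <- function(yPos, RPos, rho, nodes) {
  yPos * log(rho) - (rho - 1) * outer(RPos, nodes)
}

#' Marginal log-likelihood of a gene under the spatial (hotspot) model
#'
#' Sums over hidden hotspot paths by the forward algorithm in log space and
#' integrates the gene effect over its Gamma(a, b) posterior on a fixed
#' quadrature grid. Reduces exactly to \code{\link{nsConditionalLoglik}}
#' when \code{rho = 1}, when \code{qEnter = 0}, or when the no-hotspot flag
#' is set.
#'
#' @param counts nonnegative counts of the gene's non-synonymous rows,
#'   ordered along the gene.
#' @param effRates aligned effective rates mu * gamma (selection applied,
#'   hotspot multiplier excluded).
#' @param positions aligned genomic positions (sorted; the three alternate
#'   rows of a position share its value).
#' @param posterior gene-effect posterior: a \code{\link{GenePosterior}}
#'   restricted to one gene or a list with \code{a}, \code{b}.
#' @param hmm an \code{\link{HMMParams}}.
#' @param nNodes quadrature nodes for the gene-effect integral.
#' @param plugin if TRUE, replace the quadrature by a single evaluation at
#'   the posterior-mean gene effect.
#' @return log marginal likelihood.
#' @export
hmmMarginalLoglik <- function(counts, effRates, positions, posterior, hmm,
                              nNodes = 16L, plugin = FALSE) {
  if (hmm@rho <= 0) stop("rho must be > 0")
  if (is.unsorted(positions)) stop("positions must be sorted along the gene")
  ab <- extractAB(posterior)
  base <- nsConditionalLoglik(counts, effRates, rep(1, length(counts)),
                              ab)
  if (hmm@noHotspot || hmm@rho == 1 || hmm@qEnter == 0) return(base)
  cp <- collapseByPosition(counts, effRates, positions)
  aa <- ab$a + sum(counts)
  bb <- ab$b + sum(effRates)
  quad <- if (plugin) list(nodes = aa / bb, weights = 1)
          else gammaQuadrature(aa, bb, nNodes)
  logh <- hotspotLogFactors(cp$y, cp$R, hmm@rho, quad$nodes)
  logH <- hmmForwardLogH(logh, hmm@qEnter, 1 / hmm@meanLen)
  base + logSumExp(log(quad$weights) + logH)
}

## Precompute per-gene non-synonymous summaries used by HMM fitting and
## scoring: per-position counts/rates, posterior (a, b), base loglik and
## quadrature grid (fixed during rho/q/meanLen optimization).
prepareHMMGene <- function(counts, effRates, positions, a, b,
                           nNodes = 16L) {
  cp <- collapseByPosition(counts, effRates, positions)
  base <- pgLogMarginal(sum(counts * log(effRates)),
                        sum(lgamma(counts + 1)),
                        sum(counts), sum(effRates), a, b)
  quad <- gammaQuadrature(a + sum(counts), b + sum(effRates), nNodes)
  list(y = cp$y, R = cp$R, pos = cp$pos, base = base,
       nodes = quad$nodes, logw = log(quad$weights))
}

hmmGeneLoglik <- function(prep, qEnter, meanLen, rho) {
  if (rho == 1 || qEnter == 0) return(prep$base)
  logh <- hotspotLogFactors(prep$y, prep$R, rho, prep$nodes)
  logH <- hmmForwardLogH(logh, qEnter, 1 / meanLen)
  prep$base + logSumExp(prep$logw + logH)
}

## Build per-gene HMM inputs from a site table for a set of genes.
hmmPrepareGenes <- function(sites, counts, bmm, smm, genes,
                            nNodes = 16L, rates = NULL, gamma = NULL,
                            post = NULL) {
  if (is.null(rates) && is.null(gamma) && is.null(post)) {
    sel <- siteData(sites)$gene_id %in% genes
    sites <- sites[sel]
    counts <- counts[sel]
  }
  s <- siteData(sites)
  if (is.null(rates)) rates <- backgroundRate(sites, bmm)
  if (is.null(gamma)) gamma <- selectionEffect(sites, smm)
  if (is.null(post)) post <- genePosteriorFromData(sites, counts, bmm, rates)
  aAll <- stats::setNames(post@a, post@geneId)
  bAll <- stats::setNames(post@b, post@geneId)
  isNS <- s$impact == "NS"
  out <- list()
  for (g in genes) {
    sel <- which(isNS & s$gene_id == g)
    if (!length(sel)) next
    sel <- sel[order(s$pos[sel])]
    out[[g]] <- prepareHMMGene(counts[sel], rates[sel] * gamma[sel],
                               s$pos[sel], aAll[[g]], bAll[[g]], nNodes)
  }
  out
}

#' Fit the hotspot HMM parameters on training genes
#'
#' With the background and selection models frozen, maximizes the summed
#' spatial marginal log-likelihood of the training genes over
#' (logit qEnter, log(meanLen - 1), log rho). A coarse initialization grid
#' seeds a Nelder-Mead refinement (the likelihood surface is multi-modal).
#' When the best fit does not improve on the non-spatial likelihood, a
#' boundary fit with the no-hotspot flag is returned instead of failing.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param counts aligned count vector.
#' @param bmm fitted \code{\link{BMMParams}}.
#' @param smm fitted \code{\link{SMMParams}} for the same hypothesis.
#' @param trainGenes character vector of training gene ids.
#' @param hypothesis "OG" or "TSG".
#' @param nNodes quadrature nodes.
#' @param qGrid,lenGrid,rhoGrid initialization grid.
#' @param lrtCutoff minimum likelihood-ratio statistic 2 * (spatial -
#'   non-spatial) required to accept a spatial fit; the default is the 95th
#'   percentile of chi-squared with 3 degrees of freedom, so chance
#'   improvement from optimizing the three spatial parameters on flat data
#'   raises the no-hotspot flag about 95 percent of the time (more, given
#'   the boundary null).
#' @return an \code{\link{HMMParams}}.
#' @export
fitHMM <- function(sites, counts, bmm, smm, trainGenes, hypothesis,
                   nNodes = 16L, qGrid = c(1e-5, 1e-4),
                   lenGrid = c(3, 5, 10), rhoGrid = c(10, 100, 1000),
                   lrtCutoff = stats::qchisq(0.95, df = 3)) {
  preps <- hmmPrepareGenes(sites, counts, bmm, smm, trainGenes, nNodes)
  if (!length(preps)) stop("no training genes with non-synonymous sites")
  ll0 <- sum(vapply(preps, `[[`, numeric(1), "base"))
  total <- function(q, len, rho) {
    sum(vapply(preps, hmmGeneLoglik, numeric(1), qEnter = q,
               meanLen = len, rho = rho))
  }
  grid <- expand.grid(q = qGrid, len = lenGrid, rho = rhoGrid)
  gridLL <- mapply(total, grid$q, grid$len, grid$rho)
  bestIdx <- which.max(gridLL)
  toPar <- function(q, len, rho) c(stats::qlogis(q), log(len - 1), log(rho))
  fromPar <- function(par) list(q = stats::plogis(par[1L]),
                                len = 1 + exp(par[2L]),
                                rho = exp(par[3L]))
  negLL <- function(par) {
    pr <- fromPar(par)
    -total(pr$q, pr$len, pr$rho)
  }
  opt <- stats::optim(toPar(grid$q[bestIdx], grid$len[bestIdx],
                            grid$rho[bestIdx]),
                      negLL, method = "Nelder-Mead",
                      control = list(maxit = 500L, reltol = 1e-10))
  pr <- fromPar(opt$par)
  llFit <- -opt$value
  report <- list(loglik = llFit, loglikNoHotspot = ll0,
                 gridLoglik = gridLL, convergence = opt$convergence)
  if (2 * (llFit - ll0) < lrtCutoff || pr$q < 1e-10) {
    return(HMMParams(qEnter = 0, meanLen = max(pr$len, 1),
                     rho = 1, hypothesis = hypothesis, noHotspot = TRUE,
                     convergence = report))
  }
  HMMParams(qEnter = pr$q, meanLen = pr$len, rho = pr$rho,
            hypothesis = hypothesis, noHotspot = FALSE,
            convergence = report)
}

#' Posterior hotspot probabilities along a gene
#'
#' Forward-backward decoding of the hotspot state at every non-synonymous
#' position, averaging over the gene-effect quadrature nodes with weights
#' proportional to each node's data likelihood.
#'
#' @inheritParams hmmMarginalLoglik
#' @return data.frame with \code{pos} and \code{posterior} (probability of
#'   the hotspot state; all zeros with a warning under a no-hotspot fit).
#' @export
hotspotPosterior <- function(counts, effRates, positions, posterior, hmm,
                             nNodes = 16L) {
  cp <- collapseByPosition(counts, effRates, positions)
  if (hmm@noHotspot) {
    warning("no-hotspot fit: returning an all-zero track")
    return(data.frame(pos = cp$pos, posterior = rep(0, length(cp$pos))))
  }
  ab <- extractAB(posterior)
  aa <- ab$a + sum(counts)
  bb <- ab$b + sum(effRates)
  quad <- gammaQuadrature(aa, bb, nNodes)
  logh <- hotspotLogFactors(cp$y, cp$R, hmm@rho, quad$nodes)
  fb <- hmmForwardBackward(logh, hmm@qEnter, 1 / hmm@meanLen)
  logH <- attr(fb, "logH")
  lw <- log(quad$weights) + logH
  w <- exp(lw - logSumExp(lw))
  data.frame(pos = cp$pos, posterior = as.numeric(fb %*% w))
}

#' Likelihood-ratio test for the spatial model
#'
#' Compares the fitted spatial and non-spatial log-likelihoods on the same
#' data: the statistic is 2 * (loglikHMM - loglikNoHMM), referred to a
#' chi-squared distribution (3 free spatial parameters by default; the
#' boundary null makes this conservative).
#'
#' @param loglikHMM,loglikNoHMM fitted log-likelihoods on identical data.
#' @param df reference degrees of freedom.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
spatialModelTest <- function(loglikHMM, loglikNoHMM, df = 3) {
  stat <- 2 * (loglikHMM - loglikNoHMM)
  if (stat < -1e-6)
    stop("spatial likelihood below the non-spatial one: optimizer failure")
  stat <- max(stat, 0)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Write a hotspot posterior track
#'
#' Writes the full per-position TSV and a BED file (0-based half-open) of
#' intervals whose posterior exceeds a threshold, scored as
#' 1000 * posterior.
#'
#' @param track data.frame from \code{\link{hotspotPosterior}}.
#' @param chrom chromosome name.
#' @param tsvPath,bedPath output paths (either may be NULL).
#' @param threshold posterior cutoff for BED intervals.
#' @export
writeHotspotTrack <- function(track, chrom, tsvPath = NULL, bedPath = NULL,
                              threshold = 0.5) {
  if (!is.null(tsvPath)) {
    utils::write.table(cbind(chrom = chrom, track), tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bedPath)) {
    hot <- track[track$posterior > threshold, , drop = FALSE]
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0))
    if (nrow(hot)) {
      brk <- cumsum(c(1L, diff(hot$pos) != 1L))
      sp <- split(hot, brk)
      bed <- do.call(rbind, lapply(seq_along(sp), function(i) {
        h <- sp[[i]]
        data.frame(chrom = chrom, start = min(h$pos) - 1L,
                   end = max(h$pos), name = paste0("hotspot_", i),
                   score = round(1000 * mean(h$posterior)))
      }))
    }
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(track)
}

#' Write / read fitted hotspot model parameters
#'
#' @param hmmList named list of \code{\link{HMMParams}} (names OG/TSG).
#' @param path file path.
#' @return \code{readHMM} returns the named list back.
#' @export
writeHMM <- function(hmmList, path) {
  blocks <- lapply(hmmList, function(pm) {
    list(hypothesis = pm@hypothesis, qEnter = pm@qEnter,
         meanLen = pm@meanLen, rho = pm@rho, noHotspot = pm@noHotspot)
  })
  yaml::write_yaml(list(model = "hmm", hypotheses = blocks), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname writeHMM
#' @export
readHMM <- function(path) {
  obj <- yaml::read_yaml(path)
  stopifnot(identical(obj$model, "hmm"))
  out <- lapply(obj$hypotheses, function(bl) {
    HMMParams(qEnter = bl$qEnter, meanLen = bl$meanLen, rho = bl$rho,
              hypothesis = bl$hypothesis, noHotspot = bl$noHotspot)
  })
  names(out) <- vapply(out, function(x) x@hypothesis, character(1))
  out
}
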