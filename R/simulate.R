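## Ground-truth simulator: synthetic exome fixture, Markov-chain hotspots,
## negative-binomial background mutations over trinucleotide contexts,
## selection multipliers with per-site log-normal noise, and the simple
## dN/dS, clustering and Fisher-combination tests used for power studies.

#' Simulation configuration
#'
#' Bundles the generator settings with their default study conditions:
#' hotspot entry frequency 1e-5 per bp with mean length 5 bp, selection
#' multipliers 3 (non-hotspot) and 3000 (hotspot) on driver non-synonymous
#' rates, per-row Normal(0, 0.2^2) noise on log selection strength, and a
#' trinucleotide-context (192-class) negative-binomial background.
#'
#' @param nSamples cohort size.
#' @param roles named character vector over genes: "neutral", "OG", "TSG".
#' @param bgModel "context192" (trinucleotide-context rates, misspecified
#'   relative to the 9-type inference model) or "ninetype".
#' @param nbDispersion Gamma shape of the gene-level background effect;
#'   the marginal background counts are negative binomial. The default 10
#'   gives variance/mean of about 1.5 at typical per-gene totals.
#' @param hotspotFreq,hotspotMeanLen hotspot chain entry probability per bp
#'   and expected length in bp.
#' @param selNonhotspot,selHotspot driver selection multipliers outside and
#'   inside hotspots.
#' @param siteNoiseSd standard deviation of the per-row Gaussian noise
#'   added to log selection strength in driver genes.
#' @param fnEffects list with numeric vectors \code{TSG} and \code{OG} of
#'   log-scale functional-feature effects on driver selection (centered so
#'   the average multiplier stays at \code{selNonhotspot}); the defaults
#'   enrich loss-of-function mutations in TSGs and deplete them in OGs.
#' @param perSiteRate baseline background mutation rate per site per
#'   sample.
#' @param contextSd log-scale spread of the 192 context-specific rates
#'   around their 9-class means.
#' @param typeOffsets log-scale offsets of the nine mutation-type rates
#'   around \code{perSiteRate} (CpG transitions elevated).
#' @param bgEffects named log-scale effects of the background covariates
#'   (negative expression effect, reflecting transcription-coupled
#'   repair).
#' @param seed integer seed making the whole simulation reproducible.
#' @return a list of settings for \code{\link{simulateCounts}}.
#' @export
simConfig <- function(nSamples = 500L, roles = NULL,
                      bgModel = c("context192", "ninetype"),
                      nbDispersion = 10, hotspotFreq = 1e-5,
                      hotspotMeanLen = 5, selNonhotspot = 3,
                      selHotspot = 3000, siteNoiseSd = 0.2,
                      fnEffects = list(
                        TSG = c(LoF = 1.5, CONS = 0.5, SiFT = 0.3,
                                PhyloP = 0.3, MA = 0.5),
                        OG = c(LoF = -1.5, CONS = 0.5, SiFT = 0.3,
                               PhyloP = 0.3, MA = 0.5)),
                      perSiteRate = 5e-6, contextSd = 0.5,
                      typeOffsets = c(1.4, 0, 0.2, -0.2, 0, -0.35,
                                      -0.5, 0.4, -0.2),
                      bgEffects = c(expr = -0.3, reptime = 0.3),
                      seed = 1L) {
  bgModel <- match.arg(bgModel)
  stopifnot(nbDispersion > 0, hotspotFreq >= 0, hotspotMeanLen >= 1,
            selNonhotspot > 0, selHotspot > 0, siteNoiseSd >= 0,
            perSiteRate > 0, length(typeOffsets) == 9L)
  list(nSamples = as.integer(nSamples), roles = roles, bgModel = bgModel,
       nbDispersion = nbDispersion, hotspotFreq = hotspotFreq,
       hotspotMeanLen = hotspotMeanLen, selNonhotspot = selNonhotspot,
       selHotspot = selHotspot, siteNoiseSd = siteNoiseSd,
       fnEffects = fnEffects, perSiteRate = perSiteRate,
       contextSd = contextSd, typeOffsets = typeOffsets,
       bgEffects = bgEffects, seed = as.integer(seed))
}

#' Synthetic exome fixture with background and functional features
#'
#' Generates genes with Gamma-distributed lengths around
#' \code{meanGeneLen}, a random reference sequence providing flanking
#' contexts, three alternate-allele rows per position, an approximately 3:1
#' non-synonymous to synonymous opportunity ratio, gene-level continuous
#' background covariates (expression, replication timing) and binary
#' functional covariates on non-synonymous rows.
#'
#' @param nGenes number of genes.
#' @param meanGeneLen mean coding length in bp.
#' @param seed integer seed; runs are bit-reproducible.
#' @param pNS probability that an alternate allele is non-synonymous.
#' @param fnFreq marginal frequencies of the binary functional features on
#'   non-synonymous rows.
#' @return a \code{\link{SiteTable}}.
#' @export
makeGenomeFixture <- function(nGenes, meanGeneLen = 1500, seed = 1L,
                              pNS = 0.75,
                              fnFreq = c(LoF = 0.05, CONS = 0.25,
                                         SiFT = 0.25, PhyloP = 0.25,
                                         MA = 0.25)) {
  stopifnot(nGenes >= 1L)
  set.seed(seed)
  lens <- pmax(30L, as.integer(round(
    stats::rgamma(nGenes, shape = 8, rate = 8 / meanGeneLen))))
  geneId <- sprintf("g%04d", seq_len(nGenes))
  starts <- cumsum(c(1L, utils::head(lens, -1L) + 100L))
  ## one concatenated reference sequence (with per-gene flanks)
  seqAll <- sample(DNA_BASES, sum(lens + 2L), replace = TRUE)
  seqStart <- cumsum(c(1L, utils::head(lens + 2L, -1L)))
  geneOf <- rep(seq_len(nGenes), lens)
  within <- sequence(lens)
  seqIdx <- seqStart[geneOf] + within
  ref <- seqAll[seqIdx]
  c5 <- seqAll[seqIdx - 1L]
  c3 <- seqAll[seqIdx + 1L]
  pos <- starts[geneOf] + within - 1L
  ## three alternate alleles per position
  altsOf <- t(vapply(DNA_BASES, function(r) setdiff(DNA_BASES, r),
                     character(3)))
  ri <- match(ref, DNA_BASES)
  n3 <- rep(seq_along(ref), each = 3L)
  s <- data.frame(
    gene_id = geneId[geneOf][n3], chrom = "chr1", pos = pos[n3],
    ref = ref[n3], alt = as.vector(t(altsOf[ri, , drop = FALSE])),
    context5 = c5[n3], context3 = c3[n3], stringsAsFactors = FALSE)
  s$mutation_type <- classifyMutationType(s$ref, s$alt, s$context5, s$context3)
  s$impact <- ifelse(stats::runif(nrow(s)) < pNS, "NS", "S")
  expr <- stats::rnorm(nGenes)
  rept <- stats::rnorm(nGenes)
  gidx <- geneOf[n3]
  bg <- cbind(expr = expr[gidx], reptime = rept[gidx])
  fn <- matrix(0, nrow(s), length(fnFreq),
               dimnames = list(NULL, names(fnFreq)))
  isNS <- s$impact == "NS"
  for (j in seq_along(fnFreq))
    fn[isNS, j] <- as.numeric(stats::runif(sum(isNS)) < fnFreq[j])
  SiteTable(s, bg, fn)
}

## One two-state chain path of length L via alternating geometric
## sojourns, started at stationarity. Returns a logical hotspot vector.
simulateChain <- function(L, q, ex) {
  if (q <= 0) return(rep(FALSE, L))
  piH <- q / (q + ex)
  out <- logical(L)
  pos <- 1L
  state <- stats::runif(1) < piH
  while (pos <= L) {
    run <- stats::rgeom(1L, if (state) ex else q) + 1L
    end <- min(L, pos + run - 1L)
    if (state) out[pos:end] <- TRUE
    pos <- end + 1L
    state <- !state
  }
  out
}

#' Simulate hotspot indicators along genes
#'
#' Two-state Markov chain per gene with entry probability
#' \code{hotspotFreq}, exit probability \code{1/hotspotMeanLen}, started at
#' its stationary distribution.
#'
#' @param geneLengths integer vector of gene lengths in bp.
#' @param hotspotFreq,hotspotMeanLen chain parameters.
#' @param seed optional integer seed.
#' @return list of logical vectors, one per gene.
#' @export
simulateHotspots <- function(geneLengths, hotspotFreq = 1e-5,
                             hotspotMeanLen = 5, seed = NULL) {
  stopifnot(hotspotFreq >= 0, hotspotFreq < 1, hotspotMeanLen >= 1)
  if (!is.null(seed)) set.seed(seed)
  ex <- 1 / hotspotMeanLen
  lapply(geneLengths, simulateChain, q = hotspotFreq, ex = ex)
}

## 192 trinucleotide-context rates: per (context5, ref, context3, alt)
## log-rate drawn around the 9-class baseline. Indexed by a dense integer
## code over the 256 base combinations (ref == alt entries stay NA).
contextCode <- function(c5, ref, c3, alt) {
  b <- function(x) match(x, DNA_BASES) - 1L
  ((b(c5) * 4L + b(ref)) * 4L + b(c3)) * 4L + b(alt) + 1L
}

contextRateTable <- function(typeLogRates, contextSd) {
  grid <- expand.grid(alt = DNA_BASES, c3 = DNA_BASES, ref = DNA_BASES,
                      c5 = DNA_BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  type <- classifyMutationType(grid$ref, grid$alt, grid$c5, grid$c3)
  logRate <- typeLogRates[type] + stats::rnorm(nrow(grid), 0, contextSd)
  out <- rep(NA_real_, 256L)
  out[contextCode(grid$c5, grid$ref, grid$c3, grid$alt)] <- logRate
  out
}

#' Simulate mutation counts, records and ground truth over a site table
#'
#' Background counts are Poisson given a gene-level Gamma effect
#' (marginally negative binomial) around rates that vary either by the nine
#' mutation types or by all 192 trinucleotide contexts. Driver genes'
#' non-synonymous rates are multiplied by the non-hotspot or hotspot
#' selection strength, functional-feature effects (centered to preserve
#' the average multiplier) and per-row log-normal noise; synonymous sites
#' are untouched by selection. Aggregate counts are carved into per-sample
#' records by uniform assignment.
#'
#' @param sites a \code{\link{SiteTable}} (e.g. from
#'   \code{\link{makeGenomeFixture}}).
#' @param config a \code{\link{simConfig}} list; its \code{roles} entry
#'   must name every gene in \code{sites} (missing genes default to
#'   "neutral").
#' @return list with \code{counts} (aligned with site rows),
#'   \code{records} (MAF-like data.frame), and \code{truth} (per-gene
#'   roles and gene effects, per-row hotspot indicator and selection
#'   multiplier).
#' @export
simulateCounts <- function(sites, config) {
  stopifnot(config$nbDispersion > 0)
  set.seed(config$seed)
  s <- siteData(sites)
  genes <- geneIds(sites)
  roles <- rep("neutral", length(genes))
  names(roles) <- genes
  if (!is.null(config$roles)) {
    known <- intersect(names(config$roles), genes)
    roles[known] <- config$roles[known]
  }
  stopifnot(all(roles %in% c("neutral", "OG", "TSG")))

  ## background rates per row (per cohort)
  typeLogRates <- log(config$perSiteRate) + config$typeOffsets
  betaBgTrue <- config$bgEffects
  bg <- bgFeatures(sites)
  bgEta <- drop(bg[, names(betaBgTrue), drop = FALSE] %*% betaBgTrue)
  if (config$bgModel == "context192") {
    ctab <- contextRateTable(typeLogRates, config$contextSd)
    logMu <- ctab[contextCode(s$context5, s$ref, s$context3, s$alt)] +
      bgEta
  } else {
    logMu <- typeLogRates[s$mutation_type] + bgEta
  }
  mu <- exp(logMu) * config$nSamples

  ## gene-level background effect (negative-binomial overdispersion)
  lambda <- stats::rgamma(length(genes), config$nbDispersion,
                          config$nbDispersion)
  names(lambda) <- genes
  gidx <- match(s$gene_id, genes)

  ## hotspots along each gene's positions
  rowsByGene <- split(seq_len(nrow(s)), factor(s$gene_id, levels = genes))
  lens <- vapply(rowsByGene, function(r) length(unique(s$pos[r])),
                 integer(1))
  hotChains <- simulateHotspots(lens, config$hotspotFreq,
                                config$hotspotMeanLen)
  hotRow <- logical(nrow(s))
  for (k in seq_along(genes)) {
    rows <- rowsByGene[[k]]
    relPos <- match(s$pos[rows], sort(unique(s$pos[rows])))
    hotRow[rows] <- hotChains[[k]][relPos]
  }

  ## selection multipliers on driver non-synonymous rows
  mult <- rep(1, nrow(s))
  isNS <- s$impact == "NS"
  fn <- fnFeatures(sites)
  roleRow <- roles[gidx]
  for (role in c("TSG", "OG")) {
    driver <- roleRow == role & isNS
    if (!any(driver)) next
    beta <- config$fnEffects[[role]]
    beta <- beta[intersect(names(beta), colnames(fn))]
    eta <- if (length(beta))
      drop(fn[driver, names(beta), drop = FALSE] %*% beta) else 0
    ## center so the average non-hotspot multiplier stays at selNonhotspot
    eta <- eta - log(mean(exp(eta)))
    sel <- ifelse(hotRow[driver], config$selHotspot, config$selNonhotspot)
    noise <- stats::rnorm(sum(driver), 0, config$siteNoiseSd)
    mult[driver] <- sel * exp(eta + noise)
  }

  counts <- stats::rpois(nrow(s), mu * lambda[gidx] * mult)
  total <- sum(counts)
  rows <- rep.int(seq_len(nrow(s)), counts)
  records <- data.frame(
    sample_id = paste0("s", sample.int(config$nSamples, total,
                                       replace = TRUE)),
    chrom = s$chrom[rows], pos = s$pos[rows], ref = s$ref[rows],
    alt = s$alt[rows], stringsAsFactors = FALSE)
  list(counts = counts, records = records,
       truth = list(roles = roles, lambda = lambda, hotspot = hotRow,
                    multiplier = mult))
}

#' Simple dN/dS-style test for excess non-synonymous mutations
#'
#' Statistic \eqn{T = Poisson(y; \mu\gamma) / Poisson(y; \mu)} with the
#' alternative selection strength fixed at \code{gammaAlt}; the p-value is
#' the empirical upper-tail probability of T under Poisson background
#' draws, with the (1 + r) / (N + 1) small-sample correction.
#'
#' @param yNS total observed non-synonymous count.
#' @param muNS total non-synonymous background rate (> 0).
#' @param gammaAlt fixed alternative selection strength.
#' @param nullDraws either an integer number of null data sets to draw, or
#'   a precomputed numeric vector of null statistics.
#' @return list with \code{statistic} (log scale) and \code{p.value}.
#' @export
dndsTest <- function(yNS, muNS, gammaAlt = 3, nullDraws = 5000L) {
  stopifnot(muNS > 0, gammaAlt > 0)
  logT <- function(y) -muNS * (gammaAlt - 1) + y * log(gammaAlt)
  tObs <- logT(yNS)
  tNull <- if (length(nullDraws) > 1L) nullDraws
           else {
             if (nullDraws < 1L) stop("nullDraws must be nonempty")
             logT(stats::rpois(nullDraws, muNS))
           }
  p <- (1 + sum(tNull >= tObs)) / (length(tNull) + 1)
  list(statistic = tObs, p.value = p)
}

## Max sliding-window mutation count for sorted positions.
maxWindowCount <- function(positions, window) {
  if (!length(positions)) return(0L)
  positions <- sort(positions)
  hi <- findInterval(positions + window - 1, positions)
  max(hi - seq_along(positions) + 1L)
}

#' Spatial clustering test for mutation hotspots
#'
#' Statistic: maximum number of mutations within any sliding window
#' (default 3 bp), normalized by the gene's total mutation rate; the
#' p-value is empirical against null draws at the background rates.
#'
#' @param positions genomic positions of observed non-synonymous mutations
#'   (with multiplicity).
#' @param sitePositions,siteRates per-site positions and background rates
#'   for the gene's non-synonymous sites.
#' @param window window width in bp.
#' @param nullDraws integer number of null data sets, or a precomputed
#'   vector of null statistics.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
clusterTest <- function(positions, sitePositions, siteRates, window = 3L,
                        nullDraws = 5000L) {
  stopifnot(window >= 1L, length(sitePositions) == length(siteRates))
  M <- sum(siteRates)
  if (M <= 0) stop("total mutation rate must be > 0")
  tObs <- maxWindowCount(positions, window) / M
  tNull <- if (length(nullDraws) > 1L) nullDraws
           else {
             if (nullDraws < 1L) stop("nullDraws must be nonempty")
             n0 <- stats::rpois(nullDraws, M)
             vapply(n0, function(n) {
               if (n == 0L) return(0)
               p <- sample(sitePositions, n, replace = TRUE,
                           prob = siteRates)
               maxWindowCount(p, window) / M
             }, numeric(1))
           }
  p <- (1 + sum(tNull >= tObs)) / (length(tNull) + 1)
  list(statistic = tObs, p.value = p)
}

#' Combine two p-values with Fisher's method
#'
#' @param p1,p2 p-values in (0, 1].
#' @return combined p-value from the chi-squared distribution with 4
#'   degrees of freedom.
#' @export
fisherCombine <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    stop("p-values must be in (0, 1]")
  x <- -2 * (log(p1) + log(p2))
  stats::pchisq(x, df = 4, lower.tail = FALSE)
}

#' Score a caller's gene calls against simulation truth
#'
#' Computes, over test-set genes only (training genes excluded), the
#' true/false positive counts among called genes, the realized false
#' discovery proportion, ROC points over the caller's score, and the area
#' under the ROC curve.
#'
#' @param truthRoles named character vector of true roles per gene.
#' @param result data.frame with \code{gene_id}, a logical \code{called}
#'   column, and a numeric score column (default \code{log10_bf}).
#' @param trainGenes genes to exclude from evaluation.
#' @param scoreColumn name of the score column for the ROC.
#' @return list with \code{tp}, \code{fp}, \code{fdp}, \code{roc}
#'   (data.frame of threshold, fpr, tpr) and \code{auroc}.
#' @export
runBenchmark <- function(truthRoles, result, trainGenes = character(0),
                         scoreColumn = "log10_bf") {
  testGenes <- setdiff(names(truthRoles), trainGenes)
  isDriver <- truthRoles[testGenes] != "neutral"
  idx <- match(testGenes, result$gene_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " test gene(s) missing from the result table;",
            " treated as not called")
  called <- ifelse(is.na(idx), FALSE, result$called[idx])
  score <- ifelse(is.na(idx), -Inf, result[[scoreColumn]][idx])
  tp <- sum(called & isDriver)
  fp <- sum(called & !isDriver)
  fdp <- if (tp + fp > 0) fp / (tp + fp) else 0
  nPos <- sum(isDriver)
  nNeg <- sum(!isDriver)
  ord <- order(score, decreasing = TRUE)
  tpr <- cumsum(isDriver[ord]) / max(nPos, 1L)
  fpr <- cumsum(!isDriver[ord]) / max(nNeg, 1L)
  keep <- !duplicated(score[ord], fromLast = TRUE)
  roc <- data.frame(threshold = score[ord][keep], fpr = fpr[keep],
                    tpr = tpr[keep])
  r <- rank(score)
  auroc <- if (nPos > 0 && nNeg > 0)
    (mean(r[isDriver]) - (nPos + 1) / 2) / nNeg else NA_real_
  list(tp = tp, fp = fp, fdp = fdp, roc = roc, auroc = auroc)
}

#' Write simulation outputs to disk
#'
#' Emits the site table, the MAF-like mutation records, the ground truth
#' (per-gene roles plus per-row hotspot and multiplier) and the
#' configuration, all as plain text.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param sim output of \code{\link{simulateCounts}}.
#' @param config the \code{\link{simConfig}} used.
#' @param dir output directory (created if needed).
#' @export
writeSimulation <- function(sites, sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSiteTable(sites, file.path(dir, "sites.tsv"))
  utils::write.table(sim$records, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- siteData(sites)
  truth <- data.frame(gene_id = s$gene_id, chrom = s$chrom, pos = s$pos,
                      ref = s$ref, alt = s$alt,
                      role = sim$truth$roles[s$gene_id],
                      hotspot = as.integer(sim$truth$hotspot),
                      multiplier = sim$truth$multiplier,
                      stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- config
  cfg$roles <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
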