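test_that("background rates follow the log-linear model", {
  st <- tinySiteTable(bg = TRUE)
  s <- siteData(st)
  pm0 <- BMMParams(beta0 = rep(log(1e-6), 9))
  expect_equal(backgroundRate(st, pm0), rep(1e-6, nSites(st)))
  ## one feature with coefficient -0.3, evaluated at its raw value
  pm1 <- BMMParams(beta0 = rep(log(1e-6), 9), betaBg = c(expr = -0.3))
  mu <- backgroundRate(st, pm1)
  expect_equal(mu, 1e-6 * exp(-0.3 * bgFeatures(st)[, "expr"]))
  ## a coefficient on a zero covariate changes nothing
  st0 <- st
  bg <- bgFeatures(st)
  bg[, "expr"] <- 0
  st0 <- SiteTable(siteData(st), bg, fnFeatures(st))
  expect_equal(backgroundRate(st0, pm1), backgroundRate(st0, pm0))
})

test_that("synonymous marginal has the Gamma zero-count and Poisson limits", {
  mu <- c(0.4, 1.1, 2.0)
  M <- sum(mu)
  a <- 2.5
  expect_equal(synMarginalLoglik(c(0, 0, 0), mu, a), a * log(a / (a + M)))
  ## alpha -> infinity collapses the gene effect to 1 (pure Poisson)
  y <- c(1, 0, 3)
  expect_equal(synMarginalLoglik(y, mu, 1e6),
               sum(dpois(y, mu, log = TRUE)), tolerance = 1e-4)
  expect_error(synMarginalLoglik(y, mu, -1), "positive")
})

test_that("closed-form marginal matches quadrature on random instances", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    mu <- runif(n, 1e-3, 3)
    y <- rpois(n, pmin(mu * 2, 3))
    a <- runif(1, 0.2, 20)
    cf <- synMarginalLoglik(y, mu, a)
    expect_equal(cf, quadMarginalLoglik(y, mu, a, a), tolerance = 1e-8)
  }
})

test_that("fitting recovers symmetric intercepts for exchangeable types", {
  ## two mutation types (C>A and C>G outside CpG) living on identical site
  ## sets and given identical counts must receive equal intercepts
  n <- 300L
  mkBlock <- function(ref, c3, pos0) {
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    data.frame(gene_id = rep(paste0("g", rep(1:20, length.out = n)),
                             each = 3L),
               chrom = "chr1", pos = rep(pos0 + seq_len(n), each = 3L),
               ref = ref, alt = alts, context5 = "A", context3 = c3,
               stringsAsFactors = FALSE)
  }
  s <- rbind(mkBlock("C", "T", 0L), mkBlock("C", "G", n),
             mkBlock("T", "A", 2L * n))
  s$mutation_type <- classifyMutationType(s$ref, s$alt, s$context5,
                                          s$context3)
  s$impact <- "S"
  s <- s[order(s$gene_id, s$pos), ]
  st <- SiteTable(s)
  set.seed(11)
  counts <- integer(nrow(s))
  perSite <- rpois(n, 0.4)
  ord4 <- which(s$mutation_type == 4)
  ord6 <- which(s$mutation_type == 6)
  counts[ord4[order(s$pos[ord4])]] <- perSite
  counts[ord6[order(s$pos[ord6])]] <- perSite
  for (t in c(1:3, 5, 7:9))
    counts[s$mutation_type == t] <- rpois(sum(s$mutation_type == t), 0.3)
  fit <- suppressWarnings(fitBMM(st, counts))
  expect_equal(fit@beta0[4], fit@beta0[6], tolerance = 1e-6)
})

test_that("fitting recovers generating parameters and flags flat gene effects", {
  st <- makeGenomeFixture(120, 280, seed = 501)
  cfg <- simConfig(nSamples = 5000, bgModel = "ninetype",
                   nbDispersion = 8, seed = 502,
                   hotspotFreq = 0, siteNoiseSd = 0)
  sim <- simulateCounts(st, cfg)
  fit <- suppressWarnings(fitBMM(st, sim$counts))
  ## alpha near the generating dispersion (log-scale tolerance: the
  ## likelihood in alpha is shallow at this size)
  expect_gt(fit@alpha, cfg$nbDispersion / 4)
  expect_lt(fit@alpha, cfg$nbDispersion * 4)
  ## expression effect recovered with its negative sign
  exprHat <- fit@betaBg[["expr"]] / fit@scale[["expr"]]
  expect_lt(exprHat, 0)
  expect_lt(abs(exprHat - cfg$bgEffects[["expr"]]), 0.15)

  ## with constant gene effects the profile in alpha runs to the boundary
  lamFlat <- simConfig(nSamples = 5000, bgModel = "ninetype",
                       nbDispersion = 1e8,
                       seed = 503, hotspotFreq = 0, siteNoiseSd = 0)
  simFlat <- simulateCounts(st, lamFlat)
  fitFlat <- suppressWarnings(fitBMM(st, simFlat$counts))
  ## far above any realistic gene-effect dispersion: effectively flat
  expect_gt(fitFlat@alpha, 100)
  expect_gt(fitFlat@alpha, 10 * fit@alpha)
})

test_that("optimizer trace is monotone and the fit is deterministic", {
  d <- sharedSimulation()
  fit1 <- suppressWarnings(fitBMM(d$sites, d$sim$counts))
  fit2 <- suppressWarnings(fitBMM(d$sites, d$sim$counts))
  expect_identical(fit1@beta0, fit2@beta0)
  expect_identical(fit1@alpha, fit2@alpha)
  tr <- fit1@convergence$trace
  expect_true(all(diff(tr) >= 0))
  expect_lt(fit1@convergence$gradientNorm, 1e-2)
})

test_that("gene-effect posterior matches its closed form", {
  ## prior returned when the gene carries no data
  p0 <- geneEffectPosterior(2, 0, 0)
  expect_equal(posteriorMean(p0), c("1" = 1))
  ## direct substitution
  p1 <- geneEffectPosterior(1, 5, 3)
  expect_equal(p1@a, 6)
  expect_equal(p1@b, 4)
  expect_equal(unname(posteriorMean(p1)), 1.5)
  ## observed above expected pulls the mean above 1
  p2 <- geneEffectPosterior(3.3, 7, 4.1)
  expect_gt(unname(posteriorMean(p2)), 1)
  ## degenerate limits: data-dominated and prior-dominated
  expect_equal(unname(posteriorMean(geneEffectPosterior(1e-6, 8, 2))),
               8 / 2, tolerance = 1e-5)
  expect_equal(unname(posteriorMean(geneEffectPosterior(1e6, 8, 2))),
               1, tolerance = 1e-5)
})

test_that("gene-effect adjustment improves non-synonymous prediction", {
  wins <- 0L
  for (r in 1:12) {
    st <- makeGenomeFixture(150, 300, seed = 600 + r)
    cfg <- simConfig(nSamples = 3000, bgModel = "ninetype",
                     nbDispersion = 5,
                     seed = 700 + r, hotspotFreq = 0)
    sim <- simulateCounts(st, cfg)
    fit <- suppressWarnings(fitBMM(st, sim$counts))
    v <- validateGeneEffects(st, sim$counts, fit)
    if (v$r2[["adjusted"]] > v$r2[["unadjusted"]]) wins <- wins + 1L
  }
  expect_gte(wins, 11L)
})

test_that("without gene effects the adjustment changes nothing material", {
  st <- makeGenomeFixture(150, 300, seed = 801)
  cfg <- simConfig(bgModel = "ninetype", nbDispersion = 1e8, seed = 802,
                   hotspotFreq = 0)
  sim <- simulateCounts(st, cfg)
  fit <- suppressWarnings(fitBMM(st, sim$counts))
  v <- validateGeneEffects(st, sim$counts, fit)
  expect_equal(v$r2[["adjusted"]], v$r2[["unadjusted"]], tolerance = 0.05)
})

test_that("single-gene validation flags undefined correlations", {
  st <- tinySiteTable(nGenes = 1)
  counts <- integer(nSites(st))
  counts[which(siteData(st)$impact == "S")[1]] <- 1
  pm <- BMMParams(beta0 = rep(log(1e-3), 9), alpha = 2)
  v <- validateGeneEffects(st, counts, pm)
  expect_true(all(is.na(v$r2)))
  expect_equal(nrow(v$table), 1L)
})

test_that("fitted background models round-trip through their file format", {
  d <- sharedSimulation()
  fit <- suppressWarnings(fitBMM(d$sites, d$sim$counts))
  path <- tempfile(fileext = ".yaml")
  writeBMM(fit, path)
  back <- readBMM(path)
  expect_equal(back@beta0, fit@beta0)
  expect_equal(back@betaBg, fit@betaBg)
  expect_equal(back@alpha, fit@alpha)
  expect_equal(back@center, fit@center)
  expect_equal(back@scale, fit@scale)
})
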