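test_that("genome fixtures are reproducible and structurally sound", {
  a <- makeGenomeFixture(10, 200, seed = 5)
  b <- makeGenomeFixture(10, 200, seed = 5)
  expect_identical(siteData(a), siteData(b))
  expect_identical(bgFeatures(a), bgFeatures(b))
  expect_identical(fnFeatures(a), fnFeatures(b))
  c <- makeGenomeFixture(10, 200, seed = 6)
  expect_false(identical(siteData(a), siteData(c)))
  ## exactly three alternate rows per position (validity already enforces
  ## this; check directly as well)
  s <- siteData(a)
  expect_true(all(table(s$pos) == 3L))
  expect_true(validObject(a))
})

test_that("gene lengths and impact mix match their targets", {
  st <- makeGenomeFixture(1000, 1500, seed = 7)
  s <- siteData(st)
  lens <- tapply(s$pos, s$gene_id, function(p) length(unique(p)))
  expect_lt(abs(mean(lens) - 1500) / 1500, 0.1)
  ## roughly 3:1 non-synonymous to synonymous opportunity
  expect_lt(abs(mean(s$impact == "NS") - 0.75), 0.02)
})

test_that("hotspot chains obey their stationary law", {
  expect_true(all(!unlist(simulateHotspots(100L, 0, 5, seed = 1))))
  chains <- simulateHotspots(rep(1e6L, 10), 1e-3, 5, seed = 8)
  frac <- mean(unlist(chains))
  expect_lt(abs(frac - 1e-3 / (1e-3 + 1 / 5)) / (1e-3 / (1e-3 + 1 / 5)),
            0.1)
  ## mean run length follows the geometric law
  runs <- unlist(lapply(chains, function(h) {
    r <- rle(h)
    r$lengths[r$values]
  }))
  expect_lt(abs(mean(runs) - 5) / 5, 0.1)
})

test_that("neutral simulations keep NS and S rates balanced", {
  st <- makeGenomeFixture(300, 400, seed = 9)
  cfg <- simConfig(nSamples = 2000, seed = 10, hotspotFreq = 0)
  sim <- simulateCounts(st, cfg)
  s <- siteData(st)
  nsRate <- sum(sim$counts[s$impact == "NS"]) / sum(s$impact == "NS")
  sRate <- sum(sim$counts[s$impact == "S"]) / sum(s$impact == "S")
  expect_lt(abs(nsRate / sRate - 1), 0.1)
  ## overdispersion sanity: per-gene totals have variance above the mean
  tot <- tapply(sim$counts, s$gene_id, sum)
  expect_gt(var(tot), mean(tot))
})

test_that("driver selection multiplies NS rates by the configured factor", {
  st <- makeGenomeFixture(400, 800, seed = 11)
  genes <- geneIds(st)
  roles <- rep("TSG", 200)
  names(roles) <- genes[1:200]
  beta0 <- list(TSG = c(LoF = 0, CONS = 0, SiFT = 0, PhyloP = 0, MA = 0),
                OG = c(LoF = 0, CONS = 0, SiFT = 0, PhyloP = 0, MA = 0))
  ## flat gene effects and covariates isolate the selection multiplier
  cfg <- simConfig(nSamples = 3000, roles = roles, seed = 12,
                   hotspotFreq = 0, siteNoiseSd = 0, fnEffects = beta0,
                   bgModel = "ninetype", nbDispersion = 1e8,
                   bgEffects = c(expr = 0, reptime = 0))
  sim <- simulateCounts(st, cfg)
  s <- siteData(st)
  isNS <- s$impact == "NS"
  drv <- s$gene_id %in% genes[1:200]
  ratio <- (sum(sim$counts[isNS & drv]) / sum(isNS & drv)) /
    (sum(sim$counts[isNS & !drv]) / sum(isNS & !drv))
  expect_lt(abs(ratio - 3) / 3, 0.1)
  ## synonymous sites stay untouched by selection
  sRatio <- (sum(sim$counts[!isNS & drv]) / sum(!isNS & drv)) /
    (sum(sim$counts[!isNS & !drv]) / sum(!isNS & !drv))
  expect_lt(abs(sRatio - 1), 0.15)
  ## and the truth bookkeeping aligns with the emitted counts
  expect_equal(length(sim$truth$multiplier), nSites(st))
  expect_true(all(sim$truth$multiplier[!isNS] == 1))
  expect_equal(nrow(sim$records), sum(sim$counts))
})

test_that("simulations are bit-reproducible under a fixed seed", {
  st <- makeGenomeFixture(30, 200, seed = 13)
  cfg <- simConfig(seed = 14)
  s1 <- simulateCounts(st, cfg)
  s2 <- simulateCounts(st, cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$records, s2$records)
  s3 <- simulateCounts(st, simConfig(seed = 15))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("the dN/dS statistic follows its closed form", {
  ## zero observed mutations give the smallest possible statistic
  t0 <- dndsTest(0, 2, gammaAlt = 3, nullDraws = 500L)
  expect_equal(t0$statistic, -4)
  expect_gt(t0$p.value, 0.9)
  ## monotone in the observed count
  stats <- vapply(0:10, function(y) dndsTest(y, 2, 3, 100L)$statistic,
                  numeric(1))
  expect_true(all(diff(stats) > 0))
  ## calibration under its own null (count regime where the discrete
  ## statistic attains levels near 0.05)
  set.seed(16)
  mu <- 20
  nullStats <- -mu * 2 + rpois(5000, mu) * log(3)
  rej <- mean(vapply(rpois(1000, mu), function(y) {
    dndsTest(y, mu, 3, nullDraws = nullStats)$p.value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("the clustering statistic counts sliding windows", {
  sites <- 1:100
  rates <- rep(0.01, 100)
  tight <- clusterTest(c(10, 11, 12), sites, rates, nullDraws = 200L)
  spread <- clusterTest(c(10, 50, 90), sites, rates, nullDraws = 200L)
  expect_equal(tight$statistic / spread$statistic, 3)
  single <- clusterTest(55, sites, rates, nullDraws = 200L)
  expect_equal(single$statistic, 1 / sum(rates))
  expect_error(clusterTest(1, sites, rep(0, 100)), "rate")
  ## calibration under the null, in a count regime where the statistic is
  ## not overly discrete
  ## the max-window statistic is discrete; its attainable levels depend on
  ## the count regime, and this one admits a level near 0.05
  set.seed(17)
  bigSites <- 1:200
  bigRates <- rep(0.1, 200)
  drawStat <- function() {
    n <- rpois(1, sum(bigRates))
    p <- if (n > 0) sample(bigSites, n, replace = TRUE) else integer(0)
    clusterTest(p, bigSites, bigRates, nullDraws = 1L)$statistic
  }
  nullRef <- vapply(1:4000, function(i) drawStat(), numeric(1))
  pvals <- vapply(1:4000, function(i) {
    (1 + sum(nullRef >= drawStat())) / (length(nullRef) + 1)
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Fisher combination matches the chi-squared reference", {
  expect_equal(fisherCombine(1, 1), 1)
  expect_equal(fisherCombine(0.3, 0.7), fisherCombine(0.7, 0.3))
  ## combining with an uninformative p-value cannot sharpen a small one
  for (p in c(0.001, 0.01, 0.05, 0.2)) {
    expect_gte(fisherCombine(p, 1), p)
  }
  expect_equal(fisherCombine(0.05, 0.1),
               pchisq(-2 * (log(0.05) + log(0.1)), 4, lower.tail = FALSE))
  expect_error(fisherCombine(0, 0.5), "0, 1")
})

test_that("benchmarking scores callers against simulation truth", {
  roles <- c(rep("TSG", 20), rep("neutral", 180))
  names(roles) <- sprintf("g%03d", 1:200)
  ## perfect caller
  perfect <- data.frame(gene_id = names(roles),
                        called = roles != "neutral",
                        log10_bf = ifelse(roles != "neutral", 5, -5))
  b <- runBenchmark(roles, perfect)
  expect_equal(b$auroc, 1)
  expect_equal(b$fdp, 0)
  expect_equal(b$tp, 20)
  ## random scores hover at chance level
  set.seed(18)
  aurocs <- vapply(1:30, function(i) {
    rnd <- data.frame(gene_id = names(roles), called = FALSE,
                      log10_bf = rnorm(200))
    runBenchmark(roles, rnd)$auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
  ## training-gene exclusion never invents genes
  b2 <- runBenchmark(roles, perfect, trainGenes = names(roles)[1:10])
  expect_equal(b2$tp, 10)
  expect_true(all(b2$roc$threshold %in% perfect$log10_bf))
})

test_that("simulation outputs round-trip to disk", {
  st <- makeGenomeFixture(10, 120, seed = 19)
  roles <- c(g0001 = "TSG")
  cfg <- simConfig(roles = roles, seed = 20)
  sim <- simulateCounts(st, cfg)
  dir <- file.path(tempdir(), "simout")
  writeSimulation(st, sim, cfg, dir)
  expect_true(file.exists(file.path(dir, "sites.tsv")))
  back <- readSiteTable(file.path(dir, "sites.tsv"))
  expect_equal(siteData(back)$pos, siteData(st)$pos)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nSites(st))
  muts <- read.delim(file.path(dir, "mutations.tsv"))
  expect_equal(nrow(muts), sum(sim$counts))
})
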