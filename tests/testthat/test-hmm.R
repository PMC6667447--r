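test_that("spatial likelihood collapses to the non-spatial one at the limits", {
  inst <- randomHmmInstance(8, seed = 41)
  base <- nsConditionalLoglik(inst$counts, inst$effRates,
                              rep(1, length(inst$counts)),
                              list(a = inst$a, b = inst$b))
  for (hm in list(HMMParams(1e-4, 5, 1, "OG"),
                  HMMParams(0, 5, 50, "OG"))) {
    ll <- hmmMarginalLoglik(inst$counts, inst$effRates, inst$positions,
                            list(a = inst$a, b = inst$b), hm)
    expect_equal(ll, base, tolerance = 1e-10)
  }
  noHot <- HMMParams(1e-4, 5, 50, "OG", noHotspot = TRUE)
  expect_equal(hmmMarginalLoglik(inst$counts, inst$effRates,
                                 inst$positions,
                                 list(a = inst$a, b = inst$b), noHot),
               base, tolerance = 1e-12)
})

test_that("forward recursion matches exhaustive path enumeration", {
  for (nPos in c(1, 2, 3, 5, 8, 12)) {
    for (s in 1:4) {
      inst <- randomHmmInstance(nPos, seed = 100 * nPos + s)
      hm <- HMMParams(qEnter = 10^runif(1, -4, -1),
                      meanLen = runif(1, 2, 8),
                      rho = 10^runif(1, 0.3, 2.5), "OG")
      ll <- hmmMarginalLoglik(inst$counts, inst$effRates, inst$positions,
                              list(a = inst$a, b = inst$b), hm,
                              nNodes = 64L)
      oracle <- enumHmmLoglik(inst$counts, inst$effRates, inst$positions,
                              inst$a, inst$b, hm@qEnter, hm@meanLen,
                              hm@rho)
      expect_equal(ll, oracle, tolerance = 1e-8)
    }
  }
})

test_that("spatial likelihood validates its inputs", {
  inst <- randomHmmInstance(4, seed = 51)
  hm <- HMMParams(1e-3, 5, 100, "OG")
  expect_error(hmmMarginalLoglik(inst$counts, inst$effRates,
                                 rev(inst$positions),
                                 list(a = 1, b = 1), hm), "sorted")
  expect_error(HMMParams(1e-3, 5, -2, "OG"), "rho")
})

test_that("one-position genes match the two-term hand computation", {
  ## single position: P = piB * PG(r) + piH * PG(r * rho), both closed form
  y <- c(2, 0, 1)
  r <- c(0.02, 0.01, 0.015)
  a <- 3; b <- 4; q <- 1e-3; L <- 5; rho <- 40
  hm <- HMMParams(q, L, rho, "TSG")
  piH <- q / (q + 1 / L)
  pg <- function(rr) {
    sum(y * log(rr)) - sum(lgamma(y + 1)) + a * log(b) - lgamma(a) +
      lgamma(a + sum(y)) - (a + sum(y)) * log(b + sum(rr))
  }
  hand <- log((1 - piH) * exp(pg(r)) + piH * exp(pg(r * rho)))
  ll <- hmmMarginalLoglik(y, r, rep(5L, 3), list(a = a, b = b), hm,
                          nNodes = 32L)
  expect_equal(ll, hand, tolerance = 1e-6)
})

test_that("hotspot decoding is a proper posterior", {
  inst <- randomHmmInstance(10, seed = 61)
  hm <- HMMParams(1e-3, 5, 80, "OG")
  tr <- hotspotPosterior(inst$counts, inst$effRates, inst$positions,
                         list(a = inst$a, b = inst$b), hm)
  expect_true(all(tr$posterior >= 0 & tr$posterior <= 1))
  ## with rho = 1 the data are uninformative: the track sits at the
  ## stationary hotspot fraction everywhere
  hm1 <- HMMParams(1e-3, 5, 1, "OG")
  tr1 <- hotspotPosterior(inst$counts, inst$effRates, inst$positions,
                          list(a = inst$a, b = inst$b), hm1)
  piH <- 1e-3 / (1e-3 + 1 / 5)
  expect_equal(tr1$posterior, rep(piH, nrow(tr1)), tolerance = 1e-10)
  ## no-hotspot fits yield an all-zero track with a warning
  hm0 <- HMMParams(0, 5, 1, "OG", noHotspot = TRUE)
  expect_warning(tr0 <- hotspotPosterior(inst$counts, inst$effRates,
                                         inst$positions,
                                         list(a = 1, b = 1), hm0),
                 "all-zero")
  expect_true(all(tr0$posterior == 0))
})

test_that("decoding concentrates on true hotspots in simulation", {
  wins <- 0L
  for (r in 1:10) {
    set.seed(70 + r)
    nPos <- 120L
    hot <- rep(FALSE, nPos)
    start <- sample(20:90, 1)
    hot[start:(start + 4)] <- TRUE
    eff <- rep(rep(0.002, nPos), each = 3)
    rho <- 400
    lam <- rgamma(1, 10, 10)
    y <- rpois(3 * nPos, eff * lam * ifelse(rep(hot, each = 3), rho, 1))
    hm <- HMMParams(1e-3, 5, rho, "OG")
    tr <- hotspotPosterior(y, eff, rep(seq_len(nPos), each = 3),
                           list(a = 10, b = 10), hm)
    if (mean(tr$posterior[hot]) > mean(tr$posterior[!hot]))
      wins <- wins + 1L
  }
  expect_gte(wins, 10L)
})

test_that("fitting flags the no-hotspot boundary on spatially flat data", {
  d <- sharedSimulation()
  ## neutral genes carry no spatial signal
  neutral <- d$genes[31:60]
  bmm <- suppressWarnings(fitBMM(d$sites, d$sim$counts))
  h0 <- suppressWarnings(
    fitSMM(d$sites, d$sim$counts, bmm, neutral, "H0"))
  fitFlat <- suppressWarnings(
    fitHMM(d$sites, d$sim$counts, bmm, h0, neutral, "OG"))
  expect_true(fitFlat@noHotspot)

  ## a single training gene with zero NS mutations is flat in rho
  empty <- d$genes[which.max(vapply(d$genes, function(g) {
    sel <- siteData(d$sites)$gene_id == g
    -sum(d$sim$counts[sel & siteData(d$sites)$impact == "NS"])
  }, numeric(1)))]
  fit1 <- suppressWarnings(
    fitHMM(d$sites, d$sim$counts, bmm, h0, empty, "OG"))
  expect_true(fit1@noHotspot)
})

test_that("fitting recovers strong hotspot intensity", {
  ## concentrated spatial signal across a handful of genes
  hits <- 0L
  nRep <- 6L
  rhoTrue <- 50
  for (r in seq_len(nRep)) {
    set.seed(80 + r)
    nGene <- 30L; nPos <- 150L
    rows <- list(); counts <- integer(0)
    for (g in seq_len(nGene)) {
      hot <- driverBayes:::simulateChain(nPos, 5e-3, 1 / 5)
      eff <- rep(0.003, 3 * nPos)
      y <- rpois(3 * nPos, eff * ifelse(rep(hot, each = 3), rhoTrue, 1))
      rows[[g]] <- data.frame(
        gene_id = sprintf("h%02d", g), chrom = "chr1",
        pos = rep(seq_len(nPos) + (g - 1) * (nPos + 10), each = 3),
        ref = "C", alt = rep(c("A", "G", "T"), nPos),
        context5 = "A", context3 = "T", stringsAsFactors = FALSE)
      counts <- c(counts, y)
    }
    s <- do.call(rbind, rows)
    s$mutation_type <- classifyMutationType(s$ref, s$alt, s$context5,
                                            s$context3)
    s$impact <- "NS"
    ## add a synonymous block so the posterior machinery has S rows
    sSyn <- s[s$gene_id == "h01", ][1:30, ]
    sSyn$pos <- sSyn$pos + 1e6
    sSyn$impact <- "S"
    s <- rbind(s, sSyn)
    counts <- c(counts, rpois(30, 0.003))
    st <- SiteTable(s)
    bmm <- BMMParams(beta0 = rep(log(0.001), 9), alpha = 50)
    ## use the known background rate scale directly
    bmm@beta0[] <- log(0.003)
    smm <- SMMParams("OG")
    fit <- suppressWarnings(
      fitHMM(st, counts, bmm, smm, unique(s$gene_id), "OG"))
    if (!fit@noHotspot && fit@rho > rhoTrue / 2 && fit@rho < rhoTrue * 2)
      hits <- hits + 1L
  }
  expect_gte(hits, nRep - 2L)
})

test_that("the spatial model selection test behaves like a chi-squared LRT", {
  eq <- spatialModelTest(-100, -100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  t1 <- spatialModelTest(-95, -100, df = 3)
  expect_equal(t1$statistic, 10)
  expect_equal(t1$p.value, pchisq(10, 3, lower.tail = FALSE))
  expect_error(spatialModelTest(-101, -100), "below")
})

test_that("hotspot tracks are written as BED intervals plus a TSV", {
  tr <- data.frame(pos = c(5L, 6L, 7L, 20L), posterior = c(0.9, 0.95, 0.2, 0.7))
  tsv <- tempfile(fileext = ".tsv")
  bed <- tempfile(fileext = ".bed")
  writeHotspotTrack(tr, "chr1", tsv, bed)
  full <- read.delim(tsv)
  expect_equal(nrow(full), 4L)
  b <- read.delim(bed, header = FALSE)
  expect_equal(nrow(b), 2L)     # run 5-6 and singleton 20
  expect_equal(b$V2[1], 4L)     # 0-based start
  expect_equal(b$V3[1], 6L)     # half-open end
  expect_true(all(b$V5 <= 1000))
})

test_that("fitted hotspot models round-trip through their file format", {
  hl <- list(OG = HMMParams(1e-4, 5.2, 123.4, "OG"),
             TSG = HMMParams(0, 5, 1, "TSG", noHotspot = TRUE))
  path <- tempfile(fileext = ".yaml")
  writeHMM(hl, path)
  back <- readHMM(path)
  expect_equal(back$OG@rho, 123.4)
  expect_true(back$TSG@noHotspot)
})
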