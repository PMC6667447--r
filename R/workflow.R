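## End-to-end orchestration: sequential estimation (background model on
## synonymous data, then selection models with the background frozen, then
## hotspot HMMs, then gene scoring), plus the simulation study harness.

#' Run the full driver-gene analysis
#'
#' Executes the sequential estimation workflow: fit the background model on
#' synonymous counts from all genes; with it frozen, fit the selection
#' model for the null (all genes outside both training lists), oncogene and
#' tumor-suppressor hypotheses; optionally fit the hotspot HMM for the two
#' driver hypotheses; then score every gene by Bayes factor and call at the
#' Bayesian FDR threshold.
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param mutations either an integer count vector aligned with the site
#'   rows, or a data.frame of mutation records (aggregated internally).
#' @param ogList,tsgList training gene ids for the oncogene and
#'   tumor-suppressor models.
#' @param useFeatures FALSE drops all functional features (intercept-only
#'   selection models, the "basic" dN/dS-like variant).
#' @param useHMM FALSE disables the spatial model ("+ feature" variant).
#' @param featureSubset optional character vector restricting the
#'   functional features used.
#' @param poolDriverModels fit a single driver model on the pooled training
#'   lists and use it for both hypotheses.
#' @param pi driver fraction (estimated when NULL).
#' @param fdrThreshold Bayesian FDR calling cutoff.
#' @param nNodes quadrature nodes for the spatial likelihood.
#' @return list with \code{bmm}, \code{smm}, \code{hmm}, \code{results}
#'   (from \code{\link{scoreGenes}}) and \code{pi}.
#' @export
runFullAnalysis <- function(sites, mutations, ogList, tsgList,
                            useFeatures = TRUE, useHMM = TRUE,
                            featureSubset = NULL, poolDriverModels = FALSE,
                            pi = NULL, fdrThreshold = 0.1, nNodes = 16L) {
  counts <- if (is.data.frame(mutations)) {
    agg <- aggregateCounts(mutations, sites)
    if (nrow(agg$unmatched))
      warning(nrow(agg$unmatched), " record(s) did not match the site table")
    agg$counts
  } else {
    stopifnot(length(mutations) == nSites(sites))
    mutations
  }
  genes <- geneIds(sites)
  ogList <- intersect(ogList, genes)
  tsgList <- intersect(tsgList, genes)
  if (!length(ogList) || !length(tsgList))
    stop("both training lists must contain genes present in the site table")
  h0Genes <- setdiff(genes, union(ogList, tsgList))
  fs <- if (!useFeatures) character(0) else featureSubset

  bmm <- fitBMM(sites, counts)
  rates <- backgroundRate(sites, bmm)
  smm <- list(H0 = fitSMM(sites, counts, bmm, h0Genes, "H0",
                          featureSubset = fs, rates = rates))
  if (poolDriverModels) {
    pooled <- fitSMM(sites, counts, bmm, union(ogList, tsgList), "OG",
                     featureSubset = fs, rates = rates)
    smm$OG <- pooled
    smm$TSG <- SMMParams("TSG", beta0F = pooled@beta0F,
                         betaF = pooled@betaF, se = pooled@se,
                         convergence = pooled@convergence)
  } else {
    smm$OG <- fitSMM(sites, counts, bmm, ogList, "OG", featureSubset = fs,
                     rates = rates)
    smm$TSG <- fitSMM(sites, counts, bmm, tsgList, "TSG",
                      featureSubset = fs, rates = rates)
  }
  hmm <- NULL
  if (useHMM) {
    hmm <- list(OG = fitHMM(sites, counts, bmm, smm$OG, ogList, "OG",
                            nNodes = nNodes),
                TSG = fitHMM(sites, counts, bmm, smm$TSG, tsgList, "TSG",
                             nNodes = nNodes))
  }
  results <- scoreGenes(sites, counts, bmm, smm, hmm, pi = pi,
                        fdrThreshold = fdrThreshold, nNodes = nNodes,
                        rates = rates)
  list(bmm = bmm, smm = smm, hmm = hmm, results = results,
       pi = attr(results, "pi"))
}

#' Genome-wide simulation study with known truth
#'
#' Simulates an exome of \code{nGenes} genes with \code{nTSG + nOG} driver
#' genes, runs the full analysis with part of the drivers as training
#' lists, and benchmarks the calls against the simulation truth on test
#' genes (training genes excluded).
#'
#' @param nGenes,meanGeneLen fixture dimensions.
#' @param nTSG,nOG number of driver genes per class.
#' @param trainFraction fraction of each driver class used for training.
#' @param seed integer seed for fixture and counts.
#' @param featureSubset functional features given to the analysis (a
#'   deliberate subset of the five simulated ones, adding model
#'   misspecification).
#' @param useHMM passed to \code{\link{runFullAnalysis}}.
#' @param fdrThreshold Bayesian FDR cutoff.
#' @param ... further settings forwarded to \code{\link{simConfig}}
#'   (e.g. \code{nSamples}, \code{bgModel}, \code{siteNoiseSd}).
#' @return list with \code{benchmark} (from \code{\link{runBenchmark}}),
#'   \code{fit}, \code{truth}, \code{trainGenes} and the simulated inputs.
#' @export
runSimulationStudy <- function(nGenes = 2000L, meanGeneLen = 500,
                               nTSG = 18L, nOG = 12L,
                               trainFraction = 124 / 324, seed = 1L,
                               featureSubset = c("LoF", "CONS", "MA"),
                               useHMM = TRUE, fdrThreshold = 0.1, ...) {
  sites <- makeGenomeFixture(nGenes, meanGeneLen, seed = seed)
  genes <- geneIds(sites)
  set.seed(seed + 1L)
  drivers <- sample(genes, nTSG + nOG)
  roles <- c(rep("TSG", nTSG), rep("OG", nOG))
  names(roles) <- drivers
  config <- simConfig(roles = roles, seed = seed + 2L, ...)
  sim <- simulateCounts(sites, config)
  tsgTrain <- sample(drivers[roles == "TSG"],
                     max(2L, round(trainFraction * nTSG)))
  ogTrain <- sample(drivers[roles == "OG"],
                    max(2L, round(trainFraction * nOG)))
  fit <- runFullAnalysis(sites, sim$counts, ogList = ogTrain,
                         tsgList = tsgTrain, featureSubset = featureSubset,
                         useHMM = useHMM, fdrThreshold = fdrThreshold)
  bench <- runBenchmark(sim$truth$roles, fit$results,
                        trainGenes = c(ogTrain, tsgTrain))
  list(benchmark = bench, fit = fit, truth = sim$truth,
       trainGenes = c(ogTrain, tsgTrain), sites = sites, sim = sim,
       config = config)
}

#' Read and validate a run configuration file
#'
#' YAML mapping with input/output paths and model options; unknown keys
#' are rejected and referenced input files must exist.
#'
#' @param path YAML config path.
#' @return validated named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("sites", "mutations", "og_list", "tsg_list", "out_dir",
               "use_features", "use_hmm", "feature_subset",
               "pool_driver_models", "fdr_threshold", "hypermutator_max",
               "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in c("sites", "mutations", "og_list", "tsg_list")) {
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k)
    if (!file.exists(cfg[[k]])) stop("config file not found: ", cfg[[k]])
  }
  cfg$use_features <- cfg$use_features %||% TRUE
  cfg$use_hmm <- cfg$use_hmm %||% TRUE
  cfg$pool_driver_models <- cfg$pool_driver_models %||% FALSE
  cfg$fdr_threshold <- cfg$fdr_threshold %||% 0.1
  cfg$hypermutator_max <- cfg$hypermutator_max %||% "auto"
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg
}

#' Run a full analysis from a configuration file
#'
#' Loads the inputs named in the config, runs
#' \code{\link{runFullAnalysis}}, and writes the results table, fitted
#' model files and the sample report into the output directory.
#'
#' @param config path to a YAML config, or the list from
#'   \code{\link{readRunConfig}}.
#' @return the \code{\link{runFullAnalysis}} result, invisibly.
#' @export
runFromConfig <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  sites <- readSiteTable(config$sites)
  loaded <- loadMutations(config$mutations, config$hypermutator_max)
  ogList <- readLines(config$og_list)
  tsgList <- readLines(config$tsg_list)
  fit <- runFullAnalysis(sites, loaded$records, ogList, tsgList,
                         useFeatures = config$use_features,
                         useHMM = config$use_hmm,
                         featureSubset = config$feature_subset,
                         poolDriverModels = config$pool_driver_models,
                         fdrThreshold = config$fdr_threshold)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## run log: every option actually used, defaults filled in
  yaml::write_yaml(
    c(config,
      list(pi_estimate = fit$pi,
           n_genes = nrow(fit$results),
           n_called = sum(fit$results$called),
           hmm_no_hotspot = if (!is.null(fit$hmm))
             vapply(fit$hmm, function(h) h@noHotspot, logical(1)))),
    file.path(config$out_dir, "run_log.yaml"))
  writeResults(fit$results, file.path(config$out_dir, "results.tsv"))
  writeBMM(fit$bmm, file.path(config$out_dir, "bmm.yaml"))
  writeSMM(fit$smm, file.path(config$out_dir, "smm.yaml"))
  if (!is.null(fit$hmm))
    writeHMM(fit$hmm, file.path(config$out_dir, "hmm.yaml"))
  writeSampleReport(loaded$report,
                    file.path(config$out_dir, "samples.tsv"))
  invisible(fit)
}
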