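#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Site table of all possible coding mutations
#'
#' One row per possible single-nucleotide mutation: every sufficiently
#' sequenced coding position contributes exactly three rows, one per
#' alternate allele. Rows carry the mutation-type index (1-9), the
#' synonymous/non-synonymous impact label, position-level background
#' covariates (shared by the three alternate rows of a position) and
#' allele-level binary functional covariates.
#'
#' @slot sites data.frame with columns \code{gene_id, chrom, pos, ref, alt,
#'   mutation_type, impact, context5, context3}, ordered by gene, position,
#'   alternate allele.
#' @slot bgFeatures numeric matrix of background (mutational) covariates,
#'   one row per site row.
#' @slot fnFeatures numeric 0/1 matrix of functional covariates, one row per
#'   site row.
#' @export
setClass("SiteTable",
  representation(sites = "data.frame", bgFeatures = "matrix",
                 fnFeatures = "matrix"))

setValidity("SiteTable", function(object) {
  s <- object@sites
  need <- c("gene_id", "chrom", "pos", "ref", "alt", "mutation_type",
            "impact", "context5", "context3")
  miss <- setdiff(need, names(s))
  if (length(miss)) return(paste("missing site columns:",
                                 paste(miss, collapse = ", ")))
  n <- nrow(s)
  if (nrow(object@bgFeatures) != n) return("bgFeatures row count mismatch")
  if (nrow(object@fnFeatures) != n) return("fnFeatures row count mismatch")
  if (n == 0L) return(TRUE)
  if (!all(s$ref %in% DNA_BASES) || !all(s$alt %in% DNA_BASES))
    return("ref/alt must be single bases A/C/G/T")
  if (any(s$ref == s$alt)) return("ref must differ from alt")
  if (!all(s$impact %in% c("S", "NS"))) return("impact must be 'S' or 'NS'")
  if (!all(s$mutation_type %in% 1:9)) return("mutation_type must be in 1..9")
  key <- if (length(unique(s$chrom)) == 1L) s$pos
         else paste(s$chrom, s$pos)
  if (n %% 3L != 0L)
    return("every position must have exactly 3 alt rows")
  ord <- order(key)
  ks <- key[ord]
  i1 <- seq(1L, n, by = 3L)
  tripleOK <- all(ks[i1] == ks[i1 + 2L]) &&
    !anyDuplicated(ks[i1])
  if (!tripleOK) return("every position must have exactly 3 alt rows")
  fv <- object@fnFeatures
  if (length(fv) && !all(fv %in% c(0, 1)))
    return("functional features must be binary 0/1")
  if (ncol(object@bgFeatures)) {
    bg <- object@bgFeatures[ord, , drop = FALSE]
    same <- bg[i1, , drop = FALSE] == bg[i1 + 1L, , drop = FALSE] &
            bg[i1, , drop = FALSE] == bg[i1 + 2L, , drop = FALSE]
    if (!all(same))
      return("background features must be identical across a position's alts")
  }
  TRUE
})

#' @describeIn SiteTable-class constructor
#' @param sites,bgFeatures,fnFeatures see slots.
#' @export
SiteTable <- function(sites, bgFeatures = NULL, fnFeatures = NULL) {
  n <- nrow(sites)
  if (is.null(bgFeatures)) bgFeatures <- matrix(0, n, 0)
  if (is.null(fnFeatures)) fnFeatures <- matrix(0, n, 0)
  sites$pos <- as.integer(sites$pos)
  sites$mutation_type <- as.integer(sites$mutation_type)
  new("SiteTable", sites = as.data.frame(sites, stringsAsFactors = FALSE),
      bgFeatures = as.matrix(bgFeatures), fnFeatures = as.matrix(fnFeatures))
}

#' Background mutation model parameters
#'
#' Per-type log intercepts, background-covariate coefficients on the
#' standardized scale (standardization constants stored alongside), and the
#' Gamma(alpha, alpha) gene-effect shape.
#'
#' @slot beta0 numeric(9), per-mutation-type log baseline rate.
#' @slot betaBg named numeric, one coefficient per background feature.
#' @slot alpha positive scalar, Gamma shape/rate of gene effects.
#' @slot center,scale standardization constants applied to continuous
#'   background features before fitting.
#' @slot convergence list: optimizer report.
#' @export
setClass("BMMParams",
  representation(beta0 = "numeric", betaBg = "numeric", alpha = "numeric",
                 center = "numeric", scale = "numeric", convergence = "list"))

setValidity("BMMParams", function(object) {
  if (length(object@beta0) != 9L) return("beta0 must have length 9")
  if (!is.finite(object@alpha) || object@alpha <= 0)
    return("alpha must be > 0")
  if (any(!is.finite(object@beta0))) return("beta0 must be finite")
  if (length(object@center) != length(object@betaBg) ||
      length(object@scale) != length(object@betaBg))
    return("center/scale must align with betaBg")
  TRUE
})

#' @describeIn BMMParams-class constructor
#' @param beta0,betaBg,alpha,center,scale,convergence see slots.
#' @export
BMMParams <- function(beta0, betaBg = numeric(0), alpha = 1,
                      center = NULL, scale = NULL, convergence = list()) {
  p <- length(betaBg)
  if (is.null(center)) center <- rep(0, p)
  if (is.null(scale)) scale <- rep(1, p)
  names(center) <- names(scale) <- names(betaBg)
  new("BMMParams", beta0 = beta0, betaBg = betaBg, alpha = alpha,
      center = center, scale = scale, convergence = convergence)
}

#' Selection mutation model parameters for one hypothesis
#'
#' @slot hypothesis one of "H0", "OG", "TSG".
#' @slot beta0F intercept: average log increase of the non-synonymous rate.
#' @slot betaF named numeric, functional-feature coefficients.
#' @slot se standard errors for c(intercept, betaF) from the observed
#'   information (NA when the Hessian is singular).
#' @slot convergence list: optimizer report.
#' @export
setClass("SMMParams",
  representation(hypothesis = "character", beta0F = "numeric",
                 betaF = "numeric", se = "numeric", convergence = "list"))

setValidity("SMMParams", function(object) {
  if (!object@hypothesis %in% c("H0", "OG", "TSG"))
    return("hypothesis must be H0, OG or TSG")
  if (length(object@se) &&
      length(object@se) != length(object@betaF) + 1L)
    return("se must align with c(beta0F, betaF)")
  if (any(object@se < 0, na.rm = TRUE)) return("se must be >= 0")
  TRUE
})

#' @describeIn SMMParams-class constructor
#' @param hypothesis,beta0F,betaF,se,convergence see slots.
#' @export
SMMParams <- function(hypothesis, beta0F = 0, betaF = numeric(0),
                      se = numeric(0), convergence = list()) {
  new("SMMParams", hypothesis = hypothesis, beta0F = beta0F, betaF = betaF,
      se = se, convergence = convergence)
}

#' Hotspot hidden Markov model parameters
#'
#' Two-state chain over a gene's coding positions: background and hotspot.
#' Hotspot positions multiply non-synonymous rates by \code{rho}; the chain
#' enters hotspots with probability \code{qEnter} per step and leaves with
#' probability \code{1/meanLen}, and starts at its stationary distribution.
#'
#' @slot qEnter background-to-hotspot transition probability.
#' @slot meanLen expected hotspot length in positions (>= 1).
#' @slot rho hotspot intensity multiplier (> 0).
#' @slot hypothesis "OG" or "TSG".
#' @slot noHotspot TRUE when fitting found no spatial signal (boundary fit);
#'   the model then reduces to the non-spatial likelihood.
#' @slot convergence list: optimizer report.
#' @export
setClass("HMMParams",
  representation(qEnter = "numeric", meanLen = "numeric", rho = "numeric",
                 hypothesis = "character", noHotspot = "logical",
                 convergence = "list"))

setValidity("HMMParams", function(object) {
  if (object@qEnter < 0 || object@qEnter >= 1)
    return("qEnter must be in [0, 1)")
  if (object@meanLen < 1) return("meanLen must be >= 1")
  if (object@rho <= 0) return("rho must be > 0")
  if (!object@hypothesis %in% c("OG", "TSG"))
    return("hypothesis must be OG or TSG")
  TRUE
})

#' @describeIn HMMParams-class constructor
#' @param qEnter,meanLen,rho,hypothesis,noHotspot,convergence see slots.
#' @export
HMMParams <- function(qEnter, meanLen, rho, hypothesis = "OG",
                      noHotspot = FALSE, convergence = list()) {
  new("HMMParams", qEnter = qEnter, meanLen = meanLen, rho = rho,
      hypothesis = hypothesis, noHotspot = noHotspot,
      convergence = convergence)
}

#' Per-gene posterior of the gene-specific effect
#'
#' lambda_g | synonymous data ~ Gamma(a, b) with a = alpha + observed
#' synonymous count and b = alpha + expected synonymous count.
#'
#' @slot geneId character vector of gene ids.
#' @slot a,b posterior shape and rate, aligned with \code{geneId}.
#' @export
setClass("GenePosterior",
  representation(geneId = "character", a = "numeric", b = "numeric"))

setValidity("GenePosterior", function(object) {
  if (length(object@a) != length(object@geneId) ||
      length(object@b) != length(object@geneId))
    return("a, b must align with geneId")
  if (any(object@a <= 0) || any(object@b <= 0))
    return("posterior shape and rate must be > 0")
  TRUE
})

## -- accessors ---------------------------------------------------------------

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @describeIn SiteTable-class number of site rows
#' @param x a SiteTable
#' @export
setMethod("nSites", "SiteTable", function(x) nrow(x@sites))

#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))
#' @describeIn SiteTable-class the site data.frame
#' @export
setMethod("siteData", "SiteTable", function(x) x@sites)

#' @export
setGeneric("bgFeatures", function(x) standardGeneric("bgFeatures"))
#' @describeIn SiteTable-class background feature matrix
#' @export
setMethod("bgFeatures", "SiteTable", function(x) x@bgFeatures)

#' @export
setGeneric("fnFeatures", function(x) standardGeneric("fnFeatures"))
#' @describeIn SiteTable-class functional feature matrix
#' @export
setMethod("fnFeatures", "SiteTable", function(x) x@fnFeatures)

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @describeIn SiteTable-class unique gene ids, in table order
#' @export
setMethod("geneIds", "SiteTable", function(x) unique(x@sites$gene_id))

#' @describeIn SiteTable-class subset rows, keeping features aligned
#' @param i row index
#' @param j,drop,... ignored
#' @export
setMethod("[", "SiteTable", function(x, i, j, ..., drop = FALSE) {
  ## plain slot replacement: a row subset (e.g. the non-synonymous rows)
  ## need not satisfy the whole-table three-alts-per-position invariant
  x@sites <- x@sites[i, , drop = FALSE]
  x@bgFeatures <- x@bgFeatures[i, , drop = FALSE]
  x@fnFeatures <- x@fnFeatures[i, , drop = FALSE]
  x
})

#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @describeIn GenePosterior-class posterior mean a/b per gene
#' @param x a GenePosterior
#' @export
setMethod("posteriorMean", "GenePosterior", function(x) {
  structure(x@a / x@b, names = x@geneId)
})

#' @export
setGeneric("hypothesis", function(x) standardGeneric("hypothesis"))
#' @describeIn SMMParams-class hypothesis label
#' @param x an SMMParams or HMMParams
#' @export
setMethod("hypothesis", "SMMParams", function(x) x@hypothesis)
#' @describeIn HMMParams-class hypothesis label
#' @export
setMethod("hypothesis", "HMMParams", function(x) x@hypothesis)

## -- show methods ------------------------------------------------------------

setMethod("show", "SiteTable", function(object) {
  s <- object@sites
  cat("SiteTable:", nrow(s), "possible mutations at",
      nrow(s) %/% 3L, "positions in", length(unique(s$gene_id)),
      "genes\n")
  cat("  impact: ", sum(s$impact == "S"), " S / ",
      sum(s$impact == "NS"), " NS\n", sep = "")
  cat("  background features:",
      paste(colnames(object@bgFeatures), collapse = ", "), "\n")
  cat("  functional features:",
      paste(colnames(object@fnFeatures), collapse = ", "), "\n")
})

setMethod("show", "BMMParams", function(object) {
  cat("BMMParams (background mutation model)\n")
  cat("  alpha (gene-effect Gamma shape):", format(object@alpha, digits = 4),
      "\n")
  cat("  beta0 (per-type log rates):",
      paste(format(object@beta0, digits = 3), collapse = " "), "\n")
  if (length(object@betaBg)) {
    cat("  background coefficients:\n")
    print(round(object@betaBg, 4))
  }
})

setMethod("show", "SMMParams", function(object) {
  cat("SMMParams [", object@hypothesis, "]\n", sep = "")
  est <- c(intercept = object@beta0F, object@betaF)
  out <- data.frame(estimate = round(est, 4))
  if (length(object@se)) out$se <- round(object@se, 4)
  print(out)
})

setMethod("show", "HMMParams", function(object) {
  cat("HMMParams [", object@hypothesis, "]",
      if (object@noHotspot) " (no-hotspot boundary fit)", "\n", sep = "")
  cat("  qEnter:", format(object@qEnter, digits = 4),
      " meanLen:", format(object@meanLen, digits = 4),
      " rho:", format(object@rho, digits = 4), "\n")
})

setMethod("show", "GenePosterior", function(object) {
  cat("GenePosterior for", length(object@geneId), "genes; mean range [",
      format(min(posteriorMean(object)), digits = 3), ",",
      format(max(posteriorMean(object)), digits = 3), "]\n")
})
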