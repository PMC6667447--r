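---
title: "Modeling positive selection on somatic mutations with driverBayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling positive selection on somatic mutations with driverBayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverBayes)
```

# The problem

Tumor cohorts accumulate somatic single-nucleotide mutations through a
heterogeneous background process; driver genes additionally experience
positive selection that enriches functional (non-synonymous) mutations
and sometimes clusters them into hotspots. driverBayes models
cohort-aggregated mutation counts at single-base resolution and classifies
each gene as a non-driver (H0), oncogene (OG) or tumor suppressor gene
(TSG) via Bayes factors, with Bayesian false-discovery-rate control over
the called set.

# The model

## Coordinates

All inference runs on a *site table*: one row per possible mutation, i.e.
every sufficiently covered coding position contributes three rows, one per
alternate allele. Each row carries a mutation-type index `t` in 1..9,
an impact label (S for synonymous, NS for non-synonymous, with
splice-disrupting synonymous changes expected to be pre-labeled NS by the
upstream annotation), position-level background covariates (expression,
replication timing, chromatin features; shared by the three alternate
rows) and allele-level binary functional covariates (loss-of-function,
conservation, and impact predictions). `Y_it` denotes the cohort-summed
count for row `(i, t)`.

The nine mutation types are pyrimidine-strand substitution classes with a
CpG split for the C reference: CpG C>T, C>T, CpG C>A, C>A, CpG C>G, C>G,
T>A, T>C, T>G (indices 1..9). The classification is strand-symmetric:
purine references are folded onto the pyrimidine strand by
reverse-complementing the substitution and swapping the complemented
flanks. This is one natural 9-way partition of substitution classes by
nucleotide change and CpG context; `classifyMutationType()` is a total
function on the 192 valid (ref, alt, flank, flank) tuples and is tested
exhaustively.

## Background mutation model (BMM)

For synonymous rows,

    Y_it | lambda_g ~ Poisson(mu_it * lambda_g)
    log mu_it = beta0_t + sum_j x_ij^b beta_j^b
    lambda_g ~ Gamma(alpha, alpha)

`mu_it` is the cohort-level background rate; `lambda_g` is a
gene-specific effect capturing residual rate variation (mean 1, variance
`1/alpha`). Integrating `lambda_g` out gives a closed-form
Poisson-Gamma (negative-multinomial) marginal per gene; the product over
genes is maximized over the nine intercepts, the background coefficients
and `log alpha` by L-BFGS-B with analytic gradients. Continuous background
covariates are z-scored internally (the transform is stored in the fitted
model) so coefficients are comparable across cohorts for the shrinkage
step; binary covariates are left untouched.

The conditional posterior of the gene effect given a gene's synonymous
data is `Gamma(alpha + y_S, alpha + mu_S)` with `y_S` and `mu_S` the
observed and expected synonymous counts; its mean exceeds 1 exactly when
the gene carries more synonymous mutations than its covariates predict.
`validateGeneEffects()` reproduces the cross-validation-style diagnostic:
the posterior-mean adjustment learned from synonymous data should improve
the prediction of non-synonymous counts, measured by R-squared against
the slope-1 diagonal.

## Selection mutation model (SMM)

For non-synonymous rows under hypothesis `m`,

    Y_it | lambda_g ~ Poisson(mu_it * lambda_g * gamma_it^m * theta_i^m)
    log gamma_it^m = beta0^{f,m} + sum_j x_ijt^f beta_j^{f,m}

The functional features are binary; the intercept captures the average
rate elevation of non-synonymous mutations under the hypothesis.
Estimation is sequential, mirroring the workflow: the BMM is fitted first
on synonymous data from all genes and then frozen; the SMM for OG (TSG)
is fitted on the non-synonymous counts of the OG (TSG) training list,
conditioning on each gene's synonymous data through the Gamma posterior
above; H0 is fitted on all genes outside both training lists. The spatial
effect is ignored (theta = 1) during this step: clustered mutations are
rare enough not to move the feature coefficients materially. Standard
errors come from the inverse numerical Hessian at the maximum.

Because the likelihood depends on the binary features only through
per-gene, per-feature-pattern sums, the fit collapses the row-level data
onto that grid, which makes the H0 fit (thousands of genes) cheap.

Per-cohort coefficient estimates can be stabilized across tumor types
with `shrinkAcrossTumors()`, an empirical-Bayes normal-means model:
raw ~ Normal(truth, se^2), truth ~ Normal(m, tau^2), with `(m, tau^2)`
estimated by (profile) marginal maximum likelihood and posterior means
shrinking noisy cohorts toward the cross-tumor mean. This is the
normal-normal special case of adaptive shrinkage; it reproduces the two
properties that matter here — shrinkage toward the mean, strongest for
cohorts with large standard errors — without the nonparametric mixture
prior machinery.

## Spatial hotspot model

A two-state hidden Markov chain (background/hotspot) runs along each
gene's coding positions in genomic order. The hotspot state multiplies
non-synonymous rates by an intensity `rho`; the chain enters hotspots
with probability `qEnter` per step, leaves with probability `1/meanLen`,
and starts from its stationary distribution. Only the driver hypotheses
carry a spatial model; H0 has theta = 1.

The gene effect couples all positions, so the marginal likelihood is
computed as

    P(Y) = P_nonspatial(Y) * E[H(lambda)]

where the expectation is over the full-data posterior of `lambda` at
rho = 1, namely `Gamma(a + Y_g, b + M_g)`, and `H` is a path-averaged
correction whose per-position hotspot factor is
`rho^{y_i} exp(-(rho - 1) R_i lambda)`. `H` is evaluated by a log-space
forward recursion (compiled code) at the nodes of a generalized
Gauss-Laguerre quadrature rule adapted to that Gamma posterior (16 nodes
by default). Two consequences are worth noting:

* at `rho = 1` or `qEnter = 0` the correction is exactly 1, so the
  spatial likelihood reduces to the non-spatial one at machine precision
  rather than up to quadrature error;
* the quadrature error affects only the correction factor, which is
  mild in realistic regimes; tests compare against exhaustive path
  enumeration on short genes and use more nodes (64-128) where extreme
  intensities are probed. A plug-in mode (single node at the posterior
  mean) is available for speed.

HMM parameters are fitted by maximizing the summed training-gene
likelihood over `(logit qEnter, log(meanLen - 1), log rho)` from a coarse
grid (`q` in {1e-5, 1e-4}, length in {3, 5, 10}, `rho` in
{10, 100, 1000}) followed by Nelder-Mead, because the surface is
multi-modal. When twice the likelihood gain over the non-spatial model
falls below the 95th percentile of chi-squared with 3 degrees of freedom
— the gain one can expect from optimizing three parameters against noise
— the fit returns a boundary model with the *no-hotspot* flag, and all
downstream spatial likelihoods reduce to the non-spatial form. The
`spatialModelTest()` statistic `2 * (loglik_HMM - loglik_noHMM)` is
referred to chi-squared with df = 3 (configurable); since the null pins
parameters to a boundary, the reference is conservative.

## Gene classification

For each gene,

    BF_g = [0.5 P(Y_NS | Y_S, OG) + 0.5 P(Y_NS | Y_S, TSG)]
           / P(Y_NS | Y_S, H0)

assembled in log space. The synonymous marginal is hypothesis-independent
and cancels, which the tests verify as an identity. The equal weights
encode the assumption that OGs and TSGs are a priori equally common. The
driver fraction `pi` is estimated by maximizing
`sum_g log(pi BF_g + 1 - pi)`; posterior driver probabilities are
`pi BF / (pi BF + 1 - pi)`; genes are ranked by Bayes factor (ties broken
by gene id for reproducibility) and the q-value at rank k is the running
mean of `1 - pp` over the top k. The called set is the largest prefix
with q-value at or below the threshold (0.1 by default). The OG-vs-TSG
label is reported as the larger component likelihood but should be read
as advisory: the two driver models differ mainly in the sign of the
loss-of-function coefficient, and the label inherits the noise of that
contrast. Genes with no non-synonymous opportunity get BF = 1. Genes
absent from the mutation file but present in the site table are scored
on all-zero counts, which is informative evidence *against* selection
under driver models with positive intercepts.

`leaveOneGeneOut()` guards evaluation of training genes: the affected
driver model (and its HMM) is refitted with the target gene removed, and
the target's significance is taken from that run.

# The simulator

`makeGenomeFixture()` builds a synthetic exome: gene lengths drawn from a
Gamma distribution around a target mean, a random reference sequence
supplying trinucleotide contexts, an approximately 3:1 NS:S opportunity
ratio (typical of coding sequence), gene-level expression and
replication-timing covariates, and binary functional features with fixed
marginal frequencies (loss-of-function 5% of NS rows, the others 25%).

`simulateCounts()` generates counts by the *generating* model of the
benchmark, which deliberately differs from the inference model:

* background rates vary over all 192 trinucleotide contexts (log-normal
  spread, sd 0.5, around the nine class means) while inference uses only
  the nine classes — model misspecification by design;
* gene-level Gamma effects (`nbDispersion`, default 10) make the
  marginal background counts negative binomial with variance/mean near
  1.5 at typical per-gene totals;
* hotspots follow the two-state Markov chain with entry frequency 1e-5
  per bp and mean length 5 bp;
* driver genes multiply non-synonymous rates by 3 outside and 3000
  inside hotspots, times centered functional-feature effects
  (loss-of-function enriched in TSGs, depleted in OGs) and per-row
  log-normal noise with sd 0.2 on the log selection strength;
* synonymous sites never see selection;
* aggregate counts are carved into per-sample records uniformly.

The default burden (500 samples at 5e-6 per alternate allele per sample,
about 15 SNVs/Mb per sample) emulates a high-mutation-burden squamous
cohort, the setting the genome-wide benchmark is parameterized after;
with the scaled-down 500 bp genes used in the benchmark this preserves a
realistic per-gene information content of roughly 2-4 mutations per gene
per cohort. The benchmark passes only three of the five simulated
functional features (LoF, CONS, MA) to the analysis, adding a second
layer of misspecification.

What the generator does **not** emulate: per-sample mutational signature
mixtures (smoking, APOBEC), copy-number and coverage variation,
annotation errors in the S/NS labels, and correlated functional features.
Passing tests therefore demonstrate internal correctness and calibration
under realistic *rate* heterogeneity, not robustness to every artifact of
real cohorts.

# Problem sizes and numerical choices

* The genome-wide calibration study runs 2,000 genes of mean length 500
  bp with 30 drivers (18 TSG, 12 OG), training on a 124/324-style
  fraction of the drivers (7 TSG + 5 OG) and calling at Bayesian FDR 0.1
  with training genes excluded, pooled over 10 seeds. The realized
  false-discovery proportion is compared to the nominal level plus a
  one-sided binomial tolerance at the realized call count.
* Optimizers: L-BFGS-B with analytic gradients, `factr = 1e7`
  (relative tolerance near 1e-9), max 500 iterations; intercepts of
  mutation types with no observed synonymous mutations are clamped at
  -30 with a warning. Additive constants are kept out of the optimized
  objective to preserve line-search precision; a Nelder-Mead polish
  backs up the rare line-search abort on flat plateaus. The convergence
  report stores the monotone trace of accepted improvements.
* Quadrature: 16 Gauss-Laguerre nodes by default for the spatial
  likelihood; the rule is exact for the non-spatial limits by
  construction.
* The single-gene power study uses a 1,500 bp gene, cohort sizes
  {100, 300, 1000}, 500 replicates and 5,000 null data sets; the dN/dS
  statistic fixes gamma = 3 (the simulated truth) and the clustering
  statistic uses 3 bp windows, combined by Fisher's method (chi-squared,
  4 df). Empirical p-values use the (1 + r) / (N + 1) correction. Both
  statistics are discrete, so an empirical-p test rejects at its largest
  attainable level below the nominal 0.05. For the dN/dS statistic (a sum
  of many counts, nearly continuous) the realized type-I error pooled
  over 1,000 heterogeneous null genes sits near 0.05; for the clustering
  statistic (an extreme-value count) the attainable levels are coarse and
  the realized type-I error is typically 0.01-0.02 — valid but
  conservative. This conservatism is a property of the max-window test
  itself, and it is one reason the Fisher-combined test loses power
  relative to dN/dS alone.
* Hypermutator filtering: "auto" drops samples whose log1p mutation
  count exceeds the cohort mean by three standard deviations; an
  absolute threshold can be supplied instead. The filter is reported
  per sample and is idempotent.

# Limitations

* The OG/TSG categorization is advisory (see above).
* The driver-fraction estimate `pi` treats the fitted Bayes factors as
  exact likelihood ratios; with very small training lists the driver
  models are noisy and calibration of the FDR degrades. The benchmark's
  burden was chosen so that the per-gene synonymous information keeps
  the gene-effect dispersion `alpha` well identified; cohorts with very
  sparse synonymous counts are outside the comfortable operating regime.
* The spatial model treats coding positions as a homogeneous chain and
  ignores codon structure and 3D proximity.
* Cross-tumor shrinkage implements the normal-normal empirical-Bayes
  model, not the full nonparametric unimodal prior.
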