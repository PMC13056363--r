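## Generative fixtures: PCP datasets sampled exactly from the
## mutation-selection model with planted parameters. Children are drawn
## per site from the same Eq.-1 codon likelihood table the likelihood
## code evaluates, so the simulator's recorded sampling log-probability
## equals the model log-likelihood at the planted parameters bit for bit.

#' PlantedTruth: everything needed to recompute sampling probabilities
#'
#' @slot neutral A [NeutralModel-class] (k-mer table, multihit, chain
#'   rates).
#' @slot factors The planted [SelectionFactorMatrix-class] on the
#'   germline.
#' @slot germline Germline nucleotide sequence.
#' @slot branchLengths Planted per-PCP branch lengths.
#' @slot seed Master seed of the simulation.
#' @export
setClass("PlantedTruth", representation(
  neutral = "NeutralModel", factors = "SelectionFactorMatrix",
  germline = "character", branchLengths = "numeric", seed = "integer"))

setMethod("show", "PlantedTruth", function(object) {
  cat(sprintf("PlantedTruth: %d-codon germline, %d branch lengths, seed %d\n",
              nchar(object@germline) %/% 3L, length(object@branchLengths),
              object@seed))
})

#' Generate a random germline nucleotide sequence
#'
#' Uniform over the 61 sense codons (no stop codons), reproducible.
#'
#' @param nCodons Number of codons (>= 1).
#' @param seed Integer seed.
#' @return Nucleotide sequence string of length `3 * nCodons`.
#' @export
generateGermline <- function(nCodons, seed = 1L) {
  stopifnot(nCodons >= 1L)
  withSeed(seed, function()
    codonString(sample(SENSE_CODONS, nCodons, replace = TRUE)))
}

#' Sample a planted selection landscape
#'
#' Each non-wild-type (site, amino-acid) entry is independently neutral
#' (factor 1), deleterious (log-uniform in `deleteriousRange`) or
#' beneficial (log-uniform in `beneficialRange`) with the given
#' fractions; wild-type entries are 1 by the gauge.
#'
#' @param refAa Reference amino-acid sequence the landscape is planted
#'   on (wild-type gauge).
#' @param fracNeutral,fracDeleterious,fracBeneficial Mixture fractions
#'   (must sum to 1; defaults 0.5 / 0.35 / 0.15).
#' @param deleteriousRange,beneficialRange Factor ranges (defaults
#'   `c(0.02, 0.5)` and `c(1.5, 4)`).
#' @param seed Integer seed.
#' @return A [SelectionFactorMatrix-class].
#' @export
sampleSelectionLandscape <- function(refAa, fracNeutral = 0.5,
                                     fracDeleterious = 0.35,
                                     fracBeneficial = 0.15,
                                     deleteriousRange = c(0.02, 0.5),
                                     beneficialRange = c(1.5, 4),
                                     seed = 1L) {
  fr <- c(fracNeutral, fracDeleterious, fracBeneficial)
  if (abs(sum(fr) - 1) > 1e-9 || any(fr < 0))
    stop("category fractions must be nonnegative and sum to 1")
  wt <- strsplit(refAa, "")[[1]]
  L <- length(wt)
  withSeed(seed, function() {
    cat_ <- matrix(sample.int(3L, L * 20L, replace = TRUE, prob = fr),
                   L, 20L)
    f <- matrix(1, L, 20L)
    del <- cat_ == 2L
    f[del] <- exp(stats::runif(sum(del), log(deleteriousRange[1]),
                               log(deleteriousRange[2])))
    ben <- cat_ == 3L
    f[ben] <- exp(stats::runif(sum(ben), log(beneficialRange[1]),
                               log(beneficialRange[2])))
    SelectionFactorMatrix(f, wt)
  })
}

#' Simulate one child sequence from the mutation-selection model
#'
#' Builds the Eq.-1 codon likelihood table from the planted neutral model
#' and selection factors at branch length `t` and samples each child
#' codon independently from its site's 64-way distribution (stop codons
#' have likelihood 0, so no stops arise). Masked (ambiguous) parent
#' codons are copied unchanged.
#'
#' @param parent Parent nucleotide sequence.
#' @param neutral A [NeutralModel-class].
#' @param factors A [SelectionFactorMatrix-class] on the parent.
#' @param t Branch length.
#' @param seed Integer seed.
#' @param chainLayout Chain layout string.
#' @param clampCeiling See [codonLikelihoods()].
#' @return List with `child` (nucleotide string) and `logProb`, the sum
#'   of log sampling probabilities actually used — identical to the PCP
#'   log-likelihood at the planted parameters.
#' @export
simulatePcp <- function(parent, neutral, factors, t, seed = 1L,
                        chainLayout = "", clampCeiling = 1 - 1e-6) {
  stopifnot(t >= 0)
  parentIdx <- codonIndices(parent)
  P <- recordNeutralTable(neutral, parent, chainLayout, t)
  ell <- codonLikelihoods(P, factors, parentIdx, clampCeiling)
  L <- length(parentIdx)
  childIdx <- parentIdx
  withSeed(seed, function() {
    for (j in seq_len(L)) {
      if (is.na(parentIdx[j])) next
      childIdx[j] <<- sample.int(64L, 1L, prob = ell[j, ])
    }
    NULL
  })
  ## same accumulation path as pcpLogLikelihood, so the recorded sampling
  ## log-probability matches the likelihood bit for bit
  ok <- which(!is.na(parentIdx))
  logProb <- sum(log(ell[cbind(ok, childIdx[ok])]))
  child <- codonString(childIdx)
  ## restore the parent's literal text at masked codons
  if (anyNA(parentIdx)) {
    pc <- substring(parent, 3 * (which(is.na(parentIdx)) - 1) + 1,
                    3 * which(is.na(parentIdx)))
    for (k in seq_along(pc))
      substr(child, 3L * (which(is.na(parentIdx))[k] - 1L) + 1L,
             3L * which(is.na(parentIdx))[k]) <- pc[k]
  }
  list(child = child, logProb = logProb)
}

#' Simulate a PCP dataset with planted truth
#'
#' Generates (or accepts) a germline, a planted selection landscape, a
#' k-mer rate table and multihit coefficients; draws per-PCP branch
#' lengths from a log-normal; samples children from the model; and
#' optionally writes the standard PCP CSV plus truth sidecar files.
#'
#' @param nPcps Number of parent-child pairs.
#' @param nCodons Germline length in codons (default 100).
#' @param tMedian,tSdlog Log-normal branch-length distribution (defaults
#'   0.03 and 0.5).
#' @param neutral Optional [NeutralModel-class]; default is a random
#'   5-mer table (mean rate 1) with no multihit correction.
#' @param factors Optional planted [SelectionFactorMatrix-class];
#'   default all-neutral (factors 1).
#' @param germline Optional germline nucleotide sequence.
#' @param seed Master seed; all draws derive from it.
#' @param outDir Optional directory for the PCP CSV and truth sidecars
#'   (`pcps.csv`, `truth_selection_factors.csv`,
#'   `truth_branch_lengths.csv`, `truth_kmer_table.csv`,
#'   `truth_multihit.json`).
#' @return List with `pcps` (a [PCPSet-class] carrying the planted
#'   branch lengths), `truth` (a [PlantedTruth-class]) and `logProbs`
#'   (per-PCP sampling log-probabilities).
#' @export
simulateDataset <- function(nPcps, nCodons = 100L, tMedian = 0.03,
                            tSdlog = 0.5, neutral = NULL, factors = NULL,
                            germline = NULL, seed = 1L, outDir = NULL) {
  seed <- as.integer(seed)
  if (is.null(germline)) germline <- generateGermline(nCodons, seed)
  nCodons <- nchar(germline) %/% 3L
  if (is.null(neutral))
    neutral <- neutralModel(randomKmerRateTable(5L, seed = seed + 1L))
  if (is.null(factors))
    factors <- SelectionFactorMatrix(matrix(1, nCodons, 20L),
                                     strsplit(translateNt(germline), "")[[1]])
  tvec <- if (nPcps > 0)
    withSeed(seed + 2L, function()
      stats::rlnorm(nPcps, log(tMedian), tSdlog)) else numeric(0)
  child <- character(nPcps); logProbs <- numeric(nPcps)
  for (i in seq_len(nPcps)) {
    sim <- simulatePcp(germline, neutral, factors, tvec[i],
                       seed = seed + 2L + i)
    child[i] <- sim$child
    logProbs[i] <- sim$logProb
  }
  pcps <- new("PCPSet", id = if (nPcps > 0) paste0("sim", seq_len(nPcps))
              else character(0),
              parent = rep(germline, nPcps), child = child,
              chainLayout = rep("", nPcps), branchLength = tvec)
  truth <- new("PlantedTruth", neutral = neutral, factors = factors,
               germline = germline, branchLengths = tvec, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePcpTable(pcps, file.path(outDir, "pcps.csv"))
    writeSelectionFactors(factors,
                          file.path(outDir, "truth_selection_factors.csv"))
    utils::write.csv(data.frame(id = pcpIds(pcps), t = tvec),
                     file.path(outDir, "truth_branch_lengths.csv"),
                     row.names = FALSE, quote = FALSE)
    writeKmerRateTable(neutral@table,
                       file.path(outDir, "truth_kmer_table.csv"))
    mh <- if (is.null(neutral@multihit)) c(1, 1, 1) else neutral@multihit@m
    jsonlite::write_json(list(m1 = mh[1], m2 = mh[2], m3 = mh[3],
                              light_rate_factor = neutral@lightRateFactor,
                              seed = seed),
                         file.path(outDir, "truth_multihit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pcps = pcps, truth = truth, logProbs = logProbs)
}
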