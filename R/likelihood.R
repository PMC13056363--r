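## The mutation-selection likelihood. For parent codon sequence X, child
## Y, branch length t and selection factors f, the per-site likelihood of
## codon c is p_{j,c}(t,X) * f_{j,aa(c)}(X-bar) for non-wild-type sense
## codons, 0 for stops, and the wild-type codon receives the residual
## 1 - sum(non-wild-type). When the non-wild-type sum exceeds a ceiling
## just below 1 (early in training), the non-wild-type entries are
## proportionally rescaled so that the sum equals the ceiling.

#' NeutralModel: the fixed neutral machinery bundle
#'
#' Packages the k-mer rate table, optional multihit coefficients and the
#' light-chain rate factor that together define the neutral codon
#' mutation process.
#'
#' @slot table A [KmerRateTable-class].
#' @slot multihit A [MultihitCoefficients-class] or `NULL`.
#' @slot lightRateFactor Positive scalar (default 0.63).
#' @export
setClass("NeutralModel", representation(
  table = "KmerRateTable", multihit = "ANY", lightRateFactor = "numeric"))

#' @rdname NeutralModel-class
#' @param table,multihit,lightRateFactor See slots.
#' @export
neutralModel <- function(table, multihit = NULL, lightRateFactor = 0.63) {
  stopifnot(lightRateFactor > 0)
  new("NeutralModel", table = table, multihit = multihit,
      lightRateFactor = lightRateFactor)
}

setMethod("show", "NeutralModel", function(object) {
  cat("NeutralModel:\n  "); show(object@table)
  if (!is.null(object@multihit)) { cat("  "); show(object@multihit) }
  cat(sprintf("  light-chain rate factor: %.3g\n", object@lightRateFactor))
})

## L x 64 neutral table for record i of a PCPSet at branch length t.
recordNeutralTable <- function(neutral, parent, chainLayout, t,
                               rates = NULL) {
  parentIdx <- codonIndices(parent)
  if (is.null(rates)) {
    rates <- siteRates(parent, neutral@table)
    rates <- applyChainRates(rates, parseChainLayout(chainLayout,
                                                     nchar(parent)),
                             neutral@lightRateFactor)
  }
  neutralTableFromRates(parentIdx, rates, t, neutral@multihit)
}

#' Combine neutral probabilities with selection factors (Eq.-1 table)
#'
#' @param neutralProbs `L x 64` neutral codon probability table (rows sum
#'   to 1; masked codons `NA`).
#' @param factors A [SelectionFactorMatrix-class] (or bare `L x 20`
#'   matrix) aligned to the same parent.
#' @param parent Parent nucleotide sequence or codon-index vector.
#' @param clampCeiling Upper bound, just below 1, on the summed
#'   non-wild-type likelihood per site (default `1 - 1e-6`).
#' @return `L x 64` matrix: stop entries 0, each row summing to 1, the
#'   wild-type entry carrying the residual mass.
#' @export
codonLikelihoods <- function(neutralProbs, factors, parent,
                             clampCeiling = 1 - 1e-6) {
  if (clampCeiling <= 0 || clampCeiling >= 1)
    stop("clampCeiling must be in (0, 1)")
  parentIdx <- if (is.character(parent)) codonIndices(parent) else parent
  f <- if (methods::is(factors, "SelectionFactorMatrix"))
    factors@factors else factors
  L <- length(parentIdx)
  if (nrow(neutralProbs) != L || nrow(f) != L)
    stop("table shapes do not match the parent sequence")
  f64 <- matrix(0, L, 64)
  f64[, SENSE_CODONS] <- f[, CODON_AA_IDX[SENSE_CODONS], drop = FALSE]
  ell <- neutralProbs * f64
  ok <- !is.na(parentIdx)
  ell[cbind(which(ok), parentIdx[ok])] <- 0
  tot <- rowSums(ell)
  scale <- pmin(1, clampCeiling / tot)
  scale[!is.finite(scale)] <- 1
  ell <- ell * scale
  ell[cbind(which(ok), parentIdx[ok])] <- 1 - pmin(tot[ok], clampCeiling)
  ell[!ok, ] <- NA_real_
  ell
}

## Resolve per-record selection factors: from a model (one forward pass
## per unique parent), a single SelectionFactorMatrix, or a list of them.
resolveFactors <- function(pcps, model = NULL, factors = NULL) {
  n <- length(pcps)
  if (!is.null(factors)) {
    if (methods::is(factors, "SelectionFactorMatrix"))
      return(rep(list(factors@factors), n))
    return(lapply(factors, function(f)
      if (methods::is(f, "SelectionFactorMatrix")) f@factors else f))
  }
  if (is.null(model)) stop("supply either a model or selection factors")
  key <- paste(pcps@parent, pcps@chainLayout, sep = "\r")
  uniq <- !duplicated(key)
  fs <- lapply(which(uniq), function(i)
    predictSelectionFactors(model, translateNt(pcps@parent[i]),
                            pcps@chainLayout[i])@factors)
  fs[match(key, key[uniq])]
}

#' Per-PCP log-likelihood
#'
#' Sum over unmasked codon sites of the log Eq.-1 likelihood of the
#' observed child codon. `-Inf` if any observed child codon has zero
#' likelihood (e.g. a stop codon in the child).
#'
#' @param pcps A [PCPSet-class].
#' @param neutral A [NeutralModel-class].
#' @param t Branch length(s); defaults to the stored branch lengths.
#' @param model A [DasmModel-class] supplying selection factors, or
#' @param factors a [SelectionFactorMatrix-class] (shared reference) or
#'   list of factor matrices, used instead of `model`; with both `NULL`
#'   all factors are 1 (neutral likelihood).
#' @param clampCeiling See [codonLikelihoods()].
#' @return Numeric vector of log-likelihoods, one per record.
#' @export
pcpLogLikelihood <- function(pcps, neutral, t = NULL, model = NULL,
                             factors = NULL, clampCeiling = 1 - 1e-6) {
  n <- length(pcps)
  if (is.null(t)) t <- branchLengths(pcps)
  t <- rep_len(t, n)
  if (anyNA(t)) stop("branch lengths required (t missing)")
  if (is.null(model) && is.null(factors)) {
    factors <- lapply(seq_len(n), function(i)
      matrix(1, nchar(pcps@parent[i]) %/% 3L, 20L))
  }
  fs <- resolveFactors(pcps, model, factors)
  vapply(seq_len(n), function(i) {
    parentIdx <- codonIndices(pcps@parent[i])
    childIdx <- codonIndices(pcps@child[i])
    P <- recordNeutralTable(neutral, pcps@parent[i], pcps@chainLayout[i],
                            t[i])
    ell <- codonLikelihoods(P, fs[[i]], parentIdx, clampCeiling)
    ok <- !is.na(parentIdx) & !is.na(childIdx)
    sum(log(ell[cbind(which(ok), childIdx[ok])]))
  }, numeric(1))
}

#' Optimize a PCP branch length
#'
#' Maximizes the Eq.-1 likelihood of one record over `t`, holding the
#' selection factors fixed. Because wild-type-synonymous codons carry
#' factor 1 under the gauge, synonymous changes anchor the time scale.
#' Golden-section search over `log t` on `[1e-6, 5]`.
#'
#' @param pcps A [PCPSet-class].
#' @param neutral A [NeutralModel-class].
#' @param i Record index (default 1).
#' @param model,factors Selection factors as in [pcpLogLikelihood()];
#'   both `NULL` means neutral (all factors 1).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-7).
#' @param clampCeiling See [codonLikelihoods()].
#' @return Optimal `t`; `attr(, "logLik")` holds the attained value and
#'   `attr(, "converged")` the convergence flag.
#' @export
optimizeBranchLength <- function(pcps, neutral, i = 1L, model = NULL,
                                 factors = NULL, tol = 1e-7,
                                 clampCeiling = 1 - 1e-6) {
  f <- if (is.null(model) && is.null(factors))
    list(matrix(1, nchar(pcps@parent[i]) %/% 3L, 20L))
  else resolveFactors(pcps[i], model, factors)
  parent <- pcps@parent[i]
  parentIdx <- codonIndices(parent)
  childIdx <- codonIndices(pcps@child[i])
  rates <- siteRates(parent, neutral@table)
  rates <- applyChainRates(rates,
                           parseChainLayout(pcps@chainLayout[i],
                                            nchar(parent)),
                           neutral@lightRateFactor)
  ok <- !is.na(parentIdx) & !is.na(childIdx)
  obs <- cbind(which(ok), childIdx[ok])
  ll <- function(logt) {
    P <- neutralTableFromRates(parentIdx, rates, exp(logt),
                               neutral@multihit)
    ell <- codonLikelihoods(P, f[[1]], parentIdx, clampCeiling)
    sum(log(ell[obs]))
  }
  out <- goldenMax(ll, log(1e-6), log(5), tol = tol)
  t <- exp(out$x)
  attr(t, "logLik") <- out$value
  attr(t, "converged") <- out$converged
  t
}

## Golden-section maximization of fn over [lo, hi]; stops when the
## bracketed improvement in fn drops below tol (or after maxit).
goldenMax <- function(fn, lo, hi, tol = 1e-7, maxit = 200L) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- fn(x1); f2 <- fn(x2)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- fn(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- fn(x1)
    }
    if (abs(f1 - f2) < tol && abs(hi - lo) < 1e-6) { converged <- TRUE; break }
  }
  if (f1 > f2) list(x = x1, value = f1, converged = converged)
  else list(x = x2, value = f2, converged = converged)
}

#' Per-site amino-acid substitution probabilities
#'
#' Aggregates the Eq.-1 codon likelihood table to amino-acid level: the
#' probability of amino acid `a` at site `j` is the sum of likelihoods of
#' the codons encoding it (the wild-type amino acid collects the parent
#' codon's residual plus synonymous codons). Each site sums to 1. The
#' per-site amino-acid substitution probability is 1 minus the wild-type
#' amino-acid probability: the neutral mutation probability modulated by
#' selection.
#'
#' @param parent Parent nucleotide sequence.
#' @param neutral A [NeutralModel-class].
#' @param t Branch length.
#' @param model,factors Selection source as in [pcpLogLikelihood()].
#' @param chainLayout Chain layout string.
#' @param clampCeiling See [codonLikelihoods()].
#' @return List with `dist` (`L x 20` per-site amino-acid distribution,
#'   `NA` rows at masked sites) and `substProb` (per-site probability of
#'   an amino-acid substitution).
#' @export
siteSubstitutionProbabilities <- function(parent, neutral, t, model = NULL,
                                          factors = NULL, chainLayout = "",
                                          clampCeiling = 1 - 1e-6) {
  parentIdx <- codonIndices(parent)
  L <- length(parentIdx)
  if (is.null(model) && is.null(factors)) factors <- matrix(1, L, 20L)
  f <- if (!is.null(model))
    predictSelectionFactors(model, translateNt(parent), chainLayout)
  else factors
  P <- recordNeutralTable(neutral, parent, chainLayout, t)
  ell <- codonLikelihoods(P, f, parentIdx, clampCeiling)
  dist <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  for (a in seq_len(20L)) {
    cods <- which(CODON_AA_IDX == a)
    dist[, a] <- rowSums(ell[, cods, drop = FALSE])
  }
  ok <- !is.na(parentIdx)
  dist[!ok, ] <- NA_real_
  wt <- CODON_AA_IDX[parentIdx]
  substProb <- rep(NA_real_, L)
  substProb[ok] <- 1 - dist[cbind(which(ok), wt[ok])]
  list(dist = dist, substProb = substProb)
}
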