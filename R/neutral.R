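## Neutral codon mutation probabilities. Per-nucleotide-site rates are
## converted to mutation probabilities by competing exponentials,
## p = 1 - exp(-lambda * t), with a time-independent conditional
## substitution distribution; per-codon 64-way probabilities are the
## product of the three per-position outcomes. A hit-class "multihit"
## correction multiplies codons 1, 2 or 3 nucleotide changes away from the
## parent and renormalizes, capturing the spatial clustering of SHM.

#' Per-site neutral mutation probability
#'
#' `p = 1 - exp(-lambda * t)`: the probability that a site with relative
#' mutability `lambda` mutates at least once in branch length `t`
#' (expected neutral substitutions per site at unit rate).
#'
#' @param rate Nonnegative rate(s) `lambda`.
#' @param t Nonnegative branch length.
#' @return Probability in `[0, 1)`, vectorized over `rate`.
#' @export
siteMutationProbability <- function(rate, t) {
  if (any(rate < 0, na.rm = TRUE) || any(t < 0))
    stop("rate and t must be nonnegative")
  -expm1(-rate * t)
}

#' Neutral 64-way codon mutation probabilities for one codon
#'
#' The probability of mutating from the parent codon to codon `c` is the
#' product over the three nucleotide positions of the per-position
#' probability: `1 - p_i` if the base is unchanged, `p_i * csp_i(base)`
#' otherwise. The result sums to 1 over the 64 codons.
#'
#' @param parentCodon Parent codon string (e.g. `"AAA"`) or index 1..64.
#' @param p Numeric length-3 vector of per-position mutation probabilities.
#' @param csp `3 x 4` matrix of conditional substitution distributions
#'   (rows = codon positions, columns = A,C,G,T; parent base entry
#'   ignored/zero).
#' @return Numeric vector of 64 probabilities in codon-index order, or a
#'   vector of `NA` if the parent codon is ambiguous (masked site).
#' @export
codonProbabilities <- function(parentCodon, p, csp) {
  if (is.character(parentCodon)) parentCodon <- codonIndices(parentCodon)
  if (is.na(parentCodon)) return(rep(NA_real_, 64))
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  pb <- CODON_BASES[parentCodon, ]
  out <- rep(1, 64)
  for (pos in 1:3) {
    w <- p[pos] * csp[pos, ]
    w[pb[pos]] <- 1 - p[pos]
    out <- out * w[CODON_BASES[, pos]]
  }
  out
}

## Vectorized neutral table: L x 64 matrix of codon probabilities for a
## whole parent sequence. p is the per-nt-site mutation probability vector
## (length 3L), csp the per-nt-site substitution matrix (3L x 4). Masked
## (ambiguous) parent codons give NA rows.
neutralTableFromSiteProbs <- function(parentIdx, p, csp) {
  L <- length(parentIdx)
  W <- p * csp                        # (3L) x 4: prob of mutating to base b
  ntParent <- integer(3L * L)
  ok <- !is.na(parentIdx)
  ntParent[rep(ok, each = 3)] <- t(CODON_BASES[parentIdx[ok], , drop = FALSE])
  rows <- seq_len(3L * L)
  W[cbind(rows[rep(ok, each = 3)], ntParent[rep(ok, each = 3)])] <-
    (1 - p)[rep(ok, each = 3)]
  P <- W[seq(1L, 3L * L, by = 3L), CODON_BASES[, 1], drop = FALSE] *
       W[seq(2L, 3L * L, by = 3L), CODON_BASES[, 2], drop = FALSE] *
       W[seq(3L, 3L * L, by = 3L), CODON_BASES[, 3], drop = FALSE]
  P[!ok, ] <- NA_real_
  P
}

#' Neutral codon probability table for a parent sequence
#'
#' Builds the `L x 64` per-codon-site neutral mutation probability table
#' for a parent nucleotide sequence: k-mer site rates (optionally
#' light-chain-scaled), converted to probabilities at branch length `t`,
#' multiplied into per-codon products, with optional multihit correction.
#'
#' @param parent Parent nucleotide sequence string, in frame.
#' @param table A [KmerRateTable-class].
#' @param t Branch length.
#' @param multihit Optional [MultihitCoefficients-class].
#' @param chainLayout Chain layout string (`""` = all heavy).
#' @param lightRateFactor Light-chain rate scaling (default 0.63).
#' @return `L x 64` matrix; rows sum to 1; masked codons are `NA` rows.
#' @export
neutralCodonTable <- function(parent, table, t, multihit = NULL,
                              chainLayout = "", lightRateFactor = 0.63) {
  rates <- siteRates(parent, table)
  labels <- parseChainLayout(chainLayout, nchar(parent))
  rates <- applyChainRates(rates, labels, lightRateFactor)
  parentIdx <- codonIndices(parent)
  neutralTableFromRates(parentIdx, rates, t, multihit)
}

## Same, from precomputed site rates (hot path during training).
neutralTableFromRates <- function(parentIdx, rates, t, multihit = NULL) {
  p <- siteMutationProbability(rates$rate, t)
  p[is.na(p)] <- 0
  P <- neutralTableFromSiteProbs(parentIdx, p, rates$csp)
  if (!is.null(multihit)) P <- applyMultihit(P, parentIdx, multihit)
  P
}

#' MultihitCoefficients: hit-class rate multipliers
#'
#' Multipliers for codon changes requiring 1, 2 or 3 nucleotide mutations
#' (the parent codon's class-0 multiplier is fixed at 1). Values above 1
#' raise the relative probability of that hit class, modelling the spatial
#' clustering of SHM that makes multi-nucleotide codon changes more common
#' than independent per-site mutation predicts.
#'
#' @slot m Numeric length-3 vector `(m1, m2, m3)`, strictly positive.
#' @export
setClass("MultihitCoefficients", representation(m = "numeric"))

setValidity("MultihitCoefficients", function(object) {
  if (length(object@m) != 3L) return("need exactly (m1, m2, m3)")
  if (any(!is.finite(object@m)) || any(object@m <= 0))
    return("coefficients must be strictly positive")
  TRUE
})

#' @rdname MultihitCoefficients-class
#' @param m1,m2,m3 Positive multipliers for 1-, 2- and 3-nucleotide codon
#'   changes.
#' @export
MultihitCoefficients <- function(m1 = 1, m2 = 1, m3 = 1) {
  new("MultihitCoefficients", m = c(m1, m2, m3))
}

setMethod("show", "MultihitCoefficients", function(object) {
  cat(sprintf("MultihitCoefficients: m1 = %.4g, m2 = %.4g, m3 = %.4g\n",
              object@m[1], object@m[2], object@m[3]))
})

#' @rdname MultihitCoefficients-class
#' @param x A `MultihitCoefficients`.
#' @export
multihitCoefs <- function(x) stats::setNames(x@m, c("m1", "m2", "m3"))

#' Apply multihit correction to codon probabilities
#'
#' Each codon's probability is multiplied by the coefficient of its
#' nucleotide Hamming distance from the parent codon (distance 0 keeps
#' multiplier 1) and the full 64-vector is renormalized to sum 1.
#'
#' @param probs 64-vector or `L x 64` matrix of codon probabilities (rows
#'   summing to 1).
#' @param parentCodon Parent codon index/indices (1..64), one per row.
#' @param coeffs A [MultihitCoefficients-class].
#' @return Corrected probabilities, same shape as `probs`.
#' @export
applyMultihit <- function(probs, parentCodon, coeffs) {
  vec <- is.null(dim(probs))
  if (vec) probs <- matrix(probs, nrow = 1)
  if (is.character(parentCodon))
    parentCodon <- codonIndices(paste0(parentCodon, collapse = ""))
  mult <- c(1, coeffs@m)
  ok <- !is.na(parentCodon)
  out <- probs
  if (any(ok)) {
    h <- CODON_HAMMING[parentCodon[ok], , drop = FALSE]
    scaled <- probs[ok, , drop = FALSE] *
      matrix(mult[h + 1L], nrow = sum(ok))
    out[ok, ] <- scaled / rowSums(scaled)
  }
  if (vec) out[1, ] else out
}

#' Fit multihit coefficients on neutrally evolving PCPs
#'
#' Maximizes, over `(m1, m2, m3)` in log space, the product across PCPs
#' and unmasked codon sites of the observed child-codon probability under
#' the multihit-corrected neutral model (selection identically 1). Branch
#' lengths must be present on the PCPs (known from simulation or
#' pre-optimized under the uncorrected neutral model).
#'
#' @param pcps A [PCPSet-class] with branch lengths set.
#' @param table A [KmerRateTable-class].
#' @param lightRateFactor Light-chain rate scaling (default 0.63).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @return A [MultihitCoefficients-class]; the attained mean per-site
#'   log-likelihood is in `attr(, "logLik")`.
#' @export
fitMultihit <- function(pcps, table, lightRateFactor = 0.63, tol = 1e-6) {
  if (length(pcps) == 0L) stop("empty PCP dataset")
  if (anyNA(branchLengths(pcps)))
    stop("all PCPs need branch lengths before multihit fitting")
  ## Precompute, per codon site: baseline probability of the observed
  ## child codon, its hit class, and the baseline mass in each hit class.
  n <- length(pcps)
  Sl <- vector("list", n); pl <- vector("list", n); hl <- vector("list", n)
  for (i in seq_len(n)) {
    parentIdx <- codonIndices(pcps@parent[i])
    childIdx <- codonIndices(pcps@child[i])
    P <- neutralCodonTable(pcps@parent[i], table, branchLengths(pcps)[i],
                           multihit = NULL,
                           chainLayout = pcps@chainLayout[i],
                           lightRateFactor = lightRateFactor)
    ok <- !is.na(parentIdx) & !is.na(childIdx)
    if (!any(ok)) next
    h <- CODON_HAMMING[parentIdx[ok], , drop = FALSE]
    Pok <- P[ok, , drop = FALSE]
    Sl[[i]] <- vapply(0:3, function(d) rowSums(Pok * (h == d)),
                      numeric(sum(ok)))
    pl[[i]] <- Pok[cbind(seq_len(sum(ok)), childIdx[ok])]
    hl[[i]] <- h[cbind(seq_len(sum(ok)), childIdx[ok])]
  }
  S <- do.call(rbind, Sl[!vapply(Sl, is.null, TRUE)])
  pObs <- unlist(pl); hObs <- unlist(hl)
  if (is.null(S) || !length(hObs)) stop("no usable codon sites in dataset")
  counts <- tabulate(hObs, nbins = 3L)
  free <- counts > 0L
  if (!any(free)) {
    warning("no mutated codons observed; returning unit coefficients")
    return(MultihitCoefficients())
  }
  if (!all(free))
    warning("no observed codon changes in hit class(es) ",
            paste(which(!free), collapse = ", "),
            "; fixing those coefficients at 1")
  nll <- function(logm) {
    m <- c(1, 1, 1); m[free] <- exp(logm)
    denom <- as.vector(S %*% c(1, m))
    -(sum(log(m[hObs])) + sum(log(pObs)) - sum(log(denom)))
  }
  grad <- function(logm) {
    m <- c(1, 1, 1); m[free] <- exp(logm)
    denom <- as.vector(S %*% c(1, m))
    g <- vapply(1:3, function(j)
      -(counts[j] - m[j] * sum(S[, j + 1L] / denom)), numeric(1))
    g[free]
  }
  fit <- stats::optim(rep(0, sum(free)), nll, grad, method = "BFGS",
                      control = list(reltol = tol, maxit = 500))
  m <- c(1, 1, 1); m[free] <- exp(fit$par)
  out <- MultihitCoefficients(m[1], m[2], m[3])
  attr(out, "logLik") <- -fit$value / length(hObs)
  out
}
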