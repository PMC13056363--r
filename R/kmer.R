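## k-mer neutral somatic-hypermutation model: per-site relative mutabilities
## and conditional substitution distributions looked up from the local
## nucleotide context (default 5-mers, the classical S5F-style
## parameterization). Flanking positions beyond the sequence are N-padded
## and resolved by averaging over all matching k-mers.

#' KmerRateTable: k-mer neutral mutabilities and substitution distributions
#'
#' @slot k odd integer context width (default 5).
#' @slot rate numeric vector of length `4^k`, nonnegative relative
#'   mutability per k-mer, named by k-mer, lexicographic in A,C,G,T.
#' @slot csp `4^k x 4` matrix of conditional substitution probabilities
#'   (columns A,C,G,T); each row sums to 1 with 0 at the center base.
#' @export
setClass("KmerRateTable", representation(
  k = "integer", rate = "numeric", csp = "matrix"))

setValidity("KmerRateTable", function(object) {
  k <- object@k
  if (length(k) != 1L || k < 1L || k %% 2L == 0L)
    return("k must be a single odd positive integer")
  nk <- 4L^k
  if (length(object@rate) != nk) return("rate must have 4^k entries")
  if (any(object@rate < 0)) return("negative rate")
  if (!all(dim(object@csp) == c(nk, 4L))) return("csp must be 4^k x 4")
  if (any(object@csp < 0)) return("negative csp entry")
  if (any(abs(rowSums(object@csp) - 1) > 1e-9))
    return("csp rows must sum to 1")
  ctr <- centerBaseIdx(k)
  if (any(object@csp[cbind(seq_len(nk), ctr)] != 0))
    return("csp must be 0 at the center base")
  TRUE
})

setMethod("show", "KmerRateTable", function(object) {
  cat(sprintf("KmerRateTable: k = %d (%d k-mers), mean rate %.4g\n",
              object@k, 4L^object@k, mean(object@rate)))
})

## All k-mers in lexicographic order (first character most significant,
## consistent with the positional weights 4^(k-1)..4^0 used for lookup).
allKmers <- function(k) {
  idx <- 0:(4^k - 1)
  m <- vapply((k - 1L):0L, function(p) (idx %/% 4^p) %% 4 + 1,
              numeric(length(idx)))
  apply(m, 1L, function(b) paste0(NT_ALPHABET[b], collapse = ""))
}

centerBaseIdx <- function(k) {
  nk <- 4L^k
  h <- (k - 1L) %/% 2L
  ((seq_len(nk) - 1L) %/% 4L^h) %% 4L + 1L
}

#' Construct a KmerRateTable
#'
#' @param rate Numeric vector of length `4^k` (lexicographic k-mer order,
#'   or named by k-mer).
#' @param csp `4^k x 4` conditional substitution matrix (columns A,C,G,T).
#' @param k Odd context width.
#' @return A validated [KmerRateTable-class].
#' @export
KmerRateTable <- function(rate, csp, k = 5L) {
  k <- as.integer(k)
  km <- allKmers(k)
  if (!is.null(names(rate))) rate <- rate[km]
  new("KmerRateTable", k = k,
      rate = stats::setNames(as.numeric(rate), km), csp = csp)
}

#' Uniform k-mer table: all rates 1, uniform substitution distribution
#' @param k Odd context width (default 5).
#' @return A [KmerRateTable-class].
#' @export
uniformKmerRateTable <- function(k = 5L) {
  k <- as.integer(k)
  nk <- 4L^k
  csp <- matrix(1 / 3, nk, 4)
  csp[cbind(seq_len(nk), centerBaseIdx(k))] <- 0
  new("KmerRateTable", k = k,
      rate = stats::setNames(rep(1, nk), allKmers(k)), csp = csp)
}

#' Random k-mer table with log-normal mutabilities
#'
#' Rates are drawn log-normal and normalized to mean 1 so branch lengths
#' stay on the expected-substitutions-per-site scale; substitution
#' distributions are Dirichlet(1) over the three non-center bases.
#'
#' @param k Odd context width.
#' @param sdlog Log-scale spread of mutabilities (default 0.5).
#' @param seed Integer seed.
#' @return A [KmerRateTable-class].
#' @export
randomKmerRateTable <- function(k = 5L, sdlog = 0.5, seed = 1L) {
  k <- as.integer(k)
  nk <- 4L^k
  rs <- localRNG(seed)
  rate <- rs(function() stats::rlnorm(nk, 0, sdlog))
  rate <- rate / mean(rate)
  g <- rs(function() matrix(stats::rexp(nk * 3), nk, 3))
  g <- g / rowSums(g)
  csp <- matrix(0, nk, 4)
  ctr <- centerBaseIdx(k)
  for (b in 1:4) {
    rows <- which(ctr == b)
    csp[rows, -b] <- g[rows, ]
  }
  new("KmerRateTable", k = k, rate = stats::setNames(rate, allKmers(k)),
      csp = csp)
}

## Run fn under a local, restored RNG state with the given seed.
localRNG <- function(seed) {
  seed <- as.integer(seed)
  state <- new.env()
  state$seed <- seed
  function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(state$seed)
    out <- fn()
    state$seed <- state$seed + 1L
    out
  }
}

#' Read a k-mer rate table from CSV
#'
#' Columns: `kmer`, `rate`, `p_to_A`, `p_to_C`, `p_to_G`, `p_to_T`. The
#' center-base column of each row must be 0 and rows must sum to 1.
#'
#' @param path CSV path covering all `4^k` k-mers.
#' @return A [KmerRateTable-class].
#' @export
readKmerRateTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kmer", "rate", "p_to_A", "p_to_C", "p_to_G", "p_to_T")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("k-mer table is missing column(s): ", paste(miss, collapse = ", "))
  k <- as.integer(nchar(df$kmer[1]))
  km <- allKmers(k)
  ord <- match(km, df$kmer)
  if (anyNA(ord))
    stop("k-mer table does not cover all 4^k k-mers")
  csp <- as.matrix(df[ord, c("p_to_A", "p_to_C", "p_to_G", "p_to_T")])
  dimnames(csp) <- NULL
  new("KmerRateTable", k = k, rate = stats::setNames(df$rate[ord], km),
      csp = csp)
}

#' Write a k-mer rate table to CSV
#' @param table A [KmerRateTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeKmerRateTable <- function(table, path) {
  df <- data.frame(kmer = allKmers(table@k), rate = unname(table@rate),
                   p_to_A = table@csp[, 1], p_to_C = table@csp[, 2],
                   p_to_G = table@csp[, 3], p_to_T = table@csp[, 4])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-nucleotide-site rates and substitution distributions
#'
#' Looks up every site's k-mer context in the table. Sites whose context
#' runs off the sequence end (N-padded flanks) get the average rate and
#' average substitution distribution over all k-mers compatible with the
#' observed bases; sites with ambiguous center base get `NA` rate.
#'
#' @param seq Nucleotide sequence string (length >= 1).
#' @param table A [KmerRateTable-class].
#' @return List with `rate` (numeric, one per nt site) and `csp`
#'   (`n x 4` matrix, columns A,C,G,T).
#' @export
siteRates <- function(seq, table) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  k <- table@k
  h <- (k - 1L) %/% 2L
  padded <- c(rep(NA_integer_, h),
              match(strsplit(seq, "")[[1]], NT_ALPHABET),
              rep(NA_integer_, h))
  rate <- numeric(n)
  csp <- matrix(NA_real_, n, 4)
  win <- if (n + 2L * h >= k) {
    w <- stats::embed(padded, k)[, k:1, drop = FALSE]
    w
  } else matrix(padded, nrow = 1)
  pow <- 4L^((k - 1L):0L)
  hasN <- rowSums(is.na(win)) > 0L
  if (any(!hasN)) {
    idx <- as.vector((win[!hasN, , drop = FALSE] - 1L) %*% pow) + 1L
    rate[!hasN] <- table@rate[idx]
    csp[!hasN, ] <- table@csp[idx, , drop = FALSE]
  }
  for (i in which(hasN)) {
    ctr <- win[i, h + 1L]
    if (is.na(ctr)) { rate[i] <- NA_real_; next }
    idx <- kmerExpansions(win[i, ], pow)
    rate[i] <- mean(table@rate[idx])
    csp[i, ] <- colMeans(table@csp[idx, , drop = FALSE])
  }
  list(rate = unname(rate), csp = csp)
}

## Indices of all k-mers compatible with a window containing NAs.
kmerExpansions <- function(window, pow) {
  free <- which(is.na(window))
  combos <- as.matrix(do.call(expand.grid,
                              replicate(length(free), 1:4, simplify = FALSE)))
  base <- window; base[free] <- 0L
  fixedPart <- sum((base[-free] - 1L) * pow[-free])
  as.vector(fixedPart + (combos - 1L) %*% pow[free]) + 1L
}

#' Scale light-chain site rates
#'
#' Light chains accumulate somatic mutations more slowly than heavy
#' chains; neutral rates at light-chain positions are multiplied by a
#' fixed adjustment factor (default 0.63, the median light/heavy relative
#' rate estimated from paired-chain phylogenies), while heavy-chain rates
#' are unchanged.
#'
#' @param rates Output of [siteRates()].
#' @param chainLabels Per-nucleotide `"H"`/`"L"` labels (see
#'   [parseChainLayout()]) matching the rate vector length.
#' @param lightRateFactor Positive scalar, default 0.63.
#' @return Rates list with scaled `rate`.
#' @export
applyChainRates <- function(rates, chainLabels, lightRateFactor = 0.63) {
  if (lightRateFactor <= 0) stop("lightRateFactor must be positive")
  if (length(chainLabels) != length(rates$rate))
    stop("chain layout length ", length(chainLabels),
         " does not match sequence length ", length(rates$rate))
  rates$rate <- rates$rate * ifelse(chainLabels == "L", lightRateFactor, 1)
  rates
}
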