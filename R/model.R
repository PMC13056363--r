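## The deep amino-acid selection model (DASM): a transformer encoder
## mapping an amino-acid sequence (heavy chain, light chain, or a paired
## heavy-light concatenation) to per-site, per-amino-acid selection
## factors in one forward pass. The output layer uses a bounded "wiggle"
## activation in log-factor space, and the wild-type entry at every site
## is gauge-fixed to exactly 1. Forward and backward passes are written in
## base R matrix operations; gradients are exercised against finite
## differences in the test suite.

DASM_VOCAB <- c(AA_ALPHABET, "X", "|")   # 20 aa, ambiguous, chain separator
SEP_TOKEN <- 22L
X_TOKEN <- 21L

#' DasmConfig: selection-model architecture
#'
#' @slot layers Number of transformer encoder layers (default 5).
#' @slot heads Attention heads (default 8).
#' @slot headDim Dimensions per head (default 32); the embedding dimension
#'   is `heads * headDim`.
#' @slot ffDim Feedforward hidden width (default 1024).
#' @slot dropout Dropout probability applied to each sublayer output
#'   during training (default 0.1).
#' @slot wiggleBeta Curvature scale of the output activation in log-factor
#'   units (default 0.3).
#' @slot maxLen Positional-encoding capacity (default 1024).
#' @export
setClass("DasmConfig", representation(
  layers = "integer", heads = "integer", headDim = "integer",
  ffDim = "integer", dropout = "numeric", wiggleBeta = "numeric",
  maxLen = "integer"))

setValidity("DasmConfig", function(object) {
  if (object@layers < 0L) return("layers must be >= 0")
  if (object@heads < 1L || object@headDim < 1L || object@ffDim < 1L)
    return("heads, headDim and ffDim must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@wiggleBeta <= 0) return("wiggleBeta must be positive")
  TRUE
})

#' @rdname DasmConfig-class
#' @param layers,heads,headDim,ffDim,dropout,wiggleBeta,maxLen See slots.
#' @export
DasmConfig <- function(layers = 5L, heads = 8L, headDim = 32L,
                       ffDim = 1024L, dropout = 0.1, wiggleBeta = 0.3,
                       maxLen = 1024L) {
  new("DasmConfig", layers = as.integer(layers), heads = as.integer(heads),
      headDim = as.integer(headDim), ffDim = as.integer(ffDim),
      dropout = dropout, wiggleBeta = wiggleBeta,
      maxLen = as.integer(maxLen))
}

embedDim <- function(config) config@heads * config@headDim

setMethod("show", "DasmConfig", function(object) {
  cat(sprintf(
    "DasmConfig: %d layers, %d heads x %d dims (embed %d), ff %d, dropout %.2g\n",
    object@layers, object@heads, object@headDim, embedDim(object),
    object@ffDim, object@dropout))
})

#' DasmModel: a built selection model
#'
#' @slot config The [DasmConfig-class].
#' @slot params Named list of parameter matrices/vectors.
#' @export
setClass("DasmModel", representation(config = "DasmConfig", params = "list"))

setMethod("show", "DasmModel", function(object) {
  show(object@config)
  cat(sprintf("  %s trainable parameters\n",
              format(countParameters(object), big.mark = ",")))
})

## Evaluate fn under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Build a DASM with deterministic initialization
#'
#' Linear weights are uniform in `(-1/sqrt(fan_in), +1/sqrt(fan_in))`,
#' biases zero, layer norms identity, embeddings Gaussian with standard
#' deviation `1/sqrt(embed_dim)`. The output head starts near zero so the
#' untrained model predicts selection factors close to 1 everywhere
#' (a neutral starting point).
#'
#' @param config A [DasmConfig-class].
#' @param seed Integer seed for the initialization.
#' @return A [DasmModel-class].
#' @export
buildDasm <- function(config = DasmConfig(), seed = 1L) {
  methods::validObject(config)
  d <- embedDim(config)
  withSeed(seed, function() {
    lin <- function(fin, fout) matrix(
      stats::runif(fin * fout, -1, 1) / sqrt(fin), fin, fout)
    p <- list(
      tok = matrix(stats::rnorm(length(DASM_VOCAB) * d, 0, 1 / sqrt(d)),
                   length(DASM_VOCAB), d),
      chain = matrix(stats::rnorm(2L * d, 0, 1 / sqrt(d)), 2L, d))
    for (l in seq_len(config@layers)) {
      pre <- sprintf("l%d_", l)
      p[[paste0(pre, "Wq")]] <- lin(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
      p[[paste0(pre, "Wk")]] <- lin(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
      p[[paste0(pre, "Wv")]] <- lin(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
      p[[paste0(pre, "Wo")]] <- lin(d, d); p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "g1")]] <- rep(1, d); p[[paste0(pre, "o1")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- lin(d, config@ffDim)
      p[[paste0(pre, "b1")]] <- numeric(config@ffDim)
      p[[paste0(pre, "W2")]] <- lin(config@ffDim, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
      p[[paste0(pre, "g2")]] <- rep(1, d); p[[paste0(pre, "o2")]] <- numeric(d)
    }
    p$Wh <- matrix(stats::runif(d * 20L, -0.01, 0.01), d, 20L)
    p$bh <- numeric(20L)
    new("DasmModel", config = config, params = p)
  })
}

#' Count trainable parameters
#' @param model A [DasmModel-class].
#' @return Integer: total number of trainable scalars.
#' @export
countParameters <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

#' Bounded output activation ("wiggle")
#'
#' Maps the unbounded network output to a log selection factor:
#' `wiggle(x) = beta * log(1 + x/beta)` for `x >= 0` and `wiggle(x) = x`
#' for `x < 0`. It fixes 0 (factor 1), is continuous and strictly
#' increasing, grows sub-linearly for beneficial outputs, and leaves the
#' log factor unbounded below so the factor itself asymptotes to 0 for
#' strongly deleterious ones.
#'
#' @param x Numeric vector/matrix of raw outputs.
#' @param beta Positive curvature scale (default 0.3).
#' @return Log selection factors, same shape as `x`.
#' @export
wiggle <- function(x, beta = 0.3) {
  pos <- x >= 0
  out <- x
  out[pos] <- beta * log1p(x[pos] / beta)
  out
}

## Derivative of wiggle (needed by backprop).
wiggleGrad <- function(x, beta = 0.3) {
  pos <- x >= 0
  out <- 1 + 0 * x
  out[pos] <- 1 / (1 + x[pos] / beta)
  out
}

## Sinusoidal positional encodings: maxLen x d.
positionalEncoding <- function(maxLen, d) {
  pos <- seq_len(maxLen) - 1L
  i <- 0:(d - 1L)
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / d))
  pe <- matrix(0, maxLen, d)
  even <- which(i %% 2L == 0L); odd <- which(i %% 2L == 1L)
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, odd] <- cos(angle[, odd, drop = FALSE])
  pe
}

## Encode an amino-acid input (single chain or paired) into model tokens.
## chainCodonLabels: per-aa-site "H"/"L" labels; a separator token is
## inserted at the H->L boundary for paired inputs. Returns tokens, chain
## ids, the output-row indices corresponding to real aa sites, and wt aa.
encodeAaInput <- function(aaSeq, chainCodonLabels = NULL) {
  aa <- strsplit(aaSeq, "")[[1]]
  bad <- !(aa %in% DASM_VOCAB[1:21])
  if (any(bad))
    stop("invalid amino-acid character(s): ",
         paste(unique(aa[bad]), collapse = ", "))
  if (is.null(chainCodonLabels)) chainCodonLabels <- rep("H", length(aa))
  stopifnot(length(chainCodonLabels) == length(aa))
  tokens <- match(aa, DASM_VOCAB)
  chains <- ifelse(chainCodonLabels == "L", 2L, 1L)
  boundary <- which(chainCodonLabels[-1] == "L" &
                    chainCodonLabels[-length(aa)] == "H")
  if (length(boundary) == 1L) {
    pos <- boundary
    tokens <- append(tokens, SEP_TOKEN, after = pos)
    chains <- append(chains, 1L, after = pos)
    aaRows <- setdiff(seq_along(tokens), pos + 1L)
  } else aaRows <- seq_along(tokens)
  list(tokens = tokens, chains = chains, aaRows = aaRows, aa = aa)
}

## Transformer encoder forward pass. Returns raw L x 20 outputs at aa rows
## plus (optionally) the cache needed for backprop.
dasmForward <- function(model, tokens, chains, training = FALSE,
                        keepCache = FALSE) {
  cfg <- model@config
  p <- model@params
  d <- embedDim(cfg)
  L <- length(tokens)
  if (L > cfg@maxLen)
    stop("sequence of ", L, " tokens exceeds positional-encoding capacity ",
         cfg@maxLen)
  pe <- dasmPE(cfg)
  x <- p$tok[tokens, , drop = FALSE] + pe[seq_len(L), , drop = FALSE] +
    p$chain[chains, , drop = FALSE]
  keep <- if (training && cfg@dropout > 0) 1 - cfg@dropout else 1
  scale <- 1 / sqrt(cfg@headDim)
  hs <- lapply(seq_len(cfg@heads), function(h)
    ((h - 1L) * cfg@headDim + 1L):(h * cfg@headDim))
  cache <- if (keepCache) list(tokens = tokens, chains = chains,
                               layers = vector("list", cfg@layers)) else NULL
  for (l in seq_len(cfg@layers)) {
    pre <- sprintf("l%d_", l)
    xin <- x
    Q <- x %*% p[[paste0(pre, "Wq")]] + rep(p[[paste0(pre, "bq")]], each = L)
    K <- x %*% p[[paste0(pre, "Wk")]] + rep(p[[paste0(pre, "bk")]], each = L)
    V <- x %*% p[[paste0(pre, "Wv")]] + rep(p[[paste0(pre, "bv")]], each = L)
    A <- vector("list", cfg@heads)
    concat <- matrix(0, L, d)
    for (h in seq_len(cfg@heads)) {
      sc <- (Q[, hs[[h]], drop = FALSE] %*%
             t(K[, hs[[h]], drop = FALSE])) * scale
      sc <- sc - apply(sc, 1L, max)
      e <- exp(sc)
      A[[h]] <- e / rowSums(e)
      concat[, hs[[h]]] <- A[[h]] %*% V[, hs[[h]], drop = FALSE]
    }
    ao <- concat %*% p[[paste0(pre, "Wo")]] +
      rep(p[[paste0(pre, "bo")]], each = L)
    m1 <- if (keep < 1)
      matrix(stats::rbinom(L * d, 1L, keep) / keep, L, d) else NULL
    if (!is.null(m1)) ao <- ao * m1
    ln1 <- layerNorm(xin + ao, p[[paste0(pre, "g1")]], p[[paste0(pre, "o1")]])
    x1 <- ln1$y
    z1 <- x1 %*% p[[paste0(pre, "W1")]] + rep(p[[paste0(pre, "b1")]], each = L)
    a1 <- pmax(z1, 0)
    ff <- a1 %*% p[[paste0(pre, "W2")]] + rep(p[[paste0(pre, "b2")]], each = L)
    m2 <- if (keep < 1)
      matrix(stats::rbinom(L * d, 1L, keep) / keep, L, d) else NULL
    if (!is.null(m2)) ff <- ff * m2
    ln2 <- layerNorm(x1 + ff, p[[paste0(pre, "g2")]], p[[paste0(pre, "o2")]])
    x <- ln2$y
    if (keepCache)
      cache$layers[[l]] <- list(xin = xin, Q = Q, K = K, V = V, A = A,
                                concat = concat, m1 = m1, ln1 = ln1,
                                x1 = x1, z1 = z1, a1 = a1, m2 = m2,
                                ln2 = ln2)
  }
  raw <- x %*% p$Wh + rep(p$bh, each = L)
  if (keepCache) cache$xout <- x
  list(raw = raw, cache = cache)
}

## Layer norm over the feature dimension; returns output and backprop stats.
layerNorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invsig <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invsig
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, invsig = invsig)
}

## Cached positional encodings per (maxLen, d), kept in the package env.
.dasmCache <- new.env(parent = emptyenv())
dasmPE <- function(cfg) {
  key <- sprintf("pe_%d_%d", cfg@maxLen, embedDim(cfg))
  if (is.null(.dasmCache[[key]]))
    .dasmCache[[key]] <- positionalEncoding(cfg@maxLen, embedDim(cfg))
  .dasmCache[[key]]
}

#' SelectionFactorMatrix: per-site, per-amino-acid selection factors
#'
#' Strictly positive multiplicative factors `f[j, a]` for every amino acid
#' `a` at every site `j` of a reference sequence; values above 1 predict a
#' beneficial substitution during affinity maturation, below 1 a
#' deleterious one. The wild-type entry at each site is gauge-fixed to
#' exactly 1 (sites with ambiguous wild type are exempt).
#'
#' @slot factors `L x 20` numeric matrix, columns in alphabetical
#'   amino-acid order.
#' @slot wtAA Character vector of wild-type residues per site (`"X"` for
#'   ambiguous).
#' @export
setClass("SelectionFactorMatrix", representation(
  factors = "matrix", wtAA = "character"))

setValidity("SelectionFactorMatrix", function(object) {
  if (ncol(object@factors) != 20L) return("factors must have 20 columns")
  if (nrow(object@factors) != length(object@wtAA))
    return("wtAA length must match site count")
  if (any(object@factors <= 0)) return("factors must be strictly positive")
  wt <- match(object@wtAA, AA_ALPHABET)
  ok <- !is.na(wt)
  if (any(object@factors[cbind(which(ok), wt[ok])] != 1))
    return("wild-type entries must equal exactly 1 (gauge)")
  TRUE
})

#' @rdname SelectionFactorMatrix-class
#' @param factors `L x 20` positive matrix.
#' @param wtAA Wild-type residue per site.
#' @param gauge If `TRUE` (default), overwrite wild-type entries with 1.
#' @export
SelectionFactorMatrix <- function(factors, wtAA, gauge = TRUE) {
  colnames(factors) <- AA_ALPHABET
  wt <- match(wtAA, AA_ALPHABET)
  if (gauge) {
    ok <- !is.na(wt)
    factors[cbind(which(ok), wt[ok])] <- 1
  }
  new("SelectionFactorMatrix", factors = factors, wtAA = wtAA)
}

setMethod("show", "SelectionFactorMatrix", function(object) {
  cat(sprintf("SelectionFactorMatrix: %d sites x 20 amino acids\n",
              nrow(object@factors)))
  lf <- log(object@factors[object@factors != 1])
  if (length(lf))
    cat(sprintf("  log-factor range: [%.3g, %.3g]\n", min(lf), max(lf)))
})

#' @rdname SelectionFactorMatrix-class
#' @param x A `SelectionFactorMatrix`.
#' @export
selectionFactors <- function(x) x@factors

#' @rdname SelectionFactorMatrix-class
#' @export
wildTypeAa <- function(x) x@wtAA

#' @describeIn SelectionFactorMatrix-class number of sites
#' @export
setMethod("nrow", "SelectionFactorMatrix", function(x) nrow(x@factors))

#' Predict selection factors for a sequence
#'
#' Runs the DASM in evaluation mode (no dropout): one forward pass yields
#' factors for all 20 amino acids at every site. The wild-type entry at
#' each site is set to exactly 1 by the gauge convention. For paired
#' records the input is encoded heavy chain, separator, light chain, with
#' a learned chain embedding added to the token embeddings.
#'
#' @param model A [DasmModel-class].
#' @param aaSeq Amino-acid sequence (may contain `X`); for paired input,
#'   the heavy-then-light concatenation.
#' @param chainLayout Chain layout string over nucleotides
#'   (`"H:336,L:321"`) or `NULL`/`""` for a single heavy chain.
#' @return A [SelectionFactorMatrix-class].
#' @export
predictSelectionFactors <- function(model, aaSeq, chainLayout = NULL) {
  labels <- if (is.null(chainLayout) || identical(chainLayout, ""))
    NULL else codonChainLabels(chainLayout, 3L * nchar(aaSeq))
  enc <- encodeAaInput(aaSeq, labels)
  fw <- dasmForward(model, enc$tokens, enc$chains, training = FALSE)
  raw <- fw$raw[enc$aaRows, , drop = FALSE]
  f <- exp(wiggle(raw, model@config@wiggleBeta))
  SelectionFactorMatrix(f, enc$aa)
}

#' Write selection factors to CSV
#'
#' Columns: `site` (0-based), `wt_aa`, then the 20 amino acids.
#'
#' @param x A [SelectionFactorMatrix-class].
#' @param path Output path.
#' @param id Optional sequence identifier written as a leading column.
#' @param append Append without header (for multi-sequence output).
#' @return `path`, invisibly.
#' @export
writeSelectionFactors <- function(x, path, id = NULL, append = FALSE) {
  df <- data.frame(site = seq_len(nrow(x@factors)) - 1L, wt_aa = x@wtAA,
                   stringsAsFactors = FALSE)
  m <- as.data.frame(x@factors)
  names(m) <- AA_ALPHABET
  df <- cbind(df, m)
  if (!is.null(id)) df <- cbind(data.frame(id = id), df)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}

#' Serialize a DASM to disk
#'
#' Writes the configuration and all parameter arrays to a single file.
#'
#' @param model A [DasmModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveDasm <- function(model, path) {
  cfg <- model@config
  obj <- list(
    config = list(layers = cfg@layers, heads = cfg@heads,
                  headDim = cfg@headDim, ffDim = cfg@ffDim,
                  dropout = cfg@dropout, wiggleBeta = cfg@wiggleBeta,
                  maxLen = cfg@maxLen),
    params = model@params)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a serialized DASM
#'
#' @param path File written by [saveDasm()].
#' @param config Optional [DasmConfig-class]; if supplied, loading fails
#'   unless it matches the stored configuration.
#' @return A [DasmModel-class].
#' @export
loadDasm <- function(path, config = NULL) {
  obj <- readRDS(path)
  cfg <- do.call(DasmConfig, obj$config)
  if (!is.null(config) && !identical(cfg, config))
    stop("stored model configuration does not match the requested config")
  new("DasmModel", config = cfg, params = obj$params)
}
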