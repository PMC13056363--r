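## Cyclic joint training. Each cycle runs stochastic-gradient (RMSprop)
## optimization of the network on the summed per-PCP Eq.-1 log-likelihood
## with branch lengths held fixed, then re-optimizes every branch length
## with the network held fixed. Branch lengths are initialized from the
## observed nucleotide difference fraction. PCPs that share an identical
## model input reuse a single forward/backward pass per batch, with their
## output-layer gradients summed.

#' TrainingConfig: optimizer and schedule settings
#'
#' @slot cycles Joint-optimization cycles (default 4).
#' @slot epochsPerCycle Gradient epochs per cycle (default 2).
#' @slot learningRate RMSprop step size (default 2e-3).
#' @slot batchSize PCPs per gradient step (default 32).
#' @slot rmsDecay RMSprop squared-gradient decay (default 0.99).
#' @slot rmsEps RMSprop denominator floor (default 1e-8).
#' @slot clampCeiling Non-wild-type likelihood ceiling (default 1 - 1e-6).
#' @slot blTol Branch-length optimizer log-likelihood tolerance (1e-7).
#' @slot seed Integer seed governing initialization, data order, dropout.
#' @export
setClass("TrainingConfig", representation(
  cycles = "integer", epochsPerCycle = "integer", learningRate = "numeric",
  batchSize = "integer", rmsDecay = "numeric", rmsEps = "numeric",
  clampCeiling = "numeric", blTol = "numeric", seed = "integer"))

setValidity("TrainingConfig", function(object) {
  if (object@cycles < 1L) return("cycles must be >= 1")
  if (object@clampCeiling <= 0 || object@clampCeiling >= 1)
    return("clampCeiling must be in (0, 1)")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' @rdname TrainingConfig-class
#' @param cycles,epochsPerCycle,learningRate,batchSize,rmsDecay,rmsEps,clampCeiling,blTol,seed
#'   See slots.
#' @export
TrainingConfig <- function(cycles = 4L, epochsPerCycle = 2L,
                           learningRate = 2e-3, batchSize = 32L,
                           rmsDecay = 0.99, rmsEps = 1e-8,
                           clampCeiling = 1 - 1e-6, blTol = 1e-7,
                           seed = 1L) {
  new("TrainingConfig", cycles = as.integer(cycles),
      epochsPerCycle = as.integer(epochsPerCycle),
      learningRate = learningRate, batchSize = as.integer(batchSize),
      rmsDecay = rmsDecay, rmsEps = rmsEps, clampCeiling = clampCeiling,
      blTol = blTol, seed = as.integer(seed))
}

#' Train a DASM on parent-child pairs
#'
#' Runs `cycles` cycles of network optimization (RMSprop on the summed
#' negative per-PCP log-likelihood, branch lengths fixed) followed by
#' per-PCP branch-length re-optimization (network fixed). Branch lengths
#' start at the observed nucleotide difference fraction, floored at 1e-4.
#'
#' @param pcps A [PCPSet-class] of valid PCPs.
#' @param neutral A [NeutralModel-class].
#' @param dasmConfig A [DasmConfig-class].
#' @param trainConfig A [TrainingConfig-class].
#' @param verbose Emit per-cycle progress to standard error.
#' @return List with `model` ([DasmModel-class]), `branchLengths` (named
#'   numeric), and `trace` (data frame of per-epoch mean NLL per PCP).
#' @export
trainDasm <- function(pcps, neutral, dasmConfig = DasmConfig(),
                      trainConfig = TrainingConfig(), verbose = FALSE) {
  n <- length(pcps)
  if (n == 0L) stop("empty PCP dataset")
  prep <- prepareTraining(pcps, neutral)
  if (all(vapply(prep$records, function(r) !any(r$ok), TRUE)))
    stop("all sites masked; nothing to train on")
  tc <- trainConfig
  withSeed(tc@seed, function() {
    model <- buildDasm(dasmConfig, seed = tc@seed)
    v <- lapply(model@params, function(x) x * 0)
    tvec <- pmax(prep$diffFrac, 1e-4)
    trace <- list()
    for (cycle in seq_len(tc@cycles)) {
      agg <- lapply(seq_len(n), function(i)
        recordAggregates(prep$records[[i]], neutral, tvec[i]))
      for (epoch in seq_len(tc@epochsPerCycle)) {
        ord <- sample.int(n)
        batches <- split(ord, ceiling(seq_along(ord) / tc@batchSize))
        totalLoss <- 0
        for (b in batches) {
          step <- gradientStep(model, prep, agg, b, tc)
          totalLoss <- totalLoss + step$loss
          gscale <- 1 / length(b)
          for (nm in names(model@params)) {
            g <- step$grads[[nm]] * gscale
            v[[nm]] <- tc@rmsDecay * v[[nm]] + (1 - tc@rmsDecay) * g^2
            model@params[[nm]] <- model@params[[nm]] -
              tc@learningRate * g / (sqrt(v[[nm]]) + tc@rmsEps)
          }
        }
        trace[[length(trace) + 1L]] <-
          data.frame(cycle = cycle, epoch = epoch, loss = totalLoss / n)
        if (verbose)
          message(sprintf("[cycle %d epoch %d] mean NLL %.5f",
                          cycle, epoch, totalLoss / n))
      }
      ## branch-length phase (model fixed, evaluation mode)
      fs <- evalFactorsByInput(model, prep)
      for (i in seq_len(n)) {
        r <- prep$records[[i]]
        tvec[i] <- blOptimFast(r, fs[[r$inputKey]], neutral, tc)
      }
      if (verbose)
        message(sprintf("[cycle %d] branch lengths re-optimized (median %.4g)",
                        cycle, stats::median(tvec)))
    }
    list(model = model,
         branchLengths = stats::setNames(tvec, pcpIds(pcps)),
         trace = do.call(rbind, trace))
  })
}

## Static per-record structures shared across cycles.
prepareTraining <- function(pcps, neutral) {
  n <- length(pcps)
  key <- paste(pcps@parent, pcps@chainLayout, sep = "\r")
  ukey <- unique(key)
  inputs <- lapply(ukey, function(kk) {
    i <- match(kk, key)
    labels <- codonChainLabels(pcps@chainLayout[i], nchar(pcps@parent[i]))
    encodeAaInput(translateNt(pcps@parent[i]), labels)
  })
  names(inputs) <- ukey
  rates <- lapply(ukey, function(kk) {
    i <- match(kk, key)
    r <- siteRates(pcps@parent[i], neutral@table)
    applyChainRates(r, parseChainLayout(pcps@chainLayout[i],
                                        nchar(pcps@parent[i])),
                    neutral@lightRateFactor)
  })
  names(rates) <- ukey
  diffFrac <- numeric(n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- codonIndices(pcps@parent[i]); ci <- codonIndices(pcps@child[i])
    a <- strsplit(pcps@parent[i], "")[[1]]
    b <- strsplit(pcps@child[i], "")[[1]]
    diffFrac[i] <- mean(a != b)
    records[[i]] <- list(parentIdx = pi, childIdx = ci,
                         ok = !is.na(pi) & !is.na(ci),
                         inputKey = key[i], rates = rates[[key[i]]])
  }
  list(records = records, inputs = inputs, diffFrac = diffFrac)
}

## Per-record, per-cycle aggregates at fixed branch length: neutral
## amino-acid mass PA[j,a] (non-parent sense codons), the observed child
## codon's neutral probability, its amino-acid column, and whether the
## child codon is wild type.
recordAggregates <- function(r, neutral, t) {
  P <- neutralTableFromRates(r$parentIdx, r$rates, t, neutral@multihit)
  L <- length(r$parentIdx)
  PA <- matrix(0, L, 20L)
  okRows <- which(r$ok)
  Pz <- P
  Pz[cbind(okRows, r$parentIdx[okRows])] <- 0
  for (a in seq_len(20L)) {
    cods <- which(CODON_AA_IDX == a)
    PA[, a] <- rowSums(Pz[, cods, drop = FALSE])
  }
  PA[!r$ok, ] <- 0
  pChild <- rep(0, L)
  pChild[okRows] <- P[cbind(okRows, r$childIdx[okRows])]
  list(PA = PA,
       pChild = pChild,
       childCol = CODON_AA_IDX[r$childIdx],
       childIsWT = r$parentIdx == r$childIdx,
       wtCol = CODON_AA_IDX[r$parentIdx])
}

## Loss and dLoss/df (L x 20) for one record given factors f.
recordLossGrad <- function(r, a, f, ceiling) {
  L <- nrow(f)
  T <- rowSums(a$PA * f)
  clamped <- r$ok & T > ceiling
  G <- matrix(0, L, 20L)
  loss <- 0
  wtObs <- which(r$ok & a$childIsWT)
  if (length(wtObs)) {
    uncl <- wtObs[!clamped[wtObs]]
    cl <- wtObs[clamped[wtObs]]
    loss <- loss - sum(log1p(-T[uncl])) - length(cl) * log(1 - ceiling)
    if (length(uncl))
      G[uncl, ] <- a$PA[uncl, , drop = FALSE] / (1 - T[uncl])
  }
  mutObs <- which(r$ok & !a$childIsWT)
  if (length(mutObs)) {
    cc <- a$childCol[mutObs]
    fy <- f[cbind(mutObs, cc)]
    sc <- ifelse(clamped[mutObs], ceiling / T[mutObs], 1)
    loss <- loss - sum(log(a$pChild[mutObs]) + log(fy) + log(sc))
    clm <- mutObs[clamped[mutObs]]
    if (length(clm))
      G[clm, ] <- G[clm, , drop = FALSE] +
        a$PA[clm, , drop = FALSE] / T[clm]
    G[cbind(mutObs, cc)] <- G[cbind(mutObs, cc)] - 1 / fy
  }
  ## gauge: wild-type factors are fixed at 1
  okw <- which(r$ok & !is.na(a$wtCol))
  G[cbind(okw, a$wtCol[okw])] <- 0
  list(loss = loss, G = G)
}

## One gradient accumulation over a batch: groups records by identical
## model input, one forward/backward per group.
gradientStep <- function(model, prep, agg, batch, tc) {
  keys <- vapply(batch, function(i) prep$records[[i]]$inputKey, "")
  grads <- NULL
  loss <- 0
  for (kk in unique(keys)) {
    enc <- prep$inputs[[kk]]
    fw <- dasmForward(model, enc$tokens, enc$chains, training = TRUE,
                      keepCache = TRUE)
    raw <- fw$raw[enc$aaRows, , drop = FALSE]
    beta <- model@config@wiggleBeta
    f <- exp(wiggle(raw, beta))
    wt <- match(enc$aa, AA_ALPHABET)
    okwt <- which(!is.na(wt))
    f[cbind(okwt, wt[okwt])] <- 1
    Gsum <- matrix(0, nrow(f), 20L)
    for (i in batch[keys == kk]) {
      lg <- recordLossGrad(prep$records[[i]], agg[[i]], f, tc@clampCeiling)
      loss <- loss + lg$loss
      Gsum <- Gsum + lg$G
    }
    dRawAa <- Gsum * f * wiggleGrad(raw, beta)
    dRaw <- matrix(0, length(enc$tokens), 20L)
    dRaw[enc$aaRows, ] <- dRawAa
    g <- dasmBackward(model, fw$cache, dRaw)
    grads <- if (is.null(grads)) g else
      Map(`+`, grads, g)
  }
  list(grads = grads, loss = loss)
}

## Evaluation-mode factors for every unique input.
evalFactorsByInput <- function(model, prep) {
  out <- lapply(names(prep$inputs), function(kk) {
    enc <- prep$inputs[[kk]]
    fw <- dasmForward(model, enc$tokens, enc$chains, training = FALSE)
    raw <- fw$raw[enc$aaRows, , drop = FALSE]
    f <- exp(wiggle(raw, model@config@wiggleBeta))
    wt <- match(enc$aa, AA_ALPHABET)
    okwt <- which(!is.na(wt))
    f[cbind(okwt, wt[okwt])] <- 1
    f
  })
  names(out) <- names(prep$inputs)
  out
}

## Branch-length golden-section reusing precomputed rates and factors.
blOptimFast <- function(r, f, neutral, tc) {
  okRows <- which(r$ok)
  obs <- cbind(okRows, r$childIdx[okRows])
  ll <- function(logt) {
    P <- neutralTableFromRates(r$parentIdx, r$rates, exp(logt),
                               neutral@multihit)
    ell <- codonLikelihoods(P, f, r$parentIdx, tc@clampCeiling)
    sum(log(ell[obs]))
  }
  exp(goldenMax(ll, log(1e-6), log(5), tol = tc@blTol)$x)
}
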