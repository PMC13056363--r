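## Reverse-mode gradients for the DASM forward pass. `dasmBackward` takes
## the cache from `dasmForward(..., keepCache = TRUE)` and the gradient of
## the loss with respect to the raw L x 20 outputs, and returns gradients
## for every parameter (same names/shapes as `model@params`).

dasmBackward <- function(model, cache, dRaw) {
  cfg <- model@config
  p <- model@params
  d <- embedDim(cfg)
  L <- length(cache$tokens)
  scale <- 1 / sqrt(cfg@headDim)
  hs <- lapply(seq_len(cfg@heads), function(h)
    ((h - 1L) * cfg@headDim + 1L):(h * cfg@headDim))
  g <- list()
  g$Wh <- t(cache$xout) %*% dRaw
  g$bh <- colSums(dRaw)
  dx <- dRaw %*% t(p$Wh)
  for (l in rev(seq_len(cfg@layers))) {
    pre <- sprintf("l%d_", l)
    cl <- cache$layers[[l]]
    ## LN2
    bn <- layerNormBack(dx, cl$ln2, p[[paste0(pre, "g2")]])
    g[[paste0(pre, "g2")]] <- bn$dg; g[[paste0(pre, "o2")]] <- bn$db
    dr2 <- bn$dx
    dff <- if (is.null(cl$m2)) dr2 else dr2 * cl$m2
    ## feedforward
    g[[paste0(pre, "b2")]] <- colSums(dff)
    g[[paste0(pre, "W2")]] <- t(cl$a1) %*% dff
    dz1 <- (dff %*% t(p[[paste0(pre, "W2")]])) * (cl$z1 > 0)
    g[[paste0(pre, "b1")]] <- colSums(dz1)
    g[[paste0(pre, "W1")]] <- t(cl$x1) %*% dz1
    dx1 <- dr2 + dz1 %*% t(p[[paste0(pre, "W1")]])
    ## LN1
    bn <- layerNormBack(dx1, cl$ln1, p[[paste0(pre, "g1")]])
    g[[paste0(pre, "g1")]] <- bn$dg; g[[paste0(pre, "o1")]] <- bn$db
    dr1 <- bn$dx
    dao <- if (is.null(cl$m1)) dr1 else dr1 * cl$m1
    ## attention output projection
    g[[paste0(pre, "bo")]] <- colSums(dao)
    g[[paste0(pre, "Wo")]] <- t(cl$concat) %*% dao
    dconcat <- dao %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(cfg@heads)) {
      cols <- hs[[h]]
      dOut <- dconcat[, cols, drop = FALSE]
      A <- cl$A[[h]]
      dA <- dOut %*% t(cl$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dOut
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% cl$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- (t(dS) %*% cl$Q[, cols, drop = FALSE]) * scale
    }
    g[[paste0(pre, "Wq")]] <- t(cl$xin) %*% dQ
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- t(cl$xin) %*% dK
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- t(cl$xin) %*% dV
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dx <- dr1 + dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
  }
  ## embeddings
  g$tok <- matrix(0, length(DASM_VOCAB), d)
  for (v in unique(cache$tokens)) {
    rows <- which(cache$tokens == v)
    g$tok[v, ] <- colSums(dx[rows, , drop = FALSE])
  }
  g$chain <- matrix(0, 2L, d)
  for (v in unique(cache$chains)) {
    rows <- which(cache$chains == v)
    g$chain[v, ] <- colSums(dx[rows, , drop = FALSE])
  }
  g[names(p)]
}

## Layer-norm backward for one sublayer. `ln` is the list returned by
## layerNorm (xhat, invsig); returns dx plus gamma/beta gradients.
layerNormBack <- function(dy, ln, g) {
  L <- nrow(dy)
  dg <- colSums(dy * ln$xhat)
  db <- colSums(dy)
  dxh <- dy * rep(g, each = L)
  dx <- ln$invsig *
    (dxh - rowMeans(dxh) - ln$xhat * rowMeans(dxh * ln$xhat))
  list(dx = dx, dg = dg, db = db)
}
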