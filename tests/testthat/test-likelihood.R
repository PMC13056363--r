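## Hand-set single-site tables used across several blocks: parent AAA,
## per-position mutation probabilities (0.1, 0.2, 0.3), uniform csp.
handNeutral <- function() {
  matrix(codonProbabilities("AAA", c(0.1, 0.2, 0.3), matrix(1 / 3, 3, 4)),
         1, 64)
}

test_that("with unit factors the likelihood equals the neutral table", {
  P <- handNeutral()
  ell <- codonLikelihoods(P, matrix(1, 1, 20), "AAA")
  stops <- dasm:::STOP_CODONS
  wt <- codonIndices("AAA")
  expect_equal(ell[, stops], rep(0, 3))
  nonwt <- setdiff(setdiff(1:64, stops), wt)
  expect_identical(ell[, nonwt], P[, nonwt])
  expect_identical(ell[, wt], 1 - sum(ell[, nonwt]))
  expect_equal(sum(ell), 1)
})

test_that("selection factors multiply neutral codon probabilities", {
  P <- handNeutral()
  f <- matrix(1, 1, 20)
  f[1, match("Q", aminoAcidAlphabet())] <- 2   # CAA encodes Gln
  ell <- codonLikelihoods(P, f, "AAA")
  expect_equal(ell[, codonIndices("CAA")], 2 * (0.1 / 3) * 0.8 * 0.7)
})

test_that("the clamp proportionally rescales runaway non-wild-type mass", {
  P <- handNeutral()
  f <- matrix(1.5 / sum(P[, -codonIndices("AAA")]), 1, 20)
  ## factors chosen so the raw non-wild-type sum is about 1.5; rebuild the
  ## exact sum to verify the rescale arithmetic (stops are dropped first)
  ell0 <- codonLikelihoods(P, f, "AAA", clampCeiling = 0.999)
  wt <- codonIndices("AAA")
  stops <- dasm:::STOP_CODONS
  rawSum <- sum(P[, -c(wt, stops)] * f[1, 1])
  expect_gt(rawSum, 0.999)
  nonwt <- setdiff(setdiff(1:64, stops), wt)
  expect_equal(sum(ell0[, nonwt]), 0.999)
  expect_equal(ell0[, wt], 1 - 0.999)
  ## proportionality: ratios within the non-wild-type set are preserved
  expect_equal(ell0[, nonwt] / (P[, nonwt] * f[1, 1]),
               rep(0.999 / rawSum, length(nonwt)))
})

test_that("likelihood tables conserve probability on random inputs", {
  set.seed(21)
  nm <- neutralModel(randomKmerRateTable(5, seed = 22))
  for (rep in 1:20) {
    parent <- generateGermline(8, seed = rep)
    t <- runif(1, 0, 0.5)
    P <- neutralCodonTable(parent, nm@table, t)
    f <- matrix(exp(rnorm(8 * 20, 0, 1)), 8, 20)
    ell <- codonLikelihoods(P, f, parent)
    expect_lt(max(abs(rowSums(ell) - 1)), 1e-12)
    expect_true(all(ell[, dasm:::STOP_CODONS] == 0))
  }
})

test_that("raising one factor below the clamp raises that codon's likelihood", {
  P <- handNeutral()
  f1 <- matrix(1, 1, 20)
  f2 <- f1
  qcol <- match("Q", aminoAcidAlphabet())
  f2[1, qcol] <- 1.4
  e1 <- codonLikelihoods(P, f1, "AAA")
  e2 <- codonLikelihoods(P, f2, "AAA")
  expect_gt(e2[, codonIndices("CAA")], e1[, codonIndices("CAA")])
})

test_that("PCP log-likelihoods sum per-site logs", {
  nm <- neutralModel(uniformTable5)
  ## child == parent at t = 0 has probability 1
  pcp0 <- PCPSet("ATGAAA", "ATGAAA")
  expect_equal(pcpLogLikelihood(pcp0, nm, t = 0), 0)
  ## two-codon record equals the sum of the site logs computed by hand
  pcp <- PCPSet("AAAAAA", "CAAAAA")
  t <- 0.2
  q <- 1 - exp(-t)
  siteMut <- (q / 3) * (1 - q)^2          # AAA -> CAA
  ellWt <- function() {
    P <- codonProbabilities("AAA", rep(q, 3), matrix(1 / 3, 3, 4))
    1 - sum(P[-c(codonIndices("AAA"), dasm:::STOP_CODONS)])
  }
  expect_equal(pcpLogLikelihood(pcp, nm, t = t),
               log(siteMut) + log(ellWt()))
  ## a child stop codon has zero likelihood
  pcpStop <- PCPSet("AAAAAA", "TAAAAA")
  expect_identical(pcpLogLikelihood(pcpStop, nm, t = t), -Inf)
})

test_that("branch-length optimization recovers the closed-form optimum", {
  nm <- neutralModel(uniformTable5)
  t <- optimizeBranchLength(PCPSet("AAA", "AAC"), nm)
  expect_lt(abs(as.numeric(t) - log(3 / 2)), 1e-4)
  ## identical sequences drive t to the optimizer floor
  t0 <- optimizeBranchLength(PCPSet("ATGATG", "ATGATG"), nm)
  expect_lt(as.numeric(t0), 1e-5)
})

test_that("branch lengths are recovered from simulated divergence", {
  nm <- neutralModel(randomKmerRateTable(5, seed = 31))
  germ <- generateGermline(300, seed = 32)
  L <- nchar(germ) %/% 3
  fneu <- SelectionFactorMatrix(matrix(1, L, 20),
                                strsplit(translateNt(germ), "")[[1]])
  est <- vapply(1:20, function(i) {
    child <- simulatePcp(germ, nm, fneu, t = 0.05, seed = 40 + i)$child
    as.numeric(optimizeBranchLength(PCPSet(germ, child), nm))
  }, numeric(1))
  expect_gt(median(est), 0.03)
  expect_lt(median(est), 0.07)
})

test_that("amino-acid substitution probabilities aggregate the codon table", {
  nm <- neutralModel(uniformTable5)
  ssp <- siteSubstitutionProbabilities("AAA", nm, t = 0.3)
  P <- neutralCodonTable("AAA", uniformTable5, 0.3)
  ell <- codonLikelihoods(P, matrix(1, 1, 20), "AAA")
  for (a in seq_len(20)) {
    cods <- which(dasm:::CODON_AA_IDX == a)
    expect_equal(unname(ssp$dist[1, a]), sum(ell[1, cods]))
  }
  expect_equal(sum(ssp$dist[1, ]), 1)
  ## wild-type aggregation includes the synonymous codon AAG
  kcol <- match("K", aminoAcidAlphabet())
  expect_equal(ssp$substProb[1], unname(1 - ssp$dist[1, kcol]))
  ## at t = 0 the wild type has probability 1 everywhere
  ssp0 <- siteSubstitutionProbabilities("ATGAAA", nm, t = 0)
  expect_equal(ssp0$substProb, c(0, 0))
})

test_that("masked parent codons are excluded from likelihood sums", {
  nm <- neutralModel(uniformTable5)
  ll <- pcpLogLikelihood(PCPSet("ANAAAA", "ANAAAC"), nm, t = 0.1)
  llRef <- pcpLogLikelihood(PCPSet("AAA", "AAC"), nm, t = 0.1)
  expect_equal(ll, llRef)
})
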