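test_that("germline generation is reproducible, stop-free and uniform", {
  g1 <- generateGermline(10, seed = 1)
  g2 <- generateGermline(10, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, generateGermline(10, seed = 2)))
  big <- generateGermline(10000, seed = 3)
  idx <- codonIndices(big)
  expect_false(any(idx %in% dasm:::STOP_CODONS))
  ## chi-square against the uniform distribution over 61 sense codons
  tab <- tabulate(idx, nbins = 64)[dasm:::SENSE_CODONS]
  p <- stats::chisq.test(tab, p = rep(1 / 61, 61))$p.value
  expect_gt(p, 1e-3)
})

test_that("planted selection landscapes honour their specification", {
  refAa <- translateNt(generateGermline(200, seed = 4))
  wt <- strsplit(refAa, "")[[1]]
  allNeutral <- sampleSelectionLandscape(refAa, 1, 0, 0, seed = 5)
  expect_identical(unname(selectionFactors(allNeutral)),
                   matrix(1, 200, 20))
  land <- sampleSelectionLandscape(refAa, 0.5, 0.35, 0.15, seed = 6)
  f <- selectionFactors(land)
  wtIdx <- cbind(1:200, match(wt, aminoAcidAlphabet()))
  expect_true(all(f[wtIdx] == 1))
  offwt <- f[-(seq_len(200) + 200 * (match(wt, aminoAcidAlphabet()) - 1))]
  fracNeutral <- mean(offwt == 1)
  fracDel <- mean(offwt < 1)
  fracBen <- mean(offwt > 1)
  expect_lt(abs(fracNeutral - 0.5), 0.03)
  expect_lt(abs(fracDel - 0.35), 0.03)
  expect_lt(abs(fracBen - 0.15), 0.03)
  expect_true(all(offwt[offwt < 1] >= 0.02 - 1e-12))
  expect_true(all(offwt[offwt > 1] <= 4 + 1e-12))
  expect_error(sampleSelectionLandscape(refAa, 0.9, 0.3, 0.1), "sum to 1")
})

test_that("a zero branch length copies the parent", {
  germ <- generateGermline(20, seed = 7)
  fneu <- SelectionFactorMatrix(matrix(1, 20, 20),
                                strsplit(translateNt(germ), "")[[1]])
  sim <- simulatePcp(germ, neutralModel(uniformTable5), fneu, t = 0,
                     seed = 8)
  expect_identical(sim$child, germ)
  expect_equal(sim$logProb, 0)
})

test_that("strongly deleterious sites stay unsubstituted", {
  germ <- generateGermline(5, seed = 9)
  wt <- strsplit(translateNt(germ), "")[[1]]
  f <- matrix(1, 5, 20)
  f[3, ] <- 1e-6
  sf <- SelectionFactorMatrix(f, wt)
  nm <- neutralModel(uniformTable5)
  hits <- 0
  for (i in 1:500) {
    child <- simulatePcp(germ, nm, sf, t = 0.3, seed = 100 + i)$child
    subs <- aaSubstitutions(PCPSet(germ, child))
    hits <- hits + sum(subs$site == 2)
  }
  expect_equal(hits, 0)
})

test_that("neutral per-site substitution frequencies match the model", {
  germ <- generateGermline(200, seed = 10)
  L <- 200
  wt <- strsplit(translateNt(germ), "")[[1]]
  fneu <- SelectionFactorMatrix(matrix(1, L, 20), wt)
  nm <- neutralModel(randomKmerRateTable(5, seed = 11))
  t <- 0.15
  n <- 60
  mutated <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    child <- simulatePcp(germ, nm, fneu, t = t, seed = 200 + i)$child
    mutated[i, ] <- codonIndices(child) != codonIndices(germ)
  }
  P <- neutralCodonTable(germ, nm@table, t)
  ell <- codonLikelihoods(P, matrix(1, L, 20), germ)
  pMut <- 1 - ell[cbind(1:L, codonIndices(germ))]
  ## aggregate binomial check over all sites
  expObs <- n * sum(pMut)
  sdObs <- sqrt(sum(n * pMut * (1 - pMut)))
  expect_lt(abs(sum(mutated) - expObs), 4 * sdObs)
})

test_that("multihit coefficients shift the simulated hit-class spectrum", {
  germ <- generateGermline(150, seed = 12)
  wt <- strsplit(translateNt(germ), "")[[1]]
  fneu <- SelectionFactorMatrix(matrix(1, 150, 20), wt)
  hitFrac <- function(m2) {
    nm <- neutralModel(uniformTable5, MultihitCoefficients(1, m2, 1))
    twoHits <- 0; oneHits <- 0
    for (i in 1:30) {
      child <- simulatePcp(germ, nm, fneu, t = 0.15, seed = 300 + i)$child
      h <- dasm:::CODON_HAMMING[cbind(codonIndices(germ),
                                      codonIndices(child))]
      twoHits <- twoHits + sum(h == 2)
      oneHits <- oneHits + sum(h == 1)
    }
    twoHits / oneHits
  }
  expect_gt(hitFrac(8), 2 * hitFrac(1))
})

test_that("dataset simulation is reproducible and writes sidecars", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateDataset(30, nCodons = 20, seed = 13, outDir = d1)
  simulateDataset(30, nCodons = 20, seed = 13, outDir = d2)
  for (f in c("pcps.csv", "truth_selection_factors.csv",
              "truth_branch_lengths.csv", "truth_kmer_table.csv",
              "truth_multihit.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- readPcpTable(file.path(d1, "pcps.csv"))
  expect_equal(length(back), 30L)
  ## empty dataset still writes a header-only table
  d0 <- withr::local_tempdir()
  simulateDataset(0, nCodons = 20, seed = 14, outDir = d0)
  expect_equal(length(readPcpTable(file.path(d0, "pcps.csv"))), 0L)
})

test_that("mean substitution counts match the closed-form expectation", {
  germ <- generateGermline(100, seed = 15)
  nm <- neutralModel(randomKmerRateTable(5, seed = 16))
  sim <- simulateDataset(150, germline = germ, neutral = nm,
                         tMedian = 0.05, tSdlog = 0, seed = 17)
  P <- neutralCodonTable(germ, nm@table, 0.05)
  ell <- codonLikelihoods(P, matrix(1, 100, 20), germ)
  pMut <- 1 - ell[cbind(1:100, codonIndices(germ))]
  nSub <- vapply(seq_len(150), function(i)
    sum(codonIndices(childSeqs(sim$pcps)[i]) != codonIndices(germ)),
    numeric(1))
  se <- sqrt(sum(pMut * (1 - pMut)) / 150)
  expect_lt(abs(mean(nSub) - sum(pMut)), 3 * se)
})

test_that("the simulator's sampling log-probability is the model likelihood", {
  nm <- neutralModel(randomKmerRateTable(5, seed = 18),
                     MultihitCoefficients(1, 3, 9))
  germ <- generateGermline(40, seed = 19)
  land <- sampleSelectionLandscape(translateNt(germ), seed = 20)
  sim <- simulateDataset(25, germline = germ, neutral = nm,
                         factors = land, seed = 21)
  ll <- pcpLogLikelihood(sim$pcps, nm, factors = land)
  expect_identical(ll, sim$logProbs)
})
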