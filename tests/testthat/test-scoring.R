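test_that("perplexity closed forms", {
  n <- 5
  uni <- matrix(1 / 20, n, 20, dimnames = list(NULL, aminoAcidAlphabet()))
  expect_equal(perplexity(uni, "MKTAY"), 20)
  two <- matrix(0, 2, 20, dimnames = list(NULL, aminoAcidAlphabet()))
  two[1, ] <- c(0.5, rep(0.5 / 19, 19))
  two[2, ] <- c(0.25, rep(0.75 / 19, 19))
  expect_equal(perplexity(two, "AA"), sqrt(8))
  sure <- matrix(0, 3, 20, dimnames = list(NULL, aminoAcidAlphabet()))
  sure[, 1] <- 1
  expect_equal(perplexity(sure, "AAA"), 1)
  expect_warning(expect_identical(perplexity(sure, "AAC"), Inf), "zero")
})

test_that("pseudo-perplexity equals perplexity on identical series", {
  set.seed(5)
  s <- matrix(rexp(4 * 20), 4, 20)
  s <- s / rowSums(s)
  colnames(s) <- aminoAcidAlphabet()
  expect_identical(pseudoPerplexity(s, "MKTA"), perplexity(s, "MKTA"))
})

test_that("masked-marginals identity holds for single mutants", {
  set.seed(6)
  for (rep in 1:50) {
    n <- 3
    w <- paste0(sample(aminoAcidAlphabet(), n, replace = TRUE),
                collapse = "")
    s <- matrix(rexp(n * 20), n, 20)
    s <- s / rowSums(s)
    colnames(s) <- aminoAcidAlphabet()
    j <- sample(n, 1)
    wj <- substring(w, j, j)
    mut <- sample(setdiff(aminoAcidAlphabet(), wj), 1)
    x <- w
    substring(x, j, j) <- mut
    lhs <- log(s[j, mut]) - log(s[j, wj])
    rhs <- n * (log(mmPseudoPerplexity(s, w)) - log(mmPseudoPerplexity(s, x)))
    expect_lt(abs(lhs - rhs), 1e-12)
  }
})

test_that("masked-marginals of the wild type is its own pseudo-perplexity", {
  set.seed(7)
  s <- matrix(rexp(4 * 20), 4, 20)
  s <- s / rowSums(s)
  colnames(s) <- aminoAcidAlphabet()
  expect_identical(mmPseudoPerplexity(s, "MKTA"), perplexity(s, "MKTA"))
})

test_that("double mutants expand to the mean of per-site log-probs", {
  set.seed(8)
  s <- matrix(rexp(3 * 20), 3, 20)
  s <- s / rowSums(s)
  colnames(s) <- aminoAcidAlphabet()
  w <- "MKT"
  x <- "AKC"   # mutations at sites 1 and 3
  expected <- exp(-unname(log(s[1, "A"]) + log(s[2, "K"]) +
                            log(s[3, "C"])) / 3)
  expect_equal(mmPseudoPerplexity(s, x), expected)
})

test_that("conditional perplexity closed forms and invariance", {
  pcp <- PCPSet("ATGAAA", "ATGAAC")  # K -> N at site 1
  d <- matrix(0, 1, 20, dimnames = list(NULL, aminoAcidAlphabet()))
  d[1, "N"] <- 0.25
  d[1, setdiff(aminoAcidAlphabet(), c("N", "K"))] <- 0.75 / 18
  expect_equal(conditionalPerplexity(d, pcp), 4)
  dSure <- d * 0
  dSure[1, "N"] <- 1
  expect_equal(conditionalPerplexity(dSure, pcp), 1)
  ## two substitutions with conditional probs 0.5 and 0.125
  pcp2 <- PCPSet("AAAAAATGG", "AACAAATGC")  # K->N site 0, W->C site 2
  d2 <- matrix(0, 2, 20, dimnames = list(NULL, aminoAcidAlphabet()))
  d2[1, "N"] <- 0.5
  d2[1, setdiff(aminoAcidAlphabet(), c("N", "K"))] <- 0.5 / 18
  d2[2, "C"] <- 0.125
  d2[2, setdiff(aminoAcidAlphabet(), c("C", "W"))] <- 0.875 / 18
  expect_equal(conditionalPerplexity(d2, pcp2), 4)
  expect_error(conditionalPerplexity(d2, PCPSet("AAA", "AAA")),
               "undefined|substitution")
  ## conditional distributions must exclude the parent residue
  dBad <- d
  dBad[1, "K"] <- dBad[1, "N"]
  dBad[1, "N"] <- 0
  expect_error(conditionalPerplexity(dBad, pcp), "parent")
})

test_that("single-nucleotide accessibility matches exhaustive enumeration", {
  bases <- c("A", "C", "G", "T")
  for (codon in ALL_CODONS) {
    wt <- GENETIC_CODE_ORACLE[codon]
    if (wt == "*") next
    nb <- character(0)
    for (pos in 1:3) for (b in setdiff(bases, substring(codon, pos, pos))) {
      neighbor <- codon
      substring(neighbor, pos, pos) <- b
      nb <- c(nb, GENETIC_CODE_ORACLE[neighbor])
    }
    expected <- sort(setdiff(unique(nb), c("*", wt)))
    got <- singleNtAccessible(codon)
    expect_identical(got$single, expected)
    expect_identical(got$multi,
                     sort(setdiff(setdiff(aminoAcidAlphabet(), wt),
                                  expected)))
    expect_equal(length(got$single) + length(got$multi), 19L)
  }
  expect_equal(length(singleNtAccessible("AAA")$single), 6L)
  expect_error(singleNtAccessible("TAA"), "stop")
})

test_that("DMS scoring recovers planted correlations", {
  set.seed(31)
  refNt <- generateGermline(40, seed = 30)
  refAa <- strsplit(translateNt(refNt), "")[[1]]
  ## variants: every non-wild-type amino acid at every site
  grid <- expand.grid(site = 0:39, mut_aa = aminoAcidAlphabet(),
                      stringsAsFactors = FALSE)
  grid$wt_aa <- refAa[grid$site + 1]
  grid <- grid[grid$mut_aa != grid$wt_aa, ]
  lf <- rnorm(nrow(grid))
  f <- matrix(1, 40, 20)
  f[cbind(grid$site + 1, match(grid$mut_aa, aminoAcidAlphabet()))] <- exp(lf)
  sf <- SelectionFactorMatrix(f, refAa)
  grid$measurement <- lf
  res <- scoreDmsSingle(sf, grid, parentNt = refNt)
  expect_equal(res$r, 1)
  ## permuted measurements: correlation collapses
  gridNull <- grid
  gridNull$measurement <- sample(gridNull$measurement)
  big <- gridNull[sample(nrow(gridNull), 10000, replace = TRUE), ]
  expect_lt(abs(scoreDmsSingle(sf, big)$r), 0.05)
  ## stratified counts equal the accessibility partition sizes
  nSingle <- sum(vapply(0:39, function(s)
    length(singleNtAccessible(codonIndices(refNt)[s + 1])$single),
    integer(1)))
  expect_equal(sum(res$scores$accessibility == "single"), nSingle)
  expect_equal(sum(res$scores$accessibility == "multi"),
               19 * 40 - nSingle)
  ## substitutions to wild type are excluded with a warning
  withWt <- rbind(grid, data.frame(site = 0, mut_aa = refAa[1],
                                   wt_aa = refAa[1], measurement = 0))
  expect_warning(res2 <- scoreDmsSingle(sf, withWt), "wild type")
  expect_equal(nrow(res2$scores), nrow(grid))
})

test_that("consensus takes the site-wise majority with alphabetical ties", {
  expect_identical(consensusSequence(c("AR", "AK", "AR")), "AR")
  expect_identical(consensusSequence("MKTA"), "MKTA")
  expect_identical(consensusSequence(c("AK", "AR")), "AK")
  expect_error(consensusSequence(c("AK", "AKR")), "length")
})

test_that("multi-mutant scores sum log factors over differing sites", {
  refAa <- c("M", "K", "T")
  f <- matrix(1, 3, 20)
  f[2, match("R", aminoAcidAlphabet())] <- 2
  f[3, match("S", aminoAcidAlphabet())] <- 0.5
  sf <- SelectionFactorMatrix(f, refAa)
  expect_equal(scoreVariantMulti(sf, "MKT"), 0)
  expect_equal(scoreVariantMulti(sf, "MRS"), log(2) + log(0.5))
  f2 <- matrix(1, 3, 20)
  f2[1, match("A", aminoAcidAlphabet())] <- exp(1)
  expect_equal(scoreVariantMulti(SelectionFactorMatrix(f2, refAa), "AKT"), 1)
  expect_error(scoreVariantMulti(sf, "MK"), "length")
})

test_that("replicate aggregation averages logs and filters on linear CV", {
  rec <- data.frame(variant = c("v1", "v1", "v2", "v2", "v3", "v3", "v3"),
                    log10_value = c(-8, -6, -5, -5, log10(1e-6),
                                    log10(9e-6), log10(2e-5)),
                    replicate = c(1, 2, 1, 2, 1, 2, 3))
  ## aggregation arithmetic: mean of logs (geometric mean linearly)
  all_ <- aggregateReplicates(rec, cvMax = Inf)
  expect_equal(
    all_$aggregated$log10_value[all_$aggregated$variant == "v1"], -7)
  ## identical replicates have CV 0 and are kept; v1's linear CV
  ## (1e-8 vs 1e-6) and v3's (sd/mean of 1e-6, 9e-6, 2e-5, about 0.95)
  ## both exceed 0.5 and are removed
  out <- aggregateReplicates(rec)
  expect_identical(out$aggregated$variant, "v2")
  expect_equal(out$aggregated$cv, 0)
  expect_equal(out$kept, 1)
  expect_equal(out$removed, 2)
  rec$log10_value[1] <- NA
  expect_error(aggregateReplicates(rec), "positive|finite")
})
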