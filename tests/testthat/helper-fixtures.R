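## Shared fixtures. The hard-coded genetic code below is an independent
## oracle (typed in directly from the standard code), never derived from
## the package's tables.

GENETIC_CODE_ORACLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

ALL_CODONS <- as.vector(outer(as.vector(outer(c("A","C","G","T"),
                                              c("A","C","G","T"), paste0)),
                              c("A","C","G","T"), paste0))

uniformTable5 <- uniformKmerRateTable(5L)

tinyDasmConfig <- DasmConfig(layers = 2L, heads = 2L, headDim = 4L,
                             ffDim = 16L, dropout = 0)

## Random per-position inputs for one codon site.
randomSiteInputs <- function() {
  p <- runif(3)
  csp <- matrix(runif(12), 3, 4)
  csp <- csp / rowSums(csp)
  list(p = p, csp = csp)
}

## Brute-force oracle: enumerate the 64 outcomes one by one with scalar
## arithmetic, never reusing the package's vectorized path.
bruteForceCodonProbs <- function(parentCodon, p, csp) {
  bases <- c("A", "C", "G", "T")
  pb <- strsplit(parentCodon, "")[[1]]
  out <- numeric(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    pr <- 1
    for (pos in 1:3) {
      b <- c(b1, b2, b3)[pos]
      pr <- pr * if (b == pb[pos]) (1 - p[pos]) else
        p[pos] * csp[pos, match(b, bases)]
    }
    out[k] <- pr
  }
  ## b1 varies slowest, b3 fastest: already lexicographic codon order
  out
}
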