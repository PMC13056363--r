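#' @import methods
#' @importFrom stats optim optimize rnorm runif rlnorm sd cor median setNames
#' @importFrom utils read.csv write.csv head
NULL

## Internal alphabets and codon tables. Codons are indexed 1..64 in
## lexicographic order over A < C < G < T, so codon index
## = 16*(b1-1) + 4*(b2-1) + b3 with bases coded A=1, C=2, G=3, T=4.

NT_ALPHABET <- c("A", "C", "G", "T")

#' Canonical amino-acid alphabet
#'
#' The 20 amino acids in alphabetical one-letter-code order. This ordering
#' fixes the column order of every per-site selection-factor and
#' probability matrix in the package.
#'
#' @return Character vector of length 20.
#' @export
aminoAcidAlphabet <- function() AA_ALPHABET

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## 64 x 3 integer matrix of base codes for each codon, lexicographic A,C,G,T
CODON_BASES <- cbind(
  (seq_len(64) - 1L) %/% 16L + 1L,
  ((seq_len(64) - 1L) %/% 4L) %% 4L + 1L,
  (seq_len(64) - 1L) %% 4L + 1L
)

CODON_STRS <- apply(CODON_BASES, 1L, function(b)
  paste0(NT_ALPHABET[b], collapse = ""))

## Translation table: codon index -> one-letter amino acid ("*" for stop),
## sourced from the canonical genetic code shipped with Biostrings.
CODON_AA <- {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[CODON_STRS])
}

STOP_CODONS <- which(CODON_AA == "*")          # TAA, TAG, TGA
SENSE_CODONS <- which(CODON_AA != "*")
## codon index -> column 1..20 in AA_ALPHABET order; NA for stops
CODON_AA_IDX <- match(CODON_AA, AA_ALPHABET)

## 64 x 64 nucleotide Hamming distance between codons (0..3)
CODON_HAMMING <- {
  h <- matrix(0L, 64, 64)
  for (k in 1:3) h <- h + outer(CODON_BASES[, k], CODON_BASES[, k], "!=")
  storage.mode(h) <- "integer"
  h
}

#' Map codons to integer indices
#'
#' Codons are indexed 1..64 lexicographically over the alphabet A, C, G, T.
#' Codons containing characters outside \{A,C,G,T\} (for example N) map to
#' `NA` and are treated as masked downstream.
#'
#' @param seq A single in-frame nucleotide sequence string.
#' @return Integer vector of codon indices (one per codon), `NA` where the
#'   codon contains an ambiguous base.
#' @export
codonIndices <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3 (frame violation)")
  if (n == 0L) return(integer(0))
  b <- match(strsplit(seq, "")[[1]], NT_ALPHABET)
  b <- matrix(b, ncol = 3, byrow = TRUE)
  idx <- 16L * (b[, 1] - 1L) + 4L * (b[, 2] - 1L) + b[, 3]
  idx[!stats::complete.cases(b)] <- NA_integer_
  idx
}

#' Decode codon indices back to a nucleotide string
#' @param idx Integer vector of codon indices in 1..64.
#' @return Nucleotide sequence string.
#' @export
codonString <- function(idx) {
  stopifnot(all(is.na(idx) | (idx >= 1 & idx <= 64)))
  out <- CODON_STRS[idx]
  out[is.na(idx)] <- "NNN"
  paste0(out, collapse = "")
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard genetic code. Codons containing ambiguous bases translate to
#' `X`; the three stop codons translate to `*`.
#'
#' @param seq Nucleotide sequence string, length divisible by 3.
#' @return Amino-acid string of length `nchar(seq)/3`.
#' @export
translateNt <- function(seq) {
  idx <- codonIndices(seq)
  aa <- CODON_AA[idx]
  aa[is.na(idx)] <- "X"
  paste0(aa, collapse = "")
}

#' Amino-acid sequence of a parent codon-index vector (internal)
#' @noRd
aaOfCodons <- function(idx) {
  aa <- CODON_AA[idx]
  aa[is.na(idx)] <- "X"
  aa
}
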