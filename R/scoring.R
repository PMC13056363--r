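## Evaluation statistics: the perplexity family, codon-accessibility
## diagnostics, deep-mutational-scan and multi-mutant variant scoring,
## consensus building, and replicate aggregation with CV filtering.

checkSeries <- function(series, n = NULL) {
  if (!is.matrix(series)) stop("series must be a positions x alphabet matrix")
  if (any(abs(rowSums(series) - 1) > 1e-9))
    stop("each per-position distribution must sum to 1")
  if (!is.null(n) && nrow(series) != n)
    stop("series length ", nrow(series), " does not match sequence length ", n)
  invisible(TRUE)
}

seriesProbs <- function(series, observed) {
  aa <- strsplit(observed, "")[[1]]
  checkSeries(series, length(aa))
  cols <- if (!is.null(colnames(series)))
    match(aa, colnames(series)) else match(aa, AA_ALPHABET)
  if (anyNA(cols)) stop("observed token outside the series alphabet")
  series[cbind(seq_along(aa), cols)]
}

#' Perplexity of an observed sequence under per-position distributions
#'
#' The across-site geometric mean of the inverse probability of each
#' observed token: `exp(-(1/n) * sum(log p(x_i)))`. Interpretable as the
#' effective number of tokens the model considers plausible per position.
#'
#' @param series `n x alphabet` matrix of per-position probabilities
#'   (rows sum to 1; columns named, default amino-acid alphabet).
#' @param observed Observed sequence string of length `n`.
#' @return Perplexity (>= 1); `Inf` with a warning if an observed token
#'   has zero probability.
#' @export
perplexity <- function(series, observed) {
  p <- seriesProbs(series, observed)
  if (any(p == 0)) {
    warning("observed token with zero probability; perplexity is Inf")
    return(Inf)
  }
  exp(-mean(log(p)))
}

#' Pseudo-perplexity from mask-conditioned distributions
#'
#' Identical aggregation to [perplexity()], applied to per-position
#' probabilities conditioned on all *other* tokens (`p(x_i | x_{-i})`),
#' as produced by masked (encoder-only) models. The caller supplies the
#' mask-conditioned series; this operation is the aggregation.
#'
#' @inheritParams perplexity
#' @return Pseudo-perplexity (>= 1).
#' @export
pseudoPerplexity <- function(series, observed) perplexity(series, observed)

#' Masked-marginals pseudo-perplexity
#'
#' Scores any variant using per-position probabilities computed once in
#' wild-type context: `exp(-(1/n) * sum(log p(x_i | w_{-i})))`. For a
#' single-mutation variant, the log-probability difference between the
#' variant and wild-type amino acids equals `n` times the difference in
#' log masked-marginals pseudo-perplexities (an additive-constant
#' identity used for variant ranking).
#'
#' @param wtSeries `n x alphabet` matrix of wild-type-context
#'   probabilities `p(a | w_{-i})` for all amino acids at each position.
#' @param variant Variant sequence string of length `n`.
#' @return Masked-marginals pseudo-perplexity.
#' @export
mmPseudoPerplexity <- function(wtSeries, variant) perplexity(wtSeries, variant)

#' Conditional perplexity over substituted sites
#'
#' For a parent-child pair differing at amino-acid sites `S`, the
#' perplexity of the child residues at those sites under per-site
#' distributions conditioned on a substitution occurring (mass on the 19
#' non-parent amino acids).
#'
#' @param substDists Matrix (`|S| x alphabet`, rows aligned to the
#'   substituted sites in ascending site order) of conditional
#'   distributions; each row must exclude the parent residue and sum
#'   to 1.
#' @param pcps,i A [PCPSet-class] and record index with at least one
#'   amino-acid substitution.
#' @return Conditional perplexity.
#' @export
conditionalPerplexity <- function(substDists, pcps, i = 1L) {
  subs <- aaSubstitutions(pcps, i)
  if (nrow(subs) == 0L)
    stop("conditional perplexity is undefined without substitutions")
  checkSeries(substDists, nrow(subs))
  cols <- if (!is.null(colnames(substDists)))
    match(subs$child_aa, colnames(substDists))
  else match(subs$child_aa, AA_ALPHABET)
  parentCols <- if (!is.null(colnames(substDists)))
    match(subs$parent_aa, colnames(substDists))
  else match(subs$parent_aa, AA_ALPHABET)
  if (any(substDists[cbind(seq_len(nrow(subs)), parentCols)] > 1e-9))
    stop("conditional distributions must exclude the parent amino acid")
  p <- substDists[cbind(seq_len(nrow(subs)), cols)]
  exp(-mean(log(p)))
}

#' DASM-derived conditional substitution distributions for a PCP
#'
#' At each substituted site, the per-amino-acid substitution
#' probabilities from [siteSubstitutionProbabilities()] renormalized over
#' the non-parent amino acids — the model's prediction of *which* residue
#' appears given that a substitution happened.
#'
#' @param pcps,i A [PCPSet-class] and record index.
#' @param neutral A [NeutralModel-class].
#' @param model A [DasmModel-class].
#' @param t Branch length (defaults to the stored value).
#' @return `|S| x 20` matrix suitable for [conditionalPerplexity()].
#' @export
dasmConditionalDists <- function(pcps, neutral, model, i = 1L, t = NULL) {
  if (is.null(t)) t <- branchLengths(pcps)[i]
  subs <- aaSubstitutions(pcps, i)
  if (nrow(subs) == 0L) stop("record has no amino-acid substitutions")
  ssp <- siteSubstitutionProbabilities(pcps@parent[i], neutral, t,
                                       model = model,
                                       chainLayout = pcps@chainLayout[i])
  rows <- subs$site + 1L
  d <- ssp$dist[rows, , drop = FALSE]
  d[cbind(seq_len(nrow(d)), match(subs$parent_aa, AA_ALPHABET))] <- 0
  d / rowSums(d)
}

#' Single-nucleotide accessibility partition
#'
#' Splits the 19 alternative amino acids at a codon into those encodable
#' by a codon one nucleotide change away from the parent codon and those
#' requiring multiple nucleotide changes (stop codons excluded).
#'
#' @param parentCodon Codon string or index (sense, unambiguous).
#' @return List with character vectors `single` and `multi`; the two sets
#'   are disjoint and together cover all 19 alternatives.
#' @export
singleNtAccessible <- function(parentCodon) {
  if (is.character(parentCodon)) parentCodon <- codonIndices(parentCodon)
  if (is.na(parentCodon)) stop("ambiguous parent codon")
  if (parentCodon %in% STOP_CODONS) stop("stop parent codon")
  wt <- CODON_AA[parentCodon]
  nbr <- which(CODON_HAMMING[parentCodon, ] == 1L)
  aa <- setdiff(unique(CODON_AA[nbr]), c("*", wt))
  alt <- setdiff(AA_ALPHABET, wt)
  list(single = sort(aa), multi = sort(setdiff(alt, aa)))
}

#' Score single-substitution DMS variants with selection factors
#'
#' Each variant's score is the log selection factor of its substitution;
#' scores are compared with the measurements by Pearson correlation,
#' optionally stratified by single- vs multi-nucleotide codon
#' accessibility of the substitution (which requires the parent
#' nucleotide sequence).
#'
#' @param factors A [SelectionFactorMatrix-class] on the reference.
#' @param variants Data frame with columns `site` (0-based amino-acid
#'   site), `wt_aa`, `mut_aa`, `measurement` (e.g. log enrichment).
#' @param parentNt Optional reference nucleotide sequence enabling the
#'   accessibility stratification.
#' @return List with `scores` (the variant table plus `log_selection`
#'   and, when stratified, `accessibility`), `r` (Pearson correlation on
#'   complete pairs), and per-stratum correlations `rSingle`/`rMulti`
#'   when stratified.
#' @export
scoreDmsSingle <- function(factors, variants, parentNt = NULL) {
  need <- c("site", "wt_aa", "mut_aa", "measurement")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  wt <- wildTypeAa(factors)
  bad <- variants$wt_aa != wt[variants$site + 1L]
  if (any(bad))
    stop("variant wild-type residue disagrees with the reference at site(s) ",
         paste(unique(variants$site[bad]), collapse = ", "))
  self <- variants$mut_aa == variants$wt_aa
  if (any(self)) {
    warning(sum(self), " substitution(s) to wild type excluded")
    variants <- variants[!self, , drop = FALSE]
  }
  f <- selectionFactors(factors)
  variants$log_selection <-
    log(f[cbind(variants$site + 1L, match(variants$mut_aa, AA_ALPHABET))])
  cc <- stats::complete.cases(variants$log_selection, variants$measurement)
  out <- list(scores = variants,
              r = stats::cor(variants$log_selection[cc],
                             variants$measurement[cc]))
  if (!is.null(parentNt)) {
    pidx <- codonIndices(parentNt)
    acc <- vapply(seq_len(nrow(variants)), function(k) {
      part <- singleNtAccessible(pidx[variants$site[k] + 1L])
      if (variants$mut_aa[k] %in% part$single) "single" else "multi"
    }, "")
    out$scores$accessibility <- acc
    for (s in c("single", "multi")) {
      sel <- cc & acc == s
      out[[paste0("r", toupper(substring(s, 1, 1)),
                  substring(s, 2))]] <-
        if (sum(sel) >= 3) stats::cor(variants$log_selection[sel],
                                      variants$measurement[sel]) else NA_real_
    }
  }
  out
}

#' Site-wise consensus of equal-length amino-acid sequences
#'
#' Per site, the most frequent residue; ties broken alphabetically.
#'
#' @param seqs Character vector of equal-length amino-acid sequences.
#' @return Consensus sequence string.
#' @export
consensusSequence <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences")
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences have unequal lengths")
  m <- do.call(rbind, strsplit(seqs, ""))
  paste0(apply(m, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]   # ties: first name, i.e. alphabetical
  }), collapse = "")
}

#' Score a multi-mutant variant against a reference
#'
#' Sum of log selection factors at the sites where the variant differs
#' from the reference; 0 for the reference itself.
#'
#' @param factors A [SelectionFactorMatrix-class] on the reference
#'   (typically a consensus sequence).
#' @param variant Variant amino-acid sequence, same length as the
#'   reference.
#' @return Aggregate log selection factor.
#' @export
scoreVariantMulti <- function(factors, variant) {
  ref <- wildTypeAa(factors)
  va <- strsplit(variant, "")[[1]]
  if (length(va) != length(ref))
    stop("variant length ", length(va), " != reference length ", length(ref))
  diff <- which(va != ref)
  if (!length(diff)) return(0)
  f <- selectionFactors(factors)
  sum(log(f[cbind(diff, match(va[diff], AA_ALPHABET))]))
}

#' Aggregate replicate measurements with CV filtering
#'
#' Replicate measurements on a log10 scale are aggregated by the mean of
#' logs (the geometric mean on the linear scale); variants whose
#' linear-scale coefficient of variation (sd/mean across replicates)
#' exceeds `cvMax` are removed.
#'
#' @param records Data frame with columns `variant`, `log10_value`,
#'   `replicate`.
#' @param cvMax CV threshold (default 0.5).
#' @return List with `aggregated` (data frame `variant`, `log10_value`,
#'   `n_replicates`, `cv`), `kept` and `removed` counts.
#' @export
aggregateReplicates <- function(records, cvMax = 0.5) {
  need <- c("variant", "log10_value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("replicate table missing column(s): ", paste(miss, collapse = ", "))
  lin <- 10^records$log10_value
  if (any(!is.finite(lin) | lin <= 0))
    stop("linear-scale values must be positive and finite")
  sp <- split(seq_len(nrow(records)), records$variant)
  agg <- do.call(rbind, lapply(names(sp), function(v) {
    rows <- sp[[v]]
    x <- lin[rows]
    cv <- if (length(x) > 1L) stats::sd(x) / mean(x) else 0
    data.frame(variant = v,
               log10_value = mean(records$log10_value[rows]),
               n_replicates = length(x), cv = cv,
               stringsAsFactors = FALSE)
  }))
  keep <- agg$cv <= cvMax
  list(aggregated = agg[keep, , drop = FALSE],
       kept = sum(keep), removed = sum(!keep))
}
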