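## Parent-child pair (PCP) container and validators.
##
## A PCP is one edge of a reconstructed B-cell lineage tree: two aligned,
## gap-free, in-frame nucleotide sequences (parent X, child Y) plus a chain
## layout for paired heavy/light records and an optimizable branch length t
## (expected neutral substitutions per site). Coordinates are 0-based codon
## sites at all I/O edges.

#' PCPSet: a collection of parent-child sequence pairs
#'
#' Holds aligned in-frame parent/child nucleotide sequences with per-record
#' chain layouts and branch lengths. Paired heavy/light records are stored
#' as a single heavy-then-light concatenation with an explicit layout (for
#' example `"H:336,L:321"`, nucleotide run lengths), so one PCP is one
#' training example.
#'
#' @slot id character, record identifiers.
#' @slot parent character, parent nucleotide sequences.
#' @slot child character, child nucleotide sequences.
#' @slot chainLayout character, run-length encoded chain labels
#'   (`"H:<nt>,L:<nt>"`); `""` means all-heavy.
#' @slot branchLength numeric, expected neutral substitutions per site;
#'   `NA` until optimized.
#' @export
setClass("PCPSet", representation(
  id = "character",
  parent = "character",
  child = "character",
  chainLayout = "character",
  branchLength = "numeric"
))

setValidity("PCPSet", function(object) {
  n <- length(object@id)
  if (length(object@parent) != n || length(object@child) != n ||
      length(object@chainLayout) != n || length(object@branchLength) != n)
    return("slot lengths differ")
  msg <- validatePcpRecords(object@parent, object@child, object@chainLayout)
  bad <- which(!is.na(msg))
  if (length(bad))
    return(sprintf("record %s (%s): %s", bad[1], object@id[bad[1]], msg[bad[1]]))
  if (any(!is.na(object@branchLength) & object@branchLength < 0))
    return("negative branch length")
  TRUE
})

## Per-record validation; returns NA (ok) or a reason string per record.
validatePcpRecords <- function(parent, child, chainLayout) {
  parent <- toupper(parent); child <- toupper(child)
  np <- nchar(parent); nc <- nchar(child)
  reason <- rep(NA_character_, length(parent))
  reason[np != nc] <- "parent/child length mismatch"
  ok <- is.na(reason)
  reason[ok & np %% 3L != 0L] <- "length not divisible by 3 (frame violation)"
  ok <- is.na(reason)
  badalpha <- ok & (grepl("[^ACGTN]", parent) | grepl("[^ACGTN]", child))
  reason[badalpha] <- "invalid nucleotide character"
  ok <- is.na(reason)
  for (i in which(ok & chainLayout != "")) {
    reason[i] <- tryCatch({
      parseChainLayout(chainLayout[i], np[i])
      NA_character_
    }, error = function(e) conditionMessage(e))
  }
  reason
}

#' Construct a PCPSet
#'
#' @param parent,child Character vectors of aligned in-frame nucleotide
#'   sequences (equal lengths within a record, gap-free).
#' @param id Record identifiers; defaults to `pcp1, pcp2, ...`.
#' @param chainLayout Run-length chain labels per record
#'   (`"H:336,L:321"`); `""` (default) means all-heavy.
#' @param branchLength Optional numeric branch lengths.
#' @return A validated [PCPSet-class] object.
#' @examples
#' pcps <- PCPSet(parent = "ATGAAA", child = "ATGAAC")
#' aaSubstitutions(pcps)
#' @export
PCPSet <- function(parent, child, id = NULL, chainLayout = "",
                   branchLength = NA_real_) {
  n <- length(parent)
  if (is.null(id))
    id <- if (n == 0L) character(0) else paste0("pcp", seq_len(n))
  new("PCPSet",
      id = as.character(id),
      parent = toupper(as.character(parent)),
      child = toupper(as.character(child)),
      chainLayout = rep_len(as.character(chainLayout), n),
      branchLength = rep_len(as.numeric(branchLength), n))
}

#' @describeIn PCPSet-class number of PCP records
#' @param x A `PCPSet`.
#' @export
setMethod("length", "PCPSet", function(x) length(x@id))

#' @describeIn PCPSet-class subset records
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "PCPSet", function(x, i, j, ..., drop = FALSE) {
  new("PCPSet", id = x@id[i], parent = x@parent[i], child = x@child[i],
      chainLayout = x@chainLayout[i], branchLength = x@branchLength[i])
})

setMethod("show", "PCPSet", function(object) {
  cat("PCPSet with", length(object), "parent-child pairs\n")
  if (length(object)) {
    nnt <- nchar(object@parent)
    cat("  nt length range:", min(nnt), "-", max(nnt), "\n")
    cat("  paired records:", sum(grepl("L:", object@chainLayout)), "\n")
    cat("  branch lengths set:", sum(!is.na(object@branchLength)), "\n")
  }
})

#' @rdname pcp-accessors
#' @param x A [PCPSet-class].
#' @return Character or numeric vectors aligned to the records.
#' @export
pcpIds <- function(x) x@id
#' Accessors for PCPSet slots
#' @rdname pcp-accessors
#' @export
parentSeqs <- function(x) x@parent
#' @rdname pcp-accessors
#' @export
childSeqs <- function(x) x@child
#' @rdname pcp-accessors
#' @export
chainLayouts <- function(x) x@chainLayout
#' @rdname pcp-accessors
#' @export
branchLengths <- function(x) x@branchLength
#' @rdname pcp-accessors
#' @param value Replacement branch lengths.
#' @export
`branchLengths<-` <- function(x, value) {
  x@branchLength <- rep_len(as.numeric(value), length(x))
  methods::validObject(x)
  x
}

#' Parse a run-length chain layout into per-nucleotide labels
#'
#' @param layout Layout string, e.g. `"H:336,L:321"`; `""` means all heavy.
#' @param ntLength Total nucleotide length the layout must cover.
#' @return Character vector of `"H"`/`"L"` of length `ntLength`.
#' @export
parseChainLayout <- function(layout, ntLength) {
  if (is.na(layout) || layout == "")
    return(rep("H", ntLength))
  parts <- strsplit(layout, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([HL]):([0-9]+)$", parts))
  if (any(lengths(m) != 3))
    stop("malformed chain layout: ", layout)
  lab <- vapply(m, `[`, "", 2)
  len <- as.integer(vapply(m, `[`, "", 3))
  if (any(len %% 3L != 0L))
    stop("chain segment length not divisible by 3 in layout: ", layout)
  if (sum(len) != ntLength)
    stop("chain layout covers ", sum(len), " nt but sequence has ", ntLength)
  rep(lab, len)
}

## Per-codon chain labels for one record.
codonChainLabels <- function(layout, ntLength) {
  parseChainLayout(layout, ntLength)[seq(1L, ntLength, by = 3L)]
}

#' Read a PCP table from CSV
#'
#' Expects a header with columns `parent_nt` and `child_nt`, optionally
#' `id`, `chain_layout` and `branch_length`. Records violating the PCP
#' invariants (length mismatch, frame violation, bad alphabet or layout)
#' are dropped and reported; record order is preserved.
#'
#' @param path CSV file path.
#' @return A [PCPSet-class]; rejected rows are attached as a data frame in
#'   `attr(, "rejected")` with columns `id` and `reason`.
#' @export
readPcpTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("parent_nt", "child_nt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PCP table is missing column(s): ", paste(miss, collapse = ", "))
  id <- if ("id" %in% names(df)) df$id else if (nrow(df) == 0L)
    character(0) else paste0("pcp", seq_len(nrow(df)))
  lay <- if ("chain_layout" %in% names(df)) df$chain_layout else
    rep("", nrow(df))
  lay[is.na(lay)] <- ""
  bl <- if ("branch_length" %in% names(df))
    suppressWarnings(as.numeric(df$branch_length)) else
    rep(NA_real_, nrow(df))
  parent <- toupper(df$parent_nt); child <- toupper(df$child_nt)
  reason <- validatePcpRecords(parent, child, lay)
  keep <- is.na(reason)
  rejected <- data.frame(id = id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(nrow(rejected), " record(s) rejected; see attr(x, 'rejected')")
  out <- new("PCPSet", id = id[keep], parent = parent[keep],
             child = child[keep], chainLayout = lay[keep],
             branchLength = bl[keep])
  attr(out, "rejected") <- rejected
  out
}

#' Write a PCPSet to CSV
#'
#' Inverse of [readPcpTable()]: the round trip reproduces all fields.
#'
#' @param x A [PCPSet-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePcpTable <- function(x, path) {
  bl <- ifelse(is.na(x@branchLength), "",
               sprintf("%.17g", x@branchLength))  # full double precision
  df <- data.frame(id = x@id, parent_nt = x@parent, child_nt = x@child,
                   chain_layout = x@chainLayout, branch_length = bl,
                   stringsAsFactors = FALSE)
  ## chain layouts contain commas, so character fields are quoted
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read reference/germline nucleotide sequences from FASTA
#'
#' @param path Multi-FASTA file of nucleotide sequences.
#' @return Named character vector of uppercase sequences.
#' @export
readReferenceFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Productivity validation
#'
#' A sequence is productive if it contains no in-frame stop codon and every
#' configured conserved position encodes cysteine. Position numbering
#' schemes are configuration: `conservedPositions` are 0-based codon sites.
#'
#' @param seq In-frame nucleotide sequence string.
#' @param conservedPositions Integer vector of 0-based codon sites that
#'   must encode the signature cysteines (default none).
#' @return Logical scalar; failure reasons in `attr(, "reasons")`.
#' @examples
#' validateProductive("TGTAAA", conservedPositions = 0)  # TRUE, TGT = Cys
#' @export
validateProductive <- function(seq, conservedPositions = integer(0)) {
  idx <- codonIndices(seq)
  L <- length(idx)
  if (length(conservedPositions) &&
      (any(conservedPositions < 0) || any(conservedPositions >= L)))
    stop("conserved position out of range for ", L, " codons")
  reasons <- character(0)
  if (any(idx %in% STOP_CODONS))
    reasons <- c(reasons, "stop codon")
  if (length(conservedPositions)) {
    aa <- aaOfCodons(idx)[conservedPositions + 1L]
    if (any(aa != "C"))
      reasons <- c(reasons, "conserved cysteine mutated")
  }
  structure(length(reasons) == 0L, reasons = reasons)
}

#' Amino-acid substitutions between parent and child
#'
#' Lists the amino-acid sites at which the translated parent and child
#' differ, ascending by site. Synonymous codon changes do not appear.
#' Sites where either codon is ambiguous (contains N) are skipped.
#'
#' @param pcps A [PCPSet-class].
#' @param i Record index (default 1).
#' @return Data frame with columns `site` (0-based amino-acid site),
#'   `parent_aa`, `child_aa`.
#' @export
aaSubstitutions <- function(pcps, i = 1L) {
  pi <- codonIndices(pcps@parent[i])
  ci <- codonIndices(pcps@child[i])
  pa <- CODON_AA[pi]; ca <- CODON_AA[ci]
  keep <- !is.na(pi) & !is.na(ci) & pa != ca
  data.frame(site = which(keep) - 1L, parent_aa = pa[keep],
             child_aa = ca[keep], stringsAsFactors = FALSE)
}
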