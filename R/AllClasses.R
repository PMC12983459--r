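#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib psmb8typer, .registration = TRUE
NULL

#' Scoring scheme for protein alignment
#'
#' A substitution matrix plus affine gap penalties. A gap of length \eqn{L}
#' scores \code{gapOpen + (L - 1) * gapExtend}; both penalties are negative
#' and \code{gapOpen <= gapExtend}.
#'
#' @slot matrix symmetric integer substitution matrix with identical row and
#'   column names (amino-acid one-letter codes).
#' @slot gapOpen negative number, score of the first residue of a gap.
#' @slot gapExtend negative number, score of each subsequent gap residue.
#'
#' @seealso [scoringScheme()], [blosum62Scheme()]
#' @export
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "numeric", gapExtend = "numeric"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    return("substitution matrix must have identical row and column names")
  if (!isTRUE(all.equal(m, t(m))))
    return("substitution matrix must be symmetric")
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend < 0))
    return("gap penalties must satisfy gapOpen <= gapExtend < 0")
  TRUE
})

#' Pairwise protein alignment
#'
#' Result of a global (Needleman–Wunsch) or local (Smith–Waterman) alignment
#' with affine gap penalties. `aSpan`/`bSpan` give the 0-based, half-open
#' ranges of the ungapped sequences covered by the alignment rows (for global
#' alignments these span the full sequences).
#'
#' @slot aId,bId sequence identifiers.
#' @slot aRow,bRow equal-length gapped alignment rows (gap = \code{-}).
#' @slot score alignment score.
#' @slot mode `"global"` or `"local"`.
#' @slot aSpan,bSpan integer length-2 vectors `c(start, end)`, 0-based
#'   half-open coordinates on the ungapped sequences.
#'
#' @seealso [pairwiseAlign()], [percentIdentity()], [mapRefPosition()]
#' @export
setClass("PairAlignment",
  representation(aId = "character", bId = "character",
                 aRow = "character", bRow = "character",
                 score = "numeric", mode = "character",
                 aSpan = "integer", bSpan = "integer"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@aRow) != nchar(object@bRow))
    return("alignment rows must have equal length")
  a <- strsplit(object@aRow, "")[[1]]
  b <- strsplit(object@bRow, "")[[1]]
  if (any(a == "-" & b == "-"))
    return("alignment must not contain gap/gap columns")
  if (!object@mode %in% c("global", "local"))
    return("mode must be 'global' or 'local'")
  TRUE
})

#' Multiple sequence alignment
#'
#' Ordered, equal-length gapped rows. Degapping each row recovers the input
#' sequence it was built from.
#'
#' @slot ids sequence identifiers, unique.
#' @slot rows gapped rows, same order and length as `ids`.
#'
#' @seealso [progressiveMsa()], [writeMsaFasta()], [distanceMatrix()]
#' @export
setClass("Msa",
  representation(ids = "character", rows = "character"))

setValidity("Msa", function(object) {
  if (length(object@ids) != length(object@rows))
    return("ids and rows must have equal length")
  if (anyDuplicated(object@ids))
    return("duplicate sequence ids in alignment")
  if (length(object@rows) && length(unique(nchar(object@rows))) != 1L)
    return("all alignment rows must have equal length")
  TRUE
})

#' Mature-protein coordinate map
#'
#' Links a precursor protein to mature-protein numbering. The mature protein
#' starts at the conserved TTTL motif; its first threonine (the catalytic
#' Thr1) is mature position 1, so mature position \eqn{p} corresponds to
#' precursor index \code{matureStart + p} (1-based).
#'
#' @slot precursor full precursor protein string.
#' @slot matureStart 0-based index of Thr1 within the precursor.
#' @slot mature protein string from Thr1 onwards.
#'
#' @seealso [detectMatureStart()], [callType()], [diagnosticProfile()]
#' @export
setClass("MatureMap",
  representation(precursor = "character", matureStart = "integer",
                 mature = "character"))

setValidity("MatureMap", function(object) {
  if (substr(object@precursor, object@matureStart + 1L,
             object@matureStart + 4L) != "TTTL")
    return("precursor must carry TTTL at matureStart")
  if (object@mature != substr(object@precursor, object@matureStart + 1L,
                              nchar(object@precursor)))
    return("mature must be the precursor suffix from matureStart")
  TRUE
})

#' PSMB8 analysis report
#'
#' Aggregated output of [runPipeline()]: per-sequence typing calls, codon
#' usage at the type-defining codon, a diagnostic-residue conservation
#' summary, the phylogeny (an [ape::phylo] with bootstrap node labels), the
#' screening rejection log, and run metadata.
#'
#' @slot typing data.frame, one row per kept sequence.
#' @slot codonUsage data.frame of codon counts per (group, type).
#' @slot conservation data.frame of per-group modal diagnostic residues.
#' @slot tree rooted `phylo` object, or `NULL` when too few sequences.
#' @slot rejections data.frame with columns id, group, reason, detail.
#' @slot metadata named list (seed, thresholds, stage counts, ...).
#'
#' @seealso [runPipeline()], [summarizeTypes()], [writeReport()]
#' @export
setClass("Psmb8Report",
  representation(typing = "data.frame", codonUsage = "data.frame",
                 conservation = "data.frame", tree = "ANY",
                 rejections = "data.frame", metadata = "list"))

#' @describeIn ScoringScheme-class compact display
#' @param object object to display
#' @export
setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: %d-letter matrix, gapOpen=%g, gapExtend=%g\n",
              nrow(object@matrix), object@gapOpen, object@gapExtend))
})

#' @describeIn PairAlignment-class compact display
#' @param object object to display
#' @export
setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment (%s) %s vs %s, score %g, %d columns\n",
              object@mode, object@aId, object@bId, object@score,
              nchar(object@aRow)))
  w <- min(60L, nchar(object@aRow))
  cat(" ", substr(object@aRow, 1, w), "\n ", substr(object@bRow, 1, w), "\n")
})

#' @describeIn Msa-class compact display
#' @param object object to display
#' @export
setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d sequences, %d columns\n", length(object@ids),
              if (length(object@rows)) nchar(object@rows[1]) else 0L))
})

#' @describeIn MatureMap-class compact display
#' @param object object to display
#' @export
setMethod("show", "MatureMap", function(object) {
  cat(sprintf("MatureMap: precursor %d aa, Thr1 at index %d, mature %d aa\n",
              nchar(object@precursor), object@matureStart,
              nchar(object@mature)))
})

#' @describeIn Psmb8Report-class compact display
#' @param object object to display
#' @export
setMethod("show", "Psmb8Report", function(object) {
  cat(sprintf(
    "Psmb8Report: %d typed sequences, %d rejections, tree: %s\n",
    nrow(object@typing), nrow(object@rejections),
    if (is.null(object@tree)) "none" else
      sprintf("%d tips", length(object@tree$tip.label))))
})

# ---- accessors ----

#' Typing table of a report
#' @param x a [Psmb8Report-class]
#' @return data.frame of per-sequence typing calls
#' @export
typingTable <- function(x) {
  stopifnot(is(x, "Psmb8Report"))
  x@typing
}

#' Rejection log of a report
#' @param x a [Psmb8Report-class]
#' @return data.frame with columns id, group, reason, detail
#' @export
rejectionLog <- function(x) {
  stopifnot(is(x, "Psmb8Report"))
  x@rejections
}

#' Phylogeny of a report
#' @param x a [Psmb8Report-class]
#' @return rooted `phylo` object or `NULL`
#' @export
reportTree <- function(x) {
  stopifnot(is(x, "Psmb8Report"))
  x@tree
}

#' Codon-usage table of a report
#' @param x a [Psmb8Report-class]
#' @return data.frame of codon counts per (group, type)
#' @export
codonUsageTable <- function(x) {
  stopifnot(is(x, "Psmb8Report"))
  x@codonUsage
}

#' Diagnostic-residue conservation summary of a report
#' @param x a [Psmb8Report-class]
#' @return data.frame of per-group modal residues at diagnostic positions
#' @export
conservationTable <- function(x) {
  stopifnot(is(x, "Psmb8Report"))
  x@conservation
}

#' Run metadata of a report
#' @param x a [Psmb8Report-class]
#' @return named list
#' @export
reportMetadata <- function(x) {
  stopifnot(is(x, "Psmb8Report"))
  x@metadata
}

#' Mature protein sequence of a MatureMap
#' @param x a [MatureMap-class]
#' @return character, the mature protein (Thr1 onwards)
#' @export
matureSeq <- function(x) {
  stopifnot(is(x, "MatureMap"))
  x@mature
}

#' 0-based precursor index of Thr1
#' @param x a [MatureMap-class]
#' @return integer
#' @export
matureStart <- function(x) {
  stopifnot(is(x, "MatureMap"))
  x@matureStart
}

#' Alignment ids
#' @param x an [Msa-class]
#' @return character vector of sequence ids
#' @export
msaIds <- function(x) {
  stopifnot(is(x, "Msa"))
  x@ids
}

#' Alignment rows
#' @param x an [Msa-class]
#' @return named character vector of gapped rows
#' @export
msaRows <- function(x) {
  stopifnot(is(x, "Msa"))
  stats::setNames(x@rows, x@ids)
}

#' Alignment score
#' @param x a [PairAlignment-class]
#' @return numeric score
#' @export
alignmentScore <- function(x) {
  stopifnot(is(x, "PairAlignment"))
  x@score
}

#' Gapped alignment rows of a pairwise alignment
#' @param x a [PairAlignment-class]
#' @return named character vector of the two gapped rows
#' @export
alignmentRows <- function(x) {
  stopifnot(is(x, "PairAlignment"))
  stats::setNames(c(x@aRow, x@bRow), c(x@aId, x@bId))
}
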