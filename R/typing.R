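# Residue-31 type calls, S1-pocket profiling, diagnostic-residue lineage
# classification, and codon usage at the type-defining codon.

#' Functional type implied by a residue at mature position 31
#'
#' A type: A or V; F type: F or Y; S type: S or T (threonine is grouped
#' with serine, both carrying a small linear hydroxyl side chain); K type:
#' K. Anything else is reported as `other`; `NA` or `X` is `undefined`.
#'
#' @param residue single amino-acid character (or `NA`).
#' @return one of `"A"`, `"F"`, `"S"`, `"K"`, `"other"`, `"undefined"`.
#' @export
#' @examples
#' typeFromResidue("T")  # "S"
#' typeFromResidue("K")  # "K"
typeFromResidue <- function(residue) {
  if (is.na(residue) || residue == "X" || !nzchar(residue))
    return("undefined")
  switch(residue,
         A = , V = "A",
         F = , Y = "F",
         S = , T = "S",
         K = "K",
         "other")
}

#' Call the PSMB8 type at mature residue 31
#'
#' @param map a [MatureMap-class] for the sequence.
#' @param seqId sequence id recorded in the call.
#' @param orf optional one-row ORF data.frame (from [findOrfs()]) whose
#'   protein carries `map@precursor` as its translation; when provided the
#'   codon encoding residue 31 is extracted with [codonAt()].
#' @param residue31 optional override of the residue at mature position 31
#'   (e.g. an alignment-mapped residue, `NA` for gap-mapped sites); default
#'   is direct indexing of the mature protein.
#' @return one-row data.frame: `seq_id`, `residue31`, `type_label`,
#'   `codon31` (`NA` when no ORF given).
#' @export
callType <- function(map, seqId, orf = NULL, residue31 = NULL) {
  stopifnot(is(map, "MatureMap"))
  if (is.null(residue31)) {
    residue31 <- if (nchar(map@mature) >= 31L)
      substr(map@mature, 31L, 31L) else NA_character_
  }
  if (!is.na(residue31) && residue31 == "X") residue31 <- NA_character_
  codon <- NA_character_
  if (!is.null(orf) && !is.na(residue31)) {
    codon <- tryCatch(codonAt(orf, map, 31L), error = function(e)
      NA_character_)
    if (!is.na(codon) && translateSeq(codon) != residue31)
      codon <- NA_character_ # indel shifted the frame relative to residue 31
  }
  data.frame(seq_id = seqId, residue31 = residue31,
             type_label = typeFromResidue(residue31), codon31 = codon,
             stringsAsFactors = FALSE)
}

#' Codon encoding a mature-protein position
#'
#' Extracts from the ORF nucleotide sequence the codon whose translation is
#' the residue at `maturePos` of the mature protein (assuming the ORF
#' translation equals the precursor without indels).
#'
#' @param orf one-row data.frame from [findOrfs()] (fields `nt_seq`,
#'   `protein`), or a list with those fields.
#' @param map a [MatureMap-class].
#' @param maturePos 1-based mature-protein position.
#' @return nucleotide triplet.
#' @export
codonAt <- function(orf, map, maturePos) {
  stopifnot(is(map, "MatureMap"), maturePos >= 1L)
  aaIdx <- map@matureStart + maturePos - 1L # 0-based residue index
  nt0 <- 3L * aaIdx                          # 0-based nt offset
  if (nt0 + 3L > nchar(orf$nt_seq) - 3L)     # last codon is the stop
    stop("mature position ", maturePos, " beyond ORF coding sequence")
  codon <- substr(orf$nt_seq, nt0 + 1L, nt0 + 3L)
  want <- substr(map@precursor, aaIdx + 1L, aaIdx + 1L)
  if (nzchar(want) && translateSeq(codon) != want)
    stop("codon ", codon, " at mature position ", maturePos,
         " does not translate to precursor residue ", want)
  codon
}

#' Codon usage at the type-defining codon, per group and type
#'
#' @param calls data.frame of type calls with columns `group`,
#'   `type_label`, `codon31` (rows with `NA` codons are dropped).
#' @return data.frame with one row per (group, type_label, codon):
#'   `count`, plus a per-(group, type) `conserved` flag that is `TRUE` when
#'   a single codon accounts for all counts.
#' @export
codonUsageSummary <- function(calls) {
  keep <- !is.na(calls$codon31)
  calls <- calls[keep, , drop = FALSE]
  if (!nrow(calls)) {
    return(data.frame(group = character(), type_label = character(),
                      codon = character(), count = integer(),
                      conserved = logical(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = seq_len(nrow(calls))),
                          by = list(group = calls$group,
                                    type_label = calls$type_label,
                                    codon = calls$codon31),
                          FUN = length)
  key <- paste(agg$group, agg$type_label)
  ncodons <- table(key)
  agg$conserved <- as.integer(ncodons[key]) == 1L
  agg <- agg[order(agg$group, agg$type_label, agg$codon), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Profile the S1 substrate-binding pocket
#'
#' Reports the residues at the six S1-pocket positions (mature 20, 31, 35,
#' 45, 49, 53) plus the catalytic Thr1, each annotated with a side-chain
#' chemistry class (`positive`, `negative`, `polar-hydroxyl`, `aromatic`,
#' `small-nonpolar`, `other`).
#'
#' @param map a [MatureMap-class] with mature length >= 53.
#' @param seqId sequence id.
#' @return list with `seq_id`, `pocket` (named residues), `classes` (named
#'   classes), `catalytic_thr1`, and `pocket_string` (e.g. `"20:S 31:K ..."`).
#' @export
s1Pocket <- function(map, seqId) {
  stopifnot(is(map, "MatureMap"))
  need <- max(.S1_POCKET_POSITIONS)
  if (nchar(map@mature) < need)
    stop("mature protein of '", seqId, "' has ", nchar(map@mature),
         " residues; ", need, " required (", need - nchar(map@mature),
         " short)")
  pos <- .S1_POCKET_POSITIONS
  res <- stats::setNames(substring(map@mature, pos, pos), pos)
  list(seq_id = seqId,
       pocket = res,
       classes = stats::setNames(.residueClass(res), pos),
       catalytic_thr1 = substr(map@mature, 1L, 1L),
       pocket_string = paste(sprintf("%d:%s", pos, res), collapse = " "))
}

#' Diagnostic-residue profile of a sequence
#'
#' Residues at the eight lineage-diagnostic mature positions (13, 99, 147,
#' 150, 156, 188, 189, 194); positions beyond the mature length, or carrying
#' `X`, are `NA`.
#'
#' @param map a [MatureMap-class].
#' @param seqId sequence id (stored as the `seq_id` attribute).
#' @return named character vector of length 8 (names = positions).
#' @export
diagnosticProfile <- function(map, seqId = "") {
  stopifnot(is(map, "MatureMap"))
  pos <- .DIAGNOSTIC_POSITIONS
  res <- ifelse(pos <= nchar(map@mature),
                substring(map@mature, pos, pos), NA_character_)
  res[!is.na(res) & res == "X"] <- NA_character_
  structure(stats::setNames(res, pos), seq_id = seqId)
}

#' Classify a sequence into the A or F lineage by diagnostic residues
#'
#' Counts agreements of the profile with the A- and F-lineage reference
#' residues; undefined positions match neither. The call is the lineage
#' with more matches, or `"ambiguous"` at a tie (ties are not forced —
#' phylogenetic placement is the recommended arbiter).
#'
#' @param profile named character vector from [diagnosticProfile()] (or any
#'   8 residues named by the diagnostic positions; `NA` = undefined).
#' @param refs list with elements `A` and `F` as returned by
#'   [lineageRefProfiles()].
#' @return list with `seq_id`, `matches_A`, `matches_F`, `call`.
#' @export
#' @examples
#' bowfin <- stats::setNames(c("M","T","L","P","A","S","Q","E"),
#'                           classifierPositions()$diagnostic)
#' classifyLineage(bowfin)  # 7 matches to the F lineage
classifyLineage <- function(profile, refs = lineageRefProfiles()) {
  stopifnot(all(c("A", "F") %in% names(refs)),
            length(refs$A) == 8L, length(refs$F) == 8L)
  pos <- names(refs$A)
  if (!all(pos %in% names(profile)))
    stop("profile must be named by the diagnostic positions")
  p <- profile[pos]
  mA <- sum(!is.na(p) & p == refs$A[pos])
  mF <- sum(!is.na(p) & p == refs$F[pos])
  call <- if (mA > mF) "A" else if (mF > mA) "F" else "ambiguous"
  list(seq_id = attr(profile, "seq_id"), matches_A = as.integer(mA),
       matches_F = as.integer(mF), call = call)
}

#' Per-group conservation of diagnostic residues
#'
#' For each group and diagnostic position: the modal residue, its
#' frequency, and whether it matches the A reference, the F reference, both
#' or neither.
#'
#' @param profiles list of profiles from [diagnosticProfile()].
#' @param groups character vector of group tags, parallel to `profiles`.
#' @param refs lineage reference profiles ([lineageRefProfiles()]).
#' @return data.frame with columns `group`, `position`, `modal_residue`,
#'   `frequency`, `matches` (`"A"`, `"F"`, `"both"`, `"neither"`).
#' @export
conservationSummary <- function(profiles, groups,
                                refs = lineageRefProfiles()) {
  stopifnot(length(profiles) == length(groups), length(profiles) >= 1L)
  pos <- names(refs$A)
  out <- list()
  for (g in unique(groups)) {
    sub <- profiles[groups == g]
    for (p in pos) {
      res <- vapply(sub, function(x) x[[p]], character(1))
      res <- res[!is.na(res)]
      if (!length(res)) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, position = as.integer(p),
          modal_residue = NA_character_, frequency = NA_real_,
          matches = NA_character_, stringsAsFactors = FALSE)
        next
      }
      tab <- sort(table(res), decreasing = TRUE)
      modal <- names(tab)[1]
      mA <- modal == refs$A[[p]]
      mF <- modal == refs$F[[p]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, position = as.integer(p), modal_residue = modal,
        frequency = as.numeric(tab[1]) / length(res),
        matches = if (mA && mF) "both" else if (mA) "A" else if (mF) "F"
                  else "neither",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
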