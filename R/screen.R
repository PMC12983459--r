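# Reference-guided identification of PSMB8 candidate ORFs, mature-protein
# start detection via the conserved TTTL motif, and QC filtering.

#' Screening configuration
#'
#' @param references named character vector (or `AAStringSet`) of reference
#'   precursor proteins; names carry the id, and the `family` attribute (or
#'   `mcols()$family`) labels each as `"PSMB8"` or `"PSMB5"`. If no family
#'   vector is supplied, ids containing "PSMB5" (case-insensitive) are taken
#'   as decoys. At least one PSMB5 decoy reference is required.
#' @param family optional character vector parallel to `references`.
#' @param minScore minimum local alignment score to retain a candidate.
#' @param minIdentity minimum fractional identity over aligned columns.
#' @param minProteinLen minimum ORF protein length passed to [findOrfs()].
#' @param ttlWindow mature-start search window: the TTTL motif must begin
#'   within the first `ttlWindow` precursor residues.
#' @param scheme a [ScoringScheme-class] used for the local alignments.
#' @return a list of class `ScreenConfig`
#' @export
screenConfig <- function(references, family = NULL, minScore = 100,
                         minIdentity = 0.40, minProteinLen = 100L,
                         ttlWindow = 90L, scheme = blosum62Scheme()) {
  if (is(references, "AAStringSet")) {
    fam <- S4Vectors::mcols(references)$family
    if (is.null(family)) family <- fam
    references <- stats::setNames(as.character(references), names(references))
  }
  if (!length(references)) stop("references must be nonempty")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named")
  if (is.null(family))
    family <- ifelse(grepl("PSMB5", names(references), ignore.case = TRUE),
                     "PSMB5", "PSMB8")
  if (!all(family %in% c("PSMB8", "PSMB5")))
    stop("reference family must be 'PSMB8' or 'PSMB5'")
  if (!any(family == "PSMB5"))
    stop("references must include at least one PSMB5 decoy")
  if (minScore <= 0 || minIdentity <= 0 || minProteinLen <= 0)
    stop("screen thresholds must be positive")
  structure(list(references = references, family = family,
                 minScore = minScore, minIdentity = minIdentity,
                 minProteinLen = as.integer(minProteinLen),
                 ttlWindow = as.integer(ttlWindow), scheme = scheme),
            class = "ScreenConfig")
}

#' Screen contigs for PSMB8-like ORFs
#'
#' Enumerates ORFs in every contig ([findOrfs()]) and aligns each ORF protein
#' locally against every reference. ORFs whose best alignment reaches both
#' the score and identity thresholds are retained; candidates whose best
#' reference is a PSMB5 decoy are kept but flagged (they are rejected
#' downstream by [applyQc()]).
#'
#' @param contigs `DNAStringSet` from [readFasta()] (or named character
#'   vector of nucleotide contigs).
#' @param cfg a `ScreenConfig` from [screenConfig()].
#' @return data.frame with one row per retained ORF: contig/ORF columns,
#'   `group`, `best_ref`, `score`, `identity`, `best_ref_family`.
#' @export
screenCandidates <- function(contigs, cfg) {
  stopifnot(inherits(cfg, "ScreenConfig"))
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  groups <- seqGroups(contigs)
  out <- list()
  for (i in seq_along(contigs)) {
    cid <- names(contigs)[i]
    orfs <- findOrfs(as.character(contigs[[i]]),
                     minProteinLen = cfg$minProteinLen, id = cid)
    for (k in seq_len(nrow(orfs))) {
      best <- NULL
      for (r in seq_along(cfg$references)) {
        aln <- pairwiseAlign(orfs$protein[k], cfg$references[r],
                             scheme = cfg$scheme, mode = "local",
                             aId = cid, bId = names(cfg$references)[r])
        if (is.null(best) || aln@score > best$score)
          best <- list(score = aln@score, ref = r, aln = aln)
      }
      idn <- if (nchar(best$aln@aRow)) percentIdentity(best$aln) else 0
      if (best$score >= cfg$minScore && idn >= cfg$minIdentity) {
        row <- orfs[k, , drop = FALSE]
        row$group <- unname(groups[i])
        row$best_ref <- names(cfg$references)[best$ref]
        row$score <- best$score
        row$identity <- idn
        row$best_ref_family <- cfg$family[best$ref]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), nt_seq = character(),
                      protein = character(), group = character(),
                      best_ref = character(), score = numeric(),
                      identity = numeric(), best_ref_family = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locate the mature-protein start (TTTL motif)
#'
#' The mature PSMB8 protein begins at the conserved TTTL (Thr-Thr-Thr-Leu)
#' motif; its first threonine is the catalytic Thr1. The first occurrence
#' whose start lies within the first `window` precursor residues is used.
#'
#' @param precursor precursor protein string.
#' @param window search window (residues) for the motif start.
#' @return a [MatureMap-class], or `NULL` when no TTTL motif is found in the
#'   window (the sequence is then excluded downstream with reason
#'   `no_TTTL`).
#' @export
#' @examples
#' detectMatureStart("MALRTTTLQK")  # Thr1 at 0-based index 4
detectMatureStart <- function(precursor, window = 90L) {
  stopifnot(is.character(precursor), nzchar(precursor))
  precursor <- toupper(precursor)
  hit <- regexpr("TTTL", substr(precursor, 1L, window + 3L), fixed = TRUE)
  if (hit == -1L || hit > window) return(NULL)
  ms <- as.integer(hit) - 1L
  new("MatureMap", precursor = precursor, matureStart = ms,
      mature = substr(precursor, ms + 1L, nchar(precursor)))
}

# Alignment-based residue-31 lookup: align the reference mature protein to
# the query mature protein and map mature position `pos` across. Returns
# list(pos, residue); pos is NA when the query has a gap at that column
# (e.g. a deletion spanning the site), residue "X" counts as undefined.
.mappedResidue <- function(map, refMature, pos = 31L,
                           scheme = blosum62Scheme()) {
  aln <- pairwiseAlign(refMature, map@mature, scheme = scheme,
                       mode = "global", aId = ".ref", bId = ".qry")
  p <- mapRefPosition(aln, ".ref", pos, ".qry")
  if (is.na(p)) return(list(pos = NA_integer_, residue = NA_character_))
  list(pos = p, residue = substr(map@mature, p, p))
}

#' Apply QC filters to screened candidates
#'
#' Checks each candidate in a fixed order and records the first failing
#' check as its rejection reason:
#' \enumerate{
#'   \item `no_TTTL` — no mature-start motif ([detectMatureStart()]);
#'   \item `truncated_before_31` — mature protein shorter than 31 residues;
#'   \item `undefined_31` — residue 31 is `X`, or (when `refMatures` is
#'     given) mature position 31 of the reference maps to a gap in the
#'     query, as happens for deletions spanning the site;
#'   \item `decoy_family` — best screening hit was a PSMB5 decoy;
#'   \item `duplicate` — identical mature protein already kept for the same
#'     group (first by id wins).
#' }
#'
#' @param candidates data.frame from [screenCandidates()] (or any frame with
#'   columns `contig_id`, `group`, `protein`, `best_ref_family`).
#' @param refMatures optional named character vector of reference mature
#'   proteins (names = reference ids matching `best_ref`); enables the
#'   alignment-based residue-31 check.
#' @param window TTTL search window passed to [detectMatureStart()].
#' @param scheme scoring scheme for the alignment-based check.
#' @return list with elements `kept` (candidate rows plus `mature` and
#'   `mature_start` columns), `rejected` (columns id, group, reason,
#'   detail) and `maps` (named list of [MatureMap-class] for kept rows).
#' @export
applyQc <- function(candidates, refMatures = NULL, window = 90L,
                    scheme = blosum62Scheme()) {
  if (nrow(candidates))
    candidates <- candidates[order(candidates$contig_id), , drop = FALSE]
  kept <- list()
  maps <- list()
  rej <- list()
  seen <- character(0) # "group\x1fmature" keys already kept
  reject <- function(id, group, reason, detail = "") {
    rej[[length(rej) + 1L]] <<- data.frame(
      id = id, group = group, reason = reason, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(candidates))) {
    row <- candidates[k, , drop = FALSE]
    id <- row$contig_id
    grp <- if ("group" %in% names(row)) row$group else ""
    map <- detectMatureStart(row$protein, window = window)
    if (is.null(map)) { reject(id, grp, "no_TTTL"); next }
    if (nchar(map@mature) < 31L) {
      reject(id, grp, "truncated_before_31",
             sprintf("mature length %d", nchar(map@mature)))
      next
    }
    res31 <- substr(map@mature, 31L, 31L)
    gapMapped <- FALSE
    if (!is.null(refMatures) && row$best_ref %in% names(refMatures)) {
      mr <- .mappedResidue(map, refMatures[[row$best_ref]], 31L, scheme)
      if (is.na(mr$pos)) gapMapped <- TRUE else res31 <- mr$residue
    }
    if (res31 == "X" || gapMapped) {
      reject(id, grp, "undefined_31",
             if (gapMapped) "position 31 maps to a gap" else "residue X")
      next
    }
    if (identical(row$best_ref_family, "PSMB5")) {
      reject(id, grp, "decoy_family", row$best_ref)
      next
    }
    key <- paste(grp, map@mature, sep = "\x1f")
    if (key %in% seen) { reject(id, grp, "duplicate"); next }
    seen <- c(seen, key)
    row$mature <- map@mature
    row$mature_start <- map@matureStart
    kept[[length(kept) + 1L]] <- row
    maps[[id]] <- map
  }
  keptDf <- if (length(kept)) do.call(rbind, kept) else
    data.frame(contig_id = character(), group = character(),
               protein = character(), mature = character(),
               mature_start = integer(), stringsAsFactors = FALSE)
  rejDf <- if (length(rej)) do.call(rbind, rej) else
    data.frame(id = character(), group = character(), reason = character(),
               detail = character(), stringsAsFactors = FALSE)
  rownames(keptDf) <- NULL
  rownames(rejDf) <- NULL
  list(kept = keptDf, rejected = rejDf, maps = maps)
}

#' Write a rejection log as TSV
#'
#' @param rejected data.frame with columns id, group, reason, detail.
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeRejectionLog <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
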