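# Pairwise and progressive protein alignment, plus coordinate mapping
# through alignments. The affine-gap DP lives in src/align_dp.cpp; R code
# prepares the cell-score matrix (for pairs, substitution scores; for
# profiles, sum-of-pairs expected scores) and assembles the gapped rows.

#' Construct a scoring scheme
#'
#' @param matrix symmetric substitution matrix with amino-acid row/column
#'   names.
#' @param gapOpen score of the first gap residue (negative).
#' @param gapExtend score of each further gap residue (negative,
#'   `>= gapOpen`).
#' @return a [ScoringScheme-class]
#' @export
scoringScheme <- function(matrix, gapOpen = -11, gapExtend = -1) {
  new("ScoringScheme", matrix = matrix, gapOpen = as.numeric(gapOpen),
      gapExtend = as.numeric(gapExtend))
}

#' Default protein scoring scheme (BLOSUM62, gaps -11/-1)
#'
#' BLOSUM62 with gap open -11 and gap extend -1, the canonical protein
#' BLAST parameters.
#'
#' @return a [ScoringScheme-class]
#' @export
blosum62Scheme <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  scoringScheme(e$BLOSUM62, gapOpen = -11, gapExtend = -1)
}

.asProtein <- function(x, id, default) {
  if (is(x, "AAString") || is(x, "AAStringSet")) {
    if (is(x, "AAStringSet")) {
      if (missing(id) || is.null(id)) id <- names(x)[1]
      x <- x[[1]]
    }
    x <- as.character(x)
  }
  if (is.null(id) && !is.null(names(x))) id <- names(x)[1]
  if (is.null(id)) id <- default
  list(id = id, seq = unname(toupper(x)))
}

#' Optimal pairwise protein alignment
#'
#' Global (Needleman–Wunsch) or local (Smith–Waterman) alignment with affine
#' gap penalties (Gotoh). The traceback is deterministic: at score ties a
#' substitution is preferred over a gap in the first sequence's row, which is
#' preferred over a gap in the second's.
#'
#' @param a,b protein strings (optionally named) or `AAString(Set)`s.
#' @param scheme a [ScoringScheme-class]; default [blosum62Scheme()].
#' @param mode `"global"` or `"local"`.
#' @param aId,bId optional ids (default: names of `a`/`b`, else "a"/"b").
#' @return a [PairAlignment-class]
#' @export
#' @examples
#' aln <- pairwiseAlign("TTTLG", "TTTLG")
#' percentIdentity(aln)
pairwiseAlign <- function(a, b, scheme = blosum62Scheme(),
                          mode = c("global", "local"),
                          aId = NULL, bId = NULL) {
  mode <- match.arg(mode)
  pa <- .asProtein(a, aId, "a")
  pb <- .asProtein(b, bId, "b")
  if (!nzchar(pa$seq) || !nzchar(pb$seq))
    stop("cannot align empty sequence")
  mat <- scheme@matrix
  ca <- strsplit(pa$seq, "")[[1]]
  cb <- strsplit(pb$seq, "")[[1]]
  ia <- match(ca, rownames(mat))
  ib <- match(cb, rownames(mat))
  if (anyNA(ia)) stop("residue(s) absent from scoring matrix in '", pa$id,
                      "': ", paste(unique(ca[is.na(ia)]), collapse = ""))
  if (anyNA(ib)) stop("residue(s) absent from scoring matrix in '", pb$id,
                      "': ", paste(unique(cb[is.na(ib)]), collapse = ""))
  S <- mat[ia, ib, drop = FALSE]
  dp <- .affineDP(S, scheme@gapOpen, scheme@gapExtend,
                  if (mode == "local") 1L else 0L)
  ops <- strsplit(dp$ops, "")[[1]]
  na <- sum(ops != "X") # consumed from a
  nb <- sum(ops != "Y") # consumed from b
  ai <- dp$a0
  bi <- dp$b0
  arow <- character(length(ops))
  brow <- character(length(ops))
  pa_i <- ai
  pb_i <- bi
  for (k in seq_along(ops)) {
    if (ops[k] != "X") { pa_i <- pa_i + 1L; arow[k] <- ca[pa_i] }
    else arow[k] <- "-"
    if (ops[k] != "Y") { pb_i <- pb_i + 1L; brow[k] <- cb[pb_i] }
    else brow[k] <- "-"
  }
  new("PairAlignment", aId = pa$id, bId = pb$id,
      aRow = paste(arow, collapse = ""), bRow = paste(brow, collapse = ""),
      score = dp$score, mode = mode,
      aSpan = c(as.integer(ai), as.integer(ai + na)),
      bSpan = c(as.integer(bi), as.integer(bi + nb)))
}

#' Percent identity of a pairwise alignment
#'
#' Identical columns divided by aligned (both-residue) columns; columns with
#' a gap in either row are excluded from the denominator.
#'
#' @param aln a [PairAlignment-class]
#' @return fraction in \[0, 1\]
#' @export
percentIdentity <- function(aln) {
  stopifnot(is(aln, "PairAlignment"))
  a <- strsplit(aln@aRow, "")[[1]]
  b <- strsplit(aln@bRow, "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) stop("alignment has no aligned (gap-free) columns")
  sum(a[both] == b[both]) / sum(both)
}

# 3-mer count distance used for the guide tree: 1 - shared/(minlen - k + 1).
.kmerDist <- function(seqs, k = 3L) {
  n <- length(seqs)
  tabs <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character()))
    table(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- tabs[[i]]; tj <- tabs[[j]]
    shared <- intersect(names(ti), names(tj))
    m <- sum(pmin(ti[shared], tj[shared]))
    denom <- max(1L, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L)
    D[i, j] <- D[j, i] <- 1 - m / denom
  }
  D
}

# Sum-of-pairs expected score between two profile columns. Gap fractions
# score gapExtend against residue mass and 0 against gap mass.
.profileScoreMatrix <- function(Fa, ga, Fb, gb, M, ge) {
  S <- crossprod(Fa, M %*% Fb)
  ra <- colSums(Fa)
  rb <- colSums(Fb)
  S + ge * (outer(ga, rb) + outer(ra, gb))
}

.msaProfile <- function(rows, alpha) {
  L <- nchar(rows[1])
  chars <- matrix(unlist(strsplit(rows, ""), use.names = FALSE),
                  nrow = length(rows), byrow = TRUE)
  Fm <- matrix(0, length(alpha), L)
  for (a in seq_along(alpha))
    Fm[a, ] <- colSums(chars == alpha[a]) / length(rows)
  gp <- colSums(chars == "-") / length(rows)
  list(F = Fm, gap = gp)
}

.mergeMsas <- function(ra, rb, scheme, alpha) {
  M <- scheme@matrix[alpha, alpha]
  pa <- .msaProfile(ra, alpha)
  pb <- .msaProfile(rb, alpha)
  S <- .profileScoreMatrix(pa$F, pa$gap, pb$F, pb$gap, M, scheme@gapExtend)
  dp <- .affineDP(S, scheme@gapOpen, scheme@gapExtend, 0L)
  ops <- strsplit(dp$ops, "")[[1]]
  La <- nchar(ra[1])
  # expand each side's rows according to ops
  idxa <- integer(0); idxb <- integer(0)
  ia <- 0L; ib <- 0L
  for (op in ops) {
    if (op != "X") ia <- ia + 1L
    if (op != "Y") ib <- ib + 1L
    idxa <- c(idxa, if (op == "X") NA_integer_ else ia)
    idxb <- c(idxb, if (op == "Y") NA_integer_ else ib)
  }
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(is.na(idx), "-", ch[idx]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  c(expand(ra, idxa), expand(rb, idxb))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by UPGMA clustering of 3-mer count distances, then
#' merges profiles along the tree by global profile–profile alignment with
#' sum-of-pairs scoring (gap fractions score `gapExtend` against residues).
#' Deterministic for a fixed input order; no randomness involved.
#'
#' @param seqs named character vector of protein sequences, or an
#'   `AAStringSet` (>= 2 sequences, unique ids).
#' @param scheme a [ScoringScheme-class]; default [blosum62Scheme()].
#' @return an [Msa-class] with rows in the input sequence order.
#' @export
progressiveMsa <- function(seqs, scheme = blosum62Scheme()) {
  if (is(seqs, "AAStringSet")) seqs <- stats::setNames(as.character(seqs),
                                                       names(seqs))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  alpha <- setdiff(rownames(scheme@matrix), "*")

  if (length(seqs) == 2L) {
    aln <- pairwiseAlign(seqs[1], seqs[2], scheme, "global",
                         aId = ids[1], bId = ids[2])
    return(new("Msa", ids = ids, rows = c(aln@aRow, aln@bRow)))
  }

  D <- .kmerDist(unname(seqs))
  dimnames(D) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  clusters <- vector("list", nrow(hc$merge))
  getClust <- function(k) {
    if (k < 0) list(ids = ids[-k], rows = unname(seqs[-k]))
    else clusters[[k]]
  }
  for (r in seq_len(nrow(hc$merge))) {
    a <- getClust(hc$merge[r, 1])
    b <- getClust(hc$merge[r, 2])
    # deterministic orientation: lexicographically smallest id first
    if (min(b$ids) < min(a$ids)) { tmp <- a; a <- b; b <- tmp }
    merged <- .mergeMsas(a$rows, b$rows, scheme, alpha)
    clusters[[r]] <- list(ids = c(a$ids, b$ids), rows = merged)
  }
  fin <- clusters[[nrow(hc$merge)]]
  ord <- match(ids, fin$ids)
  new("Msa", ids = ids, rows = fin$rows[ord])
}

#' Write an alignment as aligned FASTA
#'
#' @param msa an [Msa-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMsaFasta <- function(msa, path) {
  stopifnot(is(msa, "Msa"))
  writeFasta(stats::setNames(msa@rows, msa@ids), path)
}

.alnRowsOf <- function(aln) {
  if (is(aln, "Msa")) {
    list(ids = aln@ids, rows = aln@rows,
         offs = rep(0L, length(aln@ids)))
  } else if (is(aln, "PairAlignment")) {
    list(ids = c(aln@aId, aln@bId), rows = c(aln@aRow, aln@bRow),
         offs = c(aln@aSpan[1], aln@bSpan[1]))
  } else stop("expected an Msa or PairAlignment")
}

#' Map a reference position through an alignment
#'
#' Returns the 1-based ungapped position in `targetId` aligned to the same
#' column as 1-based ungapped position `refPos` of `refId`, or `NA` when the
#' target carries a gap at that column (or, for local alignments, when
#' `refPos` falls outside the aligned span).
#'
#' @param aln a [PairAlignment-class] or [Msa-class]
#' @param refId,targetId sequence ids present in the alignment
#' @param refPos 1-based position on the ungapped reference sequence
#' @return integer position or `NA_integer_`
#' @export
mapRefPosition <- function(aln, refId, refPos, targetId) {
  x <- .alnRowsOf(aln)
  ri <- match(refId, x$ids)
  ti <- match(targetId, x$ids)
  if (is.na(ri)) stop("unknown reference id: ", refId)
  if (is.na(ti)) stop("unknown target id: ", targetId)
  stopifnot(refPos >= 1L)
  rch <- strsplit(x$rows[ri], "")[[1]]
  tch <- strsplit(x$rows[ti], "")[[1]]
  local <- refPos - x$offs[ri] # 1-based position within the covered slice
  if (local < 1L) return(NA_integer_)
  nong <- which(rch != "-")
  if (local > length(nong)) {
    if (is(aln, "PairAlignment") && aln@mode == "local") return(NA_integer_)
    stop("refPos ", refPos, " beyond length of '", refId, "'")
  }
  col <- nong[local]
  if (tch[col] == "-") return(NA_integer_)
  as.integer(x$offs[ti] + sum(tch[seq_len(col)] != "-"))
}
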