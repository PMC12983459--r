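# Sequence I/O, translation and ORF enumeration.

.GENCODE <- NULL # filled at load time from Biostrings::GENETIC_CODE

.onLoad <- function(libname, pkgname) {
  gc0 <- Biostrings::GENETIC_CODE
  assign(".GENCODE", stats::setNames(as.character(gc0), names(gc0)),
         envir = parent.env(environment()))
}

.validAlphabet <- function(moltype) {
  if (moltype == "nucleotide") c("A", "C", "G", "T", "U", .NT_AMBIG)
  else c(.AA20, "X", "*", "-")
}

#' Read a FASTA file of named sequences
#'
#' Headers are split at the first `|`: the part before is the sequence id
#' (unique within the file), the remainder is an optional group tag (species
#' or population), stored in `mcols(x)$group` (empty string when absent).
#'
#' @param path path to a FASTA file.
#' @param moltype `"nucleotide"` or `"protein"`; sequences are validated
#'   against the corresponding IUPAC alphabet (ambiguity codes allowed for
#'   nucleotides, `X` for protein).
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] with
#'   ids as names and the group tag in `mcols()`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1|Leposs", "TTTLGK"), f)
#' readFasta(f, "protein")
readFasta <- function(path, moltype = c("nucleotide", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  hdr <- names(raw)
  if (length(raw) && (is.null(hdr) || any(!nzchar(hdr))))
    stop("malformed FASTA header (empty) in ", path)
  ids <- sub("\\|.*$", "", hdr)
  grp <- ifelse(grepl("\\|", hdr), sub("^[^|]*\\|", "", hdr), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  ok <- .validAlphabet(moltype)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for record '", ids[i], "'")
    ch <- unique(strsplit(seqs[i], "")[[1]])
    bad <- setdiff(ch, ok)
    if (length(bad))
      stop("illegal ", moltype, " character(s) ",
           paste(bad, collapse = ""), " in record '", ids[i], "'")
  }
  out <- if (moltype == "nucleotide") {
    Biostrings::DNAStringSet(gsub("U", "T", seqs))
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out)$group <- grp
  out
}

#' Write sequences to FASTA
#'
#' Ids and group tags are written as `id|group` headers (plain `id` when the
#' group is empty); lines wrap at 60 columns.
#'
#' @param x an `XStringSet` (group taken from `mcols(x)$group` if present)
#'   or a named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- Biostrings::BStringSet(x)
  }
  grp <- S4Vectors::mcols(x)$group
  nm <- names(x)
  if (!is.null(grp)) nm <- ifelse(nzchar(grp), paste0(nm, "|", grp), nm)
  y <- x
  names(y) <- nm
  Biostrings::writeXStringSet(y, path, width = 60L)
  invisible(path)
}

#' Group tags of a sequence set
#'
#' @param x an `XStringSet` read by [readFasta()].
#' @return character vector of group tags (named by sequence id).
#' @export
seqGroups <- function(x) {
  grp <- S4Vectors::mcols(x)$group
  if (is.null(grp)) grp <- rep("", length(x))
  stats::setNames(grp, names(x))
}

#' Translate a nucleotide string
#'
#' Standard genetic code; stops are rendered `*`, a trailing partial codon is
#' dropped, and any codon containing an ambiguity code translates to `X`.
#'
#' @param nt nucleotide string.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return protein string (possibly empty).
#' @export
#' @examples
#' translateSeq("ATGTCTTAA")   # "MS*"
#' translateSeq("ATNGGG")      # "XG"
translateSeq <- function(nt, frame = 0L) {
  stopifnot(length(nt) == 1L, frame %in% 0:2)
  nt <- toupper(gsub("U", "T", nt))
  n <- nchar(nt) - frame
  if (n < 3L) return("")
  ncod <- n %/% 3L
  starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- .GENCODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' @param nt nucleotide string (IUPAC ambiguity codes supported).
#' @return reverse-complemented string.
#' @export
revComp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Enumerate open reading frames in a contig
#'
#' Finds all ATG-to-stop ORFs on both strands and all three frames whose
#' encoded protein (without the stop) has at least `minProteinLen` residues.
#' Within each (strand, frame, stop) group only the longest ORF (earliest
#' ATG after the previous stop) is reported. Coordinates are 0-based,
#' half-open on the forward strand of the input contig; for `-` strand ORFs
#' `nt_seq` is the reverse-complement slice.
#'
#' @param contig nucleotide string, or a length-1 `DNAStringSet` /
#'   `DNAString`.
#' @param minProteinLen minimum protein length (residues).
#' @param id contig id recorded in the output (defaults to the name of
#'   `contig` when present).
#' @return data.frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `frame`, `nt_seq`, `protein`, sorted by decreasing protein length, then
#'   forward-strand offset, then strand (`+` first).
#' @export
#' @examples
#' findOrfs("AAATGGCTTAAAA", minProteinLen = 1)
findOrfs <- function(contig, minProteinLen = 1L, id = NULL) {
  if (is(contig, "DNAStringSet")) {
    if (is.null(id)) id <- names(contig)[1]
    contig <- as.character(contig[[1]])
  } else if (is(contig, "DNAString")) {
    contig <- as.character(contig)
  } else if (is.character(contig) && is.null(id) && !is.null(names(contig))) {
    id <- names(contig)[1]
  }
  if (is.null(id)) id <- "contig"
  contig <- toupper(gsub("U", "T", contig))
  L <- nchar(contig)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()

  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revComp(contig)
    for (frame in 0:2) {
      n <- (nchar(s) - frame) %/% 3L
      if (n < 2L) next
      st <- frame + 1L + 3L * (seq_len(n) - 1L)
      codons <- substring(s, st, st + 2L)
      atg_open <- NA_integer_ # codon index of earliest ATG since last stop
      for (k in seq_len(n)) {
        if (codons[k] %in% stops) {
          if (!is.na(atg_open)) {
            i0 <- st[atg_open] - 1L          # 0-based local start
            i1 <- st[k] + 2L                 # 0-based local end (exclusive)
            plen <- (i1 - i0) %/% 3L - 1L
            if (plen >= minProteinLen) {
              ntseq <- substr(s, i0 + 1L, i1)
              fs <- if (strand == "+") i0 else L - i1
              fe <- if (strand == "+") i1 else L - i0
              res[[length(res) + 1L]] <- data.frame(
                contig_id = id, start = fs, end = fe, strand = strand,
                frame = frame, nt_seq = ntseq,
                protein = translateSeq(ntseq, 0L) |>
                  (\(p) substr(p, 1L, nchar(p) - 1L))(),
                stringsAsFactors = FALSE)
            }
          }
          atg_open <- NA_integer_
        } else if (is.na(atg_open) && codons[k] == "ATG") {
          atg_open <- k
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), nt_seq = character(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(-nchar(out$protein), out$start,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
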