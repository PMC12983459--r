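# Synthetic transcriptome generator with truth tables.
#
# Templates are fixed constants: an A-lineage and an F-lineage PSMB8
# precursor (20-residue propeptide, then a 204-residue mature protein
# beginning TTTL, with the lineage-diagnostic residues embedded) and a
# PSMB5-like decoy (30-residue propeptide, mature at ~55% identity to both
# PSMB8 templates). Coding sequences are reverse-translated with a fixed
# preferred-codon table, so synonymous variation arises only through the
# simulated substitution process.

.TEMPLATE_A_PRECURSOR <- paste0(
  "MNIPMEDCAHWLMAEEKTKETTTLIMEAKHKGILWPWTPSPGWMMGPGHRALISKDFTVI",
  "FTRVGAGTVRGEMKNFYSSDEQEYIVMQFCYPPSSYMMEWWYHCRMFCAFDFNAHCGASS",
  "RWILLKEGAKVSYRIDTRTMFQEVGWMDFKQDWIEVMMRAENNNKSMSCEYEVFQGIVYH",
  "AQTDDPNNEWRHERFWQLVCEFNSVPYCKLVEEENFYDNQAWFR")

.TEMPLATE_F_PRECURSOR <- paste0(
  "MNIPMEDCAHWLMAEEKTKETTTLIMPAKHKGMLWPWTPSPGWMMGPGHRFLISKDFTVI",
  "FTRVGAGTVKGEMKNTYSSDEQEYIVMQFCYPCLSYMMEWWYHCRFFDAFLFVAHCGATS",
  "RWILRKEGAKVSYRLETRTMFQEVGQMDFKQDWIEVMKRAEMNNKSLSCPYEVFQAIVHH",
  "AQTDDPNNEWRHERFWLLVIEFVSVPYSQLVEMDNFYDNQAWFR")

.TEMPLATE_DECOY_PRECURSOR <- paste0(
  "MEKGQCTETLTQWNEKNQWGYYTVSPSSMETTTLIMEMENKIKYWGWVYLPGWVMGFGHR",
  "KGNVIDFLVIATRMGAGTARGQPKNFVSGDEQTYIVSACGYPCRSYHWEWWFRVRMFQAF",
  "LKVHHCGASMYWHLMKERSKVWNRPKTRTMFEVVGQKDFGFDWICMMGRYNHNNCIMSCE",
  "CESSHIPVHKCLLGDPNNEWRMYRFWQTNIWFVWVPYSELVEETIYYDNQGWTD")

# Preferred codons for reverse translation. Leu/Ser/Thr/Ile deliberately
# use CTA/TCA/ACT/ATC: these seed stop codons into the antisense reading
# frames, so the coding region cannot harbour long spurious ORFs on the
# opposite strand.
.PREF_CODON <- c(
  A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTA", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "TCA", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTG")

.reverseTranslate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(.PREF_CODON[aa], collapse = ""), "TAA")
}

# Synonymous codons per amino acid (standard code), for spurious-ORF repair.
.SYNONYMS <- local({
  gc0 <- Biostrings::GENETIC_CODE
  split(names(gc0), as.character(gc0))
})

# A reverse-translated CDS can harbour long ORFs in shifted or antisense
# frames. Break every such ORF (>= minLen residues) by swapping single
# codons to synonymous alternatives until only the true reading frame
# remains; the encoded protein is untouched. Deterministic.
.breakSpuriousOrfs <- function(cdna, protectAa, minLen = 100L) {
  ncod <- nchar(cdna) %/% 3L - 1L
  for (iter in 1:100) {
    orfs <- findOrfs(cdna, minProteinLen = minLen)
    main <- orfs$start == 0L & orfs$end == nchar(cdna) & orfs$strand == "+"
    extra <- orfs[!main, , drop = FALSE]
    if (!nrow(extra)) return(cdna)
    span <- c(extra$start[1] + 3L, extra$end[1] - 3L) # nt range, 0-based
    fixed <- FALSE
    for (ci in setdiff(seq_len(ncod) - 1L, protectAa)) {
      if (3L * ci + 3L <= span[1] || 3L * ci >= span[2]) next
      cur <- substr(cdna, 3L * ci + 1L, 3L * ci + 3L)
      for (alt in setdiff(.SYNONYMS[[translateSeq(cur)]], cur)) {
        tmp <- cdna
        substr(tmp, 3L * ci + 1L, 3L * ci + 3L) <- alt
        o2 <- findOrfs(tmp, minProteinLen = minLen)
        m2 <- o2$start == 0L & o2$end == nchar(tmp) & o2$strand == "+"
        if (sum(m2) == 1L && nrow(o2) < nrow(orfs)) {
          cdna <- tmp
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) stop("could not repair spurious ORF in template CDS")
  }
  stop("could not repair spurious ORFs in template CDS")
}

.templateCache <- new.env(parent = emptyenv())

#' Fixed sequence templates used by the generator
#'
#' @return named list: `A` and `F` (PSMB8 precursor templates, 20-residue
#'   propeptide + 204-residue mature protein) and `decoy` (PSMB5-like,
#'   30-residue propeptide), each a list with `precursor`, `cdna`,
#'   `matureStart` (0-based Thr1 index) and `family`.
#' @export
makeTemplates <- function() {
  if (!is.null(.templateCache$templates)) return(.templateCache$templates)
  mk <- function(pre, ms, fam) {
    protect <- c(0L, ms + c(1:4, .S1_POCKET_POSITIONS,
                            .DIAGNOSTIC_POSITIONS) - 1L)
    cdna <- .breakSpuriousOrfs(.reverseTranslate(pre), protect)
    list(precursor = pre, cdna = cdna,
         matureStart = as.integer(ms), family = fam)
  }
  out <- list(A = mk(.TEMPLATE_A_PRECURSOR, 20L, "PSMB8"),
              F = mk(.TEMPLATE_F_PRECURSOR, 20L, "PSMB8"),
              decoy = mk(.TEMPLATE_DECOY_PRECURSOR, 30L, "PSMB5"))
  .templateCache$templates <- out
  out
}

.TYPE_RESIDUES <- list(A = c("A", "V"), F = c("F", "Y"), S = c("S", "T"),
                       K = "K")

.checkCodonType <- function(codon31, type) {
  res <- translateSeq(codon31)
  ok <- if (type %in% names(.TYPE_RESIDUES)) res %in% .TYPE_RESIDUES[[type]]
        else !(res %in% unlist(.TYPE_RESIDUES)) && res != "*"
  if (!ok)
    stop("codon31 ", codon31, " (", res, ") inconsistent with type ", type)
  invisible(res)
}

#' Default simulation group table
#'
#' Mirrors the structure of the study system: one gar-like A-lineage group
#' with A-type (8), S-type/T31 (24, codon ACC) and K-type (3, codon AAG)
#' haplotypes, and one bowfin-like F-lineage group with F-type (6) and
#' S-type (16, codon TCT) haplotypes.
#'
#' @param mu per-site substitution rate applied to unconstrained codons.
#' @param indelProb per-sequence probability of a 6-nt deletion spanning
#'   the type-defining codon.
#' @return data.frame with columns `group`, `n`, `lineage`, `type`,
#'   `codon31`, `mu`, `indel_prob`.
#' @export
defaultSimGroups <- function(mu = 0.02, indelProb = 0) {
  data.frame(
    group = c("Leposs", "Leposs", "Leposs", "Amical", "Amical"),
    n = c(8L, 24L, 3L, 6L, 16L),
    lineage = c("A", "A", "A", "F", "F"),
    type = c("A", "S", "K", "F", "S"),
    codon31 = c("GCC", "ACC", "AAG", "TTC", "TCT"),
    mu = mu, indel_prob = indelProb,
    stringsAsFactors = FALSE)
}

#' Simulation settings for a mock transcriptome
#'
#' @param groups data.frame as returned by [defaultSimGroups()].
#' @param decoys number of PSMB5-like decoy contigs.
#' @param randomContigs number of random (non-coding) contigs.
#' @param utrLen length of the random UTR flanking each coding region.
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @return list of class `SimSpec`.
#' @export
simSpec <- function(groups = defaultSimGroups(), decoys = 3L,
                    randomContigs = 5L, utrLen = 100L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  need <- c("group", "n", "lineage", "type", "codon31", "mu", "indel_prob")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (any(groups$mu < 0 | groups$mu > 0.3))
    stop("mu must lie in [0, 0.3]")
  if (!all(groups$lineage %in% c("A", "F")))
    stop("lineage must be 'A' or 'F'")
  for (r in seq_len(nrow(groups)))
    .checkCodonType(groups$codon31[r], groups$type[r])
  structure(list(groups = groups, decoys = as.integer(decoys),
                 randomContigs = as.integer(randomContigs),
                 utrLen = as.integer(utrLen), seed = as.integer(seed)),
            class = "SimSpec")
}

# Mutate a coding sequence at rate mu per site with a 2:1 third-position
# bias, never touching codons in `protectAa` (0-based residue indices),
# never introducing a stop, and never creating a premature TTTL motif
# upstream of `ttlStart` (0-based residue index of the true motif).
.mutateCds <- function(cdna, mu, protectAa, ttlStart) {
  if (mu <= 0) return(cdna)
  nt <- strsplit(cdna, "")[[1]]
  ncod <- length(nt) %/% 3L - 1L            # exclude the stop codon
  eligible <- setdiff(seq_len(ncod) - 1L, protectAa)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  p <- c(0.75, 0.75, 1.5) * mu              # 2:1 third-position bias
  for (ci in eligible) {
    hit <- stats::runif(3) < p
    if (!any(hit)) next
    old <- nt[ci * 3L + 1:3]
    new <- old
    for (s in which(hit)) new[s] <- sample(setdiff(bases, old[s]), 1L)
    if (paste(new, collapse = "") %in% stops) next
    nt[ci * 3L + 1:3] <- new
  }
  out <- paste(nt, collapse = "")
  prot <- translateSeq(out)
  # revert any codon whose mutation created a TTTL upstream of the real one
  guard <- 0L
  while (guard < 50L) {
    hit <- regexpr("TTTL", substr(prot, 1L, ttlStart + 3L), fixed = TRUE)
    if (hit == -1L || hit - 1L >= ttlStart) break
    idx <- (as.integer(hit) - 1L):(as.integer(hit) + 2L) # 0-based residues
    for (ci in idx)
      substr(out, ci * 3L + 1L, ci * 3L + 3L) <-
        substr(cdna, ci * 3L + 1L, ci * 3L + 3L)
    prot <- translateSeq(out)
    guard <- guard + 1L
  }
  out
}

.randomNt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Assemble a contig around a coding sequence and certify that the emitted
# contig carries exactly one ORF of >= 100 residues, located at the truth
# coordinates (both strands checked). Spurious long ORFs (e.g. spanning a
# UTR junction) are rare by construction; when one occurs the mutation and
# UTR draws are simply repeated from the seeded stream.
.assembleContig <- function(base, mu, protect, ms, utrLen, hasIndel) {
  for (try in 1:50) {
    cdna <- .mutateCds(base, mu, protect, ms)
    if (hasIndel) {
      # delete mature codons 30 and 31 (6 nt, frame preserved)
      d0 <- (ms + 29L) * 3L
      cdna <- paste0(substr(cdna, 1L, d0),
                     substr(cdna, d0 + 7L, nchar(cdna)))
    }
    utr5 <- .randomNt(utrLen)
    # seal the 5' UTR with an in-frame stop so the ORF start is the ATG
    if (utrLen >= 3L) substr(utr5, utrLen - 2L, utrLen) <- "TAG"
    fwd <- paste0(utr5, cdna, .randomNt(utrLen))
    orfs <- findOrfs(fwd, minProteinLen = 100L)
    if (nrow(orfs) == 1L && orfs$start == utrLen &&
        orfs$end == utrLen + nchar(cdna) && orfs$strand == "+")
      return(list(cdna = cdna, fwd = fwd))
  }
  stop("could not assemble a contig with a unique ORF")
}

#' Simulate one PSMB8-bearing contig
#'
#' Starts from the lineage template coding sequence, sets the codon at
#' mature position 31, applies random nucleotide substitutions at rate `mu`
#' (third position favoured 2:1) to codons outside the diagnostic and
#' S1-pocket positions and the TTTL motif, optionally deletes 6 nt spanning
#' the type-defining codon, flanks the ORF with random UTRs (with an
#' in-frame stop sealing the 5' end so the ORF start is well defined), and
#' randomly orients the contig. Uses the ambient RNG stream.
#'
#' @param entry one-row data.frame (a row of the `groups` table).
#' @param id contig id.
#' @param templates output of [makeTemplates()].
#' @param utrLen UTR length.
#' @return list with `contig` (nucleotide string) and `truth` (one-row
#'   data.frame).
#' @export
simulateSequence <- function(entry, id, templates = makeTemplates(),
                             utrLen = 100L) {
  res31 <- .checkCodonType(entry$codon31, entry$type)
  tpl <- templates[[entry$lineage]]
  ms <- tpl$matureStart
  base <- tpl$cdna
  # set the type-defining codon (mature position 31)
  c31 <- ms + 30L # 0-based residue index
  substr(base, c31 * 3L + 1L, c31 * 3L + 3L) <- entry$codon31
  protect <- ms + c(1:4, .S1_POCKET_POSITIONS, .DIAGNOSTIC_POSITIONS) - 1L
  protect <- c(0L, protect) # never touch the start codon

  hasIndel <- stats::runif(1) < entry$indel_prob
  asm <- .assembleContig(base, entry$mu, protect, ms, utrLen, hasIndel)
  cdna <- asm$cdna
  fwd <- asm$fwd
  L <- nchar(fwd)
  start <- utrLen
  end <- utrLen + nchar(cdna)
  flip <- stats::runif(1) < 0.5
  contig <- if (flip) revComp(fwd) else fwd
  prec <- translateSeq(cdna)
  prec <- substr(prec, 1L, nchar(prec) - 1L)
  mature <- substr(prec, ms + 1L, nchar(prec))
  diag <- ifelse(.DIAGNOSTIC_POSITIONS <= nchar(mature),
                 substring(mature, .DIAGNOSTIC_POSITIONS,
                           .DIAGNOSTIC_POSITIONS), NA_character_)
  truth <- data.frame(
    contig_id = id, group = entry$group,
    start = if (flip) L - end else start,
    end = if (flip) L - start else end,
    strand = if (flip) "-" else "+",
    mature_start = ms, lineage = entry$lineage, type = entry$type,
    residue31 = res31, codon31 = entry$codon31,
    diagnostic = paste(sprintf("%d:%s", .DIAGNOSTIC_POSITIONS, diag),
                       collapse = ","),
    has_indel = hasIndel, is_decoy = FALSE, stringsAsFactors = FALSE)
  list(contig = contig, truth = truth)
}

#' Simulate a mock transcriptome with a truth table
#'
#' Generates all group sequences, PSMB5-like decoys (lightly mutated copies
#' of the decoy template) and random contigs, shuffled deterministically by
#' the simulation seed.
#'
#' @param spec a `SimSpec` from [simSpec()].
#' @return list with `contigs` (a `DNAStringSet`, group tags in `mcols`)
#'   and `truth` (data.frame, one row per contig).
#' @export
simulateTranscriptome <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  templates <- makeTemplates()
  contigs <- character(0)
  groups <- character(0)
  truth <- list()
  counter <- 0L
  for (r in seq_len(nrow(spec$groups))) {
    entry <- spec$groups[r, , drop = FALSE]
    for (i in seq_len(entry$n)) {
      counter <- counter + 1L
      id <- sprintf("%s_%s%03d", entry$group, entry$type, counter)
      sim <- simulateSequence(entry, id, templates, spec$utrLen)
      contigs[id] <- sim$contig
      groups <- c(groups, entry$group)
      truth[[length(truth) + 1L]] <- sim$truth
    }
  }
  for (i in seq_len(spec$decoys)) {
    counter <- counter + 1L
    id <- sprintf("decoy%03d", counter)
    tpl <- templates$decoy
    protect <- c(0L, tpl$matureStart + (1:4) - 1L)
    asm <- .assembleContig(tpl$cdna, 0.02, protect, tpl$matureStart,
                           spec$utrLen, hasIndel = FALSE)
    cdna <- asm$cdna
    contigs[id] <- asm$fwd
    groups <- c(groups, "decoy")
    truth[[length(truth) + 1L]] <- data.frame(
      contig_id = id, group = "decoy", start = spec$utrLen,
      end = spec$utrLen + nchar(cdna), strand = "+",
      mature_start = tpl$matureStart, lineage = NA_character_,
      type = NA_character_, residue31 = NA_character_,
      codon31 = NA_character_, diagnostic = NA_character_,
      has_indel = FALSE, is_decoy = TRUE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$randomContigs)) {
    counter <- counter + 1L
    id <- sprintf("rand%03d", counter)
    contigs[id] <- .randomNt(2L * spec$utrLen + 600L)
    groups <- c(groups, "random")
    truth[[length(truth) + 1L]] <- data.frame(
      contig_id = id, group = "random", start = NA_integer_,
      end = NA_integer_, strand = NA_character_,
      mature_start = NA_integer_, lineage = NA_character_,
      type = NA_character_, residue31 = NA_character_,
      codon31 = NA_character_, diagnostic = NA_character_,
      has_indel = FALSE, is_decoy = FALSE, stringsAsFactors = FALSE)
  }
  ord <- sample.int(length(contigs))
  truthDf <- do.call(rbind, truth)[ord, , drop = FALSE]
  rownames(truthDf) <- NULL
  out <- Biostrings::DNAStringSet(contigs[ord])
  S4Vectors::mcols(out)$group <- groups[ord]
  list(contigs = out, truth = truthDf)
}

#' Write a truth table as TSV
#' @param truth data.frame from [simulateTranscriptome()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
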