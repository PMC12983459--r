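# End-to-end orchestration: screen -> QC -> typing -> codon usage ->
# conservation -> phylogeny -> report.

#' Bundled reference sequence set
#'
#' The fixed A- and F-lineage PSMB8 precursor templates plus the PSMB5-like
#' decoy, used as screening references, lineage-labeled tree references and
#' outgroup.
#'
#' @return `AAStringSet` with `mcols()$family` labels.
#' @export
bundledReferences <- function() {
  tpl <- makeTemplates()
  out <- Biostrings::AAStringSet(c(ref_PSMB8_A = tpl$A$precursor,
                                   ref_PSMB8_F = tpl$F$precursor,
                                   ref_PSMB5 = tpl$decoy$precursor))
  S4Vectors::mcols(out)$family <- c("PSMB8", "PSMB8", "PSMB5")
  out
}

.refMatures <- function(references, window = 90L) {
  refs <- stats::setNames(as.character(references), names(references))
  out <- character(0)
  for (nm in names(refs)) {
    m <- detectMatureStart(refs[[nm]], window = window)
    if (!is.null(m)) out[nm] <- m@mature
  }
  out
}

#' Run the PSMB8 typing pipeline
#'
#' From nucleotide contigs: ORF screening against the references, TTTL
#' mature-start detection, QC filtering, residue-31 typing (with codon
#' extraction), S1-pocket profiling, diagnostic-residue lineage
#' classification, codon-usage and conservation summaries, and a
#' neighbor-joining phylogeny (bootstrap supports, PSMB5 outgroup rooting)
#' from which a clade-based lineage is assigned. Both lineage classifiers
#' are always reported with an agreement flag; the phylogenetic call is the
#' recommended one when they disagree.
#'
#' From mature-protein input the screen is skipped and codon fields are
#' absent.
#'
#' @param contigs `DNAStringSet` (e.g. from [readFasta()] or
#'   [simulateTranscriptome()]); exclusive with `proteins`.
#' @param proteins `AAStringSet` of mature (or precursor) proteins;
#'   exclusive with `contigs`.
#' @param references reference `AAStringSet` with family labels
#'   (default [bundledReferences()]).
#' @param minScore,minIdentity,minProteinLen,ttlWindow screening thresholds,
#'   see [screenConfig()].
#' @param distModel distance model for the phylogeny, `"p"` or `"poisson"`.
#' @param bootstrapReps bootstrap replicates (0 = no supports).
#' @param seed seed for the bootstrap resampling.
#' @param scheme a [ScoringScheme-class].
#' @return a [Psmb8Report-class]
#' @export
runPipeline <- function(contigs = NULL, proteins = NULL,
                        references = bundledReferences(),
                        minScore = 100, minIdentity = 0.40,
                        minProteinLen = 100L, ttlWindow = 90L,
                        distModel = c("p", "poisson"),
                        bootstrapReps = 200L, seed = 42L,
                        scheme = blosum62Scheme()) {
  distModel <- match.arg(distModel)
  if (is.null(contigs) == is.null(proteins))
    stop("provide exactly one of 'contigs' or 'proteins'")
  cfg <- screenConfig(references, minScore = minScore,
                      minIdentity = minIdentity,
                      minProteinLen = minProteinLen, ttlWindow = ttlWindow,
                      scheme = scheme)
  refMat <- .refMatures(references, window = ttlWindow)
  nIn <- if (is.null(contigs)) length(proteins) else length(contigs)

  if (!is.null(contigs)) {
    cand <- screenCandidates(contigs, cfg)
  } else {
    # protein input: no ORFs to screen; label each sequence by its best
    # global alignment against the references so decoys can be flagged
    groups <- seqGroups(proteins)
    rows <- lapply(seq_along(proteins), function(i) {
      scores <- vapply(seq_along(cfg$references), function(r) {
        pairwiseAlign(as.character(proteins[[i]]), cfg$references[r],
                      scheme = scheme, mode = "global")@score
      }, numeric(1))
      best <- which.max(scores)
      data.frame(contig_id = names(proteins)[i], start = NA_integer_,
                 end = NA_integer_, strand = NA_character_,
                 frame = NA_integer_, nt_seq = NA_character_,
                 protein = as.character(proteins[[i]]),
                 group = unname(groups[i]),
                 best_ref = names(cfg$references)[best],
                 score = scores[best], identity = NA_real_,
                 best_ref_family = cfg$family[best],
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, rows)
  }

  qc <- applyQc(cand, refMatures = refMat, window = ttlWindow,
                scheme = scheme)
  # record conservation: contigs yielding no retained candidate are logged,
  # so input ids = kept ids + rejected ids at every stage boundary
  inputIds <- if (is.null(contigs)) names(proteins) else names(contigs)
  inputGroups <- if (is.null(contigs)) seqGroups(proteins) else
    seqGroups(contigs)
  unscreened <- setdiff(inputIds, cand$contig_id)
  if (length(unscreened)) {
    qc$rejected <- rbind(qc$rejected, data.frame(
      id = unscreened, group = unname(inputGroups[unscreened]),
      reason = "no_candidate", detail = "no ORF passed the screen",
      stringsAsFactors = FALSE))
  }
  kept <- qc$kept

  typing <- list()
  profiles <- list()
  for (k in seq_len(nrow(kept))) {
    row <- kept[k, , drop = FALSE]
    map <- qc$maps[[row$contig_id]]
    mr <- .mappedResidue(map, refMat[[row$best_ref]], 31L, scheme)
    orf <- if (!is.na(row$nt_seq)) row else NULL
    tc <- callType(map, row$contig_id, orf = orf, residue31 = mr$residue)
    prof <- diagnosticProfile(map, row$contig_id)
    lc <- classifyLineage(prof)
    pocket <- tryCatch(s1Pocket(map, row$contig_id)$pocket_string,
                       error = function(e) NA_character_)
    tc$group <- row$group
    tc$matches_A <- lc$matches_A
    tc$matches_F <- lc$matches_F
    tc$lineage_diagnostic <- lc$call
    tc$s1_pocket <- pocket
    typing[[k]] <- tc
    profiles[[row$contig_id]] <- prof
  }
  typing <- if (length(typing)) do.call(rbind, typing) else
    data.frame(seq_id = character(), residue31 = character(),
               type_label = character(), codon31 = character(),
               group = character(), matches_A = integer(),
               matches_F = integer(), lineage_diagnostic = character(),
               s1_pocket = character(), stringsAsFactors = FALSE)

  codonUsage <- codonUsageSummary(typing)
  conservation <- if (length(profiles))
    conservationSummary(unname(profiles), typing$group) else
    data.frame(group = character(), position = integer(),
               modal_residue = character(), frequency = numeric(),
               matches = character(), stringsAsFactors = FALSE)

  # phylogeny: kept matures + PSMB8 lineage references + PSMB5 outgroup
  tree <- NULL
  typing$lineage_clade <- rep(NA_character_, nrow(typing))
  treeSeqs <- c(stats::setNames(kept$mature, kept$contig_id), refMat)
  outgroup <- names(refMat)[grepl("PSMB5", names(refMat))]
  lineageRefs <- stats::setNames(
    ifelse(grepl("PSMB8_A", setdiff(names(refMat), outgroup)), "A", "F"),
    setdiff(names(refMat), outgroup))
  if (length(treeSeqs) >= 3L && nrow(typing) > 0L) {
    msa <- progressiveMsa(treeSeqs, scheme)
    tree <- if (bootstrapReps >= 1L)
      bootstrapSupport(msa, distModel, nReps = bootstrapReps, seed = seed)
    else neighborJoining(distanceMatrix(msa, distModel))
    tree <- rootWithOutgroup(tree, outgroup)
    typing$lineage_clade <- vapply(typing$seq_id, function(q)
      assignLineageByClade(tree, lineageRefs, q), character(1),
      USE.NAMES = FALSE)
  }
  typing$lineage_agreement <- typing$lineage_diagnostic == typing$lineage_clade
  typing$lineage_call <- ifelse(
    typing$lineage_clade %in% c("A", "F"), typing$lineage_clade,
    ifelse(typing$lineage_diagnostic %in% c("A", "F"),
           typing$lineage_diagnostic, "unresolved"))

  meta <- list(
    n_input = nIn, n_candidates = nrow(cand), n_kept = nrow(kept),
    n_rejected = nrow(qc$rejected), min_score = minScore,
    min_identity = minIdentity, min_protein_len = minProteinLen,
    ttl_window = ttlWindow, dist_model = distModel,
    bootstrap_reps = bootstrapReps, seed = seed,
    package_version = as.character(utils::packageVersion("psmb8typer")))

  new("Psmb8Report", typing = typing, codonUsage = codonUsage,
      conservation = conservation, tree = tree,
      rejections = qc$rejected, metadata = meta)
}

#' Tabulate type counts per group and lineage
#'
#' Counts kept sequences by (group, lineage, type). Sequences rejected for
#' an undefined residue 31 are appended as type `"undefined"` rows rather
#' than silently dropped.
#'
#' @param report a [Psmb8Report-class]
#' @return data.frame with columns `group`, `lineage`, `type`, `count`.
#' @export
summarizeTypes <- function(report) {
  stopifnot(is(report, "Psmb8Report"))
  ty <- report@typing
  rows <- list()
  if (nrow(ty)) {
    agg <- stats::aggregate(list(count = seq_len(nrow(ty))),
                            by = list(group = ty$group,
                                      lineage = ty$lineage_call,
                                      type = ty$type_label), FUN = length)
    rows[[1]] <- agg
  }
  rej <- report@rejections
  und <- rej[rej$reason == "undefined_31", , drop = FALSE]
  if (nrow(und)) {
    agg2 <- stats::aggregate(list(count = seq_len(nrow(und))),
                             by = list(group = und$group), FUN = length)
    agg2$lineage <- NA_character_
    agg2$type <- "undefined"
    rows[[length(rows) + 1L]] <- agg2[, c("group", "lineage", "type",
                                          "count")]
  }
  if (!length(rows)) {
    return(data.frame(group = character(), lineage = character(),
                      type = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$lineage, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write report artifacts to a directory
#'
#' Writes `typing.tsv`, `codon_usage.tsv`, `conservation.tsv`,
#' `rejections.tsv`, `type_counts.tsv`, `tree.nwk` (when a tree exists) and
#' `metadata.json`. Outputs are byte-identical across reruns of the same
#' configuration and seed.
#'
#' @param report a [Psmb8Report-class]
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "Psmb8Report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(report@typing, "typing.tsv")
  tsv(report@codonUsage, "codon_usage.tsv")
  tsv(report@conservation, "conservation.tsv")
  tsv(report@rejections, "rejections.tsv")
  tsv(summarizeTypes(report), "type_counts.tsv")
  if (!is.null(report@tree))
    writeNewick(report@tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(report@metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
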