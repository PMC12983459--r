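scheme <- blosum62Scheme()
B62 <- scheme@matrix

test_that("self-alignment is gap-free with the diagonal score", {
  aln <- pairwiseAlign("TTTLG", "TTTLG")
  rows <- alignmentRows(aln)
  expect_false(any(grepl("-", rows)))
  expect_equal(alignmentScore(aln),
               sum(diag(B62[c("T", "T", "T", "L", "G"),
                            c("T", "T", "T", "L", "G")])))
  expect_equal(percentIdentity(aln), 1)
})

test_that("global alignment places the expected single gap", {
  aln <- pairwiseAlign("ACD", "AD")
  rows <- alignmentRows(aln)
  expect_equal(unname(rows[1]), "ACD")
  expect_equal(unname(rows[2]), "A-D")
  expect_equal(alignmentScore(aln), B62["A", "A"] + -11 + B62["D", "D"])
  expect_error(pairwiseAlign("", "AD"), "empty")
})

test_that("global scores match a linear-gap DP oracle exhaustively", {
  # exhaustive over all pairs of strings of length 0..3 over a 4-letter
  # alphabet, with gapOpen == gapExtend so the affine machinery reduces to
  # the oracle's linear model
  alpha <- c("A", "C", "G", "T")
  lin <- scoringScheme(B62, gapOpen = -4, gapExtend = -4)
  strs <- unlist(lapply(1:3, function(L) {
    apply(do.call(expand.grid, rep(list(alpha), L)), 1, paste, collapse = "")
  }))
  for (a in strs) for (b in strs) {
    expect_equal(alignmentScore(pairwiseAlign(a, b, lin)),
                 nwLinearScore(a, b, B62, -4),
                 info = paste(a, b))
  }
  # seeded random longer pairs up to length 6
  set.seed(62)
  for (k in 1:200) {
    a <- paste(sample(alpha, sample(4:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(alignmentScore(pairwiseAlign(a, b, lin)),
                 nwLinearScore(a, b, B62, -4),
                 info = paste(a, b))
  }
})

test_that("affine scores agree with an independent aligner", {
  # Biostrings::pairwiseAlignment as cross-check; its gap model
  # (gapOpening + L * gapExtension) equals ours with open 10, extend 1
  set.seed(17)
  for (k in 1:20) {
    a <- randomProtein(sample(10:60, 1))
    b <- randomProtein(sample(10:60, 1))
    for (mode in c("global", "local")) {
      mine <- alignmentScore(pairwiseAlign(a, b, scheme, mode))
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = B62, gapOpening = 10, gapExtension = 1,
        type = mode, scoreOnly = TRUE)
      expect_equal(mine, ref, info = paste(mode, k))
    }
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(23)
  for (k in 1:10) {
    a <- randomProtein(30)
    b <- randomProtein(25)
    expect_equal(alignmentScore(pairwiseAlign(a, b)),
                 alignmentScore(pairwiseAlign(b, a)))
  }
})

test_that("local alignment recovers an embedded motif exactly", {
  set.seed(41)
  motif <- randomProtein(30)
  host <- paste0(randomProtein(140), motif, randomProtein(130))
  aln <- pairwiseAlign(motif, host, mode = "local")
  expect_equal(aln@aSpan, c(0L, 30L))
  expect_equal(aln@bSpan, c(140L, 170L))
  expect_equal(percentIdentity(aln), 1)
})

test_that("percent identity counts identical over aligned columns", {
  set.seed(7)
  # ~20% forced identity between otherwise scrambled 100-mers
  n <- 100
  a <- strsplit(randomProtein(n), "")[[1]]
  b <- strsplit(randomProtein(n), "")[[1]]
  keep <- sample(n, 20)
  b[keep] <- a[keep]
  aln <- new("PairAlignment", aId = "a", bId = "b",
             aRow = paste(a, collapse = ""), bRow = paste(b, collapse = ""),
             score = 0, mode = "global", aSpan = c(0L, as.integer(n)),
             bSpan = c(0L, as.integer(n)))
  expect_gte(percentIdentity(aln), 20 / 100)
  expect_lte(percentIdentity(aln), 0.35)
})

test_that("progressive MSA reduces to pairwise for two sequences", {
  set.seed(3)
  a <- randomProtein(40)
  b <- randomProtein(35)
  msa <- progressiveMsa(c(x = a, y = b))
  aln <- pairwiseAlign(a, b, aId = "x", bId = "y")
  expect_equal(unname(msaRows(msa)), unname(alignmentRows(aln)))
})

test_that("progressive MSA: identical sequences align gap-free, rows degap
           to inputs, duplicate ids rejected", {
  s <- randomProtein(50)
  msa <- progressiveMsa(stats::setNames(rep(s, 4), paste0("s", 1:4)))
  expect_false(any(grepl("-", msaRows(msa))))

  set.seed(9)
  seqs <- stats::setNames(vapply(1:6, function(i)
    randomProtein(sample(40:60, 1)), character(1)), paste0("q", 1:6))
  msa2 <- progressiveMsa(seqs)
  expect_equal(gsub("-", "", msaRows(msa2)), seqs)
  expect_error(progressiveMsa(stats::setNames(c(s, s), c("a", "a"))),
               "duplicate")
})

test_that("diagnostic columns are gap-free in an indel-free simulated MSA", {
  sim <- simulateTranscriptome(smallSpec(seed = 55))
  rep <- runPipeline(contigs = sim$contigs, bootstrapReps = 0)
  kept <- typingTable(rep)
  tpl <- makeTemplates()
  seqs <- c(stats::setNames(
    vapply(kept$seq_id, function(id) {
      tr <- sim$truth[sim$truth$contig_id == id, ]
      orfs <- findOrfs(as.character(
        sim$contigs[[match(id, names(sim$contigs))]]), 100, id = id)
      matureSeq(detectMatureStart(orfs$protein))
    }, character(1)), kept$seq_id))
  msa <- progressiveMsa(seqs)
  chm <- do.call(rbind, strsplit(unname(msaRows(msa)), ""))
  # columns of mature positions (no indels simulated): alignment should be
  # gap-free everywhere, in particular at the 8 diagnostic positions
  diagCols <- classifierPositions()$diagnostic
  expect_false(any(chm[, diagCols] == "-"))
})

test_that("mapRefPosition maps through gaps and inverts", {
  # gap-free equal-length alignment: identity map
  msa <- new("Msa", ids = c("r", "t"), rows = c("TTTLG", "TTTAG"))
  expect_equal(mapRefPosition(msa, "r", 4, "t"), 4L)
  # target gap at the mapped column -> undefined
  msa2 <- new("Msa", ids = c("r", "t"), rows = c("TTTLG", "TT-LG"))
  expect_true(is.na(mapRefPosition(msa2, "r", 3, "t")))
  expect_equal(mapRefPosition(msa2, "r", 4, "t"), 3L)
  expect_error(mapRefPosition(msa2, "zz", 1, "t"), "unknown")
  # inverse property on a real alignment
  set.seed(19)
  a <- randomProtein(40)
  b <- paste0(substr(a, 1, 15), substr(a, 20, 40)) # deletion in b
  aln <- pairwiseAlign(a, b, aId = "a", bId = "b")
  for (p in 1:36) {
    q <- mapRefPosition(aln, "a", p, "b")
    if (!is.na(q)) expect_equal(mapRefPosition(aln, "b", q, "a"), p)
  }
})

test_that("deletion spanning mature position 31 maps to undefined", {
  tpl <- makeTemplates()
  pre <- tpl$A$precursor
  # drop mature residues 30 and 31 (precursor indices 50, 51)
  del <- paste0(substr(pre, 1, 49), substr(pre, 52, nchar(pre)))
  aln <- pairwiseAlign(substr(pre, 21, nchar(pre)),
                       substr(del, 21, nchar(del)),
                       aId = "ref", bId = "mut")
  expect_true(is.na(mapRefPosition(aln, "ref", 31, "mut")))
  expect_equal(mapRefPosition(aln, "ref", 40, "mut"), 38L)
})
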