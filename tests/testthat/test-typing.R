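aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
         "M", "F", "P", "S", "T", "W", "Y", "V")

test_that("the residue-to-type map is exhaustive and mutually exclusive", {
  expected <- ifelse(aas %in% c("A", "V"), "A",
              ifelse(aas %in% c("F", "Y"), "F",
              ifelse(aas %in% c("S", "T"), "S",
              ifelse(aas == "K", "K", "other"))))
  got <- vapply(aas, typeFromResidue, character(1))
  expect_equal(unname(got), expected)
  expect_equal(typeFromResidue("X"), "undefined")
  expect_equal(typeFromResidue(NA_character_), "undefined")
  # every residue maps to exactly one label
  expect_true(all(table(aas) == 1))
})

test_that("callType reads residue 31 and its codon from the ORF", {
  tpl <- makeTemplates()
  entry <- data.frame(group = "g", n = 1L, lineage = "A", type = "K",
                      codon31 = "AAG", mu = 0, indel_prob = 0)
  set.seed(1)
  sim <- simulateSequence(entry, "k1", tpl, utrLen = 50L)
  orfs <- findOrfs(sim$contig, minProteinLen = 100, id = "k1")
  map <- detectMatureStart(orfs$protein)
  tc <- callType(map, "k1", orf = orfs[1, ])
  expect_equal(tc$residue31, "K")
  expect_equal(tc$type_label, "K")
  expect_equal(tc$codon31, "AAG")
  # T at 31 is an S-type call
  entry$type <- "S"; entry$codon31 <- "ACC"
  sim2 <- simulateSequence(entry, "s1", tpl, utrLen = 50L)
  orfs2 <- findOrfs(sim2$contig, minProteinLen = 100, id = "s1")
  tc2 <- callType(detectMatureStart(orfs2$protein), "s1", orf = orfs2[1, ])
  expect_equal(tc2$residue31, "T")
  expect_equal(tc2$type_label, "S")
  expect_equal(tc2$codon31, "ACC")
})

test_that("codonAt extracts the encoding triplet and checks bounds", {
  tpl <- makeTemplates()
  orf <- list(nt_seq = tpl$A$cdna, protein = tpl$A$precursor)
  map <- detectMatureStart(tpl$A$precursor)
  c31 <- codonAt(orf, map, 31)
  expect_equal(translateSeq(c31),
               substr(matureSeq(map), 31, 31))
  expect_equal(codonAt(orf, map, 1), "ACT") # Thr1
  expect_error(codonAt(orf, map, 1000), "beyond")
})

test_that("codon usage summary flags conservation per (group, type)", {
  calls <- data.frame(
    group = c(rep("bowfin", 5), "gar", "gar"),
    type_label = c(rep("S", 5), "S", "S"),
    codon31 = c(rep("TCT", 5), "ACC", "ACA"),
    stringsAsFactors = FALSE)
  cu <- codonUsageSummary(calls)
  bow <- cu[cu$group == "bowfin", ]
  expect_equal(bow$codon, "TCT")
  expect_equal(bow$count, 5L)
  expect_true(bow$conserved)
  gar <- cu[cu$group == "gar", ]
  expect_equal(nrow(gar), 2L)
  expect_false(any(gar$conserved))
  expect_equal(nrow(codonUsageSummary(calls[0, ])), 0L)
})

test_that("S1 pocket profile annotates residue chemistry", {
  tpl <- makeTemplates()
  # K-type gar-like sequence: positive charge in the pocket
  preK <- tpl$A$precursor
  substr(preK, 51, 51) <- "K" # mature position 31 = precursor index 51
  pk <- s1Pocket(detectMatureStart(preK), "k")
  expect_equal(unname(pk$pocket["31"]), "K")
  expect_equal(unname(pk$classes["31"]), "positive")
  # bowfin-like S type: small hydroxyl side chain
  preS <- tpl$F$precursor
  substr(preS, 51, 51) <- "S"
  ps <- s1Pocket(detectMatureStart(preS), "s")
  expect_equal(unname(ps$classes["31"]), "polar-hydroxyl")
  # the catalytic Thr1 is forced by the TTTL motif
  expect_equal(pk$catalytic_thr1, "T")
  expect_length(pk$pocket, 6L)
  # too-short mature protein: error names the deficit
  expect_error(s1Pocket(detectMatureStart(paste0("MTTTL", strrep("G", 20))),
                        "short"), "required")
})

test_that("diagnostic profiles read the 8 positions with NA beyond length", {
  tpl <- makeTemplates()
  profA <- diagnosticProfile(detectMatureStart(tpl$A$precursor), "A")
  expect_equal(as.character(profA), unname(lineageRefProfiles()$A))
  profF <- diagnosticProfile(detectMatureStart(tpl$F$precursor), "F")
  expect_equal(as.character(profF), unname(lineageRefProfiles()$F))
  # mature length 100: positions 147-194 undefined
  short <- detectMatureStart(paste0("M", "TTTL", randomProtein(96)))
  p <- diagnosticProfile(short, "s")
  expect_false(anyNA(p[c("13", "99")]))
  expect_true(all(is.na(p[c("147", "150", "156", "188", "189", "194")])))
})

test_that("lineage classification reproduces the published match counts", {
  pos <- classifierPositions()$diagnostic
  bowfin <- stats::setNames(c("M", "T", "L", "P", "A", "S", "Q", "E"), pos)
  lc <- classifyLineage(bowfin)
  expect_equal(lc$matches_F, 7L)
  expect_equal(lc$matches_A, 1L)
  expect_equal(lc$call, "F")
  gar <- stats::setNames(c("V", "S", "L", "E", "G", "C", "Q", "E"), pos)
  lg <- classifyLineage(gar)
  expect_equal(lg$matches_A, 5L)
  expect_equal(lg$matches_F, 2L)
  expect_equal(lg$call, "A")
  # identity with a reference profile
  la <- classifyLineage(stats::setNames(lineageRefProfiles()$A, pos))
  expect_equal(la$matches_A, 8L)
  expect_equal(la$call, "A")
})

test_that("lineage classification properties: swap symmetry, NA handling,
           disjoint references", {
  refs <- lineageRefProfiles()
  # the two reference profiles differ at every diagnostic position
  expect_true(all(refs$A != refs$F))
  pos <- names(refs$A)
  set.seed(4)
  for (k in 1:20) {
    prof <- stats::setNames(sample(aas, 8, replace = TRUE), pos)
    lc <- classifyLineage(prof, refs)
    swapped <- classifyLineage(prof, list(A = refs$F, F = refs$A))
    expect_equal(lc$matches_A, swapped$matches_F)
    expect_equal(lc$matches_F, swapped$matches_A)
    expect_lte(lc$matches_A + lc$matches_F, 8L)
  }
  # undefined positions match neither side and can force ambiguity
  und <- stats::setNames(rep(NA_character_, 8), pos)
  lu <- classifyLineage(und, refs)
  expect_equal(lu$matches_A + lu$matches_F, 0L)
  expect_equal(lu$call, "ambiguous")
})

test_that("conservation summary reports modal residues and frequencies", {
  tpl <- makeTemplates()
  mapA <- detectMatureStart(tpl$A$precursor)
  profs <- replicate(4, diagnosticProfile(mapA, "x"), simplify = FALSE)
  # one divergent sequence at position 13
  preD <- tpl$A$precursor
  substr(preD, 33, 33) <- "W" # mature position 13 = precursor index 33
  profs[[5]] <- diagnosticProfile(detectMatureStart(preD), "d")
  cs <- conservationSummary(profs, rep("gar", 5))
  r13 <- cs[cs$position == 13, ]
  expect_equal(r13$modal_residue, "I")
  expect_equal(r13$frequency, 4 / 5)
  expect_equal(r13$matches, "A")
  expect_true(all(cs$frequency[cs$position != 13] == 1))
  # single sequence: all frequencies 1
  cs1 <- conservationSummary(profs[1], "solo")
  expect_true(all(cs1$frequency == 1))
})
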