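library(ape)

mkMsa <- function(rows) new("Msa", ids = names(rows), rows = unname(rows))

test_that("distance matrix follows the p and Poisson definitions", {
  rows <- c(a = strrep("A", 100), b = strrep("A", 100),
            c = paste0(strrep("A", 99), "C"))
  msa <- mkMsa(rows)
  Dp <- distanceMatrix(msa, "p")
  expect_equal(Dp["a", "b"], 0)
  expect_equal(Dp["a", "c"], 0.01)
  Dq <- distanceMatrix(msa, "poisson")
  expect_equal(Dq["a", "c"], -log(0.99))
  expect_equal(Dq["a", "b"], 0)
  # saturation error under the Poisson correction
  sat <- mkMsa(c(a = "AAAA", b = "CCCC", c = "AAAA"))
  expect_error(distanceMatrix(sat, "poisson"), "saturated")
  # zero shared columns
  disj <- mkMsa(c(a = "AA--", b = "--CC", c = "AACC"))
  expect_error(distanceMatrix(disj, "p"), "shared")
  # gap columns excluded from the denominator
  gp <- mkMsa(c(a = "AC-G", b = "ACTG", c = "AATG"))
  D <- distanceMatrix(gp, "p")
  expect_equal(D["a", "c"], 1 / 3)
})

test_that("three-taxon NJ matches the closed-form pendant lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(D)
  pl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(unname(pl["a"]), (3 + 4 - 5) / 2, tolerance = 1e-5)
  expect_equal(unname(pl["b"]), (3 + 5 - 4) / 2, tolerance = 1e-5)
  expect_equal(unname(pl["c"]), (4 + 5 - 3) / 2, tolerance = 1e-5)
})

test_that("NJ recovers generating topology and path lengths on additive
           matrices (brute-force oracle)", {
  set.seed(99)
  for (ntax in c(4, 5)) {
    for (k in 1:10) {
      ra <- randomAdditive(ntax)
      tr <- neighborJoining(ra$D)
      # oracle: least-squares over all 3 (or 15) unrooted topologies
      best <- bestTopologyLS(ra$D)
      expect_true(sameTopology(tr, best))
      expect_true(sameTopology(tr, ra$tree))
      ids <- rownames(ra$D)
      expect_equal(ape::cophenetic.phylo(tr)[ids, ids], ra$D,
                   tolerance = 1e-4)
    }
  }
})

test_that("NJ path-length recovery holds across 50 seeded 5-taxon draws", {
  set.seed(1234)
  for (k in 1:50) {
    ra <- randomAdditive(5)
    tr <- neighborJoining(ra$D)
    ids <- rownames(ra$D)
    expect_true(sameTopology(tr, ra$tree))
    expect_equal(ape::cophenetic.phylo(tr)[ids, ids], ra$D,
                 tolerance = 1e-4)
  }
})

test_that("NJ topology agrees with an independent implementation", {
  set.seed(7)
  for (k in 1:10) {
    n <- sample(5:9, 1)
    D <- as.matrix(stats::dist(matrix(stats::rnorm(n * 6), n)))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_true(sameTopology(neighborJoining(D), ape::nj(D)))
  }
  expect_error(neighborJoining(matrix(c(0, Inf, Inf, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "taxa|finite")
})

test_that("bootstrap supports are deterministic, order-invariant and
           degenerate at one replicate", {
  set.seed(21)
  seqs <- c(stats::setNames(vapply(1:4, function(i) {
    s <- strsplit(randomProtein(120), "")[[1]]
    s[sample(120, 6)] <- "A"
    paste(s, collapse = "")
  }, character(1)), paste0("u", 1:4)))
  msa <- progressiveMsa(seqs)
  t1 <- bootstrapSupport(msa, "p", nReps = 20, seed = 5)
  t2 <- bootstrapSupport(msa, "p", nReps = 20, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # taxon order invariance after canonical sorting
  ord <- c(3, 1, 4, 2)
  msaR <- new("Msa", ids = msaIds(msa)[ord], rows = msaRows(msa)[ord])
  t3 <- bootstrapSupport(msaR, "p", nReps = 20, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t3))
  # single replicate: supports only 0 or 100
  t4 <- bootstrapSupport(msa, "p", nReps = 1, seed = 9)
  sup <- suppressWarnings(as.numeric(t4$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("well-separated simulated clades get high bootstrap support", {
  sim <- simulateTranscriptome(smallSpec(seed = 2024))
  rep <- runPipeline(contigs = sim$contigs, bootstrapReps = 100, seed = 11)
  tree <- reportTree(rep)
  ty <- typingTable(rep)
  aTips <- c(ty$seq_id[ty$lineage_diagnostic == "A"], "ref_PSMB8_A")
  fTips <- c(ty$seq_id[ty$lineage_diagnostic == "F"], "ref_PSMB8_F")
  expect_true(isMonophyletic(tree, aTips))
  expect_true(isMonophyletic(tree, fTips))
  ntip <- length(tree$tip.label)
  supOf <- function(tips) {
    as.numeric(tree$node.label[ape::getMRCA(tree, tips) - ntip])
  }
  expect_gte(supOf(aTips), 95)
  expect_gte(supOf(fTips), 95)
})

test_that("outgroup rooting splits outgroup from ingroup at the midpoint", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,og:1):1);")
  tr <- ape::unroot(tr)
  rooted <- rootWithOutgroup(tr, "og")
  expect_true(ape::is.rooted(rooted))
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  sides <- lapply(kids, function(k) {
    if (k <= length(rooted$tip.label)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label
  })
  og <- vapply(sides, function(s) identical(s, "og"), logical(1))
  expect_true(any(og))
  expect_setequal(sides[[which(!og)]], c("a", "b", "c"))
  # midpoint: the two root edges have equal length
  re <- which(rooted$edge[, 1] == root)
  expect_equal(rooted$edge.length[re[1]], rooted$edge.length[re[2]])
  # scattered outgroup -> error
  expect_error(rootWithOutgroup(tr, c("a", "og")), "monophyletic")
  expect_error(rootWithOutgroup(tr, "zz"), "not in tree")
})

test_that("monophyly checks and clade-based lineage assignment", {
  tr <- ape::read.tree(
    text = "(((q1:1,refA:1):1,refA2:1):2,((q2:1,refF:1):1,og:3):2);")
  expect_true(isMonophyletic(tr, c("q1", "refA", "refA2")))
  expect_false(isMonophyletic(tr, c("q1", "refF")))
  expect_true(isMonophyletic(tr, "q1"))
  expect_true(isMonophyletic(tr, tr$tip.label))
  expect_error(isMonophyletic(tr, "nope"), "unknown")

  refs <- c(refA = "A", refA2 = "A", refF = "F")
  expect_equal(assignLineageByClade(tr, refs, "q1"), "A")
  expect_equal(assignLineageByClade(tr, refs, "q2"), "F")
  expect_error(assignLineageByClade(tr, refs, "refA"), "itself")
  # query hanging at the root between the two reference clades: unresolved
  tr2 <- ape::read.tree(text = "((refA:1,refF:1):1,(q3:1,og:1):1);")
  expect_equal(assignLineageByClade(tr2, c(refA = "A", refF = "F"), "q3"),
               "unresolved")
})

test_that("newick output round-trips through the reader", {
  set.seed(8)
  ra <- randomAdditive(6)
  tr <- neighborJoining(ra$D)
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  back <- readNewick(f)
  expect_true(sameTopology(tr, back))
  expect_setequal(back$tip.label, tr$tip.label)
})
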