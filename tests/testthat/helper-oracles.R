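# Independent oracles and small fixture builders used across the suite.

# Plain Needleman-Wunsch score with LINEAR gap penalty (no affine states):
# the brute-force oracle for the global aligner when gapOpen == gapExtend.
nwLinearScore <- function(a, b, mat, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1, m + 1)
  D[1, ] <- gap * (0:m)
  D[, 1] <- gap * (0:n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- max(D[i, j] + mat[ca[i], cb[j]],
                           D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# Random unrooted tree with strictly positive branch lengths and its
# additive path-distance matrix.
randomAdditive <- function(ntax) {
  tr <- ape::rtree(ntax, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1.5)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Brute-force topology oracle: least-squares branch-length fit of every
# unrooted topology on the taxa; the generating topology of an additive
# matrix fits with (near-)zero residual and uniquely minimises it.
bestTopologyLS <- function(D) {
  ids <- rownames(D)
  tops <- phangorn::allTrees(length(ids), rooted = FALSE, tip.label = ids)
  resid <- vapply(tops, function(tp) {
    fit <- phangorn::nnls.tree(D, tp, method = "unrooted")
    sum((ape::cophenetic.phylo(fit)[ids, ids] - D)^2)
  }, numeric(1))
  tops[[which.min(resid)]]
}

sameTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Small simulation spec (subset of the default study structure) for tests
# that do not need the full cohort.
smallSpec <- function(seed, mu = 0.02, indelProb = 0, decoys = 3L,
                      randomContigs = 3L) {
  g <- defaultSimGroups(mu = mu, indelProb = indelProb)
  g$n <- c(3L, 4L, 2L, 3L, 4L)
  simSpec(groups = g, decoys = decoys, randomContigs = randomContigs,
          seed = seed)
}

randomProtein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

tmpFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
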