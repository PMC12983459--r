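# Distance-based phylogeny: p/Poisson distances, neighbor joining with
# deterministic tie-breaking, nonparametric column-resampling bootstrap,
# outgroup rooting, and lineage assignment by clade membership. Trees are
# ape "phylo" objects throughout.

.msaCharMatrix <- function(msa) {
  m <- matrix(unlist(strsplit(msa@rows, ""), use.names = FALSE),
              nrow = length(msa@rows), byrow = TRUE)
  rownames(m) <- msa@ids
  m
}

.distFromChars <- function(chm, model) {
  n <- nrow(chm)
  ids <- rownames(chm)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  isres <- chm != "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- isres[i, ] & isres[j, ]
    ns <- sum(shared)
    if (ns == 0L)
      stop("no shared (gap-free) columns between '", ids[i], "' and '",
           ids[j], "'")
    p <- sum(chm[i, shared] != chm[j, shared]) / ns
    d <- if (model == "poisson") {
      if (p >= 1) stop("saturated distance (p = 1) between '", ids[i],
                       "' and '", ids[j], "' under the Poisson correction")
      -log(1 - p)
    } else p
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance over columns where both rows carry a residue; the Poisson
#' correction is \eqn{-\ln(1 - p)}.
#'
#' @param msa an [Msa-class] with at least 3 rows.
#' @param model `"p"` or `"poisson"`.
#' @return symmetric numeric matrix with sequence ids as dimnames.
#' @export
distanceMatrix <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(is(msa, "Msa"))
  if (length(msa@ids) < 3L) stop("need at least 3 sequences")
  .distFromChars(.msaCharMatrix(msa), model)
}

.quoteTip <- function(x) ifelse(grepl("\\s", x), sprintf("'%s'", x), x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining with the standard Q-criterion. Ties in the
#' Q matrix are broken by the lexicographically smallest index pair, making
#' the result deterministic. Negative branch-length estimates are clamped
#' to zero with the deficit transferred to the sister branch.
#'
#' @param dm symmetric distance matrix with ids as dimnames (>= 3 taxa,
#'   finite entries).
#' @return unrooted `phylo` object.
#' @export
neighborJoining <- function(dm) {
  if (is.null(rownames(dm))) stop("distance matrix must have ids as dimnames")
  if (any(!is.finite(dm))) stop("non-finite distances")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  D <- dm
  nodes <- .quoteTip(rownames(dm)) # newick fragment per active node

  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lexicographically smallest (i, j) among the minima, i < j
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    newn <- sprintf("(%s:%.6f,%s:%.6f)", nodes[i], li, nodes[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newn)
    D <- D2
  }
  # terminal three-node star: closed-form pendant lengths
  la <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.6f,%s:%.6f,%s:%.6f);",
                 nodes[1], la, nodes[2], lb, nodes[3], lc)
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the point-estimate NJ tree, then resamples alignment columns with
#' replacement `nReps` times, rebuilds the tree for each replicate, and
#' records for each internal bipartition of the point tree the percentage
#' of replicates containing it (stored in `node.label`). Rows are sorted by
#' id before any computation, so supports do not depend on input order.
#'
#' @param msa an [Msa-class] (>= 3 rows).
#' @param model distance model, `"p"` or `"poisson"`.
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed RNG seed; the whole computation is deterministic given
#'   `seed`.
#' @return unrooted `phylo` with `node.label` = support in \[0, 100\].
#' @export
bootstrapSupport <- function(msa, model = c("p", "poisson"), nReps = 200L,
                             seed = 42L) {
  model <- match.arg(model)
  stopifnot(nReps >= 1L)
  ord <- order(msa@ids)
  msa <- new("Msa", ids = msa@ids[ord], rows = msa@rows[ord])
  chm <- .msaCharMatrix(msa)
  point <- neighborJoining(.distFromChars(chm, model))
  L <- ncol(chm)
  trees <- vector("list", nReps)
  set.seed(as.integer(seed))
  for (b in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    trees[[b]] <- neighborJoining(.distFromChars(chm[, cols, drop = FALSE],
                                                 model))
  }
  class(trees) <- "multiPhylo"
  cnt <- ape::prop.clades(point, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  point$node.label <- as.character(round(100 * cnt / nReps))
  point
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the branch separating the outgroup
#' from the ingroup. The outgroup must be monophyletic in the unrooted
#' tree.
#'
#' @param tree a `phylo`.
#' @param outgroupIds character vector of outgroup tip labels.
#' @return rooted `phylo`.
#' @export
rootWithOutgroup <- function(tree, outgroupIds) {
  stopifnot(length(outgroupIds) >= 1L)
  missing <- setdiff(outgroupIds, tree$tip.label)
  if (length(missing))
    stop("outgroup tip(s) not in tree: ", paste(missing, collapse = ", "))
  rooted <- tryCatch(
    # edgelabel: node labels are bootstrap supports, i.e. edge-associated;
    # this keeps them attached to the correct bipartition across rerooting
    ape::root(tree, outgroup = outgroupIds, resolve.root = TRUE,
              edgelabel = TRUE),
    error = function(e)
      stop("outgroup is not monophyletic: ",
           paste(outgroupIds, collapse = ", "), call. = FALSE))
  if (!ape::is.monophyletic(rooted, outgroupIds))
    stop("outgroup is not monophyletic: ",
         paste(outgroupIds, collapse = ", "))
  rootNode <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == rootNode)
  if (length(re) == 2L) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  rooted
}

# tip labels descending from an internal node
.cladeTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .cladeTips, tree = tree))
}

#' Is a set of tips monophyletic?
#'
#' True iff some node's descendant tip set equals `tips` exactly.
#'
#' @param tree rooted `phylo`.
#' @param tips character vector of tip labels.
#' @return logical
#' @export
isMonophyletic <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("unknown tip(s): ", paste(missing, collapse = ", "))
  if (length(tips) <= 1L) return(TRUE)
  if (setequal(tips, tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Assign a lineage by clade membership
#'
#' Walks from the query tip toward the root; the first ancestor with at
#' least one labeled reference among its descendant tips decides: if all
#' such references carry one label, that label is returned, otherwise the
#' walk ends `"unresolved"` (adding ancestors can never make a mixed set
#' uniform).
#'
#' @param tree rooted `phylo`.
#' @param labeledRefs named character vector, reference tip label ->
#'   lineage label (both lineages must be represented).
#' @param query tip label to place (must not itself be a reference).
#' @return one of the reference labels, or `"unresolved"`.
#' @export
assignLineageByClade <- function(tree, labeledRefs, query) {
  stopifnot(length(unique(labeledRefs)) >= 2L)
  if (query %in% names(labeledRefs))
    stop("query '", query, "' is itself a labeled reference")
  if (!query %in% tree$tip.label) stop("unknown tip: ", query)
  missing <- setdiff(names(labeledRefs), tree$tip.label)
  if (length(missing))
    stop("reference tip(s) not in tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  node <- match(query, tree$tip.label)
  rootNode <- ntip + 1L
  repeat {
    node <- parent[node]
    if (node == 0L) return("unresolved")
    tips <- .cladeTips(tree, node)
    lab <- unique(labeledRefs[intersect(tips, names(labeledRefs))])
    if (length(lab) == 1L) return(unname(lab))
    if (length(lab) > 1L) return("unresolved")
    if (node == rootNode) return("unresolved")
  }
}

#' Write a tree as Newick
#'
#' Bootstrap supports (node labels) are written as internal node labels.
#'
#' @param tree `phylo`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path input path
#' @return `phylo`
#' @export
readNewick <- function(path) {
  ape::read.tree(path)
}
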