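## Phylogenetic sanity layer: p-distances, neighbor-joining, outgroup
## rooting and monophyly tests. This layer exists to assert clade structure
## on synthetic benchmark sets at desk scale; it is a distance-based stand-in,
## not a maximum-likelihood phylogeny.

#' Pairwise p-distance matrix from an aligned set
#'
#' `d(i, j)` is the mismatch fraction over columns where both rows hold a
#' residue (gaps excluded pairwise). Pairs with no comparable column raise
#' an error.
#'
#' @param aln An [alignedSet()] with at least three rows.
#' @return A symmetric numeric matrix with zero diagonal, labelled by ids.
#' @export
#' @examples
#' aln <- alignedSet(c(a = "KKKK", b = "KKKA", c = "KAAA"))
#' pDistance(aln)["a", "b"]
pDistance <- function(aln) {
  if (length(aln$rows) < 3) stop("need at least three rows")
  M <- .alnMatrix(aln)
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between ", aln$ids[i], " and ", aln$ids[j])
    d[i, j] <- d[j, i] <- mean(M[i, ok] != M[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; negative branch lengths are
#' clamped to zero. Additive distances are recovered exactly.
#'
#' @param d Symmetric distance matrix with labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("need at least three labels")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Test monophyly of a leaf set after outgroup rooting
#'
#' Roots the tree at the outgroup (a single label, or the most recent
#' common ancestor branch of several labels) and reports whether `leaf_set`
#' is exactly the leaf set of some rooted subtree.
#'
#' @param tree An `ape::phylo` tree.
#' @param leaf_set Character vector of leaf labels (non-empty).
#' @param outgroup Character vector of outgroup leaf labels.
#' @return Logical scalar.
#' @export
isMonophyletic <- function(tree, leaf_set, outgroup) {
  labs <- tree$tip.label
  unknown <- setdiff(c(leaf_set, outgroup), labs)
  if (length(unknown)) stop("unknown labels: ", paste(unknown, collapse = ", "))
  if (length(leaf_set) == 0) stop("leaf_set must be non-empty")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, leaf_set)
}

## Pairwise p-distances from per-pair global alignments (BLOSUM62, affine
## gaps); more robust across divergent tails than a single multiple
## alignment.
.pairwiseDistances <- function(seqs) {
  n <- length(seqs)
  ss <- Biostrings::AAStringSet(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- Biostrings::pairwiseAlignment(ss[i], ss[j],
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5,
                                       type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]]
    ok <- p != "-" & s != "-"
    d[i, j] <- d[j, i] <- mean(p[ok] != s[ok])
  }
  d
}

#' Class monophyly report for a labelled benchmark set
#'
#' Computes pairwise p-distances from per-pair global alignments, builds a
#' neighbor-joining tree, roots it on the H2A.Z leaves, and reports per
#' class whether the class forms a clade.
#'
#' @param set An [H2ASet-class] with truth labels including `H2A.Z`.
#' @param outgroup_class Class used as outgroup (default `"H2A.Z"`).
#' @return A list with `tree` (rooted `phylo`) and `monophyly` (named
#'   logical per class).
#' @export
classMonophyly <- function(set, outgroup_class = "H2A.Z") {
  truth <- truthLabels(set)
  if (!outgroup_class %in% truth) stop("outgroup class absent from set")
  seqs <- stats::setNames(
    vapply(seq_along(sequences(set)),
           function(i) as.character(sequences(set)[[i]]), character(1)),
    names(sequences(set)))
  tr <- njTree(.pairwiseDistances(seqs))
  og <- names(truth)[truth == outgroup_class]
  rooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
  classes <- setdiff(unique(truth), outgroup_class)
  mono <- vapply(classes, function(cl)
    ape::is.monophyletic(rooted, names(truth)[truth == cl]), logical(1))
  ## the outgroup itself: monophyletic iff it forms one side of the root
  mono[outgroup_class] <- ape::is.monophyletic(rooted, og)
  list(tree = rooted, monophyly = mono)
}

#' Write a tree as newick
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
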