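#' Pairwise p-distance matrix from a protein alignment
#'
#' p-distance = fraction of mismatching residue pairs over the columns
#' compared. Under pairwise deletion (`mode = "pairwise"`, the default)
#' each pair skips only the columns where either sequence has a gap; under
#' complete deletion (`mode = "complete"`) columns containing any gap are
#' dropped for all pairs before counting. `X` is treated as a residue and
#' compared literally.
#'
#' @param alignment a gapped [Biostrings::AAStringSet] (>= 2 sequences).
#' @param mode `"pairwise"` (pairwise deletion) or `"complete"`
#'   (complete deletion).
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence ID.
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "AAAA", b = "AATT"))
#' pDistanceMatrix(aln)["a", "b"]  # 0.5
#' @export
pDistanceMatrix <- function(alignment, mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  .checkAlignment(alignment)
  chars <- do.call(rbind, strsplit(as.character(alignment), ""))
  rownames(chars) <- names(alignment)
  if (mode == "complete") {
    keep <- colSums(chars == GAP_CHAR) == 0L
    if (!any(keep))
      stop("no gap-free columns for complete-deletion distances")
    chars <- chars[, keep, drop = FALSE]
  }
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  isGap <- chars == GAP_CHAR
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- !isGap[i, ] & !isGap[j, ]
      nc <- sum(use)
      if (nc == 0L)
        stop("no comparable columns between ", rownames(chars)[i],
             " and ", rownames(chars)[j])
      mis <- sum(chars[i, use] != chars[j, use])
      d[i, j] <- d[j, i] <- mis / nc
    }
  }
  d
}

#' Write a distance matrix as TSV
#'
#' @param d labelled symmetric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row and column labels")
  if (any(d < 0))
    stop("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei Q-criterion, via [ape::nj()]).
#' For an additive input matrix the leaf-to-leaf path lengths of the
#' reconstructed tree reproduce the matrix exactly. Negative branch-length
#' estimates (possible on non-additive input) are clamped to zero with the
#' deficit transferred to the sibling edge, which keeps leaf-to-leaf path
#' lengths approximately intact.
#'
#' @param d labelled symmetric non-negative matrix with zero diagonal,
#'   >= 3 labels.
#' @return an [ape::phylo] tree (unrooted, branch lengths >= 0).
#' @export
neighborJoining <- function(d) {
  .checkDistanceMatrix(d)
  if (nrow(d) < 3L) stop("neighbor joining requires >= 3 labels")
  tree <- ape::nj(as.dist(d))
  .clampNegativeEdges(tree)
}

# Set negative edge estimates to 0 and transfer the deficit to the sibling
# edge (the edge of the other child of the same parent node), preserving
# path lengths through the parent as far as possible.
.clampNegativeEdges <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sibs)) {
      s <- sibs[1L]
      el[s] <- el[s] + el[e]
    }
    el[e] <- 0
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return symmetric matrix of patristic distances, labelled by leaf.
#' @export
pathLengthMatrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

#' Assign every leaf to the clade of its nearest reference enzyme
#'
#' Clades are seeded by characterized reference enzymes: each leaf is
#' assigned the clade of the reference with the smallest leaf-to-leaf path
#' length, ties broken lexicographically by clade name. References map to
#' themselves. This nearest-reference rule reads subclades off the tree
#' without enforcing monophyly.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param references named character vector: reference leaf label ->
#'   clade name.
#' @return named character vector: leaf label -> clade name.
#' @export
assignClades <- function(tree, references) {
  if (length(references) == 0L) stop("references must be non-empty")
  refLeaves <- names(references)
  absent <- setdiff(refLeaves, tree$tip.label)
  if (length(absent))
    stop("reference leaf/leaves not in tree: ", paste(absent, collapse = ", "))
  pd <- pathLengthMatrix(tree)
  out <- vapply(tree$tip.label, function(leaf) {
    dist <- pd[leaf, refLeaves]
    best <- which(dist == min(dist))
    cand <- sort(unname(references[refLeaves[best]]))
    cand[1L]
  }, "")
  names(out) <- tree$tip.label
  out
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
readNewick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  tree
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
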