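# Independent brute-force oracles and random fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# textbook sum-form Pearson coefficient, coded independently of stats::cor
pearsonOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# per-pair column scan p-distance with pairwise deletion
pdistOracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  used <- 0L; mis <- 0L
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      used <- used + 1L
      if (a[k] != b[k]) mis <- mis + 1L
    }
  }
  mis / used
}

randomAlignment <- function(n, width, gapProb = 0.1, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("sq%02d", seq_len(n))
  m <- matrix(sample(AA20, n * width, replace = TRUE), n, width)
  if (gapProb > 0) {
    g <- matrix(runif(n * width) < gapProb, n, width)
    # keep at least one residue per row and one shared gap-free column
    g[, 1] <- FALSE
    m[g] <- "-"
  }
  aln <- Biostrings::AAStringSet(apply(m, 1, paste, collapse = ""))
  names(aln) <- ids
  aln
}

randomUngappedSet <- function(n, width) {
  m <- matrix(sample(AA20, n * width, replace = TRUE), n, width)
  seqs <- Biostrings::AAStringSet(apply(m, 1, paste, collapse = ""))
  names(seqs) <- sprintf("rec%03d", seq_len(n))
  seqs
}

# random additive distance matrix: path lengths of a random bifurcating
# tree with strictly positive branch lengths
randomAdditiveMatrix <- function(nTaxa) {
  tree <- ape::rtree(nTaxa, br = function(n) runif(n, 0.05, 1))
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(d = d[ord, ord], tree = tree)
}

# state table built directly, bypassing alignment extraction
makeStateTable <- function(states, positions, clusters = NULL,
                           templateId = rownames(states)[1]) {
  if (is.null(clusters)) clusters <- rep("S", length(positions))
  methods::new("SiteStateTable", states = states,
               positions = as.integer(positions), clusters = clusters,
               templateId = templateId)
}
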