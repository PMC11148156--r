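# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness flows through this one seeded stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct a FamilySpec
#'
#' Defaults emulate the study conditions the package's analyses assume: a
#' handful of homologous oxidases (8 members) split over three clades,
#' moderate sequence divergence, and a multiplicative activity model
#' (linear in log10 space) with planted property couplings at chosen
#' positions.
#'
#' @param nSequences number of family members (default 8).
#' @param length sequence length (default 60).
#' @param cladeSizes clade sizes summing to `nSequences` (default: 3
#'   near-equal clades).
#' @param substitutionRate per-position substitution probability away from
#'   the clade founder (default 0.15; founders diverge from the common
#'   ancestor at twice this rate, capped at 1).
#' @param plantedPositions positions carrying an activity coupling.
#' @param plantedResidues list of allowed residue sets per planted
#'   position.
#' @param plantedSlopes slope b (log10 activity per property unit) per
#'   planted position.
#' @param baselineLog10 intercept of the activity model (default 0).
#' @param noiseSd Gaussian noise sd in log10 units (default 0.2).
#' @param detectionFloor rates below this (s^-1) are reported
#'   not-detected (default 1e-3).
#' @param indelRate per-position gap probability in non-template
#'   sequences (default 0).
#' @param seed RNG seed (generation is bit-reproducible given the seed).
#' @return a [FamilySpec-class] object.
#' @export
familySpec <- function(nSequences = 8L, length = 60L,
                       cladeSizes = NULL, substitutionRate = 0.15,
                       plantedPositions = integer(),
                       plantedResidues = list(),
                       plantedSlopes = numeric(),
                       baselineLog10 = 0, noiseSd = 0.2,
                       detectionFloor = 1e-3, indelRate = 0,
                       seed = 1L) {
  nSequences <- as.integer(nSequences)
  if (is.null(cladeSizes)) {
    k <- min(3L, nSequences)
    base <- nSequences %/% k
    cladeSizes <- rep(base, k)
    extra <- nSequences - base * k
    if (extra > 0) cladeSizes[seq_len(extra)] <- cladeSizes[seq_len(extra)] + 1L
  }
  methods::new("FamilySpec",
               nSequences = nSequences, length = as.integer(length),
               cladeSizes = as.integer(cladeSizes),
               substitutionRate = substitutionRate,
               plantedPositions = as.integer(plantedPositions),
               plantedResidues = plantedResidues,
               plantedSlopes = as.numeric(plantedSlopes),
               baselineLog10 = baselineLog10, noiseSd = noiseSd,
               detectionFloor = detectionFloor, indelRate = indelRate,
               seed = as.integer(seed))
}

.mutateSeq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    # draw a replacement different from the current residue
    repl <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_CANONICAL, a), 1L)
    }, "")
    chars[hit] <- repl
  }
  chars
}

#' Generate a synthetic enzyme family
#'
#' Evolves a random ancestor along a simple clade topology: each clade
#' founder diverges from the ancestor at twice the within-clade
#' substitution rate (capped at 1), and each member diverges from its
#' founder at the within-clade rate, independently per position (uniform
#' substitution model, no rate heterogeneity). Planted positions are then
#' overwritten with states drawn uniformly from their allowed residue
#' sets, so their variation is decoupled from the phylogeny. Optional
#' indels place gaps in non-template sequences to exercise gap handling.
#' The first sequence (`enz01`) is the designated template and stays
#' ungapped.
#'
#' The same seed yields bit-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [FamilySpec-class].
#' @return list with `alignment` (gapped [Biostrings::AAStringSet]),
#'   `tree` (the generating topology as [ape::phylo], branch lengths =
#'   expected substitutions per site), `clades` (named character vector
#'   sequence -> clade label), and `ancestor` (character string).
#' @export
generateFamily <- function(spec) {
  stopifnot(methods::is(spec, "FamilySpec"))
  methods::validObject(spec)
  .withSeed(spec@seed, {
    L <- spec@length
    ancestor <- sample(AA_CANONICAL, L, replace = TRUE)
    founderRate <- min(1, 2 * spec@substitutionRate)
    ids <- sprintf("enz%02d", seq_len(spec@nSequences))
    cladeLab <- rep(sprintf("clade%d", seq_along(spec@cladeSizes)),
                    spec@cladeSizes)
    seqs <- character(spec@nSequences)
    i <- 0L
    for (c in seq_along(spec@cladeSizes)) {
      founder <- .mutateSeq(ancestor, founderRate)
      for (k in seq_len(spec@cladeSizes[c])) {
        i <- i + 1L
        seqs[i] <- paste(.mutateSeq(founder, spec@substitutionRate),
                         collapse = "")
      }
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    # planted states: uniform over the allowed set, independent of clade
    for (p in seq_along(spec@plantedPositions)) {
      pos <- spec@plantedPositions[p]
      mat[, pos] <- sample(spec@plantedResidues[[p]], spec@nSequences,
                           replace = TRUE)
    }
    if (spec@indelRate > 0 && spec@nSequences > 1L) {
      gap <- matrix(stats::runif(length(mat)) < spec@indelRate,
                    nrow(mat), ncol(mat))
      gap[1L, ] <- FALSE  # template stays ungapped
      mat[gap] <- GAP_CHAR
    }
    aln <- Biostrings::AAStringSet(apply(mat, 1L, paste, collapse = ""))
    names(aln) <- ids
    nwkClades <- vapply(seq_along(spec@cladeSizes), function(c) {
      members <- ids[cladeLab == sprintf("clade%d", c)]
      if (length(members) == 1L)
        sprintf("%s:%g", members, spec@substitutionRate + founderRate)
      else
        sprintf("(%s):%g",
                paste(sprintf("%s:%g", members, spec@substitutionRate),
                      collapse = ","),
                founderRate)
    }, "")
    tree <- ape::read.tree(text = paste0("(", paste(nwkClades,
                                                    collapse = ","), ");"))
    list(alignment = aln, tree = tree,
         clades = stats::setNames(cladeLab, ids),
         ancestor = paste(ancestor, collapse = ""))
  })
}

#' Build a SiteScheme over positions of a synthetic family
#'
#' Convenience for pipeline tests: anchors a scheme on the family's
#' template sequence (`enz01` by default), taking the expected residues
#' from that sequence itself.
#'
#' @param family list returned by [generateFamily()].
#' @param positions template positions to include.
#' @param cluster single cluster label for all positions (default "S"),
#'   or a character vector parallel to `positions`.
#' @param templateId template sequence ID.
#' @return a [SiteScheme-class].
#' @export
familyScheme <- function(family, positions, cluster = "S",
                         templateId = names(family$alignment)[1L]) {
  tmpl <- strsplit(as.character(family$alignment[[templateId]]), "")[[1]]
  tmpl <- tmpl[tmpl != GAP_CHAR]
  if (any(positions > length(tmpl)))
    stop("position(s) beyond template length")
  if (length(cluster) == 1L) cluster <- rep(cluster, length(positions))
  tokens <- split(paste0(tmpl[positions], positions), cluster)
  siteScheme(templateId, tokens)
}

#' Generate activities from the planted sequence-function model
#'
#' For each enzyme and substrate, the activity follows the multiplicative
#' model `log10(rate) = a + sum_p b_p * property(state_p) + eps`,
#' `eps ~ N(0, noiseSd)`, with the sum over the planted positions.
#' Enzymes with a gap at a planted position, and rates falling below the
#' detection floor, are reported not-detected. Seed-deterministic: the
#' RNG stream is `spec@seed + 1` so that activities are reproducible
#' independently of family generation.
#'
#' @param alignment the family alignment from [generateFamily()].
#' @param spec the [FamilySpec-class] used to generate the family.
#' @param scale a [PropertyScale-class] giving `property(state)`.
#' @param substrates substrate IDs (one independent noise draw each).
#' @return an [ActivityTable-class].
#' @export
generateActivities <- function(alignment, spec, scale,
                               substrates = "s1") {
  stopifnot(methods::is(spec, "FamilySpec"))
  vals <- scaleValues(scale)
  mat <- do.call(rbind, strsplit(as.character(alignment), ""))
  rownames(mat) <- names(alignment)
  .withSeed(spec@seed + 1L, {
    n <- nrow(mat)
    rates <- matrix(NA_real_, n, length(substrates),
                    dimnames = list(rownames(mat), substrates))
    signal <- rep(spec@baselineLog10, n)
    missing <- rep(FALSE, n)
    for (p in seq_along(spec@plantedPositions)) {
      st <- mat[, spec@plantedPositions[p]]
      prop <- ifelse(st %in% names(vals), vals[st], NA_real_)
      missing <- missing | is.na(prop)
      signal <- signal + spec@plantedSlopes[p] * prop
    }
    for (j in seq_along(substrates)) {
      eps <- stats::rnorm(n, 0, spec@noiseSd)
      lg <- signal + eps
      r <- 10^lg
      r[missing] <- NA_real_
      r[!is.na(r) & r < spec@detectionFloor] <- NA_real_
      rates[, j] <- r
    }
    activityTable(rates, detectionFloor = spec@detectionFloor)
  })
}

#' Write a FamilySpec as a YAML config
#'
#' @param spec a [FamilySpec-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFamilySpec <- function(spec, path) {
  yaml::write_yaml(list(
    nSequences = spec@nSequences, length = spec@length,
    cladeSizes = as.list(spec@cladeSizes),
    substitutionRate = spec@substitutionRate,
    plantedPositions = as.list(spec@plantedPositions),
    plantedResidues = spec@plantedResidues,
    plantedSlopes = as.list(spec@plantedSlopes),
    baselineLog10 = spec@baselineLog10, noiseSd = spec@noiseSd,
    detectionFloor = spec@detectionFloor, indelRate = spec@indelRate,
    seed = spec@seed), path)
  invisible(path)
}

#' Read a FamilySpec from YAML
#'
#' @param path path written by [writeFamilySpec()].
#' @return a [FamilySpec-class].
#' @export
readFamilySpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  familySpec(nSequences = cfg$nSequences, length = cfg$length,
             cladeSizes = unlist(cfg$cladeSizes),
             substitutionRate = cfg$substitutionRate,
             plantedPositions = unlist(cfg$plantedPositions),
             plantedResidues = lapply(cfg$plantedResidues, unlist),
             plantedSlopes = unlist(cfg$plantedSlopes),
             baselineLog10 = cfg$baselineLog10, noiseSd = cfg$noiseSd,
             detectionFloor = cfg$detectionFloor,
             indelRate = cfg$indelRate, seed = cfg$seed)
}
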