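# Published amino-acid property tables shipped with the package.
# volume: Zamyatnin (1972), total residue volume in A^3.
# hydropathy: Kyte & Doolittle (1982).
# polarity: Grantham (1974).
.SCALE_TABLES <- list(
  volume = c(
    A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0
  ),
  hydropathy = c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  ),
  polarity = c(
    A =  8.1, R = 10.5, N = 11.6, D = 13.0, C =  5.5,
    Q = 10.5, E = 12.3, G =  9.0, H = 10.4, I =  5.2,
    L =  4.9, K = 11.3, M =  5.7, F =  5.2, P =  8.0,
    S =  9.2, T =  8.6, W =  5.4, Y =  6.2, V =  5.9
  )
)

.SCALE_META <- list(
  volume = c(units = "A^3",
             citation = "Zamyatnin (1972) Prog Biophys Mol Biol 24:107-123"),
  hydropathy = c(units = "",
                 citation = "Kyte & Doolittle (1982) J Mol Biol 157:105-132"),
  polarity = c(units = "",
               citation = "Grantham (1974) Science 185:862-864")
)

#' Construct a PropertyScale
#'
#' @param name scale name.
#' @param values named numeric vector covering the 20 canonical residues
#'   (one-letter codes).
#' @param units measurement units ("" if dimensionless).
#' @param citation provenance of the table.
#' @return a [PropertyScale-class] object.
#' @export
propertyScale <- function(name, values, units = "", citation = "user-supplied") {
  methods::new("PropertyScale", name = name, units = units,
               values = values[AA_CANONICAL], citation = citation)
}

#' Built-in amino-acid property scales
#'
#' Ships one canonical published table per property axis: total residue
#' volume (Zamyatnin 1972, A^3), hydropathy (Kyte-Doolittle 1982) and
#' polarity (Grantham 1974). Users may override any axis with their own
#' [propertyScale()] or a YAML file via [readPropertyScale()].
#'
#' @return named list of [PropertyScale-class] objects
#'   (`volume`, `hydropathy`, `polarity`).
#' @examples
#' builtinScales()$volume
#' @export
builtinScales <- function() {
  out <- lapply(names(.SCALE_TABLES), function(nm) {
    propertyScale(nm, .SCALE_TABLES[[nm]],
                  units = .SCALE_META[[nm]][["units"]],
                  citation = .SCALE_META[[nm]][["citation"]])
  })
  names(out) <- names(.SCALE_TABLES)
  out
}

#' Read a user property scale from YAML
#'
#' Layout: `name`, optional `units` and `citation`, and `values` mapping
#' each one-letter residue code to a number.
#'
#' @param path path to the YAML file.
#' @return a [PropertyScale-class] object.
#' @export
readPropertyScale <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$values))
    stop("scale config must provide 'name' and 'values'")
  vals <- unlist(cfg$values)
  propertyScale(as.character(cfg$name), vals,
                units = if (is.null(cfg$units)) "" else cfg$units,
                citation = if (is.null(cfg$citation)) "user-supplied"
                           else cfg$citation)
}

#' Per-clade residue diversity profiles
#'
#' For every (template position, clade) pair, the frequency of each residue
#' observed among the clade's sequences. Gap states are excluded from the
#' count `n`; frequencies are computed over non-gap states and sum to 1.
#' Clades with no sequence (or only gaps at a position) yield no profile
#' row for that position; an entirely empty clade raises a warning.
#'
#' @param states a [SiteStateTable-class].
#' @param clades named character vector mapping every sequence ID to a
#'   clade label.
#' @return a data.frame with columns `position`, `cluster`, `clade`,
#'   `residue`, `frequency`, `n`.
#' @export
diversityProfiles <- function(states, clades) {
  m <- siteStates(states)
  missing <- setdiff(rownames(m), names(clades))
  if (length(missing))
    stop("no clade label for sequence(s): ", paste(missing, collapse = ", "))
  cladeLevels <- unique(clades)
  clades <- clades[rownames(m)]
  rows <- list()
  for (cl in cladeLevels) {
    seqs <- rownames(m)[clades == cl]
    if (length(seqs) == 0L) {
      warning("clade '", cl, "' is empty; profile omitted")
      next
    }
    for (j in seq_along(states@positions)) {
      obs <- m[seqs, j]
      obs <- obs[obs != GAP_CHAR]
      if (length(obs) == 0L) next
      tab <- table(obs)
      rows[[length(rows) + 1L]] <- data.frame(
        position = states@positions[j],
        cluster = states@clusters[j],
        clade = cl,
        residue = names(tab),
        frequency = as.numeric(tab) / length(obs),
        n = length(obs),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write diversity profiles as TSV
#'
#' @param profiles data.frame from [diversityProfiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.stateProperty <- function(state, scale) {
  v <- scaleValues(scale)
  ifelse(state %in% names(v), v[state], NA_real_)
}

#' Aggregate a residue property over positions, per sequence
#'
#' Computes, for every sequence, the sum (or mean/max) of the scale value
#' of its residues at the requested positions. A sequence with a gap or an
#' `X` at any requested position gets `NA` (flagged missing, never zero).
#'
#' @param states a [SiteStateTable-class].
#' @param scale a [PropertyScale-class].
#' @param positions subset of the table's template positions
#'   (default: all).
#' @param aggregator `"sum"` (default, the combined-property convention),
#'   `"mean"` or `"max"`.
#' @return named numeric vector, one value per sequence (`NA` = missing).
#' @examples
#' # combined side-chain volume of a T/H-cluster triple is the sum of the
#' # per-residue volumes
#' @export
aggregateProperty <- function(states, scale, positions = NULL,
                              aggregator = c("sum", "mean", "max")) {
  aggregator <- match.arg(aggregator)
  if (is.null(positions)) positions <- states@positions
  idx <- match(positions, states@positions)
  if (anyNA(idx))
    stop("position(s) not in the state table: ",
         paste(positions[is.na(idx)], collapse = ", "))
  m <- siteStates(states)[, idx, drop = FALSE]
  vals <- apply(m, c(1, 2), .stateProperty, scale = scale)
  f <- switch(aggregator, sum = rowSums,
              mean = rowMeans,
              max = function(x) apply(x, 1, max))
  out <- f(vals)
  out[apply(is.na(vals), 1, any)] <- NA_real_
  out
}

#' Construct a SelectionCriterion
#'
#' A predicate over the aggregate of a property scale within one functional
#' cluster, e.g. "T-cluster volume sum at most 400 A^3" picks enzymes with
#' a wide substrate tunnel.
#'
#' @param cluster cluster name (must exist in the state table's scheme).
#' @param scale scale name (must exist in the supplied scale set).
#' @param aggregator `"sum"`, `"mean"` or `"max"`.
#' @param comparator `"<="` or `">="`.
#' @param threshold numeric cutoff.
#' @return a `selectionCriterion` list.
#' @export
selectionCriterion <- function(cluster, scale,
                               aggregator = c("sum", "mean", "max"),
                               comparator = c("<=", ">="), threshold) {
  aggregator <- match.arg(aggregator)
  comparator <- match.arg(comparator)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  structure(list(cluster = cluster, scale = scale, aggregator = aggregator,
                 comparator = comparator, threshold = threshold),
            class = "selectionCriterion")
}

#' Read selection criteria from YAML
#'
#' Layout: a `criteria` list, each entry with `cluster`, `scale`,
#' `aggregator`, `comparator` and `threshold`.
#'
#' @param path path to the YAML file.
#' @return list of [selectionCriterion()] objects.
#' @export
readCriteria <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$criteria)) stop("criteria config must provide 'criteria'")
  lapply(cfg$criteria, function(cr) {
    selectionCriterion(cr$cluster, cr$scale, cr$aggregator, cr$comparator,
                       as.numeric(cr$threshold))
  })
}

#' Criterion-based enzyme candidate selection
#'
#' Evaluates each criterion's cluster-level aggregate for every sequence
#' and flags pass/fail. The ranking follows the first criterion's
#' aggregate: ascending for a `<=` comparator (smaller is better),
#' descending for `>=`; ties are broken by sequence ID, so the order is
#' deterministic. Sequences with a gap or `X` in a referenced cluster are
#' ineligible for that criterion (NA aggregate, fail), never scored 0.
#'
#' @param states a [SiteStateTable-class].
#' @param criteria non-empty list of [selectionCriterion()] objects.
#' @param scales named list of [PropertyScale-class] objects (default
#'   [builtinScales()]).
#' @return a data.frame with one row per sequence: `enzyme`, one
#'   `<cluster>.<scale>` value column and one `pass.<k>` column per
#'   criterion, `passAll`, and `rank`.
#' @export
selectCandidates <- function(states, criteria, scales = builtinScales()) {
  if (length(criteria) == 0L) stop("criteria must be non-empty")
  known <- unique(states@clusters)
  aggs <- list()
  passes <- list()
  for (k in seq_along(criteria)) {
    cr <- criteria[[k]]
    if (!cr$cluster %in% known)
      stop("criterion ", k, " references unknown cluster '", cr$cluster, "'")
    if (!cr$scale %in% names(scales))
      stop("criterion ", k, " references unknown scale '", cr$scale, "'")
    pos <- states@positions[states@clusters == cr$cluster]
    a <- aggregateProperty(states, scales[[cr$scale]], pos, cr$aggregator)
    ok <- !is.na(a) & do.call(cr$comparator, list(a, cr$threshold))
    aggs[[k]] <- a
    passes[[k]] <- ok
  }
  ids <- rownames(siteStates(states))
  first <- aggs[[1L]]
  decreasing <- criteria[[1L]]$comparator == ">="
  ord <- order(if (decreasing) -first else first, ids, na.last = TRUE)
  out <- data.frame(enzyme = ids, stringsAsFactors = FALSE)
  for (k in seq_along(criteria)) {
    cr <- criteria[[k]]
    out[[paste0(cr$cluster, ".", cr$scale, ".", cr$aggregator)]] <- aggs[[k]]
    out[[paste0("pass.", k)]] <- passes[[k]]
  }
  out$passAll <- Reduce(`&`, passes)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
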