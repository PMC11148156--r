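#' Construct a SiteScheme
#'
#' @param templateId sequence ID of the template.
#' @param clusters named list; each element a character vector of
#'   residue+position tokens such as `"Y91"` (expected template residue
#'   followed by the 1-based template position).
#' @return a [SiteScheme-class] object.
#' @examples
#' siteScheme("RjEUGO", list(P = c("Y91", "Y471", "R472"),
#'                           H = c("H390", "G392")))
#' @export
siteScheme <- function(templateId, clusters) {
  if (!is.list(clusters) || is.null(names(clusters)) ||
      any(!nzchar(names(clusters))))
    stop("clusters must be a named list of residue+position tokens")
  if (anyDuplicated(names(clusters)))
    stop("cluster names must be unique")
  tok <- unlist(clusters, use.names = FALSE)
  m <- regmatches(tok, regexec("^([A-Z])([0-9]+)$", tok))
  bad <- tok[vapply(m, length, 1L) != 3L]
  if (length(bad))
    stop("malformed residue token(s): ", paste(bad, collapse = ", "))
  residues <- vapply(m, `[`, "", 2L)
  positions <- as.integer(vapply(m, `[`, "", 3L))
  clusterLab <- rep(names(clusters), lengths(clusters))
  methods::new("SiteScheme", templateId = templateId, positions = positions,
               residues = residues, clusters = clusterLab)
}

#' The default first-shell scheme of the 4-phenol oxidoreductase template
#'
#' The 17 first-shell positions of the catalytic pocket of the eugenol
#' oxidase template (RjEUGO crystal-structure numbering), grouped into the
#' five functional clusters: P (phenolate binding), T (substrate tunnel,
#' o-substituent contact), H (second o-substituent contact), W (polar
#' cluster at the p-substituent) and A (hydrophobic cluster restricting the
#' p-substituent).
#'
#' @param templateId ID the template sequence carries in your alignment
#'   (default the UniProt accession of the RjEUGO template).
#' @return a [SiteScheme-class] object.
#' @export
firstShellScheme <- function(templateId = "Q0SBK1") {
  siteScheme(templateId, list(
    P = c("Y91", "Y471", "R472"),
    T = c("G165", "V166", "I427"),
    H = c("H390", "G392"),
    W = c("D151", "Y169", "R278", "E378", "Q425"),
    A = c("M282", "L381", "L438", "V436")
  ))
}

#' Read a SiteScheme from a YAML config
#'
#' Expected layout:
#' ```yaml
#' template: Q0SBK1
#' clusters:
#'   P: [Y91, Y471, R472]
#'   H: [H390, G392]
#' ```
#' @param path path to the YAML file.
#' @return a [SiteScheme-class] object.
#' @export
readSiteScheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$template) || is.null(cfg$clusters))
    stop("scheme config must provide 'template' and 'clusters'")
  clusters <- lapply(cfg$clusters, function(x) as.character(unlist(x)))
  siteScheme(as.character(cfg$template), clusters)
}

#' Write a SiteScheme to a YAML config
#'
#' @param scheme a [SiteScheme-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSiteScheme <- function(scheme, path) {
  cl <- schemeClusters(scheme)
  tokens <- lapply(cl, function(p) {
    idx <- match(p, scheme@positions)
    paste0(scheme@residues[idx], p)
  })
  yaml::write_yaml(list(template = scheme@templateId, clusters = tokens),
                   path)
  invisible(path)
}

#' Map template residue numbering onto alignment columns
#'
#' For every non-gap character of the template row one (position, column)
#' pair is recorded; the map is a bijection between the 1-based ungapped
#' residue numbering of the template and the 1-based alignment columns
#' holding those residues.
#'
#' @param alignment a gapped [Biostrings::AAStringSet].
#' @param templateId ID of the sequence to anchor on.
#' @return a [PositionMap-class] object.
#' @examples
#' aln <- Biostrings::AAStringSet(c(tpl = "A-CD", other = "AYCD"))
#' buildPositionMap(aln, "tpl")
#' @export
buildPositionMap <- function(alignment, templateId) {
  .checkAlignment(alignment)
  if (!templateId %in% names(alignment))
    stop("template '", templateId, "' not found in alignment")
  row <- strsplit(as.character(alignment[[templateId]]), "")[[1]]
  cols <- which(row != GAP_CHAR)
  if (length(cols) == 0L)
    stop("template '", templateId, "' is all gaps")
  methods::new("PositionMap", templateId = templateId,
               templatePos = seq_along(cols), column = as.integer(cols),
               nColumns = length(row))
}

#' Alignment column of a template position
#'
#' @param map a [PositionMap-class].
#' @param templatePos 1-based ungapped template position(s).
#' @return 1-based alignment column(s).
#' @export
positionToColumn <- function(map, templatePos) {
  idx <- match(templatePos, map@templatePos)
  if (anyNA(idx))
    stop("position(s) outside template length: ",
         paste(templatePos[is.na(idx)], collapse = ", "))
  map@column[idx]
}

#' Template position at an alignment column
#'
#' @param map a [PositionMap-class].
#' @param column 1-based alignment column(s).
#' @return 1-based template position(s); `NA` where the template has a gap.
#' @export
columnToPosition <- function(map, column) {
  if (any(column < 1L | column > map@nColumns))
    stop("column outside the alignment")
  map@templatePos[match(column, map@column)]
}

#' Convert a template position into another sequence's numbering
#'
#' Looks up the alignment column of `templatePos` under `mapFrom` and
#' returns the ungapped index of the target sequence at that column under
#' `mapTo`; both maps must come from the same alignment. If the target
#' sequence has a gap in that column the result is `NA` (gap flag), never a
#' number.
#'
#' @param templatePos 1-based position(s) in the source numbering.
#' @param mapFrom [PositionMap-class] of the source sequence.
#' @param mapTo [PositionMap-class] of the target sequence.
#' @return integer position(s) in the target numbering, `NA` at gaps.
#' @export
renumberPosition <- function(templatePos, mapFrom, mapTo) {
  if (mapFrom@nColumns != mapTo@nColumns)
    stop("maps were built from alignments of different widths")
  cols <- positionToColumn(mapFrom, templatePos)
  columnToPosition(mapTo, cols)
}

#' Extract residue states at the scheme positions
#'
#' Pulls, for every sequence, the residue found in the alignment column of
#' each scheme position. The template's own states are checked against the
#' expected residues declared in the scheme and a mismatch aborts (this
#' guards against off-by-one numbering or the wrong template); pass
#' `checkTemplate = FALSE` only when anchoring a homologous template.
#'
#' @param alignment a gapped [Biostrings::AAStringSet].
#' @param map [PositionMap-class] of the scheme's template
#'   (built with [buildPositionMap()] from the same alignment).
#' @param scheme a [SiteScheme-class].
#' @param checkTemplate check expected template residues (default TRUE).
#' @return a [SiteStateTable-class] object.
#' @export
extractSiteStates <- function(alignment, map, scheme, checkTemplate = TRUE) {
  .checkAlignment(alignment)
  if (map@templateId != scheme@templateId)
    stop("map and scheme anchor different templates")
  maxPos <- max(map@templatePos)
  out <- scheme@positions[scheme@positions > maxPos]
  if (length(out))
    stop("scheme position(s) beyond template length ", maxPos, ": ",
         paste(out, collapse = ", "))
  # keep the scheme's declaration order so cluster grouping (P, T, H, W, A)
  # carries through to profiles and heatmaps
  positions <- scheme@positions
  residues <- scheme@residues
  clusterLab <- scheme@clusters
  cols <- positionToColumn(map, positions)
  chars <- do.call(rbind, strsplit(as.character(alignment), ""))
  states <- chars[, cols, drop = FALSE]
  dimnames(states) <- list(names(alignment), as.character(positions))
  if (checkTemplate) {
    tmpl <- states[scheme@templateId, ]
    bad <- which(tmpl != residues)
    if (length(bad))
      stop("template residue mismatch at position ", positions[bad[1]],
           ": expected ", residues[bad[1]], ", found ", tmpl[bad[1]],
           " (check numbering or template choice)")
  }
  methods::new("SiteStateTable", states = states, positions = positions,
               clusters = clusterLab, templateId = scheme@templateId)
}
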