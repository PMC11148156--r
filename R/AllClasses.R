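#' @import methods
NULL

AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALLOWED <- c(AA_CANONICAL, "X")
GAP_CHAR <- "-"

#' SiteScheme: template-anchored active-site definition
#'
#' A `SiteScheme` names the active-site positions of a template (reference
#' crystal structure) sequence and groups them into functional clusters.
#' Positions are 1-based indices into the ungapped template sequence; each
#' position carries the residue expected in the template, which is used as a
#' mandatory sanity anchor when states are extracted from an alignment.
#'
#' @slot templateId sequence ID of the template within the family alignment.
#' @slot positions integer vector of 1-based template positions (unique).
#' @slot residues expected template residue (one-letter code) per position.
#' @slot clusters cluster label per position (e.g. P, T, H, W, A).
#'
#' @seealso [siteScheme()], [firstShellScheme()], [readSiteScheme()]
#' @exportClass SiteScheme
setClass("SiteScheme",
  representation(
    templateId = "character",
    positions = "integer",
    residues = "character",
    clusters = "character"
  )
)

setValidity("SiteScheme", function(object) {
  msg <- character()
  if (length(object@templateId) != 1L || !nzchar(object@templateId))
    msg <- c(msg, "templateId must be a single non-empty string")
  n <- length(object@positions)
  if (length(object@residues) != n || length(object@clusters) != n)
    msg <- c(msg, "positions, residues and clusters must have equal length")
  if (n == 0L)
    msg <- c(msg, "scheme must contain at least one position")
  if (anyDuplicated(object@positions))
    msg <- c(msg, "positions must be unique across clusters")
  if (n > 0L && any(object@positions < 1L))
    msg <- c(msg, "positions must be >= 1")
  bad <- setdiff(unique(object@residues), AA_CANONICAL)
  if (length(bad))
    msg <- c(msg, paste0("unknown expected residues: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PositionMap: template residue numbering vs alignment columns
#'
#' Bijection between the 1-based ungapped positions of one sequence and the
#' 1-based alignment columns in which those residues sit. One pair per
#' non-gap character of the sequence; both coordinates strictly increasing.
#'
#' @slot templateId ID of the mapped sequence.
#' @slot templatePos 1-based ungapped residue indices.
#' @slot column 1-based alignment columns.
#' @slot nColumns total number of alignment columns (for bookkeeping).
#'
#' @seealso [buildPositionMap()], [renumberPosition()]
#' @exportClass PositionMap
setClass("PositionMap",
  representation(
    templateId = "character",
    templatePos = "integer",
    column = "integer",
    nColumns = "integer"
  )
)

setValidity("PositionMap", function(object) {
  msg <- character()
  if (length(object@templatePos) != length(object@column))
    msg <- c(msg, "templatePos and column must have equal length")
  if (length(object@templatePos) &&
      (is.unsorted(object@templatePos, strictly = TRUE) ||
       is.unsorted(object@column, strictly = TRUE)))
    msg <- c(msg, "templatePos and column must be strictly increasing")
  if (length(object@column) && max(object@column) > object@nColumns)
    msg <- c(msg, "column exceeds nColumns")
  if (length(msg)) msg else TRUE
})

#' SiteStateTable: residue states at scheme positions
#'
#' Character matrix of residue states, sequences in rows and template
#' positions in columns. A gap in a homolog at a scheme position is kept as
#' the distinct state `"-"`; downstream property aggregation and correlation
#' treat gaps (and `"X"`) as missing, never as zero.
#'
#' @slot states character matrix (rows = sequence IDs, cols = positions).
#' @slot positions integer template positions (column order).
#' @slot clusters cluster label per position, parallel to `positions`.
#' @slot templateId the anchoring template sequence ID.
#'
#' @seealso [extractSiteStates()]
#' @exportClass SiteStateTable
setClass("SiteStateTable",
  representation(
    states = "matrix",
    positions = "integer",
    clusters = "character",
    templateId = "character"
  )
)

setValidity("SiteStateTable", function(object) {
  msg <- character()
  if (!is.character(object@states))
    msg <- c(msg, "states must be a character matrix")
  if (ncol(object@states) != length(object@positions))
    msg <- c(msg, "one column per position required")
  if (length(object@clusters) != length(object@positions))
    msg <- c(msg, "clusters must be parallel to positions")
  if (is.null(rownames(object@states)))
    msg <- c(msg, "states must carry sequence IDs as rownames")
  bad <- setdiff(unique(as.vector(object@states)), c(AA_ALLOWED, GAP_CHAR))
  if (length(bad))
    msg <- c(msg, paste0("illegal states: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PropertyScale: amino-acid to numeric property mapping
#'
#' @slot name scale name (e.g. "volume").
#' @slot units measurement units ("A^3" for volume, "" if dimensionless).
#' @slot values named numeric vector over the 20 canonical residues.
#' @slot citation source of the published table.
#'
#' @seealso [propertyScale()], [builtinScales()]
#' @exportClass PropertyScale
setClass("PropertyScale",
  representation(
    name = "character",
    units = "character",
    values = "numeric",
    citation = "character"
  )
)

setValidity("PropertyScale", function(object) {
  msg <- character()
  if (!setequal(names(object@values), AA_CANONICAL) ||
      length(object@values) != 20L)
    msg <- c(msg, "values must cover exactly the 20 canonical residues")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all scale values must be finite")
  if (length(msg)) msg else TRUE
})

#' ActivityTable: enzyme x substrate rate matrix
#'
#' Measured rates in s^-1 with explicit below-detection handling: `rates`
#' holds `NA` where the assay reported not-detected, and `ndMask` records
#' those cells. Optional per-cell standard errors (from "value +/- error"
#' input) are carried but ignored by downstream statistics.
#'
#' @slot rates numeric matrix (enzymes x substrates), NA = below detection.
#' @slot ndMask logical matrix marking below-detection cells.
#' @slot errors numeric matrix of reported errors (NA where absent).
#' @slot detectionFloor positive rate in s^-1 used by the floor policy.
#'
#' @seealso [activityTable()], [readActivityTable()], [logActivities()]
#' @exportClass ActivityTable
setClass("ActivityTable",
  representation(
    rates = "matrix",
    ndMask = "matrix",
    errors = "matrix",
    detectionFloor = "numeric"
  )
)

setValidity("ActivityTable", function(object) {
  msg <- character()
  if (!identical(dim(object@rates), dim(object@ndMask)) ||
      !identical(dim(object@rates), dim(object@errors)))
    msg <- c(msg, "rates, ndMask and errors must share dimensions")
  if (is.null(rownames(object@rates)) || is.null(colnames(object@rates)))
    msg <- c(msg, "rates must carry enzyme rownames and substrate colnames")
  if (any(object@rates < 0, na.rm = TRUE))
    msg <- c(msg, "rates must be non-negative")
  if (any(is.na(object@rates) & !object@ndMask))
    msg <- c(msg, "every cell must be a rate or an explicit below-detection marker")
  if (any(!is.na(object@rates) & object@ndMask))
    msg <- c(msg, "below-detection cells cannot carry a rate")
  if (length(object@detectionFloor) != 1L || !is.finite(object@detectionFloor) ||
      object@detectionFloor <= 0)
    msg <- c(msg, "detectionFloor must be a single positive rate")
  if (length(msg)) msg else TRUE
})

#' KineticFit: fitted rate-law parameters
#'
#' @slot model one of "michaelis_menten", "substrate_inhibition", "hill",
#'   or a user-registered model name.
#' @slot parameters named numeric vector (kcat in s^-1, KM in uM, and
#'   Ki in uM or the Hill coefficient n where applicable).
#' @slot stdErrors standard errors from the local curvature at the optimum.
#' @slot rss residual sum of squares.
#' @slot nObs number of observations used.
#' @slot fitted fitted rates at the input concentrations.
#'
#' @seealso [fitKinetics()]
#' @exportClass KineticFit
setClass("KineticFit",
  representation(
    model = "character",
    parameters = "numeric",
    stdErrors = "numeric",
    rss = "numeric",
    nObs = "integer",
    fitted = "numeric"
  )
)

setValidity("KineticFit", function(object) {
  msg <- character()
  if (any(object@parameters <= 0))
    msg <- c(msg, "kinetic parameters must be positive")
  if (any(object@stdErrors < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' FamilySpec: synthetic enzyme-family specification
#'
#' Describes a synthetic protein family with clade structure and planted
#' property-to-activity couplings at chosen alignment positions, used to
#' validate the full mapping/correlation pipeline without external data.
#'
#' @slot nSequences number of family members.
#' @slot length sequence length (no indels by default, so also the
#'   alignment width).
#' @slot cladeSizes integer vector of clade sizes, summing to nSequences.
#' @slot substitutionRate per-position probability of a substitution away
#'   from the clade founder.
#' @slot plantedPositions positions carrying an activity coupling.
#' @slot plantedResidues list of allowed residue sets, one per planted
#'   position (states are drawn uniformly from these).
#' @slot plantedSlopes slope b in log10-activity units per property unit,
#'   one per planted position.
#' @slot baselineLog10 intercept a of the activity model.
#' @slot noiseSd Gaussian noise sd on log10 activity.
#' @slot detectionFloor rates below this are reported not-detected.
#' @slot indelRate per-position probability of a gap (default 0).
#' @slot seed RNG seed making generation bit-reproducible.
#'
#' @seealso [familySpec()], [generateFamily()], [generateActivities()]
#' @exportClass FamilySpec
setClass("FamilySpec",
  representation(
    nSequences = "integer",
    length = "integer",
    cladeSizes = "integer",
    substitutionRate = "numeric",
    plantedPositions = "integer",
    plantedResidues = "list",
    plantedSlopes = "numeric",
    baselineLog10 = "numeric",
    noiseSd = "numeric",
    detectionFloor = "numeric",
    indelRate = "numeric",
    seed = "integer"
  )
)

setValidity("FamilySpec", function(object) {
  msg <- character()
  if (sum(object@cladeSizes) != object@nSequences)
    msg <- c(msg, "clade sizes must sum to nSequences")
  if (any(object@cladeSizes < 1L))
    msg <- c(msg, "clades must be non-empty")
  if (object@length < 1L)
    msg <- c(msg, "length must be >= 1")
  if (object@substitutionRate < 0 || object@substitutionRate > 1)
    msg <- c(msg, "substitutionRate must lie in [0, 1]")
  if (any(object@plantedPositions < 1L) ||
      any(object@plantedPositions > object@length))
    msg <- c(msg, "planted positions must lie within the sequence length")
  if (anyDuplicated(object@plantedPositions))
    msg <- c(msg, "planted positions must be unique")
  np <- length(object@plantedPositions)
  if (length(object@plantedResidues) != np || length(object@plantedSlopes) != np)
    msg <- c(msg, "one residue set and one slope per planted position required")
  for (rs in object@plantedResidues) {
    if (!is.character(rs) || !length(rs) || !all(rs %in% AA_CANONICAL))
      msg <- c(msg, "planted residue sets must be non-empty canonical residues")
  }
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (object@detectionFloor <= 0)
    msg <- c(msg, "detectionFloor must be positive")
  if (object@indelRate < 0 || object@indelRate > 1)
    msg <- c(msg, "indelRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
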