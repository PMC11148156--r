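#' @describeIn SiteScheme-class template positions, named by cluster.
#' @export
setMethod("schemePositions", "SiteScheme", function(x) {
  structure(x@positions, names = x@clusters)
})

#' @describeIn SiteScheme-class positions split by cluster label.
#' @export
setMethod("schemeClusters", "SiteScheme", function(x) {
  split(x@positions, factor(x@clusters, levels = unique(x@clusters)))
})

#' @describeIn SiteScheme-class the template sequence ID.
#' @export
setMethod("templateId", "SiteScheme", function(x) x@templateId)

#' @describeIn PositionMap-class the mapped sequence ID.
#' @export
setMethod("templateId", "PositionMap", function(x) x@templateId)

#' @describeIn SiteStateTable-class the anchoring template ID.
#' @export
setMethod("templateId", "SiteStateTable", function(x) x@templateId)

#' @describeIn SiteStateTable-class character matrix of residue states.
#' @export
setMethod("siteStates", "SiteStateTable", function(x) x@states)

#' @describeIn SiteStateTable-class positions covered by the table.
#' @export
setMethod("schemePositions", "SiteStateTable", function(x) {
  structure(x@positions, names = x@clusters)
})

#' @describeIn SiteStateTable-class positions split by cluster label.
#' @export
setMethod("schemeClusters", "SiteStateTable", function(x) {
  split(x@positions, factor(x@clusters, levels = unique(x@clusters)))
})

#' @describeIn ActivityTable-class numeric rate matrix (NA below detection).
#' @export
setMethod("rates", "ActivityTable", function(x) x@rates)

#' @describeIn ActivityTable-class logical matrix of below-detection cells.
#' @export
setMethod("belowDetection", "ActivityTable", function(x) x@ndMask)

#' @describeIn ActivityTable-class detection floor in s^-1.
#' @export
setMethod("detectionFloor", "ActivityTable", function(x) x@detectionFloor)

#' @describeIn PropertyScale-class named numeric values over the 20 residues.
#' @export
setMethod("scaleValues", "PropertyScale", function(x) x@values)

#' @describeIn KineticFit-class named parameter estimates.
#' @export
setMethod("kineticParameters", "KineticFit", function(object, ...) {
  object@parameters
})

setMethod("show", "SiteScheme", function(object) {
  cl <- schemeClusters(object)
  cat("SiteScheme anchored to template '", object@templateId, "'\n", sep = "")
  cat(" ", length(object@positions), "positions in",
      length(cl), "clusters:\n")
  for (nm in names(cl)) {
    idx <- match(cl[[nm]], object@positions)
    cat("  ", nm, ": ",
        paste0(object@residues[idx], cl[[nm]], collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "PositionMap", function(object) {
  cat("PositionMap for '", object@templateId, "': ",
      length(object@templatePos), " residues over ",
      object@nColumns, " alignment columns\n", sep = "")
})

setMethod("show", "SiteStateTable", function(object) {
  cat("SiteStateTable: ", nrow(object@states), " sequences x ",
      ncol(object@states), " positions (template '",
      object@templateId, "')\n", sep = "")
  print(utils::head(object@states, 8L))
  if (nrow(object@states) > 8L) cat("  ...\n")
})

setMethod("show", "PropertyScale", function(object) {
  cat("PropertyScale '", object@name, "'",
      if (nzchar(object@units)) paste0(" [", object@units, "]"), "\n", sep = "")
  cat("  ", object@citation, "\n", sep = "")
  print(round(object@values, 2))
})

setMethod("show", "ActivityTable", function(object) {
  cat("ActivityTable: ", nrow(object@rates), " enzymes x ",
      ncol(object@rates), " substrates; ",
      sum(object@ndMask), " below detection (floor ",
      object@detectionFloor, " s^-1)\n", sep = "")
})

setMethod("show", "KineticFit", function(object) {
  cat("KineticFit (", object@model, "), n = ", object@nObs, "\n", sep = "")
  est <- data.frame(estimate = object@parameters,
                    std.error = object@stdErrors)
  print(est)
  cat("RSS:", format(object@rss), "\n")
})

setMethod("show", "FamilySpec", function(object) {
  cat("FamilySpec: ", object@nSequences, " sequences of length ",
      object@length, ", ", length(object@cladeSizes), " clades, ",
      length(object@plantedPositions), " planted site(s), seed ",
      object@seed, "\n", sep = "")
})
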