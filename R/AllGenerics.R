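#' @rdname SiteScheme-class
#' @param x a sitefunc object.
#' @export
setGeneric("schemePositions", function(x) standardGeneric("schemePositions"))

#' @rdname SiteScheme-class
#' @export
setGeneric("schemeClusters", function(x) standardGeneric("schemeClusters"))

#' @rdname SiteScheme-class
#' @export
setGeneric("templateId", function(x) standardGeneric("templateId"))

#' @rdname SiteStateTable-class
#' @param x a SiteStateTable.
#' @export
setGeneric("siteStates", function(x) standardGeneric("siteStates"))

#' @rdname ActivityTable-class
#' @param x an ActivityTable.
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname ActivityTable-class
#' @export
setGeneric("belowDetection", function(x) standardGeneric("belowDetection"))

#' @rdname ActivityTable-class
#' @export
setGeneric("detectionFloor", function(x) standardGeneric("detectionFloor"))

#' @rdname PropertyScale-class
#' @param x a PropertyScale.
#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))

#' @rdname KineticFit-class
#' @param object a KineticFit.
#' @param ... unused.
#' @export
setGeneric("kineticParameters",
           function(object, ...) standardGeneric("kineticParameters"))
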