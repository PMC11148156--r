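#' Log-transform an activity table
#'
#' Maps measured rates to log10 (rates in s^-1, so 1 s^-1 maps to 0).
#' Below-detection cells and exact zero rates are handled by policy:
#' `"exclude"` (default) omits them, since flooring fabricates leverage
#' points on the log scale; `"floor"` substitutes log10 of the table's
#' detection floor and flags the cell.
#'
#' @param table an [ActivityTable-class].
#' @param ndPolicy `"exclude"` or `"floor"`.
#' @return data.frame with columns `enzyme`, `substrate`, `value`
#'   (log10 rate), `floored`.
#' @examples
#' m <- matrix(c(4.58, 1, NA, 0.1), 2, 2,
#'             dimnames = list(c("e1", "e2"), c("s1", "s2")))
#' logActivities(activityTable(m), "floor")
#' @export
logActivities <- function(table, ndPolicy = c("exclude", "floor")) {
  ndPolicy <- match.arg(ndPolicy)
  stopifnot(methods::is(table, "ActivityTable"))
  r <- rates(table)
  nd <- belowDetection(table) | (!is.na(r) & r == 0)
  rows <- expand.grid(enzyme = rownames(r), substrate = colnames(r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$value <- log10(as.vector(r))
  rows$floored <- FALSE
  ndVec <- as.vector(nd)
  if (ndPolicy == "floor") {
    rows$value[ndVec] <- log10(detectionFloor(table))
    rows$floored[ndVec] <- TRUE
  } else {
    rows <- rows[!ndVec, , drop = FALSE]
  }
  rows <- rows[is.finite(rows$value) | rows$floored, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

.usablePairs <- function(states, scale, logact, substrate, positionIdx) {
  la <- logact[logact$substrate == substrate, , drop = FALSE]
  m <- siteStates(states)
  common <- intersect(rownames(m), la$enzyme)
  st <- m[common, positionIdx]
  prop <- .stateProperty(st, scale)
  act <- la$value[match(common, la$enzyme)]
  use <- !is.na(prop) & is.finite(act)
  list(property = unname(prop[use]), activity = act[use],
       enzymes = common[use])
}

#' Correlate a residue property with log activity, per position
#'
#' For one substrate and every scheme position, the correlation across
#' enzymes between the property value of the residue present and the
#' log10 activity. The sign convention: larger property values with higher
#' activity give a positive correlation, so a negative volume correlation
#' means small residues are beneficial. Enzymes with a gap or `X` at the
#' position, or without a usable activity, are dropped for that position.
#'
#' Statuses: `"ok"` (r defined, n >= 3); `"conserved"` (the property is
#' constant across the used enzymes — no correlation exists, which is not
#' r = 0); `"insufficient"` (< 3 usable pairs, or the activity itself is
#' constant so the coefficient is undefined).
#'
#' @param states a [SiteStateTable-class].
#' @param scale a [PropertyScale-class].
#' @param logact data.frame from [logActivities()].
#' @param substrate substrate ID (must occur in `logact`'s table).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns `position`, `cluster`, `substrate`,
#'   `r`, `nUsed`, `status`.
#' @export
positionActivityCorrelation <- function(states, scale, logact, substrate,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!substrate %in% logact$substrate)
    stop("substrate '", substrate, "' absent from the activity data")
  res <- lapply(seq_along(states@positions), function(j) {
    up <- .usablePairs(states, scale, logact, substrate, j)
    n <- length(up$property)
    r <- NA_real_
    status <- "ok"
    if (n >= 2L && length(unique(up$property)) == 1L) {
      status <- "conserved"
    } else if (n < 3L) {
      status <- "insufficient"
    } else if (stats::sd(up$activity) == 0) {
      status <- "insufficient"
    } else {
      r <- stats::cor(up$property, up$activity, method = method)
    }
    data.frame(position = states@positions[j],
               cluster = states@clusters[j],
               substrate = substrate, r = r, nUsed = n,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Position x substrate correlation heatmap matrix
#'
#' Assembles correlation results (typically several calls of
#' [positionActivityCorrelation()] over substrates, `rbind`-ed) into a
#' positions x substrates matrix. Rows follow the scheme's cluster order;
#' cells whose status is not `"ok"` carry `NA` (rendered neutral), with
#' the status preserved in the parallel `"status"` attribute and in the
#' TSV export — "no correlation" is never written as the number 0.
#'
#' @param results data.frame of correlation results.
#' @param substrates optional substrate order (default: order of first
#'   appearance).
#' @return numeric matrix with a `"status"` character matrix attribute.
#' @export
heatmapMatrix <- function(results, substrates = unique(results$substrate)) {
  positions <- unique(results$position)
  m <- matrix(NA_real_, length(positions), length(substrates),
              dimnames = list(as.character(positions), substrates))
  st <- matrix(NA_character_, length(positions), length(substrates),
               dimnames = dimnames(m))
  for (k in seq_len(nrow(results))) {
    i <- as.character(results$position[k])
    j <- results$substrate[k]
    if (!j %in% substrates) next
    st[i, j] <- results$status[k]
    if (results$status[k] == "ok") m[i, j] <- results$r[k]
  }
  if (anyNA(st))
    stop("results do not cover the full position x substrate grid")
  attr(m, "status") <- st
  m
}

#' Export / re-import a heatmap matrix as TSV
#'
#' The TSV carries one row per (position, substrate) cell with the
#' correlation (empty when undefined) and the explicit status, so the
#' matrix round-trips exactly.
#'
#' @param m matrix from [heatmapMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHeatmapTSV <- function(m, path) {
  st <- attr(m, "status")
  long <- expand.grid(position = rownames(m), substrate = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$r <- as.vector(m)
  long$status <- as.vector(st)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeHeatmapTSV
#' @param path path to a TSV written by [writeHeatmapTSV()].
#' @export
readHeatmapTSV <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "numeric", "character"))
  positions <- unique(long$position)
  substrates <- unique(long$substrate)
  m <- matrix(NA_real_, length(positions), length(substrates),
              dimnames = list(positions, substrates))
  st <- matrix(NA_character_, length(positions), length(substrates),
               dimnames = dimnames(m))
  m[cbind(long$position, long$substrate)] <- long$r
  st[cbind(long$position, long$substrate)] <- long$status
  attr(m, "status") <- st
  m
}

#' Plot a correlation heatmap
#'
#' Base-graphics rendering of a [heatmapMatrix()]: blue negative, red
#' positive, grey for conserved/insufficient cells.
#'
#' @param m matrix from [heatmapMatrix()].
#' @param main plot title.
#' @return invisibly, `m`.
#' @export
plotHeatmap <- function(m, main = "property-activity correlation") {
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "substrate", ylab = "position", main = main)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1)
  graphics::box()
  invisible(m)
}

#' Regress log activity on a combined residue property
#'
#' Ordinary least squares of log10 activity on the per-enzyme sum of the
#' property over the requested positions (the combined-volume analysis:
#' one point per enzyme). Enzymes missing a state at any position or a
#' usable activity are dropped.
#'
#' @param states a [SiteStateTable-class].
#' @param scale a [PropertyScale-class].
#' @param positions positions to combine (sum aggregation).
#' @param logact data.frame from [logActivities()].
#' @param substrate substrate ID.
#' @return list with `slope`, `intercept`, `r`, `nUsed`, `status`
#'   (`"ok"`, `"insufficient"`, or `"constant_property"` when the combined
#'   property does not vary and the slope is undefined), and the
#'   per-enzyme `data` used.
#' @export
combinedPropertyRegression <- function(states, scale, positions, logact,
                                       substrate) {
  if (!substrate %in% logact$substrate)
    stop("substrate '", substrate, "' absent from the activity data")
  comb <- aggregateProperty(states, scale, positions, "sum")
  la <- logact[logact$substrate == substrate, , drop = FALSE]
  common <- intersect(names(comb), la$enzyme)
  x <- comb[common]
  y <- la$value[match(common, la$enzyme)]
  use <- !is.na(x) & is.finite(y)
  x <- x[use]; y <- y[use]
  dat <- data.frame(enzyme = common[use], property = unname(x),
                    logActivity = y, stringsAsFactors = FALSE)
  if (length(x) < 3L)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                nUsed = length(x), status = "insufficient", data = dat))
  if (stats::sd(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                nUsed = length(x), status = "constant_property", data = dat))
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = r, nUsed = length(x), status = "ok", data = dat)
}

#' Rank hot-spot positions for mutagenesis
#'
#' Positions are scored by the strongest absolute correlation they reach
#' over the substrate set, counting only `"ok"` results with
#' `nUsed >= minN` and `|r| >= minAbsR`. Ties are broken by mean |r| over
#' the supporting substrates, then by position number; conserved positions
#' never rank. The supporting substrates are reported per position.
#'
#' @param results data.frame of correlation results over a substrate set.
#' @param minAbsR minimum |r| for a substrate to support a position,
#'   in (0, 1].
#' @param minN minimum enzymes behind a supporting correlation (>= 3).
#' @return data.frame ranked by descending evidence: `position`,
#'   `cluster`, `maxAbsR`, `meanAbsR`, `nSupporting`, `substrates`.
#' @export
hotspotRanking <- function(results, minAbsR = 0.5, minN = 3L) {
  stopifnot(minAbsR > 0, minAbsR <= 1, minN >= 3L)
  ok <- results[results$status == "ok" & !is.na(results$r) &
                  results$nUsed >= minN & abs(results$r) >= minAbsR, ,
                drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(position = integer(), cluster = character(),
                      maxAbsR = numeric(), meanAbsR = numeric(),
                      nSupporting = integer(), substrates = character(),
                      stringsAsFactors = FALSE))
  sp <- split(ok, ok$position)
  rows <- lapply(sp, function(d) {
    data.frame(position = d$position[1L], cluster = d$cluster[1L],
               maxAbsR = max(abs(d$r)), meanAbsR = mean(abs(d$r)),
               nSupporting = nrow(d),
               substrates = paste(d$substrate[order(-abs(d$r))],
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$maxAbsR, -out$meanAbsR, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
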