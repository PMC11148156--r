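#' Read protein sequences from FASTA
#'
#' Reads ungapped amino-acid sequences. The sequence ID is the first
#' whitespace-delimited token of the FASTA header; the remainder is kept as
#' the record description. Only the 20 canonical residues plus `X` are
#' accepted; anything else (including `B`, `Z`, `U`) is rejected with the
#' offending position, since the shipped property scales are undefined for
#' ambiguity codes.
#'
#' @param path path to a FASTA file.
#' @param format currently only `"fasta"`.
#' @return an [Biostrings::AAStringSet] named by ID, with descriptions in
#'   `S4Vectors::mcols(x)$description`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">enzA eugenol oxidase", "MKTAYV"), f)
#' readSequences(f)
#' @export
readSequences <- function(path, format = c("fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("empty sequence ID in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence ID(s): ", paste(unique(dup), collapse = ", "))
  names(seqs) <- ids
  S4Vectors::mcols(seqs)$description <- desc
  .checkResidues(seqs, allowGap = FALSE)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs an [Biostrings::AAStringSet]; descriptions in
#'   `mcols(seqs)$description` are appended to the headers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(seqs, path) {
  out <- seqs
  desc <- S4Vectors::mcols(seqs)$description
  if (!is.null(desc)) {
    keep <- !is.na(desc) & nzchar(desc)
    names(out)[keep] <- paste(names(seqs)[keep], desc[keep])
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

.checkResidues <- function(seqs, allowGap = FALSE) {
  allowed <- c(AA_ALLOWED, if (allowGap) GAP_CHAR)
  for (i in seq_along(seqs)) {
    s <- strsplit(as.character(seqs[[i]]), "")[[1]]
    if (length(s) == 0L)
      stop("empty sequence: ", names(seqs)[i])
    bad <- which(!(s %in% allowed))
    if (length(bad))
      stop("illegal residue '", s[bad[1]], "' at position ", bad[1],
           " of sequence ", names(seqs)[i])
  }
  invisible(TRUE)
}

.checkAlignment <- function(aln, context = "alignment") {
  if (length(aln) < 2L)
    stop(context, " must contain at least 2 sequences")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) {
    off <- names(aln)[which(w != w[1])[1]]
    stop("ragged ", context, ": sequence ", off,
         " has length ", w[names(aln) == off][1],
         ", expected ", w[1])
  }
  if (anyDuplicated(names(aln)))
    stop("duplicate sequence ID(s) in ", context, ": ",
         paste(unique(names(aln)[duplicated(names(aln))]), collapse = ", "))
  .checkResidues(aln, allowGap = TRUE)
  invisible(TRUE)
}

#' Read a multiple sequence alignment
#'
#' Supported formats: aligned FASTA, Clustal, Stockholm. Stockholm's `.`
#' gap character is normalized to `-` on read. All rows must have equal
#' length; a ragged input is an error naming the offending record.
#'
#' @param path path to the alignment file.
#' @param format one of `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return a gapped [Biostrings::AAStringSet] of equal widths.
#' @export
readAlignment <- function(path, format = c("fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    aln <- Biostrings::readAAStringSet(path, format = "fasta")
    names(aln) <- sub("\\s.*$", "", names(aln))
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = format)
    aln <- methods::as(msa, "AAStringSet")
  }
  if (length(aln) == 0L) stop("no sequences found in ", path)
  aln <- Biostrings::AAStringSet(toupper(gsub(".", "-", as.character(aln),
                                              fixed = TRUE)))
  .checkAlignment(aln)
  aln
}

#' Write a multiple sequence alignment
#'
#' @param aln a gapped [Biostrings::AAStringSet] of equal widths.
#' @param path output file path.
#' @param format one of `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path,
                           format = c("fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  .checkAlignment(aln)
  if (format == "fasta") {
    Biostrings::writeXStringSet(aln, path)
  } else if (format == "clustal") {
    .writeClustal(aln, path)
  } else {
    .writeStockholm(aln, path)
  }
  invisible(path)
}

.writeClustal <- function(aln, path, blockWidth = 60L) {
  ids <- names(aln)
  seqs <- as.character(aln)
  pad <- max(nchar(ids)) + 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL multiple sequence alignment", "", ""), con)
  w <- nchar(seqs[1])
  starts <- seq(1L, w, by = blockWidth)
  for (s in starts) {
    e <- min(s + blockWidth - 1L, w)
    chunk <- substr(seqs, s, e)
    writeLines(sprintf("%-*s%s", pad, ids, chunk), con)
    writeLines("", con)
  }
}

.writeStockholm <- function(aln, path) {
  ids <- names(aln)
  pad <- max(nchar(ids)) + 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s%s", pad, ids, as.character(aln)), con)
  writeLines("//", con)
}

#' Remove gaps from aligned sequences
#'
#' @param aln a gapped [Biostrings::AAStringSet].
#' @return an ungapped [Biostrings::AAStringSet] with the same names.
#' @export
degap <- function(aln) {
  Biostrings::AAStringSet(gsub("-", "", as.character(aln), fixed = TRUE))
}

#' Construct an ActivityTable
#'
#' @param rates numeric matrix, enzymes in rows, substrates in columns;
#'   `NA` cells are treated as below-detection.
#' @param errors optional numeric matrix of reported measurement errors.
#' @param detectionFloor positive rate in s^-1 substituted by the floor
#'   policy of [logActivities()].
#' @return an [ActivityTable-class] object.
#' @examples
#' m <- matrix(c(4.58, 0.1, NA, 2.6), 2, 2,
#'             dimnames = list(c("Gc4EPO", "AoEUGO"), c("c32", "c4")))
#' activityTable(m)
#' @export
activityTable <- function(rates, errors = NULL, detectionFloor = 1e-3) {
  if (!is.matrix(rates)) rates <- as.matrix(rates)
  storage.mode(rates) <- "double"
  if (is.null(errors)) {
    errors <- matrix(NA_real_, nrow(rates), ncol(rates),
                     dimnames = dimnames(rates))
  }
  methods::new("ActivityTable", rates = rates, ndMask = is.na(rates),
               errors = errors, detectionFloor = detectionFloor)
}

.parseRateCell <- function(cell, ndMarker, where) {
  cell <- trimws(cell)
  if (identical(cell, ndMarker)) return(c(rate = NA_real_, err = NA_real_))
  # accept "value", "value ± error" and the ASCII variant "value +/- error"
  parts <- strsplit(cell, "±|\\+/-")[[1]]
  v <- suppressWarnings(as.numeric(trimws(parts[1])))
  if (is.na(v))
    stop("cannot parse activity cell '", cell, "' at ", where,
         " (not a number or the marker '", ndMarker, "')")
  if (v < 0)
    stop("negative rate ", v, " at ", where)
  e <- if (length(parts) > 1L) {
    ev <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(ev)) stop("cannot parse error part of cell '", cell,
                        "' at ", where)
    ev
  } else NA_real_
  c(rate = v, err = e)
}

#' Read an enzyme x substrate activity table
#'
#' The table is rectangular with substrate IDs in the first row and enzyme
#' IDs in the first column; the delimiter (comma or tab) is auto-detected
#' from the header line. Cells hold a non-negative rate in s^-1, optionally
#' as `"value ± error"` (the error is stored but ignored by downstream
#' statistics), or the not-detected marker.
#'
#' @param path path to a CSV/TSV file.
#' @param ndMarker string marking below-detection cells (default `"n.d."`).
#' @param detectionFloor positive rate in s^-1 (see [activityTable()]).
#' @return an [ActivityTable-class] object.
#' @export
readActivityTable <- function(path, ndMarker = "n.d.", detectionFloor = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           encoding = "UTF-8", quote = "\"")
  if (ncol(raw) == 0L) stop("activity table has no substrate columns")
  rates <- matrix(NA_real_, nrow(raw), ncol(raw),
                  dimnames = list(rownames(raw), colnames(raw)))
  errs <- rates
  for (i in seq_len(nrow(raw))) {
    for (j in seq_len(ncol(raw))) {
      p <- .parseRateCell(raw[i, j], ndMarker,
                          paste0("(", rownames(raw)[i], ", ",
                                 colnames(raw)[j], ")"))
      rates[i, j] <- p[["rate"]]
      errs[i, j] <- p[["err"]]
    }
  }
  activityTable(rates, errors = errs, detectionFloor = detectionFloor)
}

#' Write an ActivityTable to CSV/TSV
#'
#' Below-detection cells are written as the marker; cells with a recorded
#' error are written as `"value ± error"` so that a write/read round
#' trip preserves the full table.
#'
#' @param x an [ActivityTable-class].
#' @param path output path.
#' @param sep `","` or `"\t"`.
#' @param ndMarker not-detected marker to emit.
#' @return `path`, invisibly.
#' @export
writeActivityTable <- function(x, path, sep = ",", ndMarker = "n.d.") {
  stopifnot(methods::is(x, "ActivityTable"))
  r <- x@rates
  e <- x@errors
  cells <- matrix(ndMarker, nrow(r), ncol(r), dimnames = dimnames(r))
  num <- !is.na(r)
  cells[num] <- format(r[num], trim = TRUE, digits = 15)
  withErr <- num & !is.na(e)
  cells[withErr] <- paste(format(r[withErr], trim = TRUE, digits = 15),
                          "±",
                          format(e[withErr], trim = TRUE, digits = 15))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("enzyme", colnames(r)), collapse = sep), con)
  for (i in seq_len(nrow(r)))
    writeLines(paste(c(rownames(r)[i], cells[i, ]), collapse = sep), con)
  invisible(path)
}
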