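#' Read a transcript coordinate table
#'
#' Reads a Molecular Cartography-style point export: a delimited text file
#' with header columns `x`, `y`, `gene` (case-insensitive; comma- or
#' tab-separated by file extension). Coordinates are converted to micrometres
#' on read, so every public coordinate downstream is in um; pixels appear only
#' at this I/O boundary. Rows with an empty gene name are rejected with a
#' warning; non-numeric coordinates are a row-level error.
#'
#' @param path Path to a CSV/TSV file.
#' @param unit Unit of the stored coordinates, `"um"` or `"px"`.
#' @param scale A [pixel_scale()]; used when `unit = "px"`.
#' @return A tibble with columns `x`, `y` (um) and `gene`, in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = 500, y = 0, gene = "Cxcl10"), f, row.names = FALSE)
#' read_transcripts(f, unit = "px")   # x = 69 um
#' @export
read_transcripts <- function(path, unit = c("um", "px"), scale = pixel_scale()) {
  unit <- match.arg(unit)
  scale <- as_pixel_scale(scale)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- tryCatch(
    read.csv(path, sep = sep, colClasses = "character", check.names = FALSE),
    error = function(e) abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(raw) == 0) abort(sprintf("empty transcript table: %s", path))
  nm <- tolower(names(raw))
  for (col in c("x", "y", "gene")) {
    if (!col %in% nm) abort(sprintf("missing required column '%s' in %s", col, path))
  }
  x <- suppressWarnings(as.numeric(raw[[which(nm == "x")[1]]]))
  y <- suppressWarnings(as.numeric(raw[[which(nm == "y")[1]]]))
  gene <- raw[[which(nm == "gene")[1]]]
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric coordinate at line %s of %s",
                  paste(bad + 1L, collapse = ", "), path))
  }
  empty <- !nzchar(trimws(gene))
  if (any(empty)) {
    warn(sprintf("%d row(s) with empty gene name rejected (%s)",
                 sum(empty), path))
    x <- x[!empty]; y <- y[!empty]; gene <- gene[!empty]
  }
  if (unit == "px") {
    x <- px_to_um(x, scale)
    y <- px_to_um(y, scale)
  }
  tibble(x = x, y = y, gene = gene)
}

#' Write a transcript table
#'
#' Inverse of [read_transcripts()]; coordinates are written in the requested
#' unit with full double precision.
#'
#' @param transcripts Tibble with columns `x`, `y` (um), `gene`.
#' @param path Output path (.csv or .tsv).
#' @param unit Output unit.
#' @param scale A [pixel_scale()]; used when `unit = "px"`.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path, unit = c("um", "px"),
                              scale = pixel_scale()) {
  unit <- match.arg(unit)
  stopifnot(all(c("x", "y", "gene") %in% names(transcripts)))
  out <- transcripts[, c("x", "y", "gene")]
  if (unit == "px") {
    out$x <- um_to_px(out$x, scale)
    out$y <- um_to_px(out$y, scale)
  }
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
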