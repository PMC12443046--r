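# Minimal GIFTI surface I/O (ASCII encoding).
#
# Surfaces are exchanged as .surf.gii files with two DataArrays: a POINTSET
# (n x 3 float vertices, world mm) and a TRIANGLE array (m x 3 0-based
# indices). ASCII encoding keeps the files plain text and round-trippable
# without base64/zlib handling.

#' Write a triangular surface mesh as GIFTI
#'
#' @param vertices n x 3 numeric matrix of world coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param path output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(vertices, faces, path) {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  fmt_rows <- function(m, fmt) {
    paste(apply(m, 1, function(r) paste(sprintf(fmt, r), collapse = " ")),
          collapse = "\n")
  }
  da <- function(intent, dtype, m, fmt) {
    sprintf(paste0(
      '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
      'Dimensionality="2" Dim0="%d" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n',
      "<Data>\n%s\n</Data>\n</DataArray>"),
      intent, dtype, nrow(m), fmt_rows(m, fmt))
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    da("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", vertices, "%.6f"), "\n",
    da("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", faces - 1L, "%d"), "\n",
    "</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read a GIFTI surface written by [write_gifti_surface()]
#'
#' @param path `.surf.gii` file with ASCII-encoded POINTSET and TRIANGLE
#'   arrays.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  out <- list()
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    enc <- xml2::xml_attr(a, "Encoding")
    if (enc != "ASCII") stopf("read_gifti_surface: only ASCII encoding is supported")
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(a, ".//Data")),
                 quiet = TRUE)
    m <- matrix(vals, ncol = 3, byrow = TRUE)
    if (intent == "NIFTI_INTENT_POINTSET") out$vertices <- m
    if (intent == "NIFTI_INTENT_TRIANGLE") out$faces <- matrix(as.integer(m), ncol = 3) + 1L
  }
  if (is.null(out$vertices) || is.null(out$faces)) {
    stopf("read_gifti_surface: file lacks POINTSET or TRIANGLE array")
  }
  out
}

#' Read/write BIDS-style task event tables
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type` (seconds).
#' @param events data.frame with columns onset, duration, trial_type.
#' @param path TSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("onset", "duration", "trial_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a numeric matrix as a headered TSV (regressors, motion, tables)
#' @param m matrix or data.frame with column names.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
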