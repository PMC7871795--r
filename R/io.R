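# Readers/writers for the two on-disk surface dialects used in
# surface-based morphometry: FreeSurfer binary surfaces / curv files and
# GIFTI (.surf.gii / .shape.gii). Vertex indices are 0-based on disk and
# 1-based in memory.

FS_TRIANGLE_MAGIC <- c(0xFF, 0xFF, 0xFE)
FS_CURV_MAGIC <- c(0xFF, 0xFF, 0xFF)

#' Read a surface mesh from disk
#'
#' @param path file path.
#' @param format "auto" (by extension: .gii is GIFTI, anything else
#'   FreeSurfer binary), "freesurfer" or "gifti".
#' @param hemisphere hemisphere tag for the returned mesh.
#' @return a \code{triangle_mesh}.
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti"),
                         hemisphere = "none") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "freesurfer"
  switch(format,
         gifti = read_gifti_surface(path, hemisphere = hemisphere),
         freesurfer = read_freesurfer_surface(path, hemisphere = hemisphere))
}

#' Write a surface mesh to disk
#' @param mesh a \code{triangle_mesh}.
#' @param path file path.
#' @param format as in \code{\link{read_surface}}.
#' @export
write_surface <- function(mesh, path, format = c("auto", "freesurfer", "gifti")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti" else "freesurfer"
  switch(format,
         gifti = write_gifti_surface(mesh, path),
         freesurfer = write_freesurfer_surface(mesh, path))
}

# ---- FreeSurfer binary surface (big-endian) --------------------------------

#' @rdname read_surface
#' @export
read_freesurfer_surface <- function(path, hemisphere = "none") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(magic) < 3 || !all(magic == FS_TRIANGLE_MAGIC))
    stop(sprintf("'%s': not a FreeSurfer triangle surface (bad magic at byte 0)", path))
  # comment: bytes up to the "\n\n" terminator
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) stop(sprintf("'%s': truncated in the comment header", path))
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2, size = 4, endian = "big")
  if (length(counts) < 2 || any(counts <= 0))
    stop(sprintf("'%s': truncated or invalid vertex/face counts", path))
  nv <- counts[1]
  nf <- counts[2]
  v <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  f <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(v) < 3 * nv || length(f) < 3 * nf)
    stop(sprintf("'%s': truncated vertex or face data", path))
  triangle_mesh(matrix(v, ncol = 3, byrow = TRUE),
                matrix(f, ncol = 3, byrow = TRUE) + 1L,
                hemisphere = hemisphere)
}

#' @rdname write_surface
#' @export
write_freesurfer_surface <- function(mesh, path) {
  stopifnot_mesh(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(FS_TRIANGLE_MAGIC), con)
  writeChar("created by sulcalpits\n\n", con, eos = NULL)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write a FreeSurfer curv (per-vertex morph) file
#' @param path file path.
#' @return numeric per-vertex vector.
#' @export
read_freesurfer_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(magic) < 3 || !all(magic == FS_CURV_MAGIC))
    stop(sprintf("'%s': not a new-format FreeSurfer curv file", path))
  hdr <- readBin(con, "integer", n = 3, size = 4, endian = "big")
  nv <- hdr[1]
  vals <- readBin(con, "numeric", n = nv * hdr[3], size = 4, endian = "big")
  if (length(vals) < nv) stop(sprintf("'%s': truncated value data", path))
  vals
}

#' @rdname read_freesurfer_curv
#' @param values numeric per-vertex vector to write.
#' @param n_faces face count recorded in the header (informational).
#' @export
write_freesurfer_curv <- function(values, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(FS_CURV_MAGIC), con)
  writeBin(c(length(values), as.integer(n_faces), 1L), con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

# ---- GIFTI (.gii, XML) -----------------------------------------------------

gifti_decode_data <- function(da, path) {
  enc <- xml2::xml_attr(da, "Encoding")
  dtype <- xml2::xml_attr(da, "DataType")
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  if (is.na(txt)) stop(sprintf("'%s': DataArray without a Data element", path))
  if (enc == "ASCII") {
    vals <- scan(text = txt, what = numeric(), quiet = TRUE)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    endian <- if (identical(xml2::xml_attr(da, "Endian"), "BigEndian")) "big" else "little"
    vals <- switch(dtype,
      NIFTI_TYPE_FLOAT32 = readBin(raw, "numeric", n = length(raw) / 4, size = 4, endian = endian),
      NIFTI_TYPE_FLOAT64 = readBin(raw, "numeric", n = length(raw) / 8, size = 8, endian = endian),
      NIFTI_TYPE_INT32 = readBin(raw, "integer", n = length(raw) / 4, size = 4, endian = endian),
      stop(sprintf("'%s': unsupported GIFTI DataType '%s'", path, dtype)))
  } else {
    stop(sprintf("'%s': unsupported GIFTI encoding '%s'", path, enc))
  }
  dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
  dim1 <- xml2::xml_attr(da, "Dim1")
  ncol <- if (is.na(dim1)) 1L else as.integer(dim1)
  if (length(vals) != dim0 * ncol)
    stop(sprintf("'%s': DataArray element count %d does not match Dim0*Dim1=%d",
                 path, length(vals), dim0 * ncol))
  order <- xml2::xml_attr(da, "ArrayIndexingOrder")
  if (ncol > 1L) {
    if (identical(order, "ColumnMajorOrder")) matrix(vals, ncol = ncol)
    else matrix(vals, ncol = ncol, byrow = TRUE)
  } else vals
}

gifti_data_arrays <- function(path) {
  doc <- try(xml2::read_xml(path), silent = TRUE)
  if (inherits(doc, "try-error"))
    stop(sprintf("'%s': malformed XML (%s)", path, attr(doc, "condition")$message))
  xml2::xml_ns_strip(doc)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(das) == 0) stop(sprintf("'%s': no DataArray elements", path))
  das
}

#' @rdname read_surface
#' @export
read_gifti_surface <- function(path, hemisphere = "none") {
  das <- gifti_data_arrays(path)
  intents <- xml2::xml_attr(das, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1 || length(it) != 1)
    stop(sprintf("'%s': need exactly one POINTSET and one TRIANGLE DataArray", path))
  v <- gifti_decode_data(das[[ip]], path)
  f <- gifti_decode_data(das[[it]], path)
  triangle_mesh(v, f + 1L, hemisphere = hemisphere)
}

gifti_write_doc <- function(arrays, path) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">', length(arrays)))
  for (a in arrays) {
    lines <- c(lines, sprintf(
      '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">',
      a$intent, a$dtype, a$dimensionality, a$dims),
      "<Data>", a$data, "</Data>", "</DataArray>")
  }
  writeLines(c(lines, "</GIFTI>"), path)
  invisible(path)
}

#' @rdname write_surface
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces - 1L
  arrays <- list(
    list(intent = "NIFTI_INTENT_POINTSET", dtype = "NIFTI_TYPE_FLOAT32",
         dimensionality = 2L,
         dims = sprintf('Dim0="%d" Dim1="3"', nrow(v)),
         data = paste(apply(v, 1, function(r) paste(format(r, digits = 9, trim = TRUE),
                                                    collapse = " ")),
                      collapse = "\n")),
    list(intent = "NIFTI_INTENT_TRIANGLE", dtype = "NIFTI_TYPE_INT32",
         dimensionality = 2L,
         dims = sprintf('Dim0="%d" Dim1="3"', nrow(f)),
         data = paste(apply(f, 1, paste, collapse = " "), collapse = "\n")))
  gifti_write_doc(arrays, path)
}

#' Read / write a per-vertex scalar field as GIFTI .shape.gii
#' @param path file path.
#' @return numeric per-vertex vector.
#' @export
read_gifti_shape <- function(path) {
  das <- gifti_data_arrays(path)
  as.numeric(gifti_decode_data(das[[1]], path))
}

#' @rdname read_gifti_shape
#' @param values numeric per-vertex vector to write.
#' @export
write_gifti_shape <- function(values, path) {
  arrays <- list(list(intent = "NIFTI_INTENT_SHAPE", dtype = "NIFTI_TYPE_FLOAT32",
                      dimensionality = 1L,
                      dims = sprintf('Dim0="%d"', length(values)),
                      data = paste(format(as.numeric(values), digits = 9, trim = TRUE),
                                   collapse = "\n")))
  gifti_write_doc(arrays, path)
}

#' Read a vertex correspondence from CSV
#'
#' Expects columns \code{source_vertex}, \code{target_vertex} with
#' 0-based indices (the on-disk convention), one row per source vertex.
#'
#' @param path CSV path.
#' @param n_target vertex count of the target mesh.
#' @return a \code{\link{vertex_correspondence}}.
#' @export
read_correspondence <- function(path, n_target) {
  df <- utils::read.csv(path)
  if (!all(c("source_vertex", "target_vertex") %in% names(df)))
    stop(sprintf("'%s': need columns source_vertex and target_vertex", path))
  df <- df[order(df$source_vertex), ]
  if (!identical(as.integer(df$source_vertex), seq_len(nrow(df)) - 1L))
    stop(sprintf("'%s': source vertices must cover 0..n-1 exactly once", path))
  vertex_correspondence(df$target_vertex + 1L, n_target)
}
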