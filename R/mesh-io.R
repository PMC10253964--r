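# Surface-mesh file I/O: STL (binary + ASCII), PLY (ASCII), OBJ.
# Coordinates are read and written as millimetres; no unit metadata is used.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "ply", "obj")) return(ext)
  stop(sprintf("cannot guess mesh format from extension '%s'", ext))
}

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Duplicate vertices closer than 1e-9 mm are merged (STL stores one copy of
#' each vertex per facet), so the in-memory mesh has shared connectivity.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, `"obj"` or `"auto"` (by extension).
#' @param label,side passed to [triangle_mesh()]; label defaults to the
#'   file name.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      label = NULL, side = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") format <- guess_format(path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path))
  if (nrow(raw$vertices) == 0L) stop(sprintf("empty mesh in %s", path))
  m <- merge_duplicate_vertices(raw$vertices, raw$faces)
  triangle_mesh(m$vertices, m$faces, label = label, side = side,
                validate = FALSE)
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' PLY and OBJ are written as decimal text with 17 significant digits, so a
#' write/read round trip is coordinate-exact; binary STL stores 32-bit
#' floats and round-trips within float rounding.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"stl"` (binary), `"stl_ascii"`, `"ply"`, `"obj"` or
#'   `"auto"` (by extension; STL resolves to binary).
#' @param quality optional per-vertex scalar written as a PLY `quality`
#'   property (used for deviation-map export).
#' @return `invisible(path)`.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl", "stl_ascii", "ply", "obj"),
                       quality = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  validate_mesh(mesh, require_nondegenerate = FALSE)
  switch(format,
    stl = write_stl_binary(mesh, path),
    stl_ascii = write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path, quality = quality),
    obj = write_obj(mesh, path))
  invisible(path)
}

merge_duplicate_vertices <- function(vertices, faces, tol = 1e-9) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])  # position within the unique rows
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3)
  keep <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  list(vertices = vertices, faces = faces[keep, , drop = FALSE])
}

# ---- STL ----

is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  identical(sz, 84 + 50 * as.numeric(ntri))
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ntri < 0) stop(sprintf("corrupt binary STL %s: negative facet count at byte 80", path))
  body <- readBin(con, "raw", 50 * ntri)
  if (length(body) < 50 * ntri)
    stop(sprintf("corrupt binary STL %s: truncated at byte %d",
                 path, 84 + length(body)))
  m <- matrix(body, nrow = 50)
  coords <- matrix(readBin(as.vector(m[1:48, ]), "double", size = 4,
                           n = 12 * ntri, endian = "little"),
                   ncol = 12, byrow = TRUE)
  verts <- rbind(coords[, 4:6, drop = FALSE], coords[, 7:9, drop = FALSE],
                 coords[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * ntri), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]  # interleave v1,v2,v3 per facet
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3 != 0)
    stop(sprintf("corrupt ASCII STL %s: vertex count %d not a multiple of 3 (line %d)",
                 path, length(vl), if (length(vl)) vl[length(vl)] else 1L))
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  verts <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(verts)))
    stop(sprintf("corrupt ASCII STL %s: non-numeric vertex at line %d",
                 path, vl[which(!stats::complete.cases(verts))[1]]))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  ntri <- nrow(mesh$faces)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  n <- face_normals_raw(mesh)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  p1 <- face_corner(mesh, 1); p2 <- face_corner(mesh, 2); p3 <- face_corner(mesh, 3)
  block <- cbind(n, p1, p2, p3)  # ntri x 12 float32
  for (i in seq_len(ntri)) {
    writeBin(as.vector(block[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

write_stl_ascii <- function(mesh, path) {
  n <- face_normals_raw(mesh)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  p1 <- face_corner(mesh, 1); p2 <- face_corner(mesh, 2); p3 <- face_corner(mesh, 3)
  fmt <- function(m) apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  body <- paste0("facet normal ", fmt(n), "\n outer loop\n  vertex ",
                 fmt(p1), "\n  vertex ", fmt(p2), "\n  vertex ", fmt(p3),
                 "\n endloop\nendfacet")
  writeLines(c(sprintf("solid %s", mesh$label), body,
               sprintf("endsolid %s", mesh$label)), path)
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1] != "ply")
    stop(sprintf("corrupt PLY %s: missing 'ply' magic at line 1", path))
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop(sprintf("corrupt PLY %s: no end_header", path))
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv)) stop(sprintf("corrupt PLY %s: no vertex element", path))
  if (is.na(nf)) nf <- 0L
  vlines <- lines[hdr_end + seq_len(nv)]
  vtok <- strsplit(trimws(vlines), "\\s+")
  verts <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  faces <- matrix(integer(0), 0, 3)
  if (nf > 0) {
    flines <- lines[hdr_end + nv + seq_len(nf)]
    ftok <- strsplit(trimws(flines), "\\s+")
    counts <- vapply(ftok, function(t) as.integer(t[1]), integer(1))
    if (any(counts != 3L))
      stop(sprintf("corrupt PLY %s: non-triangle face at line %d",
                   path, hdr_end + nv + which(counts != 3L)[1]))
    faces <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
  }
  list(vertices = verts, faces = faces)
}

write_ply <- function(mesh, path, quality = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  qhdr <- if (!is.null(quality)) "property float quality" else NULL
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment %s", mesh$label),
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           qhdr,
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vt <- apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  if (!is.null(quality)) {
    stopifnot(length(quality) == nv)
    vt <- paste(vt, format(quality, digits = 9))
  }
  ft <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vt, ft), path)
}

# ---- OBJ (geometry only) ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  if (length(vl) == 0L) stop(sprintf("corrupt OBJ %s: no vertex lines", path))
  vtok <- strsplit(trimws(lines[vl]), "\\s+")
  verts <- t(vapply(vtok, function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- matrix(integer(0), 0, 3)
  if (length(fl) > 0) {
    ftok <- strsplit(trimws(lines[fl]), "\\s+")
    idx <- function(t) as.integer(sub("/.*", "", t[2:4]))
    nverts <- vapply(ftok, length, integer(1)) - 1L
    if (any(nverts != 3L))
      stop(sprintf("corrupt OBJ %s: non-triangle face at line %d",
                   path, fl[which(nverts != 3L)[1]]))
    faces <- t(vapply(ftok, idx, integer(3)))
  }
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  vt <- apply(mesh$vertices, 1, function(r)
    paste(c("v", format(r, digits = 17)), collapse = " "))
  ft <- apply(mesh$faces, 1, function(r)
    paste(c("f", r), collapse = " "))
  writeLines(c(sprintf("# %s", mesh$label), vt, ft), path)
}
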