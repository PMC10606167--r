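# Surface mesh file I/O: STL (ascii + binary), PLY (ascii + binary little
# endian on read, ascii on write), OBJ, and VTP (ascii XML PolyData).
# Units are taken as mm and the frame as LPS; no conversion is ever applied.
# Attribute data (normals, colors) is ignored on read.

#' Read a surface mesh
#'
#' @param path Path to a mesh file.
#' @param format One of `"stl"`, `"ply"`, `"obj"`, `"vtp"`; inferred from the
#'   file extension when `NULL`.
#' @param validate Validate closedness/manifoldness (default `TRUE`).
#' @return A [surface_mesh()]. STL soups are welded: vertices sharing
#'   identical coordinates (to 1e-9 mm) are merged.
#' @export
read_mesh <- function(path, format = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  format <- tolower(format %||% tools::file_ext(path))
  mesh <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    vtp = read_vtp(path),
    stop("unsupported mesh format: ", format, call. = FALSE)
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' Write a surface mesh
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param format One of `"stl"` (binary), `"stl_ascii"`, `"ply"` (ascii),
#'   `"obj"`, `"vtp"` (ascii); inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    stl = write_stl_binary(mesh, path),
    stl_ascii = write_stl_ascii(mesh, path),
    ply = write_ply_ascii(mesh, path),
    obj = write_obj(mesh, path),
    vtp = write_vtp(mesh, path),
    stop("unsupported mesh format: ", format, call. = FALSE)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && !nzchar(a))) b else a

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  sz <- file.info(path)$size
  is_binary <- FALSE
  if (sz >= 84) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (!is_binary && !grepl("^solid", rawToChar(head[1:5]))) {
    stop("STL parse error: not a recognizable ascii or binary STL", call. = FALSE)
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", 50 * ntri)
    m <- matrix(rec, nrow = 50)
    flt <- readBin(as.raw(m[1:48, ]), "numeric", size = 4, n = 12 * ntri,
                   endian = "little")
    fm <- matrix(flt, nrow = 12)          # per-triangle column: normal + 3 vertices
    pts <- matrix(as.numeric(fm[4:12, ]), ncol = 3, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop("STL parse error: vertex count not a multiple of 3", call. = FALSE)
    }
    pts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
      as.numeric(tok[2:4])
    }))
  }
  if (any(!is.finite(pts))) stop("STL parse error: non-finite coordinates", call. = FALSE)
  weld_soup_from_points(pts)
}

weld_soup_from_points <- function(pts) {
  key <- apply(round(pts, 9), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  surface_mesh(pts[first, , drop = FALSE],
               matrix(idx, ncol = 3, byrow = TRUE), validate = FALSE)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- cross3(p2 - p1, p3 - p1)
    nn <- vnorm(n); if (nn > 0) n <- n / nn
    writeLines(c(paste0("facet normal ", fmt(n)),
                 "  outer loop",
                 paste0("    vertex ", fmt(p1)),
                 paste0("    vertex ", fmt(p2)),
                 paste0("    vertex ", fmt(p3)),
                 "  endloop",
                 "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ln <- sqrt(rowSums(n^2)); ln[ln == 0] <- 1
  n <- n / ln
  rec <- t(cbind(n, p1, p2, p3))          # 12 floats per triangle
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(rec[, i]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) stop("PLY parse error: truncated header", call. = FALSE)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
    if (length(hdr) > 500) stop("PLY parse error: header not terminated", call. = FALSE)
  }
  if (!grepl("^ply", hdr[1])) stop("PLY parse error: missing magic", call. = FALSE)
  fmt_line <- grep("^format", hdr, value = TRUE)[1]
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("PLY parse error: missing element counts", call. = FALSE)
  # vertex property layout (only x,y,z retained)
  vstart <- grep("element vertex", hdr)
  vend <- grep("element face", hdr)
  vprops <- grep("^property", hdr[vstart:vend], value = TRUE)
  pnames <- vapply(strsplit(trimws(vprops), "\\s+"), function(x) x[length(x)], "")
  ptypes <- vapply(strsplit(trimws(vprops), "\\s+"), function(x) x[2], "")
  if (grepl("ascii", fmt_line)) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vtok <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    vm <- do.call(rbind, lapply(vtok, function(x) as.numeric(x[seq_along(pnames)])))
    verts <- vm[, match(c("x", "y", "z"), pnames), drop = FALSE]
    ftok <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(ftok, function(x) {
      k <- as.integer(x[1])
      if (k != 3) stop("PLY parse error: non-triangular face", call. = FALSE)
      as.integer(x[2:4]) + 1L
    }))
  } else if (grepl("binary_little_endian", fmt_line)) {
    szmap <- c(float = 4, float32 = 4, double = 8, float64 = 8, int = 4,
               int32 = 4, uint = 4, uint32 = 4, short = 2, ushort = 2,
               int16 = 2, uint16 = 2, char = 1, uchar = 1, int8 = 1, uint8 = 1)
    vs <- unname(szmap[ptypes])
    if (any(is.na(vs))) stop("PLY parse error: unknown property type", call. = FALSE)
    verts <- matrix(NA_real_, nv, 3)
    xyz <- match(c("x", "y", "z"), pnames)
    for (i in seq_len(nv)) {
      vals <- numeric(length(ptypes))
      for (j in seq_along(ptypes)) {
        what <- if (ptypes[j] %in% c("float", "float32", "double", "float64"))
          "numeric" else "integer"
        vals[j] <- readBin(con, what, 1, size = vs[j], endian = "little",
                           signed = !(vs[j] < 4 && grepl("^u", ptypes[j])))
      }
      verts[i, ] <- vals[xyz]
    }
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", k, size = 4, endian = "little")
      if (k != 3) stop("PLY parse error: non-triangular face", call. = FALSE)
      faces[i, ] <- idx + 1L
    }
  } else {
    stop("PLY parse error: unsupported format ", fmt_line, call. = FALSE)
  }
  surface_mesh(verts, faces, validate = FALSE)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) {
    stop("OBJ parse error: no vertices or faces", call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) != 3) stop("OBJ parse error: non-triangular face", call. = FALSE)
    idx
  }))
  surface_mesh(verts, faces, validate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("VTP parse error: no Piece element", call. = FALSE)
  pts_arr <- xml2::xml_find_first(piece, ".//Points/DataArray")
  coords <- as.numeric(strsplit(trimws(xml2::xml_text(pts_arr)), "\\s+")[[1]])
  verts <- matrix(coords, ncol = 3, byrow = TRUE)
  conn_arr <- xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='connectivity']")
  offs_arr <- xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='offsets']")
  conn <- as.integer(strsplit(trimws(xml2::xml_text(conn_arr)), "\\s+")[[1]])
  offs <- as.integer(strsplit(trimws(xml2::xml_text(offs_arr)), "\\s+")[[1]])
  if (any(diff(c(0L, offs)) != 3L)) stop("VTP parse error: non-triangular polys", call. = FALSE)
  surface_mesh(verts, matrix(conn + 1L, ncol = 3, byrow = TRUE), validate = FALSE)
}

write_vtp <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  pts <- paste(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), collapse = " ")
  conn <- paste(as.integer(t(f)) - 1L, collapse = " ")
  offs <- paste(seq_len(nrow(f)) * 3L, collapse = " ")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    ' <PolyData>\n',
    sprintf('  <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">\n',
            nrow(v), nrow(f)),
    '   <Points>\n',
    '    <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    pts, '</DataArray>\n',
    '   </Points>\n',
    '   <Polys>\n',
    '    <DataArray type="Int64" Name="connectivity" format="ascii">', conn,
    '</DataArray>\n',
    '    <DataArray type="Int64" Name="offsets" format="ascii">', offs,
    '</DataArray>\n',
    '   </Polys>\n',
    '  </Piece>\n',
    ' </PolyData>\n',
    '</VTKFile>\n')
  writeLines(xml, path, sep = "")
}
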