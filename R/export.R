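# Mesh export/import: STL (binary and ASCII, the TetGen pathway), OBJ and
# PLY for inspection. Re-import reproduces vertex positions within float
# precision (STL stores 32-bit floats) and identical triangle topology.

#' Export a triangle mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"stl_binary"`, `"stl_ascii"`, `"obj"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path,
                        format = c("stl_binary", "stl_ascii", "obj", "ply")) {
  stop_if_not_mesh(mesh)
  format <- match.arg(format)
  mesh <- orient_mesh(mesh)
  v <- mesh$vertices
  t <- mesh$triangles
  n <- face_normals(mesh)
  switch(format,
    stl_binary = {
      con <- file(path, "wb")
      on.exit(close(con))
      header <- charToRaw(sprintf("%-80s", "neuromesh binary STL"))[1:80]
      writeBin(header, con)
      writeBin(as.integer(nrow(t)), con, size = 4, endian = "little")
      tri_data <- matrix(0, nrow(t), 12)
      tri_data[, 1:3] <- n
      tri_data[, 4:6] <- v[t[, 1], , drop = FALSE]
      tri_data[, 7:9] <- v[t[, 2], , drop = FALSE]
      tri_data[, 10:12] <- v[t[, 3], , drop = FALSE]
      for (i in seq_len(nrow(t))) {
        writeBin(tri_data[i, ], con, size = 4, endian = "little")
        writeBin(as.raw(c(0, 0)), con)
      }
    },
    stl_ascii = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("solid neuromesh", con)
      for (i in seq_len(nrow(t))) {
        writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                           n[i, 1], n[i, 2], n[i, 3]), con)
        writeLines("    outer loop", con)
        for (c_ in 1:3) {
          p <- v[t[i, c_], ]
          writeLines(sprintf("      vertex %.9g %.9g %.9g",
                             p[1], p[2], p[3]), con)
        }
        writeLines("    endloop", con)
        writeLines("  endfacet", con)
      }
      writeLines("endsolid neuromesh", con)
    },
    obj = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("f %d %d %d", t[, 1], t[, 2], t[, 3]), con)
    },
    ply = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("ply", "format ascii 1.0",
                   sprintf("element vertex %d", nrow(v)),
                   "property float x", "property float y",
                   "property float z",
                   sprintf("element face %d", nrow(t)),
                   "property list uchar int vertex_indices",
                   "end_header"), con)
      writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", t[, 1] - 1L, t[, 2] - 1L,
                         t[, 3] - 1L), con)
    })
  invisible(path)
}

#' Import a triangle mesh
#'
#' Format detected from the extension (and STL flavour from content).
#' STL soup is welded on exactly-coincident vertices.
#'
#' @param path mesh file path.
#' @return a `triangle_mesh`.
#' @export
import_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    head <- readBin(path, "raw", 84)
    txt <- tryCatch(rawToChar(head[1:5]), error = function(e) "")
    is_ascii <- identical(txt, "solid") && {
      # binary files may also start with "solid": check size consistency
      nt <- readBin(head[81:84], "integer", size = 4, endian = "little")
      file.size(path) != 84 + 50 * nt
    }
    if (is_ascii) import_stl_ascii(path) else import_stl_binary(path)
  } else if (ext == "obj") {
    import_obj(path)
  } else if (ext == "ply") {
    import_ply(path)
  } else stop("unknown mesh format: .", ext)
}

import_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", size = 4, endian = "little")
  raw_all <- readBin(con, "raw", 50 * nt)
  m <- matrix(raw_all, nrow = 50)
  tri_raw <- as.vector(m[1:48, ])
  vals <- readBin(tri_raw, "numeric", n = 12 * nt, size = 4,
                  endian = "little")
  vals <- matrix(vals, ncol = 12, byrow = TRUE)
  verts <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
                 vals[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * nt), ncol = 3)))
  verts <- verts[ord, , drop = FALSE]
  tris <- matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE)
  weld_vertices(verts, tris)
}

import_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  parts <- strsplit(trimws(vlines), "\\s+")
  verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  nt <- nrow(verts) / 3
  tris <- matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE)
  weld_vertices(verts, tris)
}

import_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  verts <- t(vapply(strsplit(vlines, "\\s+"),
                    function(p) as.numeric(p[2:4]), numeric(3)))
  tris <- t(vapply(strsplit(flines, "\\s+"), function(p) {
    as.integer(sub("/.*$", "", p[2:4]))
  }, integer(3)))
  triangle_mesh(verts, tris)
}

import_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hend <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vlines <- lines[(hend + 1):(hend + nv)]
  flines <- lines[(hend + nv + 1):(hend + nv + nf)]
  verts <- t(vapply(strsplit(vlines, "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
  tris <- t(vapply(strsplit(flines, "\\s+"),
                   function(p) as.integer(p[2:4]) + 1L, integer(3)))
  triangle_mesh(verts, tris)
}
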