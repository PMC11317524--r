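#' Triangle mesh container
#'
#' The universal geometric currency of the pipeline: an indexed triangle set
#' with vertex positions in micrometres. Triangle indices are 1-based.
#'
#' @param vertices numeric matrix, n x 3, positions in micrometres.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param validate logical; check index ranges and degenerate index triples.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  triangles <- matrix(as.integer(triangles), ncol = 3,
                      dimnames = NULL)
  if (validate && nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stop("triangle index out of range [1, ", nrow(vertices), "]")
    if (any(triangles[, 1] == triangles[, 2] |
            triangles[, 2] == triangles[, 3] |
            triangles[, 1] == triangles[, 3]))
      stop("triangle repeats a vertex index")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<triangle_mesh: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  bbox [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] um\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

stop_if_not_mesh <- function(mesh) {
  if (!is_triangle_mesh(mesh)) stop("expected a triangle_mesh")
  invisible(mesh)
}

# Encode undirected edges as numeric keys min*nv + max. nv <= ~5e7 keeps the
# product well inside the exactly-representable double range (2^53).
edge_keys <- function(triangles, n_vertices) {
  a <- as.numeric(triangles[, c(1L, 2L, 3L)])
  b <- as.numeric(triangles[, c(2L, 3L, 1L)])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo * (n_vertices + 1) + hi
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer matrix, e x 2 (lo, hi vertex indices).
#' @export
mesh_edges <- function(mesh) {
  stop_if_not_mesh(mesh)
  nv <- nrow(mesh$vertices)
  keys <- unique(edge_keys(mesh$triangles, nv))
  lo <- floor(keys / (nv + 1))
  hi <- keys - lo * (nv + 1)
  cbind(as.integer(lo), as.integer(hi))
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed genus-0 surface, 0 for a torus.
#' @param mesh a `triangle_mesh`.
#' @return integer scalar.
#' @export
mesh_euler_characteristic <- function(mesh) {
  stop_if_not_mesh(mesh)
  v <- length(unique(as.vector(mesh$triangles)))
  e <- nrow(mesh_edges(mesh))
  f <- nrow(mesh$triangles)
  as.integer(v - e + f)
}

# per-face edge multiplicity table: named integer vector key -> count
edge_face_counts <- function(mesh) {
  nv <- nrow(mesh$vertices)
  keys <- edge_keys(mesh$triangles, nv)
  tab <- table(keys)
  list(keys = as.numeric(names(tab)), counts = as.integer(tab), nv = nv)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  e1 <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  e2 <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx * cx + cy * cy + cz * cz)
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  t <- mesh$triangles
  e1 <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  e2 <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n * n))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Surface area of a mesh
#' @param mesh a `triangle_mesh`.
#' @return total area in square micrometres.
#' @export
surface_area <- function(mesh) {
  stop_if_not_mesh(mesh)
  sum(triangle_areas(mesh))
}

# signed volume w.r.t. origin, no orientation fixing
signed_volume <- function(mesh) {
  v <- mesh$vertices
  t <- mesh$triangles
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c <- v[t[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Normalize triangle orientation
#'
#' Makes winding consistent across each connected component (propagation over
#' shared edges) and flips whole components so the total enclosed volume is
#' positive (outward normals).
#'
#' @param mesh a `triangle_mesh`.
#' @return a `triangle_mesh` with consistent outward orientation.
#' @export
orient_mesh <- function(mesh) {
  stop_if_not_mesh(mesh)
  if (nrow(mesh$triangles) == 0L) return(mesh)
  tri <- cpp_orient_triangles(mesh$vertices, mesh$triangles)
  triangle_mesh(mesh$vertices, tri, validate = FALSE)
}

#' Enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin after orientation
#' normalization; translation-invariant for closed surfaces.
#'
#' @param mesh a closed `triangle_mesh`.
#' @return volume in cubic micrometres (positive).
#' @export
enclosed_volume <- function(mesh) {
  stop_if_not_mesh(mesh)
  ef <- edge_face_counts(mesh)
  if (any(ef$counts != 2L))
    stop("enclosed_volume: mesh is not closed (",
         sum(ef$counts == 1L), " boundary edges, ",
         sum(ef$counts > 2L), " over-shared edges)")
  abs(signed_volume(orient_mesh(mesh)))
}

# drop vertices not referenced by any triangle, remap indices
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$triangles)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[mesh$triangles], ncol = 3),
                validate = FALSE)
}

# weld exactly-coincident vertices (used by STL import)
weld_vertices <- function(vertices, triangles) {
  key <- paste(vertices[, 1], vertices[, 2], vertices[, 3], sep = "/")
  first <- !duplicated(key)
  remap <- match(key, key[first])  # index into the reduced vertex table
  triangle_mesh(vertices[first, , drop = FALSE],
                matrix(remap[triangles], ncol = 3), validate = FALSE)
}

#' Merge several meshes into one vertex/triangle table
#'
#' Pure concatenation with index offsetting; no welding, no boolean union.
#' @param meshes list of `triangle_mesh`.
#' @return a `triangle_mesh`.
#' @export
concatenate_meshes <- function(meshes) {
  stopifnot(length(meshes) >= 1L)
  offs <- 0L
  vs <- vector("list", length(meshes))
  ts <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    stop_if_not_mesh(m)
    vs[[i]] <- m$vertices
    ts[[i]] <- m$triangles + offs
    offs <- offs + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, ts), validate = FALSE)
}

rigid_transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  v <- mesh$vertices %*% t(rotation) * scale
  v <- sweep(v, 2, translation, "+")
  triangle_mesh(v, mesh$triangles, validate = FALSE)
}
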