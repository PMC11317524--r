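# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's compiled code paths: brute-force R implementations used to
# cross-check the fast detectors.

# --- simple meshes ----------------------------------------------------------

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  dimnames(v) <- NULL
  t <- matrix(c(1, 3, 2, 2, 3, 4, 5, 6, 7, 6, 8, 7, 1, 2, 5, 2, 6, 5,
                3, 7, 4, 4, 7, 8, 1, 5, 3, 3, 5, 7, 2, 4, 6, 4, 8, 6),
              ncol = 3, byrow = TRUE)
  orient_mesh(triangle_mesh(v, t))
}

# axis-aligned box with each face triangulated on an n x n grid (planar
# regions with redundant vertices -> error-free quadric collapses exist)
gridded_cube_mesh <- function(n = 6) {
  verts <- matrix(numeric(0), 0, 3)
  tris <- matrix(integer(0), 0, 3)
  add_face <- function(origin, du, dv) {
    base <- nrow(verts)
    uu <- seq(0, 1, length.out = n + 1)
    grid <- as.matrix(expand.grid(u = uu, v = uu))
    pts <- matrix(rep(origin, each = nrow(grid)), ncol = 3) +
      grid[, 1] %o% du + grid[, 2] %o% dv
    verts <<- rbind(verts, pts)
    id <- function(i, j) base + (j - 1) * (n + 1) + i
    for (j in seq_len(n))
      for (i in seq_len(n)) {
        a <- id(i, j); b <- id(i + 1, j); c <- id(i, j + 1); d <- id(i + 1, j + 1)
        tris <<- rbind(tris, c(a, b, d), c(a, d, c))
      }
  }
  add_face(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # z = 0
  add_face(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))  # z = 1
  add_face(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))  # y = 0
  add_face(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))  # y = 1
  add_face(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))  # x = 0
  add_face(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))  # x = 1
  m <- neuromesh:::weld_vertices(verts, tris)
  orient_mesh(m)
}

# two tetrahedra welded along a single shared edge (classic non-manifold
# edge fixture)
welded_tets_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0),              # shared edge 1-2
             c(0.5, 1, 0.3), c(0.5, 0.6, 1),      # tet A apexes
             c(0.5, -1, 0.3), c(0.5, -0.6, -1))   # tet B apexes
  t <- rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4),
             c(1, 2, 5), c(1, 6, 2), c(2, 6, 5), c(1, 5, 6))
  triangle_mesh(v, t)
}

swc_lines_to_morph <- function(lines) {
  f <- withr::local_tempfile(fileext = ".swc",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  read_swc(f)
}

# straight dendrite along +x with a soma: radius r, length L, n samples
straight_dendrite_morph <- function(r = 0.5, L = 20, n = 11,
                                    soma_r = 2, type = 3L) {
  xs <- seq(soma_r + 0.5, soma_r + 0.5 + L, length.out = n)
  rows <- data.frame(id = seq_len(n + 1L),
                     type = c(1L, rep(type, n)),
                     x = c(0, xs), y = 0, z = 0,
                     radius = c(soma_r, rep(r, n)),
                     parent = c(-1L, 1L, seq_len(n - 1L) + 1L))
  morphology_from_samples(rows)
}

# full binary tree morphology of given depth (every section bifurcates)
binary_tree_morph <- function(depth = 3) {
  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 2, parent = -1L))
  next_id <- 2L
  grow <- function(pos, dir, order, parent_id) {
    p2 <- pos + dir * 4
    mid <- pos + dir * 2
    ids <- c(next_id, next_id + 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = ids, type = 3L,
      x = c(mid[1], p2[1]), y = c(mid[2], p2[2]), z = c(mid[3], p2[3]),
      radius = 0.5, parent = c(parent_id, ids[1]))
    next_id <<- next_id + 2L
    if (order < depth) {
      rot <- pi / 5
      d1 <- c(cos(rot) * dir[1] - sin(rot) * dir[2],
              sin(rot) * dir[1] + cos(rot) * dir[2], dir[3])
      d2 <- c(cos(-rot) * dir[1] - sin(-rot) * dir[2],
              sin(-rot) * dir[1] + cos(-rot) * dir[2], dir[3])
      grow(p2, d1 / sqrt(sum(d1^2)), order + 1L, ids[2])
      grow(p2, d2 / sqrt(sum(d2^2)), order + 1L, ids[2])
    }
  }
  start <- c(2.05, 0, 0)
  rows[[2]] <- data.frame(id = 2L, type = 3L, x = start[1], y = 0, z = 0,
                          radius = 0.5, parent = 1L)
  next_id <- 3L
  grow(start, c(1, 0, 0), 1L, 2L)
  morphology_from_samples(do.call(rbind, rows))
}

# --- independent oracles ----------------------------------------------------

# brute-force segment-triangle based triangle-triangle intersection test,
# independent of the compiled detector
oracle_tri_tri <- function(a1, a2, a3, b1, b2, b3, eps = 1e-12) {
  seg_tri <- function(p, q, t1, t2, t3) {
    # does segment p-q properly cross triangle t1 t2 t3?
    n <- pracma_cross(t2 - t1, t3 - t1)
    dp <- sum(n * (p - t1))
    dq <- sum(n * (q - t1))
    if (dp * dq >= 0) return(FALSE)          # same side or touching
    s <- dp / (dp - dq)
    x <- p + s * (q - p)
    # barycentric inside test
    v0 <- t3 - t1; v1 <- t2 - t1; v2 <- x - t1
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    if (abs(den) < eps) return(FALSE)
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    u > eps && v > eps && (1 - u - v) > eps
  }
  seg_tri(a1, a2, b1, b2, b3) || seg_tri(a2, a3, b1, b2, b3) ||
    seg_tri(a3, a1, b1, b2, b3) || seg_tri(b1, b2, a1, a2, a3) ||
    seg_tri(b2, b3, a1, a2, a3) || seg_tri(b3, b1, a1, a2, a3)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# all-pairs intersection oracle with bbox prefilter; returns sorted pair
# matrix like self_intersection_pairs()
oracle_self_intersections <- function(mesh) {
  t <- mesh$triangles
  v <- mesh$vertices
  nt <- nrow(t)
  lo <- list(); hi <- list()
  for (c_ in 1:3) {
    x <- cbind(v[t[, 1], c_], v[t[, 2], c_], v[t[, 3], c_])
    lo[[c_]] <- apply(x, 1, min)
    hi[[c_]] <- apply(x, 1, max)
  }
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (lo[[1]][i] > hi[[1]][j] || lo[[1]][j] > hi[[1]][i] ||
          lo[[2]][i] > hi[[2]][j] || lo[[2]][j] > hi[[2]][i] ||
          lo[[3]][i] > hi[[3]][j] || lo[[3]][j] > hi[[3]][i]) next
      if (length(intersect(t[i, ], t[j, ]))) next
      if (oracle_tri_tri(v[t[i, 1], ], v[t[i, 2], ], v[t[i, 3], ],
                         v[t[j, 1], ], v[t[j, 2], ], v[t[j, 3], ]))
        pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

# adjacency-table non-manifold oracle: edge counts via string keys, vertex
# fans via per-vertex DFS over shared-edge face adjacency
oracle_non_manifold <- function(mesh) {
  t <- mesh$triangles
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ekey(t[, 1], t[, 2]), ekey(t[, 2], t[, 3]), ekey(t[, 3], t[, 1]))
  tab <- table(keys)
  nm_vertices <- integer(0)
  for (v_ in sort(unique(as.vector(t)))) {
    faces <- which(t[, 1] == v_ | t[, 2] == v_ | t[, 3] == v_)
    if (length(faces) < 2) next
    # adjacency among these faces through edges incident to v_
    adj <- matrix(FALSE, length(faces), length(faces))
    for (i in seq_along(faces))
      for (j in seq_along(faces))
        if (i != j &&
            length(intersect(setdiff(t[faces[i], ], v_),
                             setdiff(t[faces[j], ], v_))) >= 1)
          adj[i, j] <- TRUE
    seen <- rep(FALSE, length(faces))
    stack <- 1L
    seen[1] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nbr <- which(adj[cur, ] & !seen)
      seen[nbr] <- TRUE
      stack <- c(stack, nbr)
    }
    if (!all(seen)) nm_vertices <- c(nm_vertices, v_)
  }
  list(boundary_edges = sum(tab == 1),
       non_manifold_edges = sum(tab > 2),
       non_manifold_vertices = nm_vertices)
}

# seeded vertex-slide defect injection that reliably self-intersects an
# icosphere (tangential displacement by ~2 edge lengths)
inject_defect <- function(mesh, seed) {
  set.seed(seed)
  v <- mesh$vertices
  j <- sample(nrow(v), 1)
  tang <- stats::rnorm(3)
  tang <- tang - sum(tang * v[j, ]) * v[j, ] / sum(v[j, ]^2)
  tang <- tang / sqrt(sum(tang^2))
  out <- mesh
  p <- v[j, ] + tang * stats::runif(1, 0.8, 1.4)
  # project back to the sphere so the displaced fan folds across the
  # surface instead of tenting above it (convexity would otherwise avoid
  # any crossing)
  out$vertices[j, ] <- p / sqrt(sum(p^2)) * sqrt(sum(v[j, ]^2))
  out
}
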