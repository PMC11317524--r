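# Closed geometric primitives used as proxy components. All swept / lathed
# geometry uses area-compensated polygonal radii (an n-gon inscribed in a
# circle of radius r*sqrt((2*pi/n)/sin(2*pi/n)) has exactly the area pi*r^2),
# so tube and spine volumes track the analytic solids instead of
# systematically undershooting them.

polygon_area_compensation <- function(sides) {
  a <- 2 * pi / sides
  sqrt(a / sin(a))
}

#' A 3D centerline path with per-point radii
#'
#' @param points n x 3 matrix of positions (micrometres).
#' @param radii length-n positive radii (micrometres).
#' @return an object of class `path3d`.
#' @export
path3d <- function(points, radii) {
  points <- matrix(as.numeric(points), ncol = 3)
  radii <- as.numeric(radii)
  if (nrow(points) < 2L) stop("path3d needs >= 2 points")
  if (length(radii) != nrow(points))
    stop("radii length must match point count")
  if (any(radii <= 0)) stop("path3d radii must be positive")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("path3d has coincident consecutive points")
  structure(list(points = points, radii = radii), class = "path3d")
}

path_arclength <- function(path) {
  p <- path$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# drop exactly-coincident consecutive points before constructing a path3d
dedupe_polyline <- function(points, radii) {
  n <- nrow(points)
  if (n < 2L) return(list(points = points, radii = radii))
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  keep <- c(TRUE, seg > 0)
  list(points = points[keep, , drop = FALSE], radii = radii[keep])
}

#' Resample a path piecewise-linearly or on a cubic spline
#'
#' With `use_spline`, coordinates are interpolated by a natural cubic spline
#' in chordal arclength and resampled at the requested step; otherwise the
#' polyline is resampled linearly. Endpoints are exact and radii follow the
#' same parameterization (linear in arclength, preserving positivity).
#'
#' @param path a `path3d`.
#' @param use_spline logical.
#' @param step arclength step in micrometres.
#' @return a `path3d`.
#' @export
interpolate_path <- function(path, use_spline = TRUE, step = 1) {
  if (step <= 0) stop("step must be positive")
  p <- path$points
  n <- nrow(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[n]
  m <- max(1L, ceiling(L / step))
  ts <- seq(0, L, length.out = m + 1L)
  if (use_spline && n >= 3L) {
    px <- stats::spline(s, p[, 1], xout = ts, method = "natural")$y
    py <- stats::spline(s, p[, 2], xout = ts, method = "natural")$y
    pz <- stats::spline(s, p[, 3], xout = ts, method = "natural")$y
  } else {
    px <- stats::approx(s, p[, 1], ts)$y
    py <- stats::approx(s, p[, 2], ts)$y
    pz <- stats::approx(s, p[, 3], ts)$y
  }
  newp <- rbind(p[1, ], cbind(px, py, pz)[c(-1L, -(m + 1L)), , drop = FALSE],
                p[n, ])
  newr <- stats::approx(s, path$radii, ts)$y
  d <- dedupe_polyline(newp, newr)
  path3d(d$points, d$radii)
}

# rotation-minimizing frames by the double-reflection method; returns list of
# n1, n2 matrices (n x 3) orthonormal to the path tangent
rmf_frames <- function(points) {
  n <- nrow(points)
  tang <- matrix(0, n, 3)
  tang[1, ] <- points[2, ] - points[1, ]
  tang[n, ] <- points[n, ] - points[n - 1, ]
  if (n > 2L)
    tang[2:(n - 1), ] <- points[3:n, , drop = FALSE] -
      points[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang * tang))
  # initial normal: least-aligned axis
  t0 <- tang[1, ]
  axis <- diag(3)[, which.min(abs(t0))]
  r0 <- axis - sum(axis * t0) * t0
  r0 <- r0 / sqrt(sum(r0 * r0))
  n1 <- matrix(0, n, 3)
  n1[1, ] <- r0
  for (i in seq_len(n - 1L)) {
    v1 <- points[i + 1L, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rl <- n1[i, ] - (2 / c1) * sum(v1 * n1[i, ]) * v1
    tl <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1L, ] - tl
    c2 <- sum(v2 * v2)
    r_next <- if (c2 > 1e-30) rl - (2 / c2) * sum(v2 * rl) * v2 else rl
    n1[i + 1L, ] <- r_next / sqrt(sum(r_next * r_next))
  }
  n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
              tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
              tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
  list(n1 = n1, n2 = n2)
}

#' Sweep a closed tube along a path
#'
#' Places `ring_sides`-gon cross-sections in planes normal to the path using
#' rotation-minimizing frames, stitches consecutive rings, and caps both ends
#' with flat triangle fans. Output is a closed two-manifold with Euler
#' characteristic 2.
#'
#' @param path a `path3d` (length >= 2).
#' @param ring_sides integer >= 3.
#' @return a `triangle_mesh`.
#' @export
sweep_tube <- function(path, ring_sides = 16L) {
  ring_sides <- as.integer(ring_sides)
  if (ring_sides < 3L) stop("ring_sides must be >= 3")
  p <- path$points
  n <- nrow(p)
  fr <- rmf_frames(p)
  comp <- polygon_area_compensation(ring_sides)
  theta <- 2 * pi * (seq_len(ring_sides) - 1L) / ring_sides
  verts <- matrix(0, n * ring_sides + 2L, 3)
  for (i in seq_len(n)) {
    r <- path$radii[i] * comp
    ring <- outer(cos(theta), fr$n1[i, ]) + outer(sin(theta), fr$n2[i, ])
    verts[((i - 1L) * ring_sides + 1L):(i * ring_sides), ] <-
      sweep(r * ring, 2, p[i, ], "+")
  }
  apex0 <- n * ring_sides + 1L
  apex1 <- n * ring_sides + 2L
  verts[apex0, ] <- p[1, ]
  verts[apex1, ] <- p[n, ]
  tris <- vector("list", n + 1L)
  idx <- function(i, j) (i - 1L) * ring_sides + ((j - 1L) %% ring_sides) + 1L
  j <- seq_len(ring_sides)
  for (i in seq_len(n - 1L)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    tris[[i]] <- rbind(cbind(a, c, b), cbind(b, c, d))
  }
  # caps: wound opposite to the side walls so normals stay outward-consistent
  tris[[n]] <- cbind(apex0, idx(1L, j + 1L), idx(1L, j))
  tris[[n + 1L]] <- cbind(apex1, idx(n, j), idx(n, j + 1L))
  orient_mesh(triangle_mesh(verts, do.call(rbind, tris), validate = FALSE))
}

#' Geodesic icosphere
#'
#' Subdivided icosahedron projected onto the sphere; closed two-manifold.
#'
#' @param center 3-vector.
#' @param radius positive scalar.
#' @param subdivisions integer >= 0 (0 = icosahedron, 20 faces).
#' @return a `triangle_mesh`.
#' @export
icosphere <- function(center = c(0, 0, 0), radius = 1, subdivisions = 2L) {
  if (radius <= 0) stop("radius must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    keys <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      hit <- keys[[k]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m * m))
      v <<- rbind(v, m)
      keys[[k]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nrow(f) * 4L, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(4L * i - 3L):(4L * i), ] <-
        rbind(c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  verts <- sweep(v * radius, 2, center, "+")
  orient_mesh(triangle_mesh(verts, f, validate = FALSE))
}

# Surface of revolution about +Z through profile (z_i, r_i), r_i > 0; closed
# by fan caps at both profile ends (flat disc, or apex when the end radius
# collapses below eps). Used for spine templates.
lathe_mesh <- function(z, r, sides = 16L, apex_eps = 1e-9) {
  stopifnot(length(z) == length(r), length(z) >= 2L)
  sides <- as.integer(sides)
  comp <- polygon_area_compensation(sides)
  theta <- 2 * pi * (seq_len(sides) - 1L) / sides
  cs <- cos(theta); sn <- sin(theta)
  ring_rows <- which(r > apex_eps)
  verts <- do.call(rbind, lapply(ring_rows, function(i)
    cbind(r[i] * comp * cs, r[i] * comp * sn, z[i])))
  nr <- length(ring_rows)
  idx <- function(i, j) (i - 1L) * sides + ((j - 1L) %% sides) + 1L
  j <- seq_len(sides)
  tris <- list()
  for (i in seq_len(nr - 1L)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    tris[[length(tris) + 1L]] <- rbind(cbind(a, c, b), cbind(b, c, d))
  }
  # bottom cap
  bot <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, z[1]))
  tris[[length(tris) + 1L]] <- cbind(bot, idx(1L, j + 1L), idx(1L, j))
  # top cap
  top <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, z[length(z)]))
  tris[[length(tris) + 1L]] <- cbind(top, idx(nr, j), idx(nr, j + 1L))
  orient_mesh(triangle_mesh(verts, do.call(rbind, tris), validate = FALSE))
}
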