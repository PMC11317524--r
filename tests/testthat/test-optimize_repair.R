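# Coarsening, smoothing, defect-vertex repair and the optimization wrapper.

test_that("coarsening halves an icosphere while preserving volume", {
  s <- icosphere(radius = 1, subdivisions = 4)      # 5120 faces
  d <- coarsen(s, 0.5)
  expect_lte(nrow(d$triangles), 2560L)
  expect_lt(abs(enclosed_volume(d) - enclosed_volume(s)) /
              enclosed_volume(s), 0.01)
  expect_true(check_watertight(d)$watertight)
  # target_ratio 1 is the identity
  expect_identical(coarsen(s, 1), s)
  expect_error(coarsen(s, 0), "target_ratio")
})

test_that("planar regions collapse error-free: gridded cube keeps volume", {
  cube <- gridded_cube_mesh(6)                      # 432 faces, all planar
  for (ratio in c(0.5, 0.2)) {
    d <- coarsen(cube, ratio)
    expect_lt(nrow(d$triangles), nrow(cube$triangles))
    expect_equal(enclosed_volume(d), 1.0, tolerance = 1e-9)
  }
})

test_that("coarsening is adaptive: corrugated half keeps more triangles", {
  # box with a corrugated top on x < 0 and a flat top on x > 0
  n <- 40
  xs <- seq(-1, 1, length.out = n + 1)
  ys <- seq(0, 1, length.out = n / 2 + 1)
  top <- as.matrix(expand.grid(x = xs, y = ys))
  z <- ifelse(top[, 1] < 0, 0.5 + 0.06 * sin(12 * pi * top[, 1]) *
                sin(6 * pi * top[, 2]), 0.5)
  verts <- cbind(top, z)
  id <- function(i, j) (j - 1) * (n + 1) + i
  tris <- NULL
  for (j in seq_len(n / 2))
    for (i in seq_len(n)) {
      a <- id(i, j); b <- id(i + 1, j); c <- id(i, j + 1); d <- id(i + 1, j + 1)
      tris <- rbind(tris, c(a, b, d), c(a, d, c))
    }
  # close the box: extrude boundary down to z = 0 with coarse walls
  # (simplest closed fixture: mirror the top to a flat bottom)
  nb <- nrow(verts)
  verts2 <- rbind(verts, cbind(top, 0))
  tris2 <- rbind(tris, tris[, c(1, 3, 2)] + nb)
  # stitch the rectangle boundary
  boundary <- c(sapply(seq_len(n), function(i) c(id(i, 1), id(i + 1, 1))))
  ring <- unique(c(seq_len(n + 1),                       # j = 1 row
                   id(n + 1, seq_len(n / 2 + 1)),
                   rev(id(seq_len(n + 1), n / 2 + 1)),
                   rev(id(1, seq_len(n / 2 + 1)))))
  wall <- NULL
  for (k in seq_along(ring)) {
    a <- ring[k]; b <- ring[k %% length(ring) + 1]
    wall <- rbind(wall, c(a, b, b + nb), c(a, b + nb, a + nb))
  }
  box <- orient_mesh(triangle_mesh(verts2, rbind(tris2, wall)))
  expect_equal(neuromesh:::edge_face_counts(box)$counts |>
                 (\(x) sum(x != 2))(), 0)
  d <- coarsen(box, 0.25)
  cen <- (d$vertices[d$triangles[, 1], ] + d$vertices[d$triangles[, 2], ] +
            d$vertices[d$triangles[, 3], ]) / 3
  top_faces <- cen[, 3] > 0.4
  left <- sum(top_faces & cen[, 1] < -0.05)
  right <- sum(top_faces & cen[, 1] > 0.05)
  expect_gte(left, 2 * right)
})

test_that("smoothing is identity at 0 iterations, denoises, keeps volume", {
  s <- icosphere(radius = 1, subdivisions = 3)
  expect_identical(smooth_mesh(s, 0L), s)
  set.seed(11)
  noisy <- triangle_mesh(s$vertices * (1 + 0.01 * rnorm(nrow(s$vertices))),
                         s$triangles)
  sm <- smooth_mesh(noisy, 10L)
  rad_sd <- function(m) stats::sd(sqrt(rowSums(m$vertices^2)))
  expect_gte(rad_sd(noisy) / rad_sd(sm), 2.5)
  expect_lt(abs(enclosed_volume(sm) - enclosed_volume(noisy)) /
              enclosed_volume(noisy), 0.005)
  expect_identical(sm$triangles, noisy$triangles)  # vertex-move-only
})

test_that("delete_and_retriangulate closes holes around deleted vertices", {
  s <- icosphere(radius = 1, subdivisions = 2)
  # single vertex: its 5/6-ring closes
  out1 <- delete_and_retriangulate(s, 7L)
  expect_equal(check_watertight(out1, check_intersections = FALSE)$boundary_edges, 0L)
  expect_equal(mesh_euler_characteristic(out1), 2L)
  # empty set: identity
  expect_identical(delete_and_retriangulate(s, integer(0)), s)
  # two adjacent vertices: merged hole, still closed
  e <- mesh_edges(s)
  pair <- e[1, ]
  out2 <- delete_and_retriangulate(s, pair)
  expect_equal(check_watertight(out2, check_intersections = FALSE)$boundary_edges, 0L)
  expect_error(delete_and_retriangulate(s, seq_len(nrow(s$vertices))),
               "strict subset")
})

test_that("repair loop fixes injected self-intersections within 3 iterations", {
  base <- icosphere(radius = 1, subdivisions = 2)
  m <- inject_defect(base, 5)
  expect_gt(nrow(self_intersection_pairs(m)), 0L)
  res <- repair_loop(m)
  expect_true(res$trace$converged)
  expect_lte(res$trace$iterations_used, 3L)
  expect_true(check_watertight(res$mesh)$watertight)
  # already-watertight input: single check iteration, identity
  res2 <- repair_loop(base)
  expect_equal(res2$trace$iterations_used, 1L)
  expect_identical(res2$mesh, base)
})

test_that("repair fuzz: seeded displacements all converge (scaled at n=25)", {
  # the full 100-case fuzz runs in test-acceptance.R; 25 here keeps the
  # unit suite quick
  base <- icosphere(radius = 1, subdivisions = 2)
  n_ok <- 0L
  defect_trace <- integer(0)
  for (seed in 1:25) {
    m <- inject_defect(base, seed)
    res <- tryCatch(repair_loop(m), error = function(e) NULL)
    ok <- !is.null(res) && check_watertight(res$mesh)$watertight
    n_ok <- n_ok + ok
  }
  expect_equal(n_ok, 25L)
})

test_that("optimize_mesh reduces tessellation and preserves volume", {
  sp <- icosphere(radius = 2, subdivisions = 1)
  mesh <- polygonize(voxelize_solid(sp, 0.1))
  cfg <- meshing_config(optimization_target_ratio = 0.6,
                        smoothing_iterations = 3L)
  res <- optimize_mesh(mesh, cfg)
  expect_true(check_watertight(res$mesh)$watertight)
  expect_lte(nrow(res$mesh$triangles), 0.7 * nrow(mesh$triangles))
  drift <- abs(enclosed_volume(res$mesh) - enclosed_volume(mesh)) /
    enclosed_volume(mesh)
  expect_lte(drift, 0.02)
  # identity configuration
  s <- icosphere(radius = 1, subdivisions = 3)
  res2 <- optimize_mesh(s, meshing_config(optimization_target_ratio = 1,
                                          smoothing_iterations = 0L))
  expect_equal(sort(neuromesh:::signed_volume(res2$mesh)),
               sort(neuromesh:::signed_volume(s)), tolerance = 1e-12)
  expect_equal(nrow(res2$mesh$triangles), nrow(s$triangles))
})
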