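# Proxy arbor generation: primary labeling, path construction, tube
# sweeping, icospheres and joint assembly.

test_that("primary child is the largest-initial-radius child, index tie-break", {
  mk <- function(radii) {
    # soma + trunk + children with given first-sample radii
    n <- length(radii)
    rows <- list(data.frame(id = 1:3, type = c(1L, 3L, 3L),
                            x = c(0, 3, 6), y = 0, z = 0,
                            radius = c(2, 1, 1), parent = c(-1L, 1L, 2L)))
    for (i in seq_len(n))
      rows[[i + 1L]] <- data.frame(
        id = c(3L + 2L * i - 1L, 3L + 2L * i), type = 3L,
        x = c(9, 12), y = c(3 * i, 4 * i), z = 0,
        radius = radii[i], parent = c(3L, 3L + 2L * i - 1L))
    label_primary_children(morphology_from_samples(do.call(rbind, rows)))
  }
  m <- mk(c(1.0, 0.4))
  kids <- m$sections[[1]]$child_sections
  prim <- kids[vapply(m$sections[kids], `[[`, logical(1), "is_primary")]
  radii <- vapply(m$sections[kids],
                  function(s) s$radii[2], numeric(1))
  expect_equal(length(prim), 1L)
  expect_equal(radii[kids == prim], 1.0)

  m <- mk(c(0.5, 0.5))  # tie -> smallest section index
  kids <- m$sections[[1]]$child_sections
  prim <- kids[vapply(m$sections[kids], `[[`, logical(1), "is_primary")]
  expect_equal(prim, min(kids))

  m <- mk(c(0.3, 0.9, 0.6))  # trifurcation -> argmax
  kids <- m$sections[[1]]$child_sections
  prim <- kids[vapply(m$sections[kids], `[[`, logical(1), "is_primary")]
  radii <- vapply(m$sections[kids], function(s) s$radii[2], numeric(1))
  expect_equal(length(prim), 1L)
  expect_equal(radii[kids == prim], 0.9)
})

test_that("node-to-leaf paths partition sections, one path per leaf", {
  for (depth in 2:3) {
    m <- binary_tree_morph(depth)
    paths <- build_paths_node_to_leaf(m)
    expect_equal(length(paths), 2^(depth - 1L))  # leaf count
    assigned <- sort(unlist(attr(paths, "sections")))
    expect_equal(assigned, seq_along(m$sections))  # exactly once each
  }
  # unbranched: single path with soma-centroid prefix
  m <- straight_dendrite_morph()
  paths <- build_paths_node_to_leaf(m)
  expect_equal(length(paths), 1L)
  expect_equal(paths[[1]]$points[1, ], m$soma_centroid)
})

test_that("articulated build yields per-section paths and max-radius joints", {
  rows <- data.frame(id = 1:7, type = c(1L, 3L, 3L, 3L, 3L, 3L, 3L),
                     x = c(0, 3, 6, 9, 12, 9, 12),
                     y = c(0, 0, 0, 3, 6, -3, -6), z = 0,
                     radius = c(2, 0.8, 0.8, 0.5, 0.5, 0.6, 0.6),
                     parent = c(-1L, 1L, 2L, 3L, 4L, 3L, 6L))
  m <- morphology_from_samples(rows)
  art <- build_articulated(m)
  expect_equal(length(art$paths), 3L)            # one per section
  expect_equal(nrow(art$articulations), 2L)      # 1 branch + 1 root
  # branching articulation radius = largest sample at the branch point
  expect_true(any(abs(art$articulations$radius - 0.8) < 1e-12))
  # unbranched neurite: 1 path, 1 root articulation
  m2 <- straight_dendrite_morph()
  art2 <- build_articulated(m2)
  expect_equal(length(art2$paths), 1L)
  expect_equal(nrow(art2$articulations), 1L)
})

test_that("spline interpolation is exact on lines, accurate on arcs", {
  # collinear input stays collinear
  p <- path3d(rbind(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3)), c(1, 1, 1))
  out <- interpolate_path(p, use_spline = TRUE, step = 0.25)
  d <- sweep(out$points, 2, c(1, 1, 1) / sqrt(3))
  proj <- out$points - (out$points %*% rep(1 / sqrt(3), 3)) %*%
    t(rep(1 / sqrt(3), 3))
  expect_lt(max(abs(proj)), 1e-9)
  # semicircle arclength within 1%
  th <- seq(0, pi, length.out = 5)
  arc <- path3d(cbind(cos(th), sin(th), 0), rep(0.2, 5))
  chord <- sqrt(sum((c(cos(th[2]) - 1, sin(th[2])))^2))
  out <- interpolate_path(arc, use_spline = TRUE, step = chord / 10)
  L <- sum(sqrt(rowSums(diff(out$points)^2)))
  expect_lt(abs(L - pi) / pi, 0.01)
  # linear mode keeps points on the input segments
  zig <- path3d(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)), c(1, 1, 1))
  lin <- interpolate_path(zig, use_spline = FALSE, step = 0.3)
  on_seg <- apply(lin$points, 1, function(pt) {
    abs(pt[2] - (1 - abs(pt[1] - 1))) < 1e-9
  })
  expect_true(all(on_seg))
  expect_error(interpolate_path(zig, TRUE, step = 0), "positive")
})

test_that("swept tubes are closed manifolds with faithful volume", {
  p <- path3d(cbind(seq(0, 10), 0, 0), rep(1, 11))
  tb <- sweep_tube(p, 16)
  expect_equal(mesh_euler_characteristic(tb), 2L)
  rep <- check_watertight(tb)
  expect_true(rep$watertight)
  expect_lt(abs(enclosed_volume(tb) - pi * 10) / (pi * 10), 0.02)
  # minimal tube combinatorics: 2 rings of 3 + 2 apices
  tb3 <- sweep_tube(path3d(rbind(c(0, 0, 0), c(0, 0, 2)), c(1, 1)), 3)
  expect_equal(nrow(tb3$vertices), 8L)
  expect_equal(nrow(tb3$triangles), 12L)
  expect_equal(mesh_euler_characteristic(tb3), 2L)
  # 90-degree bend with radius < bend radius: no self-intersection
  bend <- rbind(cbind(seq(0, 5, 0.5), 0, 0),
                cbind(5 + 3 * sin(seq(0.1, pi / 2, length.out = 8)),
                      3 - 3 * cos(seq(0.1, pi / 2, length.out = 8)), 0),
                cbind(8, seq(3.5, 8, 0.5), 0))
  d <- neuromesh:::dedupe_polyline(bend, rep(1, nrow(bend)))
  tbb <- sweep_tube(path3d(d$points, d$radii), 12)
  expect_equal(nrow(self_intersection_pairs(tbb)), 0L)
})

test_that("area-compensated rings make straight-tube volume exact", {
  # an n-gon with area-equivalent radius has cross-section exactly pi*r^2,
  # so the prism volume equals the cylinder volume for every n
  p <- path3d(cbind(seq(0, 10), 0, 0), rep(1, 11))
  for (n in c(4L, 8L, 16L, 32L)) {
    v <- enclosed_volume(sweep_tube(p, n))
    expect_lt(abs(v - pi * 10) / (pi * 10), 1e-9)
  }
})

test_that("icosphere combinatorics and volume match closed forms", {
  s0 <- icosphere(subdivisions = 0L)
  expect_equal(nrow(s0$vertices), 12L)
  expect_equal(nrow(mesh_edges(s0)), 30L)
  expect_equal(nrow(s0$triangles), 20L)
  expect_equal(mesh_euler_characteristic(s0), 2L)
  # subdivision: V' = V + E, F' = 4F
  s1 <- icosphere(subdivisions = 1L)
  expect_equal(nrow(s1$vertices), 12L + 30L)
  expect_equal(nrow(s1$triangles), 80L)
  s4 <- icosphere(radius = 1, subdivisions = 4L)
  v <- enclosed_volume(s4)
  expect_lt(v, 4 * pi / 3)                       # inscribed: strictly below
  expect_lt((4 * pi / 3 - v) / (4 * pi / 3), 0.005)
})

test_that("joint assembly concatenates without resolving overlaps", {
  a <- icosphere(c(0, 0, 0), 1, 2)
  b <- icosphere(c(1, 0, 0), 1, 2)
  asm <- assemble_joint(list(a, b), c("soma", "arbor"))
  expect_equal(length(asm$meshes), 2L)
  joint <- neuromesh:::assembly_concatenated(asm)
  expect_equal(nrow(joint$triangles),
               nrow(a$triangles) + nrow(b$triangles))
  # overlapping members do intersect (resolved later by voxel remeshing)
  expect_gt(nrow(self_intersection_pairs(joint)), 0L)
  expect_error(assemble_joint(list()), "empty")
  # single mesh: identity
  one <- assemble_joint(list(a))
  expect_identical(neuromesh:::assembly_concatenated(one)$vertices,
                   a$vertices)
})
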