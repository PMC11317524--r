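# Watertightness certification and Verdict-style metrics.

test_that("closed cube passes; cube minus a quad reports 4 boundary edges", {
  cube <- unit_cube_mesh()
  rep <- check_watertight(cube)
  expect_true(rep$watertight)
  expect_equal(rep$component_count, 1L)
  open_cube <- triangle_mesh(cube$vertices, cube$triangles[-c(1, 2), ])
  rep2 <- check_watertight(open_cube)
  expect_false(rep2$watertight)
  expect_equal(rep2$boundary_edges, 4L)
})

test_that("welded tetrahedra expose one non-manifold edge", {
  m <- welded_tets_mesh()
  rep <- check_watertight(m, check_intersections = FALSE)
  expect_equal(rep$non_manifold_edges, 1L)
  expect_false(rep$watertight)
  # the oracle agrees
  oracle <- oracle_non_manifold(m)
  expect_equal(oracle$non_manifold_edges, 1L)
  expect_equal(sort(non_manifold_vertices(m)),
               sort(oracle$non_manifold_vertices))
})

test_that("non-manifold detectors match the adjacency oracle on fixtures", {
  fixtures <- list(unit_cube_mesh(),
                   icosphere(subdivisions = 1),
                   welded_tets_mesh(),
                   triangle_mesh(unit_cube_mesh()$vertices,
                                 unit_cube_mesh()$triangles[-5, ]))
  for (m in fixtures) {
    o <- oracle_non_manifold(m)
    ef <- neuromesh:::edge_face_counts(m)
    expect_equal(sum(ef$counts == 1L), o$boundary_edges)
    expect_equal(sum(ef$counts > 2L), o$non_manifold_edges)
    expect_equal(sort(non_manifold_vertices(m)),
                 sort(o$non_manifold_vertices))
  }
})

test_that("self-intersection detector matches the brute-force oracle", {
  base <- icosphere(subdivisions = 2)      # 320 triangles
  for (seed in c(2, 5, 9)) {
    m <- inject_defect(base, seed)
    fast <- self_intersection_pairs(m)
    slow <- oracle_self_intersections(m)
    expect_identical(fast[order(fast[, 1], fast[, 2]), , drop = FALSE],
                     slow[order(slow[, 1], slow[, 2]), , drop = FALSE],
                     info = sprintf("seed %d", seed))
  }
  # clean meshes report no pairs
  expect_equal(nrow(self_intersection_pairs(base)), 0L)
})

test_that("verdict metrics reproduce closed forms", {
  eq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                      matrix(1:3, 1))
  q <- verdict_metrics(eq)
  expect_equal(q$per_face$radius_ratio, 1.0, tolerance = 1e-12)
  expect_equal(q$per_face$edge_ratio, 1.0, tolerance = 1e-12)
  iso <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  expect_equal(verdict_metrics(iso)$per_face$edge_ratio, sqrt(2),
               tolerance = 1e-12)
  # regular tetrahedron: all dihedrals arccos(1/3)
  tet <- orient_mesh(triangle_mesh(
    rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))))
  qt <- verdict_metrics(tet)
  expect_equal(qt$per_face$min_dihedral_deg,
               rep(acos(1 / 3) * 180 / pi, 4), tolerance = 1e-9)
  expect_equal(qt$per_face$max_dihedral_deg,
               rep(acos(1 / 3) * 180 / pi, 4), tolerance = 1e-9)
  # degenerate face: infinite ratios, not an error
  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         matrix(1:3, 1))
  expect_true(is.infinite(verdict_metrics(degen)$per_face$radius_ratio))
})

test_that("enclosed volume: unit cube, icosphere, rigid invariance", {
  cube <- unit_cube_mesh()
  expect_equal(enclosed_volume(cube), 1.0, tolerance = 1e-12)
  s <- icosphere(radius = 1, subdivisions = 4)
  expect_lt(abs(enclosed_volume(s) - 4 * pi / 3) / (4 * pi / 3), 0.005)
  moved <- triangle_mesh(sweep(cube$vertices, 2, c(17, -4, 9), "+"),
                         cube$triangles)
  expect_equal(enclosed_volume(moved), 1.0, tolerance = 1e-9)
  # vertex reindexing invariance
  perm <- sample(nrow(cube$vertices))
  inv <- order(perm)
  re <- triangle_mesh(cube$vertices[perm, ],
                      matrix(inv[cube$triangles], ncol = 3))
  expect_equal(enclosed_volume(re), 1.0, tolerance = 1e-12)
  open_cube <- triangle_mesh(cube$vertices, cube$triangles[-1, ])
  expect_error(enclosed_volume(open_cube), "not closed")
})

test_that("orientation normalization fixes scrambled windings", {
  cube <- unit_cube_mesh()
  set.seed(3)
  t <- cube$triangles
  flip <- sample(nrow(t), 6)
  t[flip, ] <- t[flip, c(1, 3, 2)]
  fixed <- orient_mesh(triangle_mesh(cube$vertices, t))
  expect_equal(neuromesh:::signed_volume(fixed), 1.0, tolerance = 1e-12)
})
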