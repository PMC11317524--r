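# Solid voxelization, polygonization and fragmentation verification.

test_that("resolution rule: half the finest feature, override wins", {
  # smallest sample diameter 0.10 um, no spines, divisor 2 -> 0.05
  rows <- data.frame(id = 1:3, type = c(1L, 3L, 3L),
                     x = c(0, 3, 6), y = 0, z = 0,
                     radius = c(2, 0.05, 0.05), parent = c(-1L, 1L, 2L))
  m <- morphology_from_samples(rows)
  expect_equal(choose_resolution(m, NULL, meshing_config()), 0.05)
  # finest spine neck 0.06 -> 0.03
  tm <- list(fine = make_spine_template("thin", 2, 0.3, 0.06))
  pl <- data.frame(section = 1L, arclength = 1, azimuth_deg = 0,
                   dx = 0, dy = 0, dz = 1, px = 0, py = 0, pz = 0,
                   local_radius = 0.5, template = "fine", scale = 1)
  expect_equal(choose_resolution(m, pl, meshing_config(), tm), 0.03)
  expect_equal(choose_resolution(m, pl,
                                 meshing_config(voxel_size_override = 0.1),
                                 tm), 0.1)
})

test_that("voxelized volumes match analytic solids", {
  cube <- unit_cube_mesh()
  g <- voxelize_solid(cube, 0.1)
  expect_lt(abs(grid_volume(g) - 1) / 1, 0.10)
  sp <- icosphere(radius = 5, subdivisions = 4)
  gs <- voxelize_solid(sp, 0.1)
  va <- 4 * pi * 125 / 3
  expect_lt(abs(grid_volume(gs) - va) / va, 0.02)
})

test_that("voxelization has exact union semantics", {
  s1 <- icosphere(c(0, 0, 0), 2, 3)
  s2 <- icosphere(c(1.5, 0, 0), 2, 3)
  origin <- c(-4, -4, -4)
  dims <- c(50L, 50L, 50L)
  gA <- voxelize_solid(s1, 0.16, origin = origin, dims = dims)
  gB <- voxelize_solid(s2, 0.16, origin = origin, dims = dims)
  gAB <- voxelize_solid(assemble_joint(list(s1, s2)), 0.16,
                        origin = origin, dims = dims)
  expect_identical(gAB$occupancy, gA$occupancy | gB$occupancy)
})

test_that("memory budget produces an actionable error", {
  sp <- icosphere(radius = 5, subdivisions = 2)
  expect_error(voxelize_solid(sp, 0.01, max_voxels = 1e6), "voxel_size")
})

test_that("single-voxel polygonization is closed with bounded volume", {
  occ <- array(FALSE, c(7, 7, 7))
  occ[4, 4, 4] <- TRUE
  m <- polygonize(voxel_grid(c(0, 0, 0), 1, occ))
  expect_equal(mesh_euler_characteristic(m), 2L)
  v <- enclosed_volume(m)
  expect_gte(v, 0.3)
  expect_lte(v, 1.0)
})

test_that("polygonized sphere volume is accurate, occupancy error shrinks", {
  sp <- icosphere(radius = 5, subdivisions = 4)
  va <- 4 * pi * 125 / 3
  occ_errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    g <- voxelize_solid(sp, h)
    m <- polygonize(g)
    expect_lt(abs(enclosed_volume(m) - va) / va, 0.03)
    abs(grid_volume(g) - va)
  }, numeric(1))
  expect_true(all(diff(occ_errs) < 0))
})

test_that("a solid torus polygonizes to genus 1 (Euler characteristic 0)", {
  h <- 0.3
  xs <- seq(-4.6, 4.6, by = h)
  rho <- sqrt(outer(xs^2, rep(1, length(xs)), "+"))
  occ <- array(FALSE, c(length(xs), length(xs), length(xs)))
  for (k in seq_along(xs))
    occ[, , k] <- sqrt((sqrt(outer(xs^2, xs^2, "+")) - 3)^2 + xs[k]^2) < 1
  m <- polygonize(voxel_grid(c(-4.75, -4.75, -4.75), h, occ))
  expect_equal(mesh_euler_characteristic(m), 0L)
  expect_equal(mesh_components(m)$component_count, 1L)
})

test_that("overlapping tube and icosphere weld into one component", {
  p <- path3d(cbind(seq(0, 6), 0, 0), rep(0.5, 7))
  tube <- sweep_tube(p, 12)
  ball <- icosphere(c(6, 0, 0), 1, 2)
  g <- voxelize_solid(assemble_joint(list(tube, ball)), 0.15)
  m <- polygonize(g)
  expect_equal(mesh_components(m)$component_count, 1L)
})

test_that("fragmentation is detected when a spine loses its overlap", {
  tube <- sweep_tube(path3d(cbind(seq(0, 6), 0, 0), rep(0.5, 7)), 12)
  ball <- icosphere(c(3, 0, 2), 0.5, 2)   # 1 um gap above the tube surface
  g <- voxelize_solid(assemble_joint(list(tube, ball)), 0.2)
  m <- polygonize(g)
  rep <- verify_single_manifold(m, 0.2)
  expect_gt(rep$component_count, 1L)
  expect_lt(rep$largest_component_fraction, 1)
  # two disjoint spheres: 2 components, fraction by triangle count
  two <- polygonize(voxelize_solid(
    assemble_joint(list(icosphere(c(0, 0, 0), 1, 2),
                        icosphere(c(5, 0, 0), 1, 2))), 0.2))
  expect_equal(verify_single_manifold(two)$component_count, 2L)
  one <- largest_component(two)
  expect_equal(mesh_components(one)$component_count, 1L)
})
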