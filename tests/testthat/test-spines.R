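# Spine templates and placements.

test_that("templates are closed manifolds with the stated dimensions", {
  mu <- make_spine_template("mushroom", length = 2, head_diameter = 0.8,
                            neck_diameter = 0.2)
  expect_equal(mesh_euler_characteristic(mu$mesh), 2L)
  expect_true(check_watertight(mu$mesh)$watertight)
  expect_equal(max(mu$mesh$vertices[, 3]), 2.0)
  expect_equal(min(mu$mesh$vertices[, 3]), 0.0)
  for (tm in default_spine_templates()) {
    expect_equal(mesh_euler_characteristic(tm$mesh), 2L)
    expect_gte(tm$length, 1)
    expect_lte(tm$length, 3)
    expect_lte(tm$neck_diameter, tm$head_diameter)
    expect_gte(tm$neck_diameter, 0.06)
  }
})

test_that("stubby volume matches the hemisphere-capped cylinder closed form", {
  st <- make_spine_template("stubby", length = 1, head_diameter = 0.5,
                            neck_diameter = 0.5)
  r <- 0.25
  analytic <- pi * r^2 * (1 - r) + 2 / 3 * pi * r^3
  expect_lt(abs(enclosed_volume(st$mesh) - analytic) / analytic, 0.05)
})

test_that("volume converges under resolution refinement", {
  v16 <- enclosed_volume(make_spine_template("mushroom", 2, 0.8, 0.2,
                                             resolution = 16L)$mesh)
  v32 <- enclosed_volume(make_spine_template("mushroom", 2, 0.8, 0.2,
                                             resolution = 32L)$mesh)
  expect_lt(abs(v32 - v16) / v16, 0.01)
})

test_that("invalid template dimensions are rejected", {
  expect_error(make_spine_template("mushroom", 2, 0.4, 0.5), "neck")
  expect_error(make_spine_template("thin", 2, 0.4, 0.02), "floor")
  expect_error(make_spine_template("stubby", -1, 0.5, 0.5), "positive")
})

test_that("placement sampling is seeded, dendrite-only and Poisson-scaled", {
  m <- preprocess_morphology(straight_dendrite_morph(L = 100, n = 51))$morphology
  expect_equal(nrow(sample_spine_placements(m, density = 0)), 0L)
  p1 <- sample_spine_placements(m, density = 1, rng_seed = 42)
  p2 <- sample_spine_placements(m, density = 1, rng_seed = 42)
  expect_identical(p1, p2)                      # reproducible
  # Poisson 99% interval around 100 for ~100 um of dendrite
  expect_gt(nrow(p1), 70)
  expect_lt(nrow(p1), 130)
  # directions perpendicular to the dendrite axis (x), unit norm
  d <- as.matrix(p1[, c("dx", "dy", "dz")])
  expect_lt(max(abs(rowSums(d^2) - 1)), 1e-9)
  expect_lt(max(abs(d[, 1])), 0.3)  # tangent is ~x even after resampling
  # axon-only morphology receives no spines
  ax <- straight_dendrite_morph(type = 2L)
  expect_equal(nrow(sample_spine_placements(ax, density = 5)), 0L)
})

test_that("placement transform sinks the base 25% below the surface", {
  m <- straight_dendrite_morph(r = 0.6)
  pl <- data.frame(section = 1L, arclength = 5, azimuth_deg = 0,
                   dx = 0, dy = 0, dz = 1, px = 5, py = 0, pz = 0.6,
                   local_radius = 0.6, template = "mushroom", scale = 1)
  tm <- default_spine_templates()$mushroom
  placed <- place_spine(tm, pl, m)
  # base plane sits at surface - 0.25 * r
  expect_equal(min(placed$vertices[, 3]), 0.6 - 0.25 * 0.6,
               tolerance = 1e-9)
  expect_true(all(neuromesh:::edge_face_counts(placed)$counts == 2L))
  expect_error(place_spine(tm, transform(pl, arclength = 1e4), m),
               "arclength")
})

test_that("placed spines intersect their host tube proxy", {
  m <- preprocess_morphology(straight_dendrite_morph(r = 0.5))$morphology
  placements <- sample_spine_placements(m, density = 0.5, rng_seed = 3)
  expect_gt(nrow(placements), 0L)
  paths <- build_paths_node_to_leaf(m, meshing_config())
  tube <- sweep_tube(paths[[1]], 16)
  tm <- default_spine_templates()
  for (i in seq_len(min(3, nrow(placements)))) {
    spine <- place_spine(tm[[placements$template[i]]], placements[i, ], m)
    joint <- concatenate_meshes(list(tube, spine))
    expect_gt(nrow(self_intersection_pairs(joint)), 0L)
  }
})

test_that("spine placement CSV round trips through the sampler geometry", {
  m <- preprocess_morphology(straight_dendrite_morph(r = 0.5))$morphology
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(section_index = 1L, arclength_um = c(3, 7),
                       azimuth_deg = c(0, 120), template_id = "thin",
                       scale = 1),
            f, row.names = FALSE)
  pl <- read_spine_placements(f, m)
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$local_radius, c(0.5, 0.5))
  expect_lt(max(abs(rowSums(as.matrix(pl[, c("dx", "dy", "dz")])^2) - 1)),
            1e-9)
})
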