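# SWC reading/writing and section-graph construction.

test_that("minimal SWC parses into one neurite with a soma-anchored section", {
  m <- swc_lines_to_morph(c(
    "# minimal fixture",
    "1 1 0 0 0 2 -1",
    "2 3 4 0 0 0.5 1",
    "3 3 8 0 0 0.5 2"))
  expect_s3_class(m, "morphology")
  expect_equal(length(m$neurite_roots), 1L)
  expect_equal(length(m$sections), 1L)
  sec <- m$sections[[1]]
  # soma sample collapses to centroid/mean radius; the root section carries
  # an auxiliary lead sample at the centroid
  expect_equal(m$soma_centroid, c(0, 0, 0))
  expect_equal(m$soma_mean_radius, 2)
  expect_equal(nrow(sec$positions), 3L)
  expect_equal(sec$positions[1, ], c(0, 0, 0))
  expect_equal(sec$radii[2:3], c(0.5, 0.5))
})

test_that("forward parent references parse identically to sorted input", {
  sorted <- swc_lines_to_morph(c(
    "1 1 0 0 0 2 -1",
    "2 3 3 0 0 0.5 1",
    "3 3 6 0 0 0.4 2",
    "4 3 9 0 0 0.3 3"))
  shuffled <- swc_lines_to_morph(c(
    "4 3 9 0 0 0.3 3",
    "3 3 6 0 0 0.4 2",
    "1 1 0 0 0 2 -1",
    "2 3 3 0 0 0.5 1"))
  expect_equal(length(shuffled$sections), length(sorted$sections))
  expect_equal(shuffled$sections[[1]]$positions,
               sorted$sections[[1]]$positions)
  expect_equal(shuffled$sections[[1]]$radii, sorted$sections[[1]]$radii)
})

test_that("three-point soma dialect reduces to centroid and mean radius", {
  m <- swc_lines_to_morph(c(
    "1 1 0 0 0 3 -1",
    "2 1 0 3 0 2 1",
    "3 1 0 -3 0 4 1",
    "4 3 5 0 0 0.5 1"))
  expect_equal(m$soma_mean_radius, mean(c(3, 2, 4)))
  expect_equal(m$soma_centroid, c(0, 0, 0))
  expect_equal(length(m$sections), 1L)
})

test_that("malformed and structurally invalid files raise typed errors", {
  expect_error(swc_lines_to_morph(c("1 1 0 0 0 2 -1", "2 3 1 0 0 0.5")),
               "line")
  expect_error(swc_lines_to_morph(c("1 1 0 0 0 2 -1", "2 3 1 0 0 abc 1")),
               "line")
  expect_error(swc_lines_to_morph(c("1 3 0 0 0 2 -1", "2 3 1 0 0 0.5 1")),
               "soma")
  expect_error(swc_lines_to_morph(c("1 1 0 0 0 2 -1", "2 3 1 0 0 0.5 3",
                                    "3 3 2 0 0 0.5 2")),
               "cyclic")
  expect_error(swc_lines_to_morph(c("1 1 0 0 0 2 -1", "2 3 1 0 0 0.5 9")),
               "parent")
})

test_that("build_sections partitions samples with shared branch endpoints", {
  # Y-shape: chain of 3 then a bifurcation into two chains of 2
  m <- swc_lines_to_morph(c(
    "1 1 0 0 0 2 -1",
    "2 3 3 0 0 0.5 1",
    "3 3 6 0 0 0.5 2",
    "4 3 9 0 0 0.5 3",
    "5 3 12 2 0 0.4 4",
    "6 3 15 4 0 0.4 5",
    "7 3 12 -2 0 0.4 4",
    "8 3 15 -4 0 0.4 7"))
  expect_equal(length(m$sections), 3L)
  orders <- sort(vapply(m$sections, `[[`, integer(1), "branch_order"))
  expect_equal(orders, c(1L, 2L, 2L))
  # shared endpoints: child first sample == parent last sample exactly
  for (sec in m$sections) {
    if (is.na(sec$parent_section)) next
    parent <- m$sections[[sec$parent_section]]
    expect_identical(sec$positions[1, ],
                     parent$positions[nrow(parent$positions), ])
  }
  # segment partition: sum(samples - 1) == one segment per non-soma sample
  seg_sum <- sum(vapply(m$sections,
                        function(s) nrow(s$positions) - 1L, integer(1)))
  expect_equal(seg_sum, sum(m$samples$type != 1L))
})

test_that("full binary tree of depth d yields 2^d - 1 sections per neurite", {
  for (depth in 2:4) {
    m <- binary_tree_morph(depth)
    expect_equal(length(m$sections), 2^depth - 1L)
    leaves <- sum(vapply(m$sections,
                         function(s) length(s$child_sections) == 0L,
                         logical(1)))
    expect_equal(leaves, 2^(depth - 1L))
  }
})

test_that("unbranched chain stays one section and SWC round trips exactly", {
  lines <- c("1 1 0 0 0 2 -1",
             sprintf("%d 4 %g 0.25 0 0.5 %d", 2:11,
                     seq(3, 30, 3) + 0.1234567891234, 1:10))
  m <- swc_lines_to_morph(lines)
  expect_equal(length(m$sections), 1L)
  expect_equal(nrow(m$sections[[1]]$positions), 11L)  # aux + 10
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_identical(m2$samples$x, m$samples$x)
  expect_identical(m2$samples$radius, m$samples$radius)
  expect_identical(m2$samples$parent, m$samples$parent)
  expect_identical(m2$samples$type, m$samples$type)  # type 4 preserved
})

test_that("round trip preserves a large synthetic neuron and odd type codes", {
  m <- synthesize_morphology(rng_seed = 11, n_neurites = 5,
                             max_branch_order = 4)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_identical(m2$samples, m$samples)
  expect_equal(length(m2$sections), length(m$sections))
  # custom type code survives
  odd <- swc_lines_to_morph(c("1 1 0 0 0 2 -1", "2 7 4 0 0 0.5 1",
                              "3 7 8 0 0 0.5 2"))
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(odd, f2)
  expect_true(all(read_swc(f2)$samples$type %in% c(1L, 7L)))
})
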