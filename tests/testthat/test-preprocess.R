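# Preprocessing: connectivity verification, intra-somatic sample removal,
# adaptive resampling; structure is never modified.

test_that("soma connectivity uses the closed tolerance interval", {
  cases <- list(list(d = 1.0, r = 2.0, f = 2.0, expect = TRUE),
                list(d = 10.0, r = 2.0, f = 2.0, expect = FALSE),
                list(d = 4.0, r = 2.0, f = 2.0, expect = TRUE))  # boundary
  for (cs in cases) {
    rows <- data.frame(id = 1:3, type = c(1L, 3L, 3L),
                       x = c(0, cs$d, cs$d + 3), y = 0, z = 0,
                       radius = c(cs$r, 0.5, 0.5), parent = c(-1L, -1L, 2L))
    m <- morphology_from_samples(rows)
    rep <- verify_soma_connectivity(m, cs$f)
    expect_equal(rep$connected, cs$expect, info = sprintf("d=%g", cs$d))
  }
})

test_that("remove_inner_samples strips leading intra-somatic samples only", {
  # root section samples at distances 0.5, 1.0, 3.0, 5.0; soma radius 2
  rows <- data.frame(id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
                     x = c(0, 0.5, 1, 3, 5), y = 0, z = 0,
                     radius = c(2, 0.4, 0.4, 0.4, 0.4),
                     parent = c(-1L, 1L, 2L, 3L, 4L))
  m <- morphology_from_samples(rows)
  m2 <- remove_inner_samples(m)
  sec <- m2$sections[[1]]
  expect_equal(nrow(sec$positions), 2L)
  expect_equal(sec$positions[, 1], c(3, 5))
  # idempotent
  m3 <- remove_inner_samples(m2)
  expect_equal(m3$sections[[1]]$positions, sec$positions)
  expect_equal(attr(m3, "samples_removed"), 0L)
})

test_that("all-inside sections keep their last two samples", {
  rows <- data.frame(id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
                     x = c(0, 1, 2, 3, 4), y = 0, z = 0,
                     radius = c(10, 0.4, 0.4, 0.4, 0.4),
                     parent = c(-1L, 1L, 2L, 3L, 4L))
  m2 <- remove_inner_samples(morphology_from_samples(rows))
  expect_equal(m2$sections[[1]]$positions[, 1], c(3, 4))
})

test_that("morphology with no inner samples is unchanged", {
  m <- straight_dendrite_morph(soma_r = 1)
  before <- m$sections[[1]]$positions[-1, , drop = FALSE]  # skip aux sample
  m2 <- remove_inner_samples(m)
  # the auxiliary centroid sample is inside by construction; biological
  # samples all survive
  kept <- m2$sections[[1]]$positions
  expect_equal(kept[(nrow(kept) - nrow(before) + 1):nrow(kept), ], before)
})

test_that("adaptive resampling spaces samples at the local radius", {
  # straight section, length 10, radius 1 -> 11 samples at unit spacing
  rows <- data.frame(id = 1:3, type = c(1L, 3L, 3L),
                     x = c(-3, 0, 10), y = 0, z = 0,
                     radius = c(0.2, 1, 1), parent = c(-1L, -1L, 2L))
  m <- morphology_from_samples(rows)
  sec <- m$sections[[1]]
  out <- resample_adaptive(sec)
  expect_equal(nrow(out$positions), 11L)
  spacing <- diff(out$positions[, 1])
  expect_true(all(abs(spacing - 1) < 1e-9))
  expect_identical(out$positions[1, ], sec$positions[1, ])
  expect_identical(out$positions[11, ], sec$positions[nrow(sec$positions), ])
  # re-application is near-idempotent
  out2 <- resample_adaptive(out)
  expect_lte(abs(nrow(out2$positions) - nrow(out$positions)), 1L)
})

test_that("resampling shortens a jittered polyline (smoothing)", {
  set.seed(1)
  n <- 101
  xs <- seq(0, 20, length.out = n)
  jit <- 0.1 * sin(seq(0, 40 * pi, length.out = n)) +
    0.05 * stats::rnorm(n)
  sec <- neuromesh:::new_section(1L, 3L, rep(0L, n),
                                 cbind(xs, jit, 0), rep(1, n))
  out <- resample_adaptive(sec)
  len <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  expect_lt(len(out$positions), len(sec$positions))
})

test_that("preprocessing preserves structure and endpoints", {
  m <- synthesize_morphology(rng_seed = 4, n_neurites = 3,
                             max_branch_order = 3)
  pre <- preprocess_morphology(m)
  m2 <- pre$morphology
  expect_equal(length(m2$sections), length(m$sections))
  for (i in seq_along(m$sections)) {
    expect_identical(m2$sections[[i]]$parent_section,
                     m$sections[[i]]$parent_section)
    expect_identical(m2$sections[[i]]$child_sections,
                     m$sections[[i]]$child_sections)
    expect_identical(m2$sections[[i]]$branch_order,
                     m$sections[[i]]$branch_order)
    n2 <- nrow(m2$sections[[i]]$positions)
    expect_identical(m2$sections[[i]]$positions[n2, ],
                     m$sections[[i]]$positions[nrow(m$sections[[i]]$positions), ])
  }
  rep <- pre$report
  expect_equal(rep$samples_after,
               rep$samples_before - rep$samples_removed + rep$samples_added)
})
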