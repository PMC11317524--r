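# Synthetic morphology generator: seeded, branched, spiny-capable test
# neurons with tapering radii. Stands in for circuit-sampled cells so the
# whole pipeline is testable without any download.

unit_vector <- function(v) v / sqrt(sum(v^2))

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# rotate `axis` by a random angle <= max_angle (radians)
perturb_direction <- function(axis, max_angle) {
  a <- stats::runif(1, 0, max_angle)
  u <- random_unit_vector()
  u <- u - sum(u * axis) * axis
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) return(axis)
  u <- u / nu
  unit_vector(cos(a) * axis + sin(a) * u)
}

#' Generate a synthetic neuronal morphology
#'
#' Random binary-branching neurites with radii tapering toward the leaves
#' (floored at `radius_floor`), a soma radius drawn in 3-6 um, and sample
#' spacing of about 1-2 um with angular wander. Deterministic per seed; the
#' result satisfies every morphology invariant (unique ids, positive radii,
#' acyclic parents).
#'
#' @param rng_seed integer seed.
#' @param n_neurites number of neurites (first is an axon, rest dendrites).
#' @param max_branch_order maximum branch order (1 = unbranched).
#' @param taper radius ratio applied along each section (1 = no taper).
#' @param spatial_extent approximate diameter of the arbor, micrometres.
#' @param trunk_radius initial neurite radius, micrometres.
#' @param radius_floor smallest admissible radius, micrometres.
#' @param branch_prob probability a non-terminal section bifurcates.
#' @return a `morphology`.
#' @export
synthesize_morphology <- function(rng_seed = 1L, n_neurites = 4L,
                                  max_branch_order = 3L, taper = 0.75,
                                  spatial_extent = 40, trunk_radius = 0.9,
                                  radius_floor = 0.05, branch_prob = 0.8) {
  stopifnot(n_neurites >= 1L, max_branch_order >= 1L, taper > 0,
            spatial_extent > 0, trunk_radius > 0)
  withr::with_seed(rng_seed, {
    soma_radius <- stats::runif(1, 3, 6)
    rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                            radius = soma_radius, parent = -1L))
    next_id <- 2L
    section_len <- (spatial_extent / 2 - soma_radius) /
      max(1L, max_branch_order)
    section_len <- max(section_len, 2)
    step_len <- max(1, section_len / 5)

    grow_section <- function(start_pos, direction, r_start, order,
                             parent_id, type_code) {
      n_steps <- max(2L, as.integer(round(section_len / step_len)))
      r_end <- max(radius_floor, r_start * taper)
      pos <- start_pos
      dir <- direction
      prev <- parent_id
      last_pos <- pos
      for (s in seq_len(n_steps)) {
        dir <- perturb_direction(dir, 0.25)
        pos <- pos + dir * step_len * stats::runif(1, 0.8, 1.2)
        r_here <- r_start + (r_end - r_start) * s / n_steps
        rows[[length(rows) + 1L]] <<-
          data.frame(id = next_id, type = type_code, x = pos[1], y = pos[2],
                     z = pos[3], radius = max(radius_floor, r_here),
                     parent = prev)
        prev <- next_id
        next_id <<- next_id + 1L
        last_pos <- pos
      }
      if (order < max_branch_order &&
          stats::runif(1) < branch_prob) {
        for (k in 1:2) {
          child_dir <- perturb_direction(dir, 0.9)
          grow_section(last_pos, child_dir, r_end, order + 1L, prev,
                       type_code)
        }
      }
      invisible(NULL)
    }

    for (ni in seq_len(n_neurites)) {
      type_code <- if (ni == 1L && n_neurites > 1L) 2L else 3L
      direction <- unit_vector(c(
        cos(2 * pi * ni / n_neurites) * stats::runif(1, 0.7, 1),
        sin(2 * pi * ni / n_neurites) * stats::runif(1, 0.7, 1),
        stats::runif(1, -0.5, 0.5)))
      start <- direction * soma_radius * 1.05
      root_radius <- trunk_radius * stats::runif(1, 0.85, 1.15)
      rows[[length(rows) + 1L]] <-
        data.frame(id = next_id, type = type_code, x = start[1],
                   y = start[2], z = start[3],
                   radius = max(radius_floor, root_radius), parent = 1L)
      prev <- next_id
      next_id <- next_id + 1L
      grow_section(start, direction, root_radius, 1L, prev, type_code)
    }
    morphology_from_samples(do.call(rbind, rows))
  })
}
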