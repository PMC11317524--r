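# Soft-body somatic profile: an icosphere grown toward the initial segments
# of the connected arbors under damped mass-spring dynamics. The surface
# carries three force systems:
#   * edge springs (Hooke, stiffness k) preserving local shape,
#   * goal springs (stiffness k) tying non-pulled vertices to their rest
#     positions - the soft-body "shape memory",
#   * pull springs (fixed k_pull) driving each arbor's vertex patch toward
#     the arbor root sample.
# With edge and goal forces proportional to the one user-facing stiffness
# and the pull force fixed, higher stiffness monotonically reduces the
# deformation of non-pulled vertices (the rounder-soma behaviour), while the
# pulled patches still reach the arbor stubs.

SOMA_PULL_STRENGTH <- 1.0
SOMA_DAMPING <- 0.9

#' Initialize the somatic spring network
#'
#' Builds a subdivision-3 icosphere of radius
#' `soma_initial_radius_factor * soma_mean_radius` at the soma centroid and
#' assigns one pull target per connected arbor: the icosphere vertices inside
#' the cone subtended by the arbor's initial cross-section (half-angle
#' `atan(root radius / distance)`), targeted at the root sample. Each vertex
#' belongs to at most one target (nearest cone axis wins); an arbor whose
#' cone captures no free vertex gets its angularly-nearest free vertex.
#'
#' @param morphology a preprocessed `morphology`.
#' @param config a `meshing_config`.
#' @param connectivity optional result of [verify_soma_connectivity()].
#' @return an object of class `spring_network`.
#' @export
init_soma_network <- function(morphology, config = meshing_config(),
                              connectivity = NULL) {
  if (is.null(connectivity))
    connectivity <- verify_soma_connectivity(morphology)
  r0 <- config$soma_initial_radius_factor * morphology$soma_mean_radius
  ico <- icosphere(morphology$soma_centroid, r0, subdivisions = 3L)
  v <- ico$vertices
  centroid <- morphology$soma_centroid
  dirs <- sweep(v, 2, centroid, "-")
  dirs <- dirs / sqrt(rowSums(dirs^2))

  connected_roots <- connectivity$neurite[connectivity$connected]
  assignment <- rep(NA_integer_, nrow(v))
  angle_to <- rep(Inf, nrow(v))
  targets <- list()
  for (t_idx in seq_along(connected_roots)) {
    root <- neurite_root_sample(morphology$sections[[connected_roots[t_idx]]])
    axis <- root$position - centroid
    dist <- sqrt(sum(axis^2))
    if (dist == 0) next
    axis <- axis / dist
    half_angle <- atan(root$radius / dist)
    ang <- acos(pmin(1, pmax(-1, dirs %*% axis)))
    in_cone <- which(ang <= half_angle)
    better <- in_cone[ang[in_cone] < angle_to[in_cone]]
    assignment[better] <- t_idx
    angle_to[better] <- ang[better]
    targets[[t_idx]] <- list(target = root$position, radius = root$radius,
                             axis_angle = ang)
  }
  # guarantee every target owns at least one vertex
  for (t_idx in seq_along(targets)) {
    if (is.null(targets[[t_idx]])) next
    if (!any(assignment == t_idx, na.rm = TRUE)) {
      free <- which(is.na(assignment))
      if (length(free)) {
        pick <- free[which.min(targets[[t_idx]]$axis_angle[free])]
        assignment[pick] <- t_idx
      }
    }
  }
  pull_targets <- list()
  for (t_idx in seq_along(targets)) {
    if (is.null(targets[[t_idx]])) next
    verts <- which(assignment == t_idx)
    if (length(verts) == 0L) next
    pull_targets[[length(pull_targets) + 1L]] <-
      list(vertices = verts, target = targets[[t_idx]]$target,
           radius = targets[[t_idx]]$radius)
  }

  edges <- mesh_edges(ico)
  rest <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                        v[edges[, 2], , drop = FALSE])^2))
  structure(list(positions = v,
                 velocities = matrix(0, nrow(v), 3),
                 triangles = ico$triangles,
                 edges = edges,
                 rest_length = rest,
                 rest_positions = v,
                 stiffness = config$soma_stiffness,
                 damping = SOMA_DAMPING,
                 pull_targets = pull_targets),
            class = "spring_network")
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("<spring_network: %d vertices, %d springs, %d pull targets>\n",
              nrow(x$positions), nrow(x$edges), length(x$pull_targets)))
  invisible(x)
}

#' Integrate the soma soft body
#'
#' Damped explicit Euler. With `steps = 0` or no pull targets the input
#' surface is returned unchanged (the network starts at rest). Fully
#' deterministic: no randomness enters the integrator.
#'
#' @param network a `spring_network`.
#' @param steps integer >= 0.
#' @param dt time step (default 0.1).
#' @param convergence_tol optional; stop early once the largest per-step
#'   vertex displacement falls below this value (micrometres).
#' @return the final surface as a `triangle_mesh`.
#' @export
simulate_soma <- function(network, steps = 100L, dt = 0.1,
                          convergence_tol = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (steps < 0) stop("steps must be >= 0")
  x <- network$positions
  vel <- network$velocities
  k <- network$stiffness
  e1 <- network$edges[, 1]
  e2 <- network$edges[, 2]
  rest <- network$rest_length
  pulled <- unlist(lapply(network$pull_targets, `[[`, "vertices"))
  goal_pos <- network$rest_positions
  is_pulled <- rep(FALSE, nrow(x))
  is_pulled[pulled] <- TRUE
  n <- nrow(x)
  step_count <- 0L
  while (step_count < steps) {
    d <- x[e2, , drop = FALSE] - x[e1, , drop = FALSE]
    len <- sqrt(rowSums(d * d))
    len[len == 0] <- 1e-12
    # Hooke along the edge: positive magnitude = attraction (overstretched)
    fmag <- k * (len - rest) / len
    fe <- d * fmag
    f <- matrix(0, n, 3)
    s1 <- rowsum(fe, e1)
    f[as.integer(rownames(s1)), ] <- f[as.integer(rownames(s1)), ] + s1
    s2 <- rowsum(fe, e2)
    f[as.integer(rownames(s2)), ] <- f[as.integer(rownames(s2)), ] - s2
    # goal springs for non-pulled vertices
    f[!is_pulled, ] <- f[!is_pulled, ] +
      k * (goal_pos[!is_pulled, , drop = FALSE] -
           x[!is_pulled, , drop = FALSE])
    # pull springs
    for (pt in network$pull_targets) {
      idx <- pt$vertices
      f[idx, ] <- f[idx, ] +
        SOMA_PULL_STRENGTH *
        (matrix(pt$target, length(idx), 3, byrow = TRUE) -
         x[idx, , drop = FALSE])
    }
    vel <- (vel + dt * f) * network$damping
    dxy <- dt * vel
    x <- x + dxy
    if (!all(is.finite(x)))
      stop("soma simulation diverged: non-finite coordinates; ",
           "reduce dt or stiffness")
    step_count <- step_count + 1L
    if (!is.null(convergence_tol) &&
        max(abs(dxy)) < convergence_tol) break
  }
  triangle_mesh(x, network$triangles, validate = FALSE)
}
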