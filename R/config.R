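#' Pipeline configuration
#'
#' Collects every knob of the meshing pipeline. Defaults follow the package's
#' stated conventions (see the methods vignette): node-to-leaf proxy arbors,
#' 16-sided cross-sectional rings, soft-body soma grown from half the mean
#' somatic radius over 100 steps, and a voxel size of half the finest
#' morphological feature (>= 2 voxels across the thinnest structure).
#'
#' @param arbor_algorithm `"node_to_leaf"` or `"articulated"`.
#' @param ring_sides integer >= 3, vertices per tube cross-section ring.
#' @param use_spline resample paths on an interpolating natural cubic spline.
#' @param soma_initial_radius_factor initial icosphere radius as a fraction of
#'   the somatic mean radius.
#' @param soma_stiffness spring stiffness in (0, 1].
#' @param soma_steps integer, soft-body integration steps.
#' @param spine_density spines per micrometre of dendritic arclength.
#' @param voxel_size_override optional voxel size in micrometres; when set the
#'   feature-derived rule is bypassed.
#' @param voxel_feature_divisor >= 2; voxel size = finest feature / divisor.
#' @param optimization_target_ratio target triangle fraction for coarsening,
#'   in (0, 1].
#' @param smoothing_iterations integer, volume-compensated smoothing passes.
#' @param repair_max_iterations integer, watertightness repair-loop bound.
#' @param rng_seed integer seed controlling all randomness in a run.
#' @return an object of class `meshing_config`.
#' @export
meshing_config <- function(arbor_algorithm = c("node_to_leaf", "articulated"),
                           ring_sides = 16L,
                           use_spline = TRUE,
                           soma_initial_radius_factor = 0.5,
                           soma_stiffness = 0.1,
                           soma_steps = 100L,
                           spine_density = 1,
                           voxel_size_override = NULL,
                           voxel_feature_divisor = 2,
                           optimization_target_ratio = 0.6,
                           smoothing_iterations = 3L,
                           repair_max_iterations = 20L,
                           rng_seed = 1L) {
  arbor_algorithm <- match.arg(arbor_algorithm)
  ring_sides <- as.integer(ring_sides)
  if (ring_sides < 3L) stop("ring_sides must be >= 3")
  if (voxel_feature_divisor < 2) stop("voxel_feature_divisor must be >= 2")
  scalars <- c(soma_initial_radius_factor = soma_initial_radius_factor,
               soma_stiffness = soma_stiffness,
               voxel_feature_divisor = voxel_feature_divisor,
               optimization_target_ratio = optimization_target_ratio)
  if (any(scalars <= 0))
    stop("all scalar knobs must be strictly positive: ",
         paste(names(scalars)[scalars <= 0], collapse = ", "))
  if (soma_stiffness > 1) stop("soma_stiffness must lie in (0, 1]")
  if (optimization_target_ratio > 1)
    stop("optimization_target_ratio must lie in (0, 1]")
  if (!is.null(voxel_size_override) && voxel_size_override <= 0)
    stop("voxel_size_override must be positive")
  if (spine_density < 0) stop("spine_density must be >= 0")
  structure(list(
    arbor_algorithm = arbor_algorithm,
    ring_sides = ring_sides,
    use_spline = isTRUE(use_spline),
    soma_initial_radius_factor = soma_initial_radius_factor,
    soma_stiffness = soma_stiffness,
    soma_steps = as.integer(soma_steps),
    spine_density = spine_density,
    voxel_size_override = voxel_size_override,
    voxel_feature_divisor = voxel_feature_divisor,
    optimization_target_ratio = optimization_target_ratio,
    smoothing_iterations = as.integer(smoothing_iterations),
    repair_max_iterations = as.integer(repair_max_iterations),
    rng_seed = as.integer(rng_seed)
  ), class = "meshing_config")
}

#' @export
print.meshing_config <- function(x, ...) {
  cat("<meshing_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

as_meshing_config <- function(x) {
  if (inherits(x, "meshing_config")) return(x)
  if (is.list(x)) return(do.call(meshing_config, x))
  stop("cannot interpret object as meshing_config")
}
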