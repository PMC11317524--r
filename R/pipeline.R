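# End-to-end pipeline: SWC skeleton -> preprocessing -> proxy meshes (soma,
# arbors, spines) -> joint assembly -> solid voxelization -> polygonization
# -> fragmentation check -> optimization + repair -> watertight export.

#' Build the joint proxy assembly for a morphology
#'
#' @param morphology a preprocessed `morphology`.
#' @param config a `meshing_config`.
#' @param connectivity result of [verify_soma_connectivity()].
#' @param placements optional `spine_placements` (NULL = sample per config).
#' @param templates spine template list.
#' @return list: `assembly` (`proxy_assembly`), `placements`.
#' @export
build_proxies <- function(morphology, config = meshing_config(),
                          connectivity = NULL, placements = NULL,
                          templates = default_spine_templates()) {
  if (is.null(connectivity))
    connectivity <- verify_soma_connectivity(morphology)
  meshes <- list()
  tags <- character()

  net <- init_soma_network(morphology, config, connectivity)
  soma <- simulate_soma(net, steps = config$soma_steps)
  meshes[[1]] <- soma
  tags[1] <- "soma"

  if (config$arbor_algorithm == "node_to_leaf") {
    paths <- build_paths_node_to_leaf(morphology, config)
    tubes <- paths_to_tubes(paths, config$ring_sides)
    meshes <- c(meshes, tubes)
    tags <- c(tags, rep("arbor", length(tubes)))
  } else {
    art <- build_articulated(morphology, config)
    tubes <- paths_to_tubes(art$paths, config$ring_sides)
    meshes <- c(meshes, tubes)
    tags <- c(tags, rep("arbor", length(tubes)))
    if (nrow(art$articulations)) {
      spheres <- lapply(seq_len(nrow(art$articulations)), function(i)
        icosphere(unlist(art$articulations[i, c("x", "y", "z")]),
                  art$articulations$radius[i], subdivisions = 2L))
      meshes <- c(meshes, spheres)
      tags <- c(tags, rep("articulation", length(spheres)))
    }
  }

  if (is.null(placements))
    placements <- sample_spine_placements(morphology, config$spine_density,
                                          rng_seed = config$rng_seed,
                                          templates = templates)
  if (nrow(placements)) {
    spines <- place_all_spines(placements, templates, morphology)
    meshes <- c(meshes, spines)
    tags <- c(tags, rep("spine", length(spines)))
  }
  list(assembly = assemble_joint(meshes, tags), placements = placements)
}

#' Run the complete meshing pipeline
#'
#' Executes read -> preprocess -> soma -> arbors -> spines -> joint assembly
#' -> resolution rule -> solid voxelization -> polygonization -> single-
#' manifold verification -> optimization/repair -> final certification ->
#' export. Deterministic given `config$rng_seed`.
#'
#' @param swc_path input SWC file, or a `morphology` object.
#' @param config a `meshing_config`.
#' @param out_path output mesh path (`NULL` = no export).
#' @param format export format, see [export_mesh()].
#' @param spine_csv optional spine placement CSV (see
#'   [read_spine_placements()]).
#' @param templates spine template list.
#' @param allow_fragments keep the largest component instead of failing
#'   when polygonization yields several components.
#' @param max_voxels voxelization memory budget.
#' @return an object of class `pipeline_result`.
#' @export
run_pipeline <- function(swc_path, config = meshing_config(),
                         out_path = NULL, format = "stl_binary",
                         spine_csv = NULL,
                         templates = default_spine_templates(),
                         allow_fragments = FALSE, max_voxels = 4e8) {
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  morph <- if (inherits(swc_path, "morphology")) swc_path else
    tick("read", read_swc(swc_path))
  pre <- tick("preprocess", preprocess_morphology(morph))
  morph <- pre$morphology
  connectivity <- pre$report$arbors_connected

  placements <- if (!is.null(spine_csv))
    read_spine_placements(spine_csv, morph) else NULL
  proxies <- tick("proxies",
                  build_proxies(morph, config, connectivity, placements,
                                templates))
  voxel_size <- choose_resolution(morph, proxies$placements, config,
                                  templates)
  grid <- tick("voxelize",
               voxelize_solid(proxies$assembly, voxel_size,
                              max_voxels = max_voxels))
  raw_mesh <- tick("polygonize", polygonize(grid))
  remesh_report <- verify_single_manifold(
    raw_mesh, voxel_size, attr(grid, "report")$occupied)
  if (remesh_report$component_count > 1L) {
    if (!allow_fragments) {
      cond <- structure(class = c("neuromesh_fragmentation", "error",
                                  "condition"),
                        list(message = sprintf(
                               paste0("fragmented remesh: %d components at ",
                                      "voxel size %.4g um (finest feature ",
                                      "under-resolved); largest holds ",
                                      "%.1f%% of triangles"),
                               remesh_report$component_count, voxel_size,
                               100 * remesh_report$largest_component_fraction),
                             call = NULL, report = remesh_report))
      stop(cond)
    }
    raw_mesh <- largest_component(raw_mesh)
  }
  quality_pre <- verdict_metrics(raw_mesh)
  opt <- tick("optimize", optimize_mesh(raw_mesh, config))
  final_mesh <- opt$mesh
  final_report <- tick("check", check_watertight(final_mesh))
  quality_post <- verdict_metrics(final_mesh)
  if (!is.null(out_path))
    tick("export", export_mesh(final_mesh, out_path, format))
  structure(list(mesh = final_mesh,
                 mesh_path = out_path,
                 watertight_report = final_report,
                 quality_pre = quality_pre,
                 quality_post = quality_post,
                 preprocess_report = pre$report,
                 remesh_report = remesh_report,
                 optimization_trace = opt$trace,
                 voxel_size = voxel_size,
                 config = config,
                 timings = unlist(timings)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  watertight: %s | components: %d | voxel %.4g um\n",
              x$watertight_report$watertight,
              x$watertight_report$component_count, x$voxel_size))
  cat(sprintf("  triangles: %d -> %d | volume %.4g -> %.4g um^3\n",
              x$quality_pre$triangle_count, x$quality_post$triangle_count,
              x$quality_pre$enclosed_volume, x$quality_post$enclosed_volume))
  cat("  timings (s):",
      paste(sprintf("%s %.1f", names(x$timings), x$timings),
            collapse = ", "), "\n")
  invisible(x)
}
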