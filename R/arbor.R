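# Proxy arbor generation: overlapping, individually-closed tube meshes for
# all neurites via either node-to-leaf paths (primary-child continuations)
# or articulated sections (independent per-section tubes joined by
# icospheres at branching points).

#' Label primary children across a morphology
#'
#' At every branching point exactly one child section is primary: the child
#' with the largest first-segment radius, ties broken by smallest section
#' index. Root sections are primary.
#'
#' @param morphology a `morphology`.
#' @return the `morphology` with `is_primary` set on every section.
#' @export
label_primary_children <- function(morphology) {
  secs <- morphology$sections
  for (i in seq_along(secs)) secs[[i]]$is_primary <- FALSE
  for (r in morphology$neurite_roots) secs[[r]]$is_primary <- TRUE
  # first-segment radius: the section's own first sample (index 2; index 1
  # is the duplicated shared endpoint)
  own_radius <- function(sec) sec$radii[min(2L, length(sec$radii))]
  for (i in seq_along(secs)) {
    kids <- secs[[i]]$child_sections
    if (length(kids) == 0L) next
    radii <- vapply(secs[kids], own_radius, numeric(1))
    best <- kids[radii == max(radii)]
    primary <- min(best)                       # deterministic tie-break
    secs[[primary]]$is_primary <- TRUE
  }
  morphology$sections <- secs
  morphology
}

# sections of one neurite in DFS order
neurite_section_indices <- function(morphology, root) {
  out <- integer()
  stack <- root
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, rev(morphology$sections[[i]]$child_sections))
  }
  out
}

section_polyline <- function(sec, drop_first = FALSE, drop_aux = FALSE) {
  keep <- seq_len(nrow(sec$positions))
  if (drop_first || (drop_aux && sec$sample_ids[1] == 0L))
    keep <- keep[-1]
  list(points = sec$positions[keep, , drop = FALSE], radii = sec$radii[keep])
}

default_path_step <- function(radii) min(min(radii), 1)

maybe_interpolate <- function(path, config) {
  if (is.null(config)) return(path)
  interpolate_path(path, use_spline = config$use_spline,
                   step = default_path_step(path$radii))
}

#' Build node-to-leaf proxy paths
#'
#' Depth-first construction of one path per leaf section: each path follows
#' primary-child continuations, every section appears in exactly one path,
#' and the root-containing path is prepended with an auxiliary point at the
#' soma centroid (radius of the root sample) so the arbor welds into the
#' soma during voxel remeshing.
#'
#' @param morphology a `morphology` (primary labels are recomputed).
#' @param config optional `meshing_config`; when given, paths are resampled
#'   (spline or linear per `use_spline`) at step `min(local radius, 1)` um.
#' @return list of `path3d`, with attribute `"sections"` listing the section
#'   indices of each path.
#' @export
build_paths_node_to_leaf <- function(morphology, config = NULL) {
  morphology <- label_primary_children(morphology)
  secs <- morphology$sections
  paths <- list()
  path_sections <- list()

  walk <- function(start, points, radii) {
    i <- start
    section_ids <- integer(0)
    repeat {
      pl <- section_polyline(secs[[i]], drop_first = length(section_ids) > 0L,
                             drop_aux = FALSE)
      points <- rbind(points, pl$points)
      radii <- c(radii, pl$radii)
      section_ids <- c(section_ids, i)
      kids <- secs[[i]]$child_sections
      if (length(kids) == 0L) break
      primary <- kids[vapply(secs[kids], function(s) isTRUE(s$is_primary),
                             logical(1))][1]
      for (k in kids)
        if (k != primary)
          walk(k, matrix(numeric(0), ncol = 3), numeric(0))
      i <- primary
    }
    d <- dedupe_polyline(points, radii)
    paths[[length(paths) + 1L]] <<- path3d(d$points, d$radii)
    path_sections[[length(paths)]] <<- section_ids
    invisible(NULL)
  }

  for (r in morphology$neurite_roots) {
    root_sec <- secs[[r]]
    # auxiliary soma-centroid point (already present when build_sections
    # added it; otherwise prepend)
    if (root_sec$sample_ids[1] == 0L) {
      start_points <- matrix(numeric(0), ncol = 3)
      start_radii <- numeric(0)
    } else {
      start_points <- matrix(morphology$soma_centroid, ncol = 3)
      start_radii <- root_sec$radii[1]
    }
    walk(r, start_points, start_radii)
  }
  paths <- lapply(paths, maybe_interpolate, config = config)
  attr(paths, "sections") <- path_sections
  paths
}

#' Build articulated-section proxies
#'
#' One independent path per section plus articulation spheres: one per
#' branching point with radius equal to the largest sample meeting there,
#' and one at each neurite root.
#'
#' @param morphology a `morphology`.
#' @param config optional `meshing_config` (controls path resampling).
#' @return list with `paths` (list of `path3d`) and `articulations`
#'   (data.frame x, y, z, radius).
#' @export
build_articulated <- function(morphology, config = NULL) {
  secs <- morphology$sections
  paths <- list()
  arts <- list()
  own_radius <- function(sec) sec$radii[min(2L, length(sec$radii))]
  for (r in morphology$neurite_roots) {
    for (i in neurite_section_indices(morphology, r)) {
      sec <- secs[[i]]
      pl <- section_polyline(sec, drop_aux = TRUE)
      d <- dedupe_polyline(pl$points, pl$radii)
      if (nrow(d$points) >= 2L)
        paths[[length(paths) + 1L]] <- path3d(d$points, d$radii)
      kids <- sec$child_sections
      if (length(kids) > 0L) {
        tail_i <- nrow(sec$positions)
        r_art <- max(sec$radii[tail_i],
                     vapply(secs[kids], own_radius, numeric(1)))
        arts[[length(arts) + 1L]] <-
          c(sec$positions[tail_i, ], r_art)
      }
    }
    root_pl <- section_polyline(secs[[r]], drop_aux = TRUE)
    arts[[length(arts) + 1L]] <- c(root_pl$points[1, ], root_pl$radii[1])
  }
  paths <- lapply(paths, maybe_interpolate, config = config)
  art_df <- if (length(arts)) {
    m <- do.call(rbind, arts)
    data.frame(x = m[, 1], y = m[, 2], z = m[, 3], radius = m[, 4])
  } else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    radius = numeric(0))
  list(paths = paths, articulations = art_df)
}

#' Assemble proxy meshes into a joint (overlapping) object
#'
#' Pure concatenation with provenance tags: no boolean union and no
#' intersection removal. Mutual overlaps are intended; the voxel remesher
#' resolves them.
#'
#' @param meshes list of closed `triangle_mesh` objects.
#' @param tags character vector of provenance tags (recycled if length 1).
#' @return an object of class `proxy_assembly`.
#' @export
assemble_joint <- function(meshes, tags = "proxy") {
  if (length(meshes) == 0L) stop("assemble_joint: empty mesh list")
  tags <- rep_len(as.character(tags), length(meshes))
  structure(list(meshes = meshes, tags = tags), class = "proxy_assembly")
}

#' @export
print.proxy_assembly <- function(x, ...) {
  nt <- vapply(x$meshes, function(m) nrow(m$triangles), integer(1))
  cat(sprintf("<proxy_assembly: %d meshes, %d triangles total>\n",
              length(x$meshes), sum(nt)))
  for (tag in unique(x$tags))
    cat(sprintf("  %-12s x%d\n", tag, sum(x$tags == tag)))
  invisible(x)
}

assembly_concatenated <- function(assembly) {
  concatenate_meshes(assembly$meshes)
}

#' Export a proxy assembly as a multi-group OBJ (debugging aid)
#'
#' @param assembly a `proxy_assembly`.
#' @param path output path.
#' @export
export_assembly_obj <- function(assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  off <- 0L
  for (i in seq_along(assembly$meshes)) {
    m <- assembly$meshes[[i]]
    writeLines(sprintf("g %s_%03d", assembly$tags[i], i), con)
    writeLines(sprintf("v %.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", m$triangles[, 1] + off,
                       m$triangles[, 2] + off, m$triangles[, 3] + off), con)
    off <- off + nrow(m$vertices)
  }
  invisible(path)
}

# tube meshes for a list of paths
paths_to_tubes <- function(paths, ring_sides = 16L) {
  lapply(paths, sweep_tube, ring_sides = ring_sides)
}
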