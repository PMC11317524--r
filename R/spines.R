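# Parametric dendritic spine templates (head-sphere + neck composites in a
# canonical frame: base disc at the origin, axis +Z, height = length) and
# seeded placement along dendritic sections. These stand in for EM-derived
# spine meshes: the meshing algorithm only requires closed spine meshes that
# overlap their host dendrite.

SPINE_NECK_FLOOR <- 0.06  # um, finest admissible neck cross-section

#' Construct a parametric spine template
#'
#' The template is a surface of revolution: a cylindrical neck of diameter
#' `neck_diameter` capped by a spherical head of diameter `head_diameter`
#' whose top touches `z = length`. `stubby` spines have head = neck
#' (a hemisphere-capped cylinder), `mushroom` spines require a head wider
#' than the neck, `thin` spines a slender neck. Radial extents are
#' area-compensated (see the vignette), so composite volumes track the
#' analytic solids.
#'
#' @param shape_class `"stubby"`, `"mushroom"` or `"thin"`.
#' @param length total height, micrometres (default sensible per class).
#' @param head_diameter widest extent.
#' @param neck_diameter neck cross-section; floored at 0.06 um.
#' @param resolution ring sides (and head arc steps), default 16.
#' @return an object of class `spine_template`.
#' @export
make_spine_template <- function(shape_class = c("mushroom", "stubby", "thin"),
                                length = 2, head_diameter = 0.8,
                                neck_diameter = 0.2, resolution = 16L) {
  shape_class <- match.arg(shape_class)
  if (length <= 0 || head_diameter <= 0 || neck_diameter <= 0)
    stop("spine dimensions must be positive")
  if (neck_diameter < SPINE_NECK_FLOOR)
    stop("neck_diameter below the ", SPINE_NECK_FLOOR,
         " um resolvable floor")
  if (shape_class == "mushroom" && neck_diameter >= head_diameter)
    stop("mushroom spine requires neck_diameter < head_diameter")
  if (neck_diameter > head_diameter)
    stop("neck_diameter must be <= head_diameter")
  if (head_diameter > length)
    stop("head_diameter must not exceed length")
  r_h <- head_diameter / 2
  r_n <- neck_diameter / 2
  z_c <- length - r_h                     # head sphere center
  # junction where the sphere profile reaches the neck radius
  z_j <- z_c - sqrt(max(0, r_h^2 - r_n^2))
  n_arc <- max(6L, as.integer(resolution))
  phi0 <- asin(pmin(1, pmax(-1, (z_j - z_c) / r_h)))
  phi <- seq(phi0, pi / 2, length.out = n_arc)
  z_head <- z_c + r_h * sin(phi)
  r_head <- r_h * cos(phi)
  keep <- r_head > 1e-9
  z <- c(0, z_j, z_head[keep], length)
  r <- c(r_n, r_n, r_head[keep], 0)
  d <- !duplicated(signif(z, 12))
  mesh <- lathe_mesh(z[d], r[d], sides = as.integer(resolution))
  structure(list(mesh = mesh, length = length,
                 head_diameter = head_diameter,
                 neck_diameter = neck_diameter,
                 shape_class = shape_class),
            class = "spine_template")
}

#' @export
print.spine_template <- function(x, ...) {
  cat(sprintf("<spine_template %s: L=%.2f head=%.2f neck=%.2f um, %d tris>\n",
              x$shape_class, x$length, x$head_diameter, x$neck_diameter,
              nrow(x$mesh$triangles)))
  invisible(x)
}

#' Default spine template set
#'
#' One template per shape class with dimensions inside the biological
#' envelope (length 1-3 um, necks 0.06-0.8 um).
#' @param resolution ring sides.
#' @return named list of `spine_template`.
#' @export
default_spine_templates <- function(resolution = 16L) {
  list(mushroom = make_spine_template("mushroom", length = 2,
                                      head_diameter = 0.8,
                                      neck_diameter = 0.3,
                                      resolution = resolution),
       stubby = make_spine_template("stubby", length = 1,
                                    head_diameter = 0.5,
                                    neck_diameter = 0.5,
                                    resolution = resolution),
       thin = make_spine_template("thin", length = 2.5,
                                  head_diameter = 0.4,
                                  neck_diameter = 0.24,
                                  resolution = resolution))
}

# local geometry of a section at a given arclength: position, unit tangent
# and rotation-minimizing normal frame, interpolated radius
section_point_at <- function(section, arclength) {
  p <- section$positions
  n <- nrow(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[n]
  t <- min(max(arclength, 0), L)
  if (t > L) stop("arclength beyond section length")
  fr <- rmf_frames(p)
  i <- max(1L, min(n - 1L, findInterval(t, s)))
  u <- if (seg[i] > 0) (t - s[i]) / seg[i] else 0
  pos <- p[i, ] * (1 - u) + p[i + 1L, ] * u
  tangent <- p[i + 1L, ] - p[i, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  n1 <- fr$n1[i, ] * (1 - u) + fr$n1[i + 1L, ] * u
  n1 <- n1 - sum(n1 * tangent) * tangent
  n1 <- n1 / sqrt(sum(n1 * n1))
  n2 <- c(tangent[2] * n1[3] - tangent[3] * n1[2],
          tangent[3] * n1[1] - tangent[1] * n1[3],
          tangent[1] * n1[2] - tangent[2] * n1[1])
  radius <- stats::approx(s, section$radii, t, rule = 2)$y
  list(position = pos, tangent = tangent, n1 = n1, n2 = n2, radius = radius,
       section_length = L)
}

is_dendrite_section <- function(sec) sec$type_code %in% c(3L, 4L)

#' Sample spine placements along dendrites
#'
#' Draws `N ~ Poisson(density x total dendritic arclength)` placements,
#' uniform in arclength, with azimuth uniform about the local tangent.
#' Deterministic given `rng_seed`. Only sections with SWC type codes 3 or 4
#' (basal/apical dendrite) receive spines.
#'
#' @param morphology a preprocessed `morphology`.
#' @param density spines per micrometre of dendritic arclength.
#' @param rng_seed integer seed.
#' @param templates named list of `spine_template` (ids sampled uniformly).
#' @return data.frame of class `spine_placements`: section, arclength,
#'   azimuth_deg, direction (dx, dy, dz), surface point (px, py, pz), local
#'   dendrite radius, template id, scale.
#' @export
sample_spine_placements <- function(morphology, density, rng_seed = 1L,
                                    templates = default_spine_templates()) {
  dend <- which(vapply(morphology$sections, is_dendrite_section, logical(1)))
  lens <- vapply(morphology$sections[dend], section_length, numeric(1))
  empty <- data.frame(section = integer(0), arclength = numeric(0),
                      azimuth_deg = numeric(0), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0), px = numeric(0),
                      py = numeric(0), pz = numeric(0),
                      local_radius = numeric(0),
                      template = character(0), scale = numeric(0))
  class(empty) <- c("spine_placements", "data.frame")
  if (length(dend) == 0L || density <= 0 || sum(lens) == 0) return(empty)
  withr::with_seed(rng_seed, {
    n <- stats::rpois(1, density * sum(lens))
    if (n == 0L) {
      out <- empty
    } else {
      sec_idx <- sample(seq_along(dend), n, replace = TRUE, prob = lens)
      arc <- stats::runif(n) * lens[sec_idx]
      azim <- stats::runif(n, 0, 360)
      tmpl <- sample(names(templates), n, replace = TRUE)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        sec <- morphology$sections[[dend[sec_idx[i]]]]
        loc <- section_point_at(sec, arc[i])
        a <- azim[i] * pi / 180
        dir <- cos(a) * loc$n1 + sin(a) * loc$n2
        surf <- loc$position + loc$radius * dir
        rows[[i]] <- data.frame(section = dend[sec_idx[i]],
                                arclength = arc[i],
                                azimuth_deg = azim[i], dx = dir[1],
                                dy = dir[2], dz = dir[3], px = surf[1],
                                py = surf[2], pz = surf[3],
                                local_radius = loc$radius,
                                template = tmpl[i], scale = 1)
      }
      out <- do.call(rbind, rows)
      class(out) <- c("spine_placements", "data.frame")
    }
    out
  })
}

#' Read spine placements from a CSV table
#'
#' Columns: `section_index, arclength_um, azimuth_deg, template_id, scale`.
#' Geometry (direction, surface point, local radius) is derived from the
#' morphology.
#'
#' @param path CSV path.
#' @param morphology a `morphology`.
#' @return a `spine_placements` data.frame.
#' @export
read_spine_placements <- function(path, morphology) {
  df <- utils::read.csv(path)
  need <- c("section_index", "arclength_um", "azimuth_deg", "template_id",
            "scale")
  if (!all(need %in% names(df)))
    stop("spine CSV must have columns: ", paste(need, collapse = ", "))
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sec <- morphology$sections[[df$section_index[i]]]
    loc <- section_point_at(sec, df$arclength_um[i])
    if (df$arclength_um[i] > loc$section_length)
      stop("arclength beyond section length in row ", i)
    a <- df$azimuth_deg[i] * pi / 180
    dir <- cos(a) * loc$n1 + sin(a) * loc$n2
    surf <- loc$position + loc$radius * dir
    rows[[i]] <- data.frame(section = df$section_index[i],
                            arclength = df$arclength_um[i],
                            azimuth_deg = df$azimuth_deg[i],
                            dx = dir[1], dy = dir[2], dz = dir[3],
                            px = surf[1], py = surf[2], pz = surf[3],
                            local_radius = loc$radius,
                            template = as.character(df$template_id[i]),
                            scale = df$scale[i])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spine_placements", "data.frame")
  out
}

# rotation taking +Z to unit vector d (Rodrigues)
rotation_z_to <- function(d) {
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2],
         z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # antiparallel: flip
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Place a spine template on a dendrite
#'
#' Rotates the template so +Z aligns with the placement direction, scales it,
#' and translates it so its base sits 25% of the local dendrite radius below
#' the dendrite surface, guaranteeing overlap with the tube proxy so voxel
#' remeshing welds spine and dendrite into one manifold.
#'
#' @param template a `spine_template`.
#' @param placement one row of a `spine_placements` data.frame.
#' @param morphology the host `morphology` (used for bounds checking).
#' @return a closed `triangle_mesh`.
#' @export
place_spine <- function(template, placement, morphology = NULL) {
  dir <- c(placement$dx, placement$dy, placement$dz)
  dir <- dir / sqrt(sum(dir^2))
  if (!is.null(morphology)) {
    sec <- morphology$sections[[placement$section]]
    if (placement$arclength > section_length(sec) + 1e-9)
      stop("placement arclength beyond section length")
  }
  base <- c(placement$px, placement$py, placement$pz) -
    0.25 * placement$local_radius * dir
  rigid_transform_mesh(template$mesh, rotation = rotation_z_to(dir),
                       translation = base, scale = placement$scale)
}

# all placed spine meshes for an assembly
place_all_spines <- function(placements, templates, morphology) {
  lapply(seq_len(nrow(placements)), function(i) {
    pl <- placements[i, , drop = FALSE]
    place_spine(templates[[pl$template]], pl, morphology)
  })
}
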