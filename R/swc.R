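#' @useDynLib neuromesh, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- section / morphology containers ---------------------------------------

new_section <- function(index, type_code, sample_ids, positions, radii,
                        parent_section = NA_integer_,
                        child_sections = integer(),
                        branch_order = 1L, is_primary = NA) {
  structure(list(index = as.integer(index),
                 type_code = as.integer(type_code),
                 sample_ids = as.integer(sample_ids),
                 positions = matrix(as.numeric(positions), ncol = 3),
                 radii = as.numeric(radii),
                 parent_section = as.integer(parent_section),
                 child_sections = as.integer(child_sections),
                 branch_order = as.integer(branch_order),
                 is_primary = is_primary),
            class = "swc_section")
}

section_length <- function(section) {
  p <- section$positions
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

new_morphology <- function(samples, sections, neurite_roots,
                           soma_centroid, soma_mean_radius) {
  if (soma_mean_radius <= 0) stop("soma_mean_radius must be positive")
  structure(list(samples = samples,
                 sections = sections,
                 neurite_roots = as.integer(neurite_roots),
                 soma_centroid = as.numeric(soma_centroid),
                 soma_mean_radius = as.numeric(soma_mean_radius)),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf(paste0("<morphology: %d samples, %d sections, %d neurites, ",
                     "soma r=%.2f um at (%.2f, %.2f, %.2f)>\n"),
              nrow(x$samples), length(x$sections), length(x$neurite_roots),
              x$soma_mean_radius, x$soma_centroid[1], x$soma_centroid[2],
              x$soma_centroid[3]))
  invisible(x)
}

# ---- SWC reading ------------------------------------------------------------

parse_swc_text <- function(lines, path = "<text>") {
  raw_no <- seq_along(lines)
  stripped <- sub("#.*$", "", lines)
  keep <- grepl("\\S", stripped)
  stripped <- stripped[keep]
  raw_no <- raw_no[keep]
  if (length(stripped) == 0L)
    stop("SWC parse error in ", path, ": no data rows")
  fields <- strsplit(trimws(stripped), "\\s+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 7L)
  if (length(bad))
    stop("SWC parse error in ", path, " line ", raw_no[bad[1]],
         ": expected 7 whitespace-delimited columns, got ", n_fields[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  bad <- which(apply(m, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("SWC parse error in ", path, " line ", raw_no[bad[1]],
         ": non-numeric field")
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5],
                   radius = m[, 6], parent = as.integer(m[, 7]))
  if (anyDuplicated(df$id))
    stop("SWC structural error in ", path, ": duplicate sample id ",
         df$id[anyDuplicated(df$id)])
  if (any(df$radius <= 0))
    stop("SWC structural error in ", path, " line ",
         raw_no[which(df$radius <= 0)[1]], ": radius must be > 0")
  has_parent <- df$parent != -1L
  missing_parent <- has_parent & !(df$parent %in% df$id)
  if (any(missing_parent))
    stop("SWC structural error in ", path, " line ",
         raw_no[which(missing_parent)[1]], ": parent id ",
         df$parent[which(missing_parent)[1]], " does not exist")
  df
}

# BFS from parentless samples; anything unreached sits on a cycle
check_acyclic <- function(samples) {
  idx_of <- seq_len(nrow(samples))
  names(idx_of) <- as.character(samples$id)
  parent_idx <- ifelse(samples$parent == -1L, 0L,
                       idx_of[as.character(samples$parent)])
  visited <- parent_idx == 0L
  children <- split(seq_len(nrow(samples))[parent_idx > 0L],
                    parent_idx[parent_idx > 0L])
  frontier <- which(visited)
  while (length(frontier)) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(visited))
    stop("SWC structural error: cyclic parent links involving sample id ",
         samples$id[which(!visited)[1]])
  invisible(TRUE)
}

#' Read an SWC morphology file
#'
#' Accepts the 7-column whitespace-delimited SWC dialects in the wild:
#' `#` comments, forward parent references (two-pass parse), and
#' single-sample, three-point or multi-sample contour somata, all collapsed
#' to a soma centroid plus mean radius (the pipeline regrows the soma from
#' simulation, so only the aggregate is retained).
#'
#' @param path path to an SWC file.
#' @return a `morphology`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- parse_swc_text(readLines(path, warn = FALSE), path)
  morphology_from_samples(df)
}

#' Build a morphology from a flat sample table
#'
#' @param samples data.frame with columns id, type, x, y, z, radius, parent.
#' @return a `morphology`.
#' @export
morphology_from_samples <- function(samples) {
  check_acyclic(samples)
  soma <- samples[samples$type == 1L, , drop = FALSE]
  if (nrow(soma) == 0L)
    stop("SWC structural error: no type-1 (soma) sample")
  centroid <- c(mean(soma$x), mean(soma$y), mean(soma$z))
  mean_radius <- mean(soma$radius)
  built <- build_sections(samples, soma_centroid = centroid)
  new_morphology(samples, built$sections, built$neurite_roots,
                 centroid, mean_radius)
}

#' Assemble the section forest from a flat sample table
#'
#' Walks each neurite from its root sample, cutting sections at branching
#' points; branching samples are duplicated as shared endpoints so sections
#' are independently resamplable. Root sections are prepended with an
#' auxiliary sample at the soma centroid (radius equal to the root sample's),
#' recording the soma-to-arbor segment.
#'
#' @param samples data.frame with columns id, type, x, y, z, radius, parent.
#' @param soma_centroid optional 3-vector; defaults to the mean of type-1
#'   sample positions (required if no type-1 sample exists).
#' @return list with `sections` (list of sections) and `neurite_roots`
#'   (indices of root sections).
#' @export
build_sections <- function(samples, soma_centroid = NULL) {
  soma_ids <- samples$id[samples$type == 1L]
  if (is.null(soma_centroid)) {
    if (length(soma_ids) == 0L)
      stop("no soma samples and no explicit soma_centroid")
    s <- samples[samples$type == 1L, ]
    soma_centroid <- c(mean(s$x), mean(s$y), mean(s$z))
  }
  idx_of <- seq_len(nrow(samples))
  names(idx_of) <- as.character(samples$id)
  is_soma <- samples$type == 1L
  children <- lapply(seq_len(nrow(samples)), function(i) integer())
  for (i in seq_len(nrow(samples))) {
    p <- samples$parent[i]
    if (p != -1L) {
      pi <- idx_of[[as.character(p)]]
      if (!is_soma[i] || !is_soma[pi])    # intra-soma links are not segments
        children[[pi]] <- c(children[[pi]], i)
    }
  }
  # neurite root samples: non-soma children of soma samples, or parentless
  # non-soma samples (disconnected arbors, flagged later in preprocessing)
  root_idx <- which(!is_soma &
                    (samples$parent == -1L |
                     samples$parent %in% soma_ids))

  sections <- list()
  neurite_roots <- integer()
  pos_of <- function(i) c(samples$x[i], samples$y[i], samples$z[i])

  emit_section <- function(start_idx, parent_section, order, prefix) {
    # walk the unbranched chain starting at start_idx
    chain <- start_idx
    while (length(children[[chain[length(chain)]]]) == 1L)
      chain <- c(chain, children[[chain[length(chain)]]])
    ids <- samples$id[chain]
    pos <- cbind(samples$x[chain], samples$y[chain], samples$z[chain])
    rad <- samples$radius[chain]
    if (!is.null(prefix)) {
      ids <- c(prefix$id, ids)
      pos <- rbind(prefix$position, pos)
      rad <- c(prefix$radius, rad)
    }
    if (length(ids) < 2L)
      stop("singleton section at sample id ", samples$id[start_idx],
           ": a section needs at least 2 samples")
    sec <- new_section(length(sections) + 1L, samples$type[start_idx],
                       ids, pos, rad,
                       parent_section = parent_section,
                       branch_order = order)
    sections[[sec$index]] <<- sec
    tail_idx <- chain[length(chain)]
    for (child in children[[tail_idx]]) {
      child_sec <- emit_section(child, sec$index, order + 1L,
                                prefix = list(id = samples$id[tail_idx],
                                              position = pos_of(tail_idx),
                                              radius = samples$radius[tail_idx]))
      sections[[sec$index]]$child_sections <<-
        c(sections[[sec$index]]$child_sections, child_sec)
    }
    sec$index
  }

  for (r in root_idx) {
    connected_to_soma <- samples$parent[r] %in% soma_ids
    prefix <- if (connected_to_soma)
      list(id = 0L, position = soma_centroid, radius = samples$radius[r])
    else NULL
    neurite_roots <- c(neurite_roots,
                       emit_section(r, NA_integer_, 1L, prefix))
  }
  list(sections = sections, neurite_roots = neurite_roots)
}

# ---- SWC writing ------------------------------------------------------------

# Rebuild a flat sample table from the section forest (inverse of
# build_sections); soma becomes a single centroid sample.
sections_to_samples <- function(morph) {
  rows <- list(data.frame(id = 1L, type = 1L,
                          x = morph$soma_centroid[1],
                          y = morph$soma_centroid[2],
                          z = morph$soma_centroid[3],
                          radius = morph$soma_mean_radius, parent = -1L))
  next_id <- 2L
  # last emitted id of the tail sample of each section, for child linking
  tail_id <- integer(length(morph$sections))
  emit <- function(sec_idx, parent_sample_id) {
    sec <- morph$sections[[sec_idx]]
    # skip the duplicated shared first sample (parent's tail / soma auxiliary)
    start <- if (!is.na(sec$parent_section) || sec$sample_ids[1] == 0L) 2L else 1L
    n <- nrow(sec$positions)
    ids <- seq.int(next_id, next_id + (n - start))
    next_id <<- next_id + (n - start) + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      id = ids, type = sec$type_code,
      x = sec$positions[start:n, 1],
      y = sec$positions[start:n, 2],
      z = sec$positions[start:n, 3],
      radius = sec$radii[start:n],
      parent = c(parent_sample_id, ids[-length(ids)]))
    tail_id[sec_idx] <<- ids[length(ids)]
    for (child in sec$child_sections) emit(child, tail_id[sec_idx])
  }
  for (r in morph$neurite_roots) {
    sec <- morph$sections[[r]]
    parent <- if (sec$sample_ids[1] == 0L) 1L else -1L
    emit(r, parent)
  }
  do.call(rbind, rows)
}

#' Write a morphology to an SWC file
#'
#' Positions and radii are printed with 17 significant digits so a
#' read/write round trip reproduces them bit-exactly.
#'
#' @param morphology a `morphology`.
#' @param path output path.
#' @export
write_swc <- function(morphology, path) {
  df <- morphology$samples
  lines <- c("# written by neuromesh",
             sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                     df$id, df$type, df$x, df$y, df$z, df$radius, df$parent))
  ok <- tryCatch({writeLines(lines, path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write SWC file: ", path)
  invisible(path)
}
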