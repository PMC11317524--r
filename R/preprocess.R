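# Morphology preprocessing: soma-connectivity verification, removal of
# intra-somatic samples, adaptive resampling. None of these change the
# section topology (count, parent/child links, branch orders).

# first biological sample of a root section (skips the auxiliary centroid)
neurite_root_sample <- function(section) {
  i <- if (section$sample_ids[1] == 0L && nrow(section$positions) > 1L) 2L else 1L
  list(position = section$positions[i, ], radius = section$radii[i])
}

#' Verify arbor-soma connectivity
#'
#' A neurite is connected when its root sample lies within
#' `tolerance_factor * soma_mean_radius` of the soma centroid (closed
#' interval). Disconnected neurites are only flagged; proxy generation
#' bridges them with auxiliary segments rather than deleting them.
#'
#' @param morphology a `morphology`.
#' @param tolerance_factor multiple of the somatic mean radius; default 2.
#' @return data.frame with columns `neurite` (root section index) and
#'   `connected`.
#' @export
verify_soma_connectivity <- function(morphology, tolerance_factor = 2) {
  centroid <- morphology$soma_centroid
  lim <- tolerance_factor * morphology$soma_mean_radius
  res <- vapply(morphology$neurite_roots, function(r) {
    root <- neurite_root_sample(morphology$sections[[r]])
    sqrt(sum((root$position - centroid)^2)) <= lim
  }, logical(1))
  data.frame(neurite = morphology$neurite_roots, connected = res)
}

#' Remove samples inside the somatic extent
#'
#' Deletes leading samples of root sections that fall strictly inside the
#' mean-radius soma sphere; every section keeps at least its last two
#' samples. Idempotent, and section topology is untouched.
#'
#' @param morphology a `morphology`.
#' @return a `morphology` with attribute `"samples_removed"`.
#' @export
remove_inner_samples <- function(morphology) {
  centroid <- morphology$soma_centroid
  r_soma <- morphology$soma_mean_radius
  removed <- 0L
  for (ri in morphology$neurite_roots) {
    sec <- morphology$sections[[ri]]
    d <- sqrt(colSums((t(sec$positions) - centroid)^2))
    inside <- d < r_soma
    # leading run of inside samples only
    n_lead <- if (inside[1]) which.min(c(inside, FALSE)) - 1L else 0L
    n <- nrow(sec$positions)
    n_drop <- min(n_lead, n - 2L)
    if (n_drop > 0L) {
      keep <- (n_drop + 1L):n
      sec$positions <- sec$positions[keep, , drop = FALSE]
      sec$radii <- sec$radii[keep]
      sec$sample_ids <- sec$sample_ids[keep]
      morphology$sections[[ri]] <- sec
      removed <- removed + n_drop
    }
  }
  if (removed > 0L)
    morphology$samples <- sections_to_samples(morphology)
  attr(morphology, "samples_removed") <- removed
  morphology
}

#' Adaptively resample a section
#'
#' Re-spaces samples along the section polyline at steps equal to the local
#' radius (thin fibers sample densely, thick trunks sparsely), with radii
#' linearly interpolated along arclength and endpoints preserved exactly.
#' Spacing never exceeds twice the local radius and never undercuts half of
#' it except at the final step.
#'
#' @param section an `swc_section` with >= 2 samples.
#' @return the resampled `swc_section`.
#' @export
resample_adaptive <- function(section) {
  p <- section$positions
  r <- section$radii
  n <- nrow(p)
  if (n < 2L) stop("section needs >= 2 samples")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[n]
  if (L <= 0) return(section)
  r_at <- function(t) stats::approx(s, r, t, rule = 2)$y
  ts <- 0
  t <- 0
  repeat {
    step <- r_at(t)
    if (L - (t + step) < 0.5 * step) break
    t <- t + step
    ts <- c(ts, t)
  }
  ts <- c(ts, L)
  px <- stats::approx(s, p[, 1], ts, rule = 2)$y
  py <- stats::approx(s, p[, 2], ts, rule = 2)$y
  pz <- stats::approx(s, p[, 3], ts, rule = 2)$y
  newp <- cbind(px, py, pz)
  dimnames(newp) <- NULL
  # endpoints bit-exact
  newp[1, ] <- p[1, ]
  newp[nrow(newp), ] <- p[n, ]
  newr <- r_at(ts)
  newr[1] <- r[1]
  newr[length(newr)] <- r[n]
  ids <- rep(0L, length(ts))
  ids[1] <- section$sample_ids[1]
  ids[length(ids)] <- section$sample_ids[n]
  sec <- section
  sec$positions <- newp
  sec$radii <- newr
  sec$sample_ids <- ids
  sec
}

#' Run the full preprocessing stage
#'
#' Connectivity verification, intra-somatic sample removal and adaptive
#' resampling of every section, with an accounting report.
#'
#' @param morphology a `morphology`.
#' @param tolerance_factor connectivity tolerance, see
#'   [verify_soma_connectivity()].
#' @return list with `morphology` (cleaned) and `report`
#'   (class `preprocess_report`).
#' @export
preprocess_morphology <- function(morphology, tolerance_factor = 2) {
  count_samples <- function(m)
    sum(vapply(m$sections, function(s) nrow(s$positions), integer(1)))
  before <- count_samples(morphology)
  connectivity <- verify_soma_connectivity(morphology, tolerance_factor)
  morphology <- remove_inner_samples(morphology)
  removed <- attr(morphology, "samples_removed")
  resampled <- 0L
  for (i in seq_along(morphology$sections)) {
    old_n <- nrow(morphology$sections[[i]]$positions)
    sec <- resample_adaptive(morphology$sections[[i]])
    morphology$sections[[i]] <- sec
    if (nrow(sec$positions) != old_n) resampled <- resampled + 1L
  }
  morphology$samples <- sections_to_samples(morphology)
  after <- count_samples(morphology)
  report <- structure(list(
    arbors_connected = connectivity,
    samples_removed = removed,
    sections_resampled = resampled,
    samples_before = before,
    samples_after = after,
    samples_added = after - (before - removed)
  ), class = "preprocess_report")
  list(morphology = morphology, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0("<preprocess_report: %d/%d arbors connected, ",
                     "%d samples removed, %d sections resampled, ",
                     "%d -> %d samples>\n"),
              sum(x$arbors_connected$connected), nrow(x$arbors_connected),
              x$samples_removed, x$sections_resampled,
              x$samples_before, x$samples_after))
  invisible(x)
}
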