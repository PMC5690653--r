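# per-label voxel coordinates (physical um), centroids and principal
# directions from the voxel-coordinate covariance
.label_geometry <- function(labels) {
  lab <- labels$labels
  idx <- which(lab > 0L)
  if (length(idx) == 0) stop("label volume contains no labels", call. = FALSE)
  vals <- lab[idx]
  coords <- (arrayInd(idx, dim(lab)) - 1) * labels$spacing_um
  groups <- split(seq_along(vals), vals)
  ids <- as.integer(names(groups))
  dirs <- matrix(0, length(groups), 3)
  cents <- matrix(0, length(groups), 3)
  aniso <- numeric(length(groups))
  for (g in seq_along(groups)) {
    pts <- coords[groups[[g]], , drop = FALSE]
    cents[g, ] <- colMeans(pts)
    if (nrow(pts) < 2) { dirs[g, ] <- c(1, 0, 0); aniso[g] <- 1; next }
    eg <- eigen(cov(pts), symmetric = TRUE)
    dirs[g, ] <- eg$vectors[, 1]
    aniso[g] <- eg$values[1] / max(eg$values[2], 1e-12)
  }
  list(ids = ids, dirs = dirs, centroids = cents, anisotropy = aniso,
       sizes = lengths(groups))
}

#' Estimate the common tubule direction of a label volume
#'
#' Each component's principal direction is the dominant eigenvector of its
#' voxel-coordinate covariance; directions are sign-aligned into a common
#' hemisphere and averaged. Reslicing perpendicular to the returned vector
#' makes the slicing plane maximally perpendicular to the tubule population,
#' which is what makes the minor-axis diameter rule meaningful.
#'
#' @param labels a [label_volume()] with at least one label.
#' @return unit 3-vector (z, y, x). Low-anisotropy (blob-like) components
#'   trigger a message, since their principal direction is arbitrary.
#' @export
estimate_common_axis <- function(labels) {
  stopifnot(inherits(labels, "LabelVolume"))
  geo <- .label_geometry(labels)
  if (any(geo$anisotropy < 1.5))
    message(sum(geo$anisotropy < 1.5),
            " low-anisotropy component(s): principal direction unreliable")
  ref <- geo$dirs[which.max(geo$sizes), ]
  dirs <- geo$dirs
  flip <- as.numeric(dirs %*% ref) < 0
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  .normalize(colMeans(dirs))
}

#' Reslice a label volume perpendicular to an axis
#'
#' Resamples the labels (nearest neighbour, so label identity is preserved
#' exactly) onto a grid whose third axis is the given direction. The output
#' grid covers the rotated bounding box of the input; successive slices are
#' one voxel spacing apart along the axis. The in-plane pixel pitch
#' defaults to *half* the voxel spacing: oblique nearest-neighbour
#' resampling at full-voxel pitch systematically clips about one pixel off
#' each cross-section's extent, which biases minor-axis diameters low by up
#' to a voxel; half-pitch sampling removes that quantization loss while
#' still never inventing label values.
#'
#' @param labels a [label_volume()] (isotropic spacing).
#' @param axis slicing normal (z, y, x); normalized internally.
#' @param inplane_pitch_um in-plane pixel pitch of the resliced grid;
#'   default `spacing / 2`. Set to `spacing` for a grid commensurate with
#'   the input (e.g. for voxel-count bookkeeping).
#' @return an object of class `ReslicedLabels`: list with `slices` (integer
#'   array, `dim = c(n_slices, n_rows, n_cols)`), `pitch_um` (in-plane),
#'   `step_um` (slice step), `basis` (columns u, v, n), `origin_um`, `axis`.
#' @export
reslice_labels <- function(labels, axis, inplane_pitch_um = NULL) {
  stopifnot(inherits(labels, "LabelVolume"))
  n <- .normalize(axis)
  B <- .plane_basis(n)
  sp <- labels$spacing_um
  if (is.null(inplane_pitch_um)) inplane_pitch_um <- sp / 2
  gs <- dim(labels$labels)
  ext <- (gs - 1) * sp
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  pr <- corners %*% B  # projections onto u, v, n
  lo <- apply(pr, 2, min); hi <- apply(pr, 2, max)
  nc <- as.integer(ceiling((hi[1] - lo[1]) / inplane_pitch_um - 1e-9)) + 1L
  nr <- as.integer(ceiling((hi[2] - lo[2]) / inplane_pitch_um - 1e-9)) + 1L
  ns <- as.integer(ceiling((hi[3] - lo[3]) / sp - 1e-9)) + 1L
  origin0 <- unname(lo[1] * B[, 1] + lo[2] * B[, 2] + lo[3] * B[, 3])
  out <- cpp_resample_nn(labels$labels, gs[1], gs[2], gs[3], sp,
                         B, origin0, c(inplane_pitch_um, inplane_pitch_um, sp),
                         ns, nr, nc)
  structure(list(slices = array(out, dim = c(ns, nr, nc)),
                 pitch_um = inplane_pitch_um, step_um = sp,
                 basis = B, origin_um = origin0, axis = n),
            class = "ReslicedLabels")
}

#' Measure per-tubule diameters from a label volume
#'
#' Implements the cross-sectional diametry rule: the volume is resliced
#' perpendicular to the common tubule axis, and on every slice each label's
#' cross-section is measured as the minor-axis length of the minimum-area
#' enclosing ellipse of its pixel centers (floored at one pixel width).
#' The per-tubule summary diameter is the median over usable slices.
#'
#' A slice is usable for a tubule when its cross-section has at least
#' `min_section_pixels` pixels and does not touch the slice border (a
#' border-truncated section yields a truncated ellipse). Tubules with fewer
#' than `min_slices` usable slices, or tilted more than `max_tilt_deg` away
#' from the slicing normal, are excluded and reported in the `exclusions`
#' attribute rather than measured badly.
#'
#' @param labels a [label_volume()].
#' @param axis slicing normal; default [estimate_common_axis()].
#' @param min_section_pixels minimum cross-section size (default 3).
#' @param min_slices minimum usable slices per tubule (default 3).
#' @param max_tilt_deg maximum tubule tilt from the slicing normal
#'   (default 75; beyond this, sections elongate and pixelation dominates).
#' @param per_slice if `TRUE`, also attach every slice diameter (always
#'   present as the `slice_diameters_um` list column).
#' @return data.frame of class `TubuleMeasurements`, one row per measured
#'   tubule: `tubule_id`, `axis_z/y/x` (the tubule's own principal
#'   direction), `tilt_deg`, `summary_diameter_um`, `n_slices_used`,
#'   `centroid_z/y/x_um`, `zone` (NA until [assign_zones()]), `colocalized`
#'   (NA until [overlap_fraction()]), `slice_diameters_um` (list column).
#'   Attribute `exclusions`: data.frame of excluded tubules and reasons.
#' @export
measure_tubules <- function(labels, axis = NULL, min_section_pixels = 3,
                            min_slices = 3, max_tilt_deg = 75,
                            per_slice = FALSE) {
  stopifnot(inherits(labels, "LabelVolume"))
  geo <- .label_geometry(labels)
  if (is.null(axis)) axis <- estimate_common_axis(labels)
  axis <- .normalize(axis)
  rs <- reslice_labels(labels, axis)
  sl <- rs$slices
  ns <- dim(sl)[1]; nr <- dim(sl)[2]; ncol_ <- dim(sl)[3]
  diam <- vector("list", max(geo$ids))
  for (k in seq_len(ns)) {
    page <- sl[k, , ]
    idx <- which(page > 0L)
    if (length(idx) == 0) next
    vals <- page[idx]
    rc <- arrayInd(idx, c(nr, ncol_))
    for (grp in split(seq_along(vals), vals)) {
      id <- vals[grp[1]]
      pts <- rc[grp, , drop = FALSE]
      if (nrow(pts) < min_section_pixels) next
      if (any(pts[, 1] == 1L | pts[, 1] == nr |
              pts[, 2] == 1L | pts[, 2] == ncol_)) next
      e <- min_enclosing_ellipse(pts, min_width = 1)
      diam[[id]] <- c(diam[[id]], minor_axis_length(e, rs$pitch_um))
    }
  }
  tilt <- acos(pmin(abs(geo$dirs %*% axis), 1)) * 180 / pi
  rows <- list(); excl <- list()
  for (g in seq_along(geo$ids)) {
    id <- geo$ids[g]
    dd <- diam[[id]]
    if (length(dd) < min_slices) {
      excl[[length(excl) + 1]] <- data.frame(tubule_id = id,
                                             reason = "too_few_slices")
      next
    }
    if (tilt[g] > max_tilt_deg) {
      excl[[length(excl) + 1]] <- data.frame(tubule_id = id, reason = "tilt")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      tubule_id = id,
      axis_z = geo$dirs[g, 1], axis_y = geo$dirs[g, 2], axis_x = geo$dirs[g, 3],
      tilt_deg = tilt[g],
      summary_diameter_um = median(dd),
      n_slices_used = length(dd),
      centroid_z_um = geo$centroids[g, 1],
      centroid_y_um = geo$centroids[g, 2],
      centroid_x_um = geo$centroids[g, 3],
      zone = NA_character_, colocalized = NA)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tubule_id = integer(0), axis_z = numeric(0), axis_y = numeric(0),
               axis_x = numeric(0), tilt_deg = numeric(0),
               summary_diameter_um = numeric(0), n_slices_used = integer(0),
               centroid_z_um = numeric(0), centroid_y_um = numeric(0),
               centroid_x_um = numeric(0), zone = character(0),
               colocalized = logical(0))
  out$slice_diameters_um <- I(unname(diam[out$tubule_id]))
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(tubule_id = integer(0), reason = character(0))
  attr(out, "slicing_axis") <- axis
  class(out) <- c("TubuleMeasurements", class(out))
  out
}

#' Measure tubule diameters on a 2D labeled section
#'
#' Applies the same minor-axis-of-the-enclosing-ellipse rule directly to a
#' labeled histology section. Ring-shaped labels (stained walls) are
#' measured by their outer extent, since the enclosing ellipse sees the
#' outer boundary.
#'
#' @param section_labels 2D integer matrix of instance labels (0 background).
#' @param spacing_um physical pixel size (um).
#' @return data.frame with `label` and `diameter_um`; empty for an empty image.
#' @export
measure_section_diameters <- function(section_labels, spacing_um = 1) {
  stopifnot(is.matrix(section_labels))
  idx <- which(section_labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), diameter_um = numeric(0)))
  vals <- section_labels[idx]
  rc <- arrayInd(idx, dim(section_labels))
  groups <- split(seq_along(vals), vals)
  data.frame(label = as.integer(names(groups)),
             diameter_um = vapply(groups, function(grp) {
               e <- min_enclosing_ellipse(rc[grp, , drop = FALSE], min_width = 1)
               minor_axis_length(e, spacing_um)
             }, numeric(1)),
             row.names = NULL)
}
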