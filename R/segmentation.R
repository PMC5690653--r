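#' Segmentation parameters
#'
#' @param threshold_mode `"otsu"` (automatic, from the global intensity
#'   histogram) or `"fixed"`.
#' @param threshold_value intensity threshold when `threshold_mode = "fixed"`.
#' @param connectivity 6 (face neighbours) or 26 (face+edge+corner). The
#'   default 26 keeps the thin walls of tilted tubules connected, which
#'   fragment under 6-connectivity.
#' @param min_voxels minimum component size; smaller components are dropped
#'   as noise speckle (default 27 = 3^3).
#' @param max_voxels optional upper size bound (e.g. to drop a fused block).
#' @return an object of class `SegmentationParams`.
#' @export
segmentation_params <- function(threshold_mode = c("otsu", "fixed"),
                                threshold_value = NULL,
                                connectivity = 26, min_voxels = 27,
                                max_voxels = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(threshold_value))
    stop("fixed threshold mode needs `threshold_value`", call. = FALSE)
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (min_voxels < 1) stop("min_voxels must be >= 1", call. = FALSE)
  structure(list(threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 max_voxels = max_voxels),
            class = "SegmentationParams")
}

#' Threshold a volume into a foreground mask
#'
#' Segments dense (mineralized or contrast-stained) voxels by global
#' intensity threshold: voxels with intensity >= threshold are foreground.
#' In `"otsu"` mode the threshold is found from the pooled histogram of the
#' whole volume (256 levels).
#'
#' @param vol a [voxel_volume()].
#' @param params a [segmentation_params()].
#' @return logical 3D array (the binary foreground mask).
#' @export
threshold_segment <- function(vol, params = segmentation_params()) {
  stopifnot(inherits(vol, "VoxelVolume"))
  x <- vol$data
  if (params$threshold_mode == "fixed") {
    thr <- params$threshold_value
  } else {
    rng <- range(x)
    if (diff(rng) == 0)
      stop("constant-intensity volume: Otsu threshold undefined", call. = FALSE)
    xm <- matrix((x - rng[1]) / diff(rng), nrow = dim(x)[1])
    t01 <- EBImage::otsu(EBImage::Image(xm), range = c(0, 1), levels = 256)
    thr <- rng[1] + t01 * diff(rng)
  }
  array(x >= thr, dim = dim(x))
}

#' Digital void inversion
#'
#' Marks the void (unstained / radiolucent) space inside the organ as
#' tubules: patent lumina are exactly the organ voxels that are not tissue,
#' `organ_mask & !tissue_mask`.
#'
#' @param tissue_mask logical array of dense tissue voxels.
#' @param organ_mask logical array of the organ outline (same shape).
#' @return logical array of void voxels.
#' @export
invert_voids <- function(tissue_mask, organ_mask) {
  if (!identical(dim(tissue_mask), dim(organ_mask)))
    stop("tissue_mask and organ_mask must share shape", call. = FALSE)
  organ_mask & !tissue_mask
}

#' Label connected components in 3D
#'
#' Flood-fill labeling under the requested connectivity; components smaller
#' than `min_voxels` (or larger than `max_voxels`, when set) are dropped and
#' counted in the returned metadata. Surviving components are relabeled
#' contiguously 1..K in first-voxel order.
#'
#' @param mask logical 3D array.
#' @param params a [segmentation_params()].
#' @param spacing_um voxel size carried into the result.
#' @return a [label_volume()]; `$meta` holds `n_labels`,
#'   `dropped_components` and `dropped_voxels`.
#' @export
label_components <- function(mask, params = segmentation_params(),
                             spacing_um = 5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  lab <- cpp_label3d(as.integer(mask), d[1], d[2], d[3], params$connectivity)
  nlab <- attr(lab, "n_labels")
  dropped_comp <- 0L; dropped_vox <- 0L
  if (nlab > 0) {
    sizes <- tabulate(lab, nbins = nlab)
    keep <- sizes >= params$min_voxels
    if (!is.null(params$max_voxels)) keep <- keep & sizes <= params$max_voxels
    dropped_comp <- sum(!keep)
    dropped_vox <- sum(sizes[!keep])
    remap <- integer(nlab + 1L)
    remap[which(keep) + 1L] <- seq_len(sum(keep))
    lab <- remap[lab + 1L]
    nlab <- sum(keep)
  }
  label_volume(array(lab, dim = d), spacing_um,
               meta = list(n_labels = as.integer(nlab),
                           dropped_components = as.integer(dropped_comp),
                           dropped_voxels = as.integer(dropped_vox)))
}
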