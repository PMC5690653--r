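# translate a 3D array so that result[x] = arr[x + offset], zero-filled
.shift_array <- function(arr, offset) {
  d <- dim(arr)
  out <- array(vector(typeof(arr), 1), dim = d)
  src_lo <- pmax(1, 1 + offset); src_hi <- pmin(d, d + offset)
  if (any(src_hi < src_lo)) return(out)
  dst_lo <- src_lo - offset; dst_hi <- src_hi - offset
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Recover the rigid translation between two channels
#'
#' Finds the integer voxel shift of channel B relative to channel A
#' maximizing the normalized cross-correlation, searched over shifts within
#' `max_shift_voxels` per axis (computed via FFT on the mean-subtracted
#' volumes). The scans being registered are of the same mounted specimen
#' pre/post staining, so translation-only registration is assumed adequate;
#' rotation is out of scope.
#'
#' @param vol_a,vol_b [voxel_volume()]s of identical shape and spacing.
#' @param max_shift_voxels search radius per axis (default 10).
#' @return integer 3-vector `offset` (z, y, x) such that
#'   `B[x] ~ A[x - offset]`, with attribute `correlation` (peak NCC). A
#'   low-correlation peak (< 0.2) triggers a warning.
#' @export
register_translation <- function(vol_a, vol_b, max_shift_voxels = 10) {
  stopifnot(inherits(vol_a, "VoxelVolume"), inherits(vol_b, "VoxelVolume"))
  if (!identical(dim(vol_a$data), dim(vol_b$data)) ||
      !isTRUE(all.equal(vol_a$spacing_um, vol_b$spacing_um)))
    stop("volumes must share shape and spacing", call. = FALSE)
  a <- vol_a$data - mean(vol_a$data)
  b <- vol_b$data - mean(vol_b$data)
  d <- dim(a)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / prod(d)
  cc <- cc / sqrt(sum(a^2) * sum(b^2))
  sh <- lapply(d, function(n) {
    s <- c(0:(n - 1)); s[s > n / 2] <- s[s > n / 2] - n; s
  })
  keep <- lapply(seq_len(3), function(ax)
    which(abs(sh[[ax]]) <= max_shift_voxels))
  sub <- cc[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  offset <- c(sh[[1]][keep[[1]][best[1]]],
              sh[[2]][keep[[2]][best[2]]],
              sh[[3]][keep[[3]][best[3]]])
  peak <- max(sub)
  if (peak < 0.2)
    warning(sprintf("low registration confidence (peak NCC %.3f)", peak),
            call. = FALSE)
  structure(as.integer(offset), correlation = peak)
}

#' Per-tubule and global overlap of two labeled channels
#'
#' After aligning channel B by the given offset, computes for every
#' channel-A tubule the fraction of its voxels covered by channel-B
#' foreground, flags it co-localized when the fraction reaches
#' `coloc_threshold`, and reports the global overlap `|A & B| / |A|` and
#' the Dice coefficient `2 |A & B| / (|A| + |B|)`.
#'
#' @param labels_a,labels_b [label_volume()]s of identical shape.
#' @param offset integer (z, y, x) translation of B relative to A, as
#'   returned by [register_translation()]; default no shift.
#' @param coloc_threshold per-tubule fraction above which a tubule counts
#'   as co-localized (default 0.5).
#' @return object of class `ColocResult`: list with `global_overlap`,
#'   `dice`, `per_tubule` (data.frame: `tubule_id_a`, `overlap_fraction`,
#'   `colocalized`), `offset_voxels`.
#' @export
overlap_fraction <- function(labels_a, labels_b, offset = c(0L, 0L, 0L),
                             coloc_threshold = 0.5) {
  stopifnot(inherits(labels_a, "LabelVolume"), inherits(labels_b, "LabelVolume"))
  if (!identical(dim(labels_a$labels), dim(labels_b$labels)))
    stop("label volumes must share shape", call. = FALSE)
  la <- labels_a$labels
  fb <- .shift_array(labels_b$labels, as.integer(offset)) > 0L
  fa <- la > 0L
  inter <- sum(fa & fb)
  na <- sum(fa); nb <- sum(fb)
  idx <- which(fa)
  vals <- la[idx]
  nlab <- max(vals)
  tot <- tabulate(vals, nbins = nlab)
  cov <- tabulate(vals[fb[idx]], nbins = nlab)
  present <- which(tot > 0)
  per <- data.frame(tubule_id_a = present,
                    overlap_fraction = cov[present] / tot[present])
  per$colocalized <- per$overlap_fraction >= coloc_threshold
  structure(list(global_overlap = if (na > 0) inter / na else NA_real_,
                 dice = if (na + nb > 0) 2 * inter / (na + nb) else NA_real_,
                 per_tubule = per,
                 offset_voxels = as.integer(offset)),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: global overlap %.3f, Dice %.3f, %d/%d tubules co-localized\n",
              x$global_overlap, x$dice, sum(x$per_tubule$colocalized),
              nrow(x$per_tubule)))
  invisible(x)
}
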