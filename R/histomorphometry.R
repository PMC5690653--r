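#' Assign axial zones to tubule measurements
#'
#' Splits the organ's axial extent into `n_zones` equal intervals (the
#' default 3 matching the proximal / mid / papillary-tip zones I-III) and
#' assigns each tubule the zone containing the projection of its centroid
#' onto the organ axis. A centroid falling exactly on a boundary goes to
#' the more proximal zone.
#'
#' @param measurements data.frame from [measure_tubules()] (needs the
#'   `centroid_*_um` columns).
#' @param organ_axis organ axis direction (z, y, x).
#' @param axial_range_um length-2 numeric: the proximal and distal ends of
#'   the organ as projections onto `organ_axis` (e.g. the projection range
#'   of the volume corners).
#' @param n_zones number of zones (default 3; 5 reproduces a finer axial
#'   profile).
#' @return `measurements` with the `zone` column set to roman numerals.
#' @export
assign_zones <- function(measurements, organ_axis, axial_range_um,
                         n_zones = 3) {
  if (diff(range(axial_range_um)) <= 0)
    stop("axial extent must be positive", call. = FALSE)
  n <- .normalize(organ_axis)
  pos <- as.numeric(as.matrix(measurements[, c("centroid_z_um", "centroid_y_um",
                                               "centroid_x_um")]) %*% n)
  zi <- .zone_index(pos, min(axial_range_um), max(axial_range_um),
                    as.integer(n_zones))
  measurements$zone <- .zone_labels(n_zones)[zi]
  measurements
}

#' Axial projection range of a voxel grid
#'
#' Convenience for [assign_zones()]: the range of projections of the
#' volume's corner voxel centers onto an axis.
#'
#' @param grid_shape `(nz, ny, nx)` voxels.
#' @param spacing_um voxel size (um).
#' @param axis direction (z, y, x).
#' @return length-2 numeric range (um).
#' @export
grid_axial_range <- function(grid_shape, spacing_um, axis) {
  ext <- (grid_shape - 1) * spacing_um
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  range(corners %*% .normalize(axis))
}

#' Build a diameter histogram
#'
#' Left-closed, right-open bins of constant width; diameters at or beyond
#' the range maximum are counted in `overflow`, not in a bin. `normalized`
#' holds per-bin fractions of the in-range count `n` (all zeros when empty).
#'
#' @param diameters_um positive diameters (um).
#' @param bin_width_um bin width (um), default 10 (matching the granularity
#'   at which tubule diameter ranges are conventionally reported).
#' @param range_um histogram range, default `c(0, 100)` um.
#' @param zone label carried in the result (`"I"`, `"II"`, `"III"` or
#'   `"pooled"`).
#' @return object of class `DiameterHistogram`: `bin_edges_um`, `counts`,
#'   `normalized`, `zone`, `n`, `overflow`.
#' @export
build_histogram <- function(diameters_um, bin_width_um = 10,
                            range_um = c(0, 100), zone = "pooled") {
  if (bin_width_um <= 0) stop("bin width must be positive", call. = FALSE)
  if (any(diameters_um <= 0)) stop("diameters must be positive", call. = FALSE)
  edges <- seq(range_um[1], range_um[2], by = bin_width_um)
  if (utils::tail(edges, 1) < range_um[2]) edges <- c(edges, range_um[2])
  nb <- length(edges) - 1
  over <- sum(diameters_um >= range_um[2])
  under <- sum(diameters_um < range_um[1])
  inr <- diameters_um[diameters_um >= range_um[1] & diameters_um < range_um[2]]
  bin <- findInterval(inr, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(bin, nbins = nb)
  n <- sum(counts)
  structure(list(bin_edges_um = edges, counts = counts,
                 normalized = if (n > 0) counts / n else rep(0, nb),
                 zone = zone, n = n,
                 overflow = as.integer(over + under)),
            class = "DiameterHistogram")
}

#' @export
print.DiameterHistogram <- function(x, ...) {
  cat(sprintf("DiameterHistogram (zone %s): n = %d, %d bins of %.3g um",
              x$zone, x$n, length(x$counts), diff(x$bin_edges_um[1:2])))
  if (x$overflow > 0) cat(sprintf(", %d out of range", x$overflow))
  cat("\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  [%5.1f, %5.1f) %4d  %.3f\n", x$bin_edges_um[i],
                x$bin_edges_um[i + 1], x$counts[i], x$normalized[i]))
  invisible(x)
}

#' Detect modes of a diameter histogram
#'
#' A mode is a bin whose count is strictly greater than both neighbours
#' (edge bins compare to their single neighbour); a plateau of equal counts
#' higher than its surroundings resolves to its leftmost bin. Modes closer
#' than `min_separation_bins` to an already-accepted stronger mode are
#' suppressed. The result is ordered by count descending, ties broken
#' toward the smaller diameter.
#'
#' @param hist a [build_histogram()] result.
#' @param min_separation_bins minimum bin distance between reported modes.
#' @return data.frame with `bin` (index), `bin_lo_um`, `bin_hi_um`, `count`.
#' @export
find_modes <- function(hist, min_separation_bins = 1) {
  stopifnot(inherits(hist, "DiameterHistogram"))
  cnt <- hist$counts
  nb <- length(cnt)
  # compress plateau runs
  r <- rle(cnt)
  starts <- cumsum(c(1, utils::head(r$lengths, -1)))
  cand <- integer(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] == 0) next
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == length(r$values) || r$values[i + 1] < r$values[i]
    if (left_ok && right_ok) cand <- c(cand, starts[i])
  }
  if (length(cand) == 0)
    return(data.frame(bin = integer(0), bin_lo_um = numeric(0),
                      bin_hi_um = numeric(0), count = integer(0)))
  ord <- order(-cnt[cand], cand)
  cand <- cand[ord]
  kept <- integer(0)
  for (b in cand)
    if (all(abs(b - kept) >= min_separation_bins)) kept <- c(kept, b)
  data.frame(bin = kept,
             bin_lo_um = hist$bin_edges_um[kept],
             bin_hi_um = hist$bin_edges_um[kept + 1],
             count = cnt[kept])
}

#' Overlap coefficient between two diameter distributions
#'
#' `sum(pmin(normalized_a, normalized_b))` over identical bins: 1 for
#' identical distributions, 0 for disjoint support.
#'
#' @param hist_a,hist_b [build_histogram()] results with identical bin edges.
#' @return overlap coefficient in \[0, 1\].
#' @export
compare_distributions <- function(hist_a, hist_b) {
  stopifnot(inherits(hist_a, "DiameterHistogram"),
            inherits(hist_b, "DiameterHistogram"))
  if (!isTRUE(all.equal(hist_a$bin_edges_um, hist_b$bin_edges_um)))
    stop("histograms must share bin edges", call. = FALSE)
  sum(pmin(hist_a$normalized, hist_b$normalized))
}
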