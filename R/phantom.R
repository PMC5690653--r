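#' Specification for a synthetic tubule phantom
#'
#' Describes a two-channel voxel phantom of roughly co-oriented cylindrical
#' tubules with a known diameter mixture, emulating a pre-stain (mineralized)
#' and post-stain (contrast-enhanced) micro-CT scan pair of the same
#' specimen. Channel B contains an exact geometric duplicate of a controlled
#' fraction of the channel-A tubules, so co-localization recovery can be
#' validated against ground truth.
#'
#' The default diameter mixture, `0.5 N(25, 2^2) + 0.5 N(45, 4^2)` um, gives
#' the bimodal population (modes in the 20-30 and 40-50 um bins) that the
#' mineralized-tubule channel is expected to show; vasa-recta-like channels
#' can be emulated with a 10-30 um mixture.
#'
#' @param grid_shape voxels per axis, `(nz, ny, nx)`.
#' @param spacing_um isotropic voxel size (um); default 5, the design scan
#'   resolution.
#' @param n_tubules number of tubules in channel A.
#' @param diameter_mixture list of `c(weight, mean_um, sd_um)` components;
#'   weights must sum to 1. Draws are truncated at `2 * spacing_um` from
#'   below (thinner tubules are not resolvable on the grid).
#' @param main_axis common tubule direction, (z, y, x) components.
#' @param tilt_jitter_deg maximum angular deviation of each tubule from
#'   `main_axis` (must be < 90).
#' @param wall_mode `"filled"` (lumen uniformly bright, e.g. mineral-filled)
#'   or `"shell"` (bright wall, dark patent lumen).
#' @param wall_thickness_um shell thickness when `wall_mode = "shell"`.
#' @param intensity_fg,intensity_bg mean foreground / background intensity.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param coloc_fraction fraction of channel-A tubules duplicated into
#'   channel B (0..1).
#' @param organ_mask `"none"` or `"paraboloid"` (an axis-aligned paraboloid
#'   organ outline, wide at the proximal end, tapering to the papillary tip).
#' @param tubule_length_um tubule length; `NULL` means span the whole grid
#'   (`"none"` mask) or a quarter of the axial extent (`"paraboloid"`, so
#'   tubules fit inside the tapering outline).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return an object of class `PhantomSpec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing_um = 5,
                         n_tubules = 30,
                         diameter_mixture = list(c(0.5, 25, 2), c(0.5, 45, 4)),
                         main_axis = c(1, 0, 0), tilt_jitter_deg = 20,
                         wall_mode = c("filled", "shell"),
                         wall_thickness_um = 10,
                         intensity_fg = 800, intensity_bg = 200,
                         noise_sd = 30, coloc_fraction = 0.7,
                         organ_mask = c("none", "paraboloid"),
                         tubule_length_um = NULL, seed = 1) {
  wall_mode <- match.arg(wall_mode)
  organ_mask <- match.arg(organ_mask)
  w <- vapply(diameter_mixture, `[`, numeric(1), 1)
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must lie in [0, 1]", call. = FALSE)
  if (tilt_jitter_deg >= 90)
    stop("tilt_jitter_deg must be < 90", call. = FALSE)
  if (n_tubules < 0) stop("n_tubules must be >= 0", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape), spacing_um = spacing_um,
                 n_tubules = as.integer(n_tubules),
                 diameter_mixture = diameter_mixture,
                 main_axis = .normalize(main_axis),
                 tilt_jitter_deg = tilt_jitter_deg,
                 wall_mode = wall_mode, wall_thickness_um = wall_thickness_um,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, coloc_fraction = coloc_fraction,
                 organ_mask = organ_mask,
                 tubule_length_um = tubule_length_um, seed = seed),
            class = "PhantomSpec")
}

#' Rasterize a cylinder into a voxel mask
#'
#' A voxel belongs to the mask exactly when its center lies within
#' `diameter_um / 2` of the cylinder's axis segment (filled mode), or within
#' `[diameter/2 - wall_thickness_um, diameter/2]` (shell mode).
#'
#' @param grid_shape `(nz, ny, nx)` voxels.
#' @param spacing_um isotropic voxel size (um).
#' @param center segment midpoint, physical (z, y, x) um.
#' @param axis direction vector (need not be unit; must be nonzero).
#' @param diameter_um outer diameter; must be at least `2 * spacing_um`.
#' @param length_um segment length.
#' @param wall_mode `"filled"` or `"shell"`.
#' @param wall_thickness_um shell thickness (shell mode only).
#' @return logical 3D array of `grid_shape`.
#' @export
rasterize_cylinder <- function(grid_shape, spacing_um, center, axis,
                               diameter_um, length_um,
                               wall_mode = c("filled", "shell"),
                               wall_thickness_um = 0) {
  wall_mode <- match.arg(wall_mode)
  if (sqrt(sum(axis^2)) == 0) stop("axis must be nonzero", call. = FALSE)
  if (diameter_um < 2 * spacing_um)
    stop("diameter_um must be >= 2 * spacing_um (sub-voxel tubules are not representable)",
         call. = FALSE)
  m <- cpp_rasterize_cylinder(grid_shape[1], grid_shape[2], grid_shape[3],
                              spacing_um, as.numeric(center),
                              as.numeric(axis), diameter_um, length_um,
                              wall_mode == "shell", wall_thickness_um)
  if (sum(m) == 0) warning("cylinder lies entirely outside the grid", call. = FALSE)
  array(m == 1L, dim = grid_shape)
}

# analytic paraboloid organ outline: axis through the grid center along
# `axis`, radius R0 * sqrt(1 - t/L) at axial depth t (widest proximally,
# radius 0 at the papillary tip)
.paraboloid_geom <- function(grid_shape, spacing_um, axis) {
  n <- .normalize(axis)
  B <- .plane_basis(n)
  ext <- (grid_shape - 1) * spacing_um
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  tproj <- corners %*% n
  uproj <- corners %*% B[, "u"]
  vproj <- corners %*% B[, "v"]
  R0 <- 0.9 * min(diff(range(uproj)), diff(range(vproj))) / 2
  ctr <- ext / 2
  list(n = n, u = B[, "u"], v = B[, "v"], ctr = ctr,
       tmin = min(tproj), tmax = max(tproj), R0 = R0)
}

.paraboloid_contains <- function(g, pts, margin = 0) {
  rel <- sweep(pts, 2, g$ctr)
  t <- as.numeric(pts %*% g$n)
  para <- rel - outer(t - as.numeric(g$ctr %*% g$n), as.numeric(g$n))
  rho <- sqrt(rowSums(para^2))
  frac <- (t - g$tmin) / (g$tmax - g$tmin)
  ok <- frac >= 0 & frac <= 1
  ok & (rho + margin) <= g$R0 * sqrt(pmax(1 - frac, 0))
}

#' Voxelized paraboloid organ mask
#'
#' @param grid_shape `(nz, ny, nx)` voxels.
#' @param spacing_um voxel size (um).
#' @param axis organ axis direction (z, y, x); the outline tapers from the
#'   proximal end (low projection) to a point at the tip.
#' @return logical 3D array.
#' @export
paraboloid_mask <- function(grid_shape, spacing_um, axis = c(1, 0, 0)) {
  g <- .paraboloid_geom(grid_shape, spacing_um, axis)
  ii <- (seq_len(grid_shape[1]) - 1) * spacing_um
  jj <- (seq_len(grid_shape[2]) - 1) * spacing_um
  kk <- (seq_len(grid_shape[3]) - 1) * spacing_um
  pts <- cbind(rep(ii, times = grid_shape[2] * grid_shape[3]),
               rep(rep(jj, each = grid_shape[1]), times = grid_shape[3]),
               rep(kk, each = grid_shape[1] * grid_shape[2]))
  array(.paraboloid_contains(g, pts), dim = grid_shape)
}

# minimum distance between two 3D segments (p1 + s*d1, p2 + t*d2), s,t in [0,1]
.segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    cc <- sum(d1 * r)
    if (e <= 1e-12) { t <- 0; s <- min(max(-cc / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-12) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# clip segment center +/- (len/2) * dir to the physical grid box
# returns NULL if no intersection, else list(p0, p1, mid, length)
.clip_segment <- function(center, dir, length_um, ext) {
  p0 <- center - (length_um / 2) * dir
  t0 <- 0; t1 <- length_um
  for (ax in 1:3) {
    d <- dir[ax]
    if (abs(d) < 1e-12) {
      if (p0[ax] < 0 || p0[ax] > ext[ax]) return(NULL)
    } else {
      ta <- (0 - p0[ax]) / d; tb <- (ext[ax] - p0[ax]) / d
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  list(p0 = p0 + t0 * dir, p1 = p0 + t1 * dir,
       mid = p0 + (t0 + t1) / 2 * dir, length = t1 - t0)
}

.draw_mixture <- function(n, mixture, lower) {
  if (n == 0) return(numeric(0))
  w <- vapply(mixture, `[`, numeric(1), 1)
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  d <- numeric(n)
  for (i in seq_len(n)) {
    m <- mixture[[comp[i]]]
    repeat {
      x <- rnorm(1, m[2], m[3])
      if (x >= lower) break
    }
    d[i] <- x
  }
  d
}

# random unit vector within a cone of half-angle jitter (deg) about axis:
# polar angle uniform on [0, jitter], azimuth uniform
.jitter_axis <- function(axis, jitter_deg) {
  B <- .plane_basis(axis)
  th <- runif(1, 0, jitter_deg) * pi / 180
  ph <- runif(1, 0, 2 * pi)
  as.numeric(cos(th) * B[, "n"] +
             sin(th) * (cos(ph) * B[, "u"] + sin(ph) * B[, "v"]))
}

#' Generate a two-channel tubule phantom with ground truth
#'
#' Places `n_tubules` non-overlapping straight cylinders (rejection sampling,
#' at most 1000 attempts each), renders them into a channel-A intensity
#' volume, duplicates `round(coloc_fraction * n_tubules)` of them at
#' identical geometry into channel B, adds Gaussian noise, and returns the
#' per-tubule ground-truth table. Fully deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `TubulePhantom`: a list with `channel_a` and
#'   `channel_b` ([voxel_volume()]s), `labels_a` / `labels_b` (ground-truth
#'   [label_volume()]s of the rendered voxels), `truth` (data.frame: id,
#'   true diameter, axis, clipped centerline midpoint and length, zone,
#'   channel membership) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  gs <- spec$grid_shape; sp <- spec$spacing_um
  ext <- (gs - 1) * sp
  n <- spec$n_tubules
  para <- if (spec$organ_mask == "paraboloid")
    .paraboloid_geom(gs, sp, spec$main_axis) else NULL
  len_default <- if (is.null(spec$tubule_length_um)) {
    if (is.null(para)) 2 * sqrt(sum(ext^2))
    else (para$tmax - para$tmin) / 4
  } else spec$tubule_length_um

  diams <- .draw_mixture(n, spec$diameter_mixture, 2 * sp)

  axes <- matrix(0, n, 3)
  mids <- matrix(0, n, 3)
  lens <- numeric(n)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      ctr <- c(runif(1, 0, ext[1]), runif(1, 0, ext[2]), runif(1, 0, ext[3]))
      dir <- .jitter_axis(spec$main_axis, spec$tilt_jitter_deg)
      seg <- .clip_segment(ctr, dir, len_default, ext)
      if (is.null(seg)) next
      if (!is.null(para)) {
        # margin of one extra voxel so rasterized voxel centers (up to r
        # from the centerline) stay inside the analytic outline
        tt <- seq(0, 1, length.out = 41)
        pts <- t(vapply(tt, function(s) seg$p0 + s * (seg$p1 - seg$p0),
                        numeric(3)))
        if (!all(.paraboloid_contains(para, pts, margin = diams[i] / 2 + sp)))
          next
      }
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        dmin <- .segment_distance(seg$p0, seg$p1, segs[[j]]$p0, segs[[j]]$p1)
        # margin of 2 voxels so rasterized surfaces cannot touch even
        # diagonally (26-connectivity would merge a 1-voxel gap)
        if (dmin < (diams[i] + diams[j]) / 2 + 2 * sp) { ok <- FALSE; break }
      }
      if (!ok) next
      axes[i, ] <- dir; mids[i, ] <- seg$mid; lens[i] <- seg$length
      segs[[i]] <- seg
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place tubule %d without overlap (placed %d of %d)",
                   i, i - 1, n), call. = FALSE)
  }

  lab_a <- array(0L, dim = gs)
  shell <- spec$wall_mode == "shell"
  for (i in seq_len(n)) {
    m <- cpp_rasterize_cylinder(gs[1], gs[2], gs[3], sp, mids[i, ], axes[i, ],
                                diams[i], lens[i], shell,
                                spec$wall_thickness_um)
    lab_a[m == 1L] <- i
  }

  k <- round(spec$coloc_fraction * n)
  idx_b <- if (n > 0) sort(sample.int(n, k)) else integer(0)
  map <- integer(n + 1)
  map[idx_b + 1L] <- idx_b
  lab_b <- array(map[lab_a + 1L], dim = gs)

  render <- function(lab) {
    v <- spec$intensity_bg + (spec$intensity_fg - spec$intensity_bg) * (lab > 0L)
    v + array(rnorm(prod(gs), 0, spec$noise_sd), dim = gs)
  }
  ch_a <- voxel_volume(render(lab_a), sp)
  ch_b <- voxel_volume(render(lab_b), sp)

  ar <- if (is.null(para)) {
    corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
    range(corners %*% spec$main_axis)
  } else c(para$tmin, para$tmax)
  zone_idx <- if (n > 0)
    .zone_index(as.numeric(mids %*% spec$main_axis), ar[1], ar[2], 3L)
  else integer(0)

  truth <- data.frame(tubule_id = seq_len(n),
                      true_diameter_um = diams,
                      axis_z = axes[, 1], axis_y = axes[, 2], axis_x = axes[, 3],
                      center_z_um = mids[, 1], center_y_um = mids[, 2],
                      center_x_um = mids[, 3],
                      length_um = lens,
                      zone = .zone_labels(3)[zone_idx],
                      in_channel_a = rep(TRUE, n),
                      in_channel_b = seq_len(n) %in% idx_b)

  structure(list(channel_a = ch_a, channel_b = ch_b,
                 labels_a = label_volume(lab_a, sp),
                 labels_b = label_volume(lab_b, sp),
                 truth = truth, spec = spec),
            class = "TubulePhantom")
}

#' @export
print.TubulePhantom <- function(x, ...) {
  cat(sprintf("TubulePhantom: %d tubules on %s grid, %d in channel B\n",
              nrow(x$truth), paste(x$spec$grid_shape, collapse = "x"),
              sum(x$truth$in_channel_b)))
  invisible(x)
}

#' Write a phantom to disk (TIFF channels, JSON sidecars, truth CSV)
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$channel_a, file.path(dir, "channel_a.tif"))
  write_volume(phantom$channel_b, file.path(dir, "channel_b.tif"))
  utils::write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Match segmented labels to ground-truth tubules by majority voxel overlap
#'
#' Re-rasterizes each ground-truth tubule and finds the segmentation label
#' covering most of its voxels.
#'
#' @param labels a [label_volume()] from the segmentation of a phantom channel.
#' @param phantom the [generate_phantom()] result the channel came from.
#' @param wall_mode rasterization mode used for matching; defaults to the
#'   phantom's own mode. Use `"filled"` to match lumen (void) labels of a
#'   shell phantom.
#' @return data.frame with `tubule_id`, matched `label` (NA if no overlap)
#'   and `overlap_frac` (matched voxels / truth voxels).
#' @export
match_labels_to_truth <- function(labels, phantom,
                                  wall_mode = phantom$spec$wall_mode) {
  stopifnot(inherits(labels, "LabelVolume"), inherits(phantom, "TubulePhantom"))
  gs <- dim(labels$labels); sp <- labels$spacing_um
  tr <- phantom$truth
  out <- data.frame(tubule_id = tr$tubule_id, label = NA_integer_,
                    overlap_frac = 0)
  shell <- wall_mode == "shell"
  for (r in seq_len(nrow(tr))) {
    m <- cpp_rasterize_cylinder(gs[1], gs[2], gs[3], sp,
                                c(tr$center_z_um[r], tr$center_y_um[r], tr$center_x_um[r]),
                                c(tr$axis_z[r], tr$axis_y[r], tr$axis_x[r]),
                                tr$true_diameter_um[r], tr$length_um[r],
                                shell, phantom$spec$wall_thickness_um)
    vox <- labels$labels[m == 1L]
    nv <- length(vox)
    vox <- vox[vox > 0L]
    if (length(vox) == 0) next
    tab <- tabulate(vox)
    best <- which.max(tab)
    out$label[r] <- best
    out$overlap_frac[r] <- tab[best] / nv
  }
  out
}
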