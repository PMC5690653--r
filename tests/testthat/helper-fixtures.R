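# independent 2D brute-force disc rasterizer: pixel centers within radius
brute_disc <- function(radius_px, center = c(0, 0)) {
  r <- ceiling(radius_px)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r))
  g <- sweep(g, 2, -center)
  g[rowSums(sweep(g, 2, center)^2) <= radius_px^2, , drop = FALSE]
}

# randomized enclosing-ellipse candidate: random orientation/eccentricity,
# scaled up until it encloses all points; returns its area
random_enclosing_area <- function(P, bbox_center) {
  ang <- runif(1, 0, pi)
  ratio <- exp(runif(1, -1.5, 1.5))
  ctr <- bbox_center + runif(2, -1, 1) * (apply(P, 2, function(v) diff(range(v))) / 4)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  d <- sweep(P, 2, ctr) %*% R
  a0 <- 1; b0 <- 1 / ratio
  q <- d[, 1]^2 / a0^2 + d[, 2]^2 / b0^2
  s <- sqrt(max(q))          # inflate so the farthest point sits on the rim
  pi * (a0 * s) * (b0 * s)
}

# brute-force histogram mode scan (independent of find_modes): strict local
# maxima with plateaus resolved to their leftmost bin
brute_modes <- function(counts) {
  nb <- length(counts)
  out <- integer(0)
  for (i in seq_len(nb)) {
    if (counts[i] == 0) next
    # walk left over the plateau
    l <- i
    while (l > 1 && counts[l - 1] == counts[i]) l <- l - 1
    if (l != i) next                      # not the leftmost bin of its run
    r <- i
    while (r < nb && counts[r + 1] == counts[i]) r <- r + 1
    left_ok <- l == 1 || counts[l - 1] < counts[i]
    right_ok <- r == nb || counts[r + 1] < counts[i]
    if (left_ok && right_ok) out <- c(out, i)
  }
  out
}

# single straight cylinder as a LabelVolume on a cubic grid
cylinder_label <- function(diameter_um, tilt_deg, grid = 64, spacing = 5) {
  th <- tilt_deg * pi / 180
  ax <- c(cos(th), sin(th), 0)
  ctr <- rep((grid - 1) * spacing / 2, 3)
  m <- rasterize_cylinder(rep(grid, 3), spacing, ctr, ax, diameter_um,
                          length_um = 4 * grid * spacing)
  list(labels = label_volume(array(as.integer(m), dim = rep(grid, 3)), spacing),
       axis = ax)
}

# small deterministic phantom shared across tests
small_phantom <- function(seed = 3, n = 20, grid = c(96, 96, 96), ...) {
  generate_phantom(phantom_spec(grid_shape = grid, n_tubules = n, seed = seed,
                                ...))
}

# join measurements to phantom truth via majority-overlap matching
measurements_vs_truth <- function(m, lab, ph, wall_mode = ph$spec$wall_mode) {
  mt <- match_labels_to_truth(lab, ph, wall_mode = wall_mode)
  names(mt) <- c("truth_id", "label", "overlap_frac")
  mm <- merge(m, mt, by.x = "tubule_id", by.y = "label")
  merge(mm, ph$truth, by.x = "truth_id", by.y = "tubule_id")
}

# union of the filled outer cylinders of a phantom (the organ/tissue outline
# a stained specimen supplies; used for void inversion on shell phantoms)
filled_union <- function(ph) {
  gs <- ph$spec$grid_shape
  organ <- array(FALSE, gs)
  for (r in seq_len(nrow(ph$truth))) {
    tr <- ph$truth[r, ]
    organ <- organ | rasterize_cylinder(gs, ph$spec$spacing_um,
      c(tr$center_z_um, tr$center_y_um, tr$center_x_um),
      c(tr$axis_z, tr$axis_y, tr$axis_x),
      tr$true_diameter_um, tr$length_um)
  }
  organ
}
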