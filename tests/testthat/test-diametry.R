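test_that("common-axis estimate matches aligned cylinders and jittered truth", {
  # all tubules exactly along z
  gs <- c(48, 48, 48)
  m <- rasterize_cylinder(gs, 5, c(117.5, 60, 60), c(1, 0, 0), 30, 600) |
       rasterize_cylinder(gs, 5, c(117.5, 170, 170), c(1, 0, 0), 40, 600)
  lab <- label_components(m, spacing_um = 5)
  ax <- estimate_common_axis(lab)
  expect_lt(acos(min(abs(sum(ax * c(1, 0, 0))), 1)) * 180 / pi, 1e-3)
  # jittered phantom: within 5 degrees of the main axis
  ph <- small_phantom(seed = 3, n = 20)
  lab2 <- label_components(threshold_segment(ph$channel_a), spacing_um = 5)
  ax2 <- estimate_common_axis(lab2)
  expect_lt(acos(min(abs(sum(ax2 * c(1, 0, 0))), 1)) * 180 / pi, 5)
  # degenerate blob: flagged
  blob <- array(0L, c(16, 16, 16)); blob[6:10, 6:10, 6:10] <- 1L
  expect_message(estimate_common_axis(label_volume(blob, 5)), "low-anisotropy")
  expect_error(estimate_common_axis(label_volume(array(0L, c(4, 4, 4)), 5)),
               "no labels")
})

test_that("reslicing along a native axis is an identity re-indexing", {
  ph <- small_phantom(seed = 5, n = 6, grid = c(24, 24, 24))
  lab <- ph$labels_a
  rs <- reslice_labels(lab, c(1, 0, 0), inplane_pitch_um = lab$spacing_um)
  expect_identical(rs$slices, lab$labels)
  # axis rotated to x: slice k is the original x-index-k plane
  rsx <- reslice_labels(lab, c(0, 0, 1), inplane_pitch_um = lab$spacing_um)
  for (k in c(4, 12, 20))
    expect_setequal(as.vector(rsx$slices[k, , ]), as.vector(lab$labels[, , k]))
})

test_that("labeled voxel count is conserved under oblique reslicing", {
  ph <- small_phantom(seed = 3, n = 20)
  lab <- ph$labels_a
  n0 <- sum(lab$labels > 0)
  for (ax in list(c(cos(pi / 6), sin(pi / 6), 0), c(cos(pi / 6), 0, sin(pi / 6)))) {
    rs <- reslice_labels(lab, ax, inplane_pitch_um = 5)
    expect_lt(abs(sum(rs$slices > 0) - n0) / n0, 0.02)
  }
})

test_that("cylinder diameters are recovered tilt-invariantly", {
  for (case in list(c(30, 0), c(30, 45), c(45, 30))) {
    cl <- cylinder_label(case[1], case[2])
    m <- measure_tubules(cl$labels, axis = cl$axis)
    expect_equal(nrow(m), 1)
    expect_lt(abs(m$summary_diameter_um - case[1]), 5)
    expect_lt(abs(m$tilt_deg), 1)
  }
})

test_that("estimates never decrease with true diameter on clean cylinders", {
  est <- vapply(seq(20, 60, by = 5), function(D) {
    cl <- cylinder_label(D, 20)
    measure_tubules(cl$labels, axis = cl$axis)$summary_diameter_um
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("exclusion rules drop short and over-tilted tubules as data", {
  # a single small blob yields too few usable slices
  blob <- array(0L, c(32, 32, 32)); blob[15:16, 15:16, 15:16] <- 1L
  m <- suppressMessages(measure_tubules(label_volume(blob, 5), axis = c(1, 0, 0),
                                        min_slices = 3))
  expect_equal(nrow(m), 0)
  excl <- attr(m, "exclusions")
  expect_equal(excl$reason, "too_few_slices")
  # tilt beyond max_tilt_deg excluded with reason
  cl <- cylinder_label(30, 60)
  m2 <- measure_tubules(cl$labels, axis = c(1, 0, 0), max_tilt_deg = 45)
  expect_equal(nrow(m2), 0)
  expect_equal(attr(m2, "exclusions")$reason, "tilt")
})

test_that("median summary is robust to dropping slices", {
  cl <- cylinder_label(45, 15)
  m <- measure_tubules(cl$labels, axis = cl$axis)
  dd <- m$slice_diameters_um[[1]]
  set.seed(31)
  for (i in 1:20) {
    keep <- sample(length(dd), ceiling(0.8 * length(dd)))
    expect_lt(abs(median(dd[keep]) - m$summary_diameter_um), 2.5)
  }
})

test_that("2D section diameters follow the enclosing-ellipse rule", {
  img <- matrix(0L, 64, 64)
  d1 <- brute_disc(12, c(0, 0)); img[cbind(d1[, 1] + 20, d1[, 2] + 20)] <- 1L
  ann <- brute_disc(20, c(0, 0))
  ann <- ann[rowSums(ann^2) >= 10^2, ]
  img2 <- matrix(0L, 64, 64); img2[cbind(ann[, 1] + 30, ann[, 2] + 30)] <- 2L
  r1 <- measure_section_diameters(img, 1)
  expect_lt(abs(r1$diameter_um - 24), 1)
  # annulus measured by its outer extent
  r2 <- measure_section_diameters(img2, 1)
  expect_lt(abs(r2$diameter_um - 40), 1)
  expect_equal(nrow(measure_section_diameters(matrix(0L, 8, 8))), 0)
})

test_that("phantom diameters are recovered within a voxel on average", {
  ph <- small_phantom(seed = 3, n = 20)
  lab <- label_components(threshold_segment(ph$channel_a), spacing_um = 5)
  m <- measure_tubules(lab)
  mm <- measurements_vs_truth(m, lab, ph)
  expect_gte(nrow(mm), 18)
  expect_lt(mean(abs(mm$summary_diameter_um - mm$true_diameter_um)), 5)
})
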