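test_that("cylinder rasterization matches a brute-force 2D disc per slice", {
  m <- rasterize_cylinder(c(20, 21, 21), 5, center = c(47.5, 50, 50),
                          axis = c(1, 0, 0), diameter_um = 30, length_um = 200)
  ref <- nrow(brute_disc(3))
  for (z in 3:17) {
    sl <- which(m[z, , ], arr.ind = TRUE)
    expect_equal(nrow(sl), ref)
    # same voxel set as the brute disc centered at voxel (11, 11)
    expect_setequal(paste(sl[, 1], sl[, 2]),
                    paste(brute_disc(3)[, 1] + 11, brute_disc(3)[, 2] + 11))
  }
})

test_that("rasterization preconditions and degenerate shell mode", {
  expect_error(rasterize_cylinder(c(10, 10, 10), 5, c(25, 25, 25), c(0, 0, 0),
                                  30, 100), "nonzero")
  expect_error(rasterize_cylinder(c(10, 10, 10), 5, c(25, 25, 25), c(1, 0, 0),
                                  8, 100), "2 \\* spacing")
  expect_warning(rasterize_cylinder(c(10, 10, 10), 5, c(500, 500, 500),
                                    c(1, 0, 0), 30, 20), "outside")
  # shell with wall = diameter/2 degenerates to filled
  args <- list(c(24, 24, 24), 5, c(57.5, 57.5, 57.5), c(1, 0.2, 0), 40, 300)
  filled <- do.call(rasterize_cylinder, args)
  shell <- do.call(rasterize_cylinder, c(args, list(wall_mode = "shell",
                                                    wall_thickness_um = 20)))
  expect_identical(filled, shell)
})

test_that("rendered filled tubule volume approximates the analytic cylinder", {
  D <- 40; L <- 200
  m <- rasterize_cylinder(c(48, 48, 48), 5, c(117.5, 117.5, 117.5),
                          c(1, 0.15, -0.1), D, L)
  analytic <- pi * (D / 2)^2 * L / 5^3
  expect_lt(abs(sum(m) - analytic) / analytic, 0.15)
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(diameter_mixture = list(c(0.6, 25, 2), c(0.5, 45, 4))),
               "sum to 1")
  expect_error(phantom_spec(coloc_fraction = 1.2), "coloc_fraction")
  expect_error(phantom_spec(tilt_jitter_deg = 95), "tilt_jitter")
})

test_that("empty and fully co-localized phantoms follow their contracts", {
  ph0 <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                       n_tubules = 0, seed = 1))
  expect_equal(nrow(ph0$truth), 0)
  expect_true(all(ph0$labels_a$labels == 0))
  # background-only intensities: near intensity_bg
  expect_lt(abs(mean(ph0$channel_a$data) - 200), 10)

  ph1 <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                       n_tubules = 6, coloc_fraction = 1,
                                       seed = 2))
  expect_identical(ph1$labels_a$labels, ph1$labels_b$labels)
  expect_true(all(ph1$truth$in_channel_b))
})

test_that("phantom generation is deterministic given the seed", {
  s <- phantom_spec(grid_shape = c(32, 32, 32), n_tubules = 5, seed = 7)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$channel_a$data, p2$channel_a$data)
  expect_identical(p1$channel_b$data, p2$channel_b$data)
  expect_identical(p1$truth, p2$truth)
})

test_that("drawn diameters follow the mixture and the truncation floor", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(64, 256, 256),
                                      n_tubules = 500, tilt_jitter_deg = 5,
                                      tubule_length_um = 60, seed = 13))
  d <- ph$truth$true_diameter_um
  expect_true(all(d >= 10))           # 2 x 5 um spacing
  mix_mean <- 0.5 * 25 + 0.5 * 45
  mix_sd <- sqrt(0.5 * (2^2 + 25^2) + 0.5 * (4^2 + 45^2) - mix_mean^2)
  expect_lt(abs(mean(d) - mix_mean), 3 * mix_sd / sqrt(500))
})

test_that("coloc subset size and truth bookkeeping are exact", {
  ph <- small_phantom(seed = 5, n = 15, grid = c(64, 64, 64))
  expect_equal(sum(ph$truth$in_channel_b), round(0.7 * 15))
  expect_equal(ph$truth$tubule_id, 1:15)
  expect_true(all(sort(unique(as.vector(ph$labels_b$labels[ph$labels_b$labels > 0]))) %in%
                    ph$truth$tubule_id[ph$truth$in_channel_b]))
})

test_that("paraboloid phantoms keep every tubule inside the organ mask", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(80, 80, 80),
                                      n_tubules = 8, organ_mask = "paraboloid",
                                      seed = 9))
  organ <- paraboloid_mask(c(80, 80, 80), 5, c(1, 0, 0))
  expect_true(all(organ[ph$labels_a$labels > 0]))
})

test_that("impossible placements fail with the achieved count", {
  expect_error(generate_phantom(phantom_spec(grid_shape = c(24, 24, 24),
                                             n_tubules = 60, seed = 1)),
               "placed [0-9]+ of 60")
})
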