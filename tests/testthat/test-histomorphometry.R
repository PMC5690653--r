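test_that("zone assignment splits the axis into thirds with proximal ties", {
  m <- data.frame(centroid_z_um = c(10, 100, 100.0001, 250, 299),
                  centroid_y_um = 0, centroid_x_um = 0)
  z <- assign_zones(m, c(1, 0, 0), c(0, 300), n_zones = 3)
  expect_equal(z$zone, c("I", "I", "II", "III", "III"))
  # centroid at 10% of the axis -> zone I; exact 1/3 boundary -> zone I
  expect_error(assign_zones(m, c(1, 0, 0), c(5, 5)), "positive")
  # five zones also supported
  z5 <- assign_zones(m, c(1, 0, 0), c(0, 300), n_zones = 5)
  expect_equal(z5$zone[1], "I")
  expect_equal(z5$zone[5], "V")
})

test_that("constructed tubules in known thirds are zoned with full agreement", {
  gs <- c(96, 48, 48); sp <- 5
  zones_true <- c("I", "II", "III")
  centers_z <- c(75, 237.5, 400)  # mid-points of each third of [0, 475]
  m <- array(FALSE, gs)
  for (i in 1:3)
    m <- m | rasterize_cylinder(gs, sp, c(centers_z[i], 60 + 40 * i, 117.5),
                                c(1, 0, 0), 30, 100)
  lab <- label_components(m, spacing_um = sp)
  meas <- measure_tubules(lab, axis = c(1, 0, 0))
  meas <- assign_zones(meas, c(1, 0, 0), grid_axial_range(gs, sp, c(1, 0, 0)))
  got <- meas$zone[order(meas$centroid_z_um)]
  expect_equal(got, zones_true)
  # zone-wise counts sum to the pooled count
  pooled <- build_histogram(meas$summary_diameter_um)
  zonal <- lapply(zones_true, function(z)
    build_histogram(meas$summary_diameter_um[meas$zone == z], zone = z))
  expect_equal(Reduce(`+`, lapply(zonal, `[[`, "counts")), pooled$counts)
})

test_that("histogram binning is left-closed right-open with overflow", {
  h <- build_histogram(c(25, 25, 45))
  expect_equal(h$counts[3], 2)   # [20, 30)
  expect_equal(h$counts[5], 1)   # [40, 50)
  expect_equal(h$n, 3)
  expect_equal(sum(h$normalized), 1)
  # boundary value 30 goes to [30, 40)
  expect_equal(build_histogram(30)$counts[4], 1)
  # >= range max is overflow, not a bin
  h2 <- build_histogram(c(25, 150))
  expect_equal(h2$overflow, 1)
  expect_equal(h2$n, 1)
  # empty input: all-zero counts and normalization
  h0 <- build_histogram(numeric(0))
  expect_equal(h0$n, 0)
  expect_true(all(h0$normalized == 0))
  expect_error(build_histogram(c(10), bin_width_um = 0), "positive")
})

test_that("normalized histograms are invariant to joint rescaling", {
  set.seed(3)
  d <- runif(100, 12, 88)
  h1 <- build_histogram(d, 10, c(0, 100))
  h2 <- build_histogram(d * 2.5, 25, c(0, 250))
  expect_equal(h1$normalized, h2$normalized)
})

test_that("mode detection matches a brute-force scan on random histograms", {
  h <- build_histogram(c(25, 25, 45))
  h$counts <- c(0, 5, 2, 7, 1, 0, 0, 0, 0, 0)
  expect_equal(find_modes(h)$bin, c(4, 2))  # sorted by count desc
  h$counts <- 1:10
  expect_equal(find_modes(h)$bin, 10)
  h$counts <- c(3, 3, 3, 1, 0, 0, 2, 2, 0, 0)  # plateaus resolve left
  expect_equal(sort(find_modes(h)$bin), c(1, 7))
  set.seed(19)
  for (i in 1:300) {
    h$counts <- sample(0:6, 10, replace = TRUE)
    expect_setequal(find_modes(h)$bin, brute_modes(h$counts))
  }
})

test_that("mode ranking breaks ties toward the smaller diameter", {
  h <- build_histogram(c(25, 45))
  h$counts <- c(0, 4, 0, 4, 0, 0, 0, 0, 0, 0)
  md <- find_modes(h)
  expect_equal(md$bin, c(2, 4))
})

test_that("distribution overlap hits endpoints and same-mixture draws agree", {
  h1 <- build_histogram(c(25, 25, 45))
  expect_equal(compare_distributions(h1, h1), 1.0)
  h2 <- build_histogram(c(75, 85))
  expect_equal(compare_distributions(h1, h2), 0.0)
  expect_error(compare_distributions(h1, build_histogram(25, range_um = c(0, 50))),
               "bin edges")
  # two independent draws of 200 diameters from the same mixture
  mix <- list(c(0.5, 25, 2), c(0.5, 45, 4))
  set.seed(101); d1 <- tubulometry:::.draw_mixture(200, mix, 10)
  set.seed(202); d2 <- tubulometry:::.draw_mixture(200, mix, 10)
  ov <- compare_distributions(build_histogram(d1), build_histogram(d2))
  expect_gte(ov, 0.8)
})
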