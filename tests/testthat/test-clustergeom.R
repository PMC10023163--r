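test_that("centre of mass is the arithmetic mean", {
  expect_equal(unname(center_of_mass(matrix(c(0, 2, 0, 0), 2))), c(1, 0))
  expect_equal(unname(center_of_mass(matrix(c(5, -3), 1))), c(5, -3))
  set.seed(1)
  r <- sqrt(runif(100)); th <- runif(100, 0, 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th))
  expect_equal(unname(center_of_mass(pts)),
               c(sum(pts[, 1]) / 100, sum(pts[, 2]) / 100), tolerance = 1e-9)
  expect_error(center_of_mass(pts[0, , drop = FALSE]), "empty")
})

test_that("axial projection anchors the origin centre at 0", {
  ap <- axial_projection(matrix(c(0, 0), 1), matrix(c(100, 0), 1))
  expect_equal(ap$origin_axial, 0)
  expect_equal(ap$target_axial, 100)
  expect_equal(ap$center_distance, 100)
  expect_error(axial_projection(matrix(c(1, 1), 1), matrix(c(1, 1), 1)),
               "coincide")
})

test_that("axial coordinates are invariant to rigid motions", {
  set.seed(2)
  o <- matrix(rnorm(60, sd = 50), ncol = 2)
  t <- matrix(rnorm(80, sd = 70), ncol = 2) + 150
  ap <- axial_projection(o, t)
  for (theta in c(0.3, 1.2, pi)) {
    shift <- c(123, -456)
    o2 <- rotate_xy(o, theta, about = c(50, 80)) +
      matrix(shift, nrow(o), 2, byrow = TRUE)
    t2 <- rotate_xy(t, theta, about = c(50, 80)) +
      matrix(shift, nrow(t), 2, byrow = TRUE)
    ap2 <- axial_projection(o2, t2)
    expect_equal(ap2$origin_axial, ap$origin_axial, tolerance = 1e-9)
    expect_equal(ap2$target_axial, ap$target_axial, tolerance = 1e-9)
  }
  # swapping origin and target reverses the axis consistently
  sw <- axial_projection(t, o)
  expect_equal(sw$target_axial, ap$center_distance - ap$origin_axial,
               tolerance = 1e-9)
})

test_that("binned profiles use half-open 33 nm bins anchored at 0", {
  p1 <- binned_profile(rep(0, 5))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$fraction, 1)
  expect_equal(p1$bin_lo_nm, 0)
  p2 <- binned_profile(c(0, 33))
  expect_equal(p2$fraction, c(0.5, 0.5))
  expect_equal(p2$bin_lo_nm, c(0, 33))
  set.seed(3)
  x <- rnorm(1e4, 0, 50)
  p3 <- binned_profile(x)
  expect_equal(sum(p3$fraction), 1)
  cdf <- pnorm(p3$bin_hi_nm, 0, 50) - pnorm(p3$bin_lo_nm, 0, 50)
  expect_true(all(abs(p3$fraction - cdf) < 0.01))
})

test_that("cluster diameter is the central 95 percent interval width", {
  set.seed(4)
  u <- runif(1e5, -50, 50)
  expect_equal(cluster_diameter(u), 95, tolerance = 0.01)
  g <- rnorm(1e5, 0, 75)
  expect_equal(cluster_diameter(g), 2 * qnorm(0.975) * 75, tolerance = 0.01)
  expect_equal(cluster_diameter(rep(7, 10)), 0)
  expect_equal(cluster_diameter(3 * g), 3 * cluster_diameter(g))
  expect_error(cluster_diameter(1), "at least 2")
})

test_that("fraction within an interval behaves like the 95 percent rule", {
  set.seed(5)
  x <- rnorm(2e4)
  iv <- unname(stats::quantile(x, c(0.025, 0.975)))
  expect_equal(fraction_within(x, iv), 0.95, tolerance = 0.001)
  expect_equal(fraction_within(c(500, 600), c(-10, 10)), 0)
  expect_error(fraction_within(x, c(5, -5)))
})

test_that("cord clusters are found with planted spacing and density", {
  x <- as.vector(outer(seq(-40, 40, length.out = 25), (0:9) * 1000, "+"))
  locs <- make_locs(x, rep(0, length(x)), probe = "ELKS")
  cc <- detect_cord_clusters(locs, "ELKS")
  expect_equal(nrow(cc$centers), 10)
  expect_equal(cc$spacing_um, rep(1, 9), tolerance = 1e-9)
  expect_equal(cc$density_per_um, 1, tolerance = 1e-9)
  # a single cluster has no spacing and an undefined density
  one <- detect_cord_clusters(make_blob(0, 0), "ELKS")
  expect_equal(nrow(one$centers), 1)
  expect_length(one$spacing_um, 0)
  expect_true(is.na(one$density_per_um))
  expect_warning(detect_cord_clusters(make_locs(1, 1, probe = "X"), "X"),
                 "fewer than")
})

test_that("cord spacing parameters are recovered across cords", {
  set.seed(6)
  sp <- unlist(lapply(1:30, function(i) {
    cord <- simulate_cord(10, fiducial_n = 60)
    detect_cord_clusters(cord$locs, "ELKS")$spacing_um
  }))
  expect_equal(mean(sp), 1.10, tolerance = 0.03)
  expect_equal(sd(sp), 0.16, tolerance = 0.25)
})

test_that("planted inter-centre offsets are recovered", {
  cord <- simulate_cord(12, targets = list(
    CaV2 = list(offset_nm = 124, sd_nm = 297 / 3.92, n = 300)), seed = 7)
  rois <- segment_rois(cord$locs, "ELKS")
  offs <- vapply(rois, function(r) {
    axial_projection(r$members[r$members$probe == "ELKS", ],
                     r$members[r$members$probe == "CaV2", ])$center_distance
  }, numeric(1))
  se <- sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(offs) - 124), 3 * se + 1)
})
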