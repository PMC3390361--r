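test_that("box minima partitions follow the strip argmin contract", {
  # uniform box: ties resolve to the first pixel of each strip
  px <- matrix(7, 16, 16)
  bm <- box_minima_partitions(wt_frame(px), c(8, 8))
  expect_equal(bm$points_a[, 2], rep(5, 7))   # top row of each column
  expect_equal(bm$points_b[, 1], rep(5, 7))   # left col of each row
  # a dark horizontal centreline: column minima collinear on it
  px2 <- matrix(200, 16, 16)
  px2[9, ] <- 20
  bm2 <- box_minima_partitions(wt_frame(px2), c(8, 8))
  expect_equal(bm2$points_a[, 2], rep(8, 7))
  # dark 45-degree diagonal: both partitions' minima on the diagonal,
  # agreeing with exhaustive per-strip argmin
  px3 <- matrix(200, 16, 16)
  for (k in 0:15) px3[k + 1, k + 1] <- 10
  bm3 <- box_minima_partitions(wt_frame(px3), c(8, 8))
  expect_equal(bm3$points_a[, 1], bm3$points_a[, 2])
  expect_equal(bm3$points_b[, 1], bm3$points_b[, 2])
  for (i in 1:7) {
    col <- px3[6:12, 5 + i]
    expect_equal(bm3$points_a[i, 2], 4 + which.min(col))
  }
  expect_error(box_minima_partitions(wt_frame(px), c(1, 8)), "does not fit")
})

test_that("eccentricity and orientation match the closed-form 2x2 eigenproblem", {
  # perfect line y = x
  r <- eccentricity_and_orientation(cbind(1:7, 1:7))
  expect_equal(r$eccentricity, 1)
  expect_equal(r$angle_deg, 45)
  # 4 corners of a square: isotropic
  r2 <- eccentricity_and_orientation(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_equal(r2$eccentricity, 0)
  # identical points: documented degenerate case
  r3 <- eccentricity_and_orientation(matrix(2, 5, 2))
  expect_equal(r3$eccentricity, 0)
  expect_equal(r3$angle_deg, 0)
  # noisy 30-degree line vs an independent eigendecomposition
  set.seed(7)
  t <- seq(-3, 3, length.out = 7)
  pts <- cbind(t * cos(pi / 6), t * sin(pi / 6)) + matrix(rnorm(14, sd = 0.3), 7, 2)
  r4 <- eccentricity_and_orientation(pts)
  ev <- eigen(cov(pts) * 6 / 7)
  expect_equal(r4$eccentricity, sqrt(1 - ev$values[2] / ev$values[1]),
               tolerance = 1e-10)
  ang <- (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180
  expect_equal(r4$angle_deg, ang, tolerance = 1e-8)
})

test_that("find_seeds locates whiskers and ignores blank frames", {
  expect_equal(nrow(find_seeds(wt_frame(matrix(128, 64, 64)))), 0L)

  spec <- clean_scene(curl_px = 0, mean_angle_deg = 10)
  rf <- render_frame(spec, 0)
  seeds <- find_seeds(rf$frame)
  expect_gt(nrow(seeds), 0)
  bb <- rf$truth$whiskers[[1]]$backbone
  d <- dist_to_polyline_pub(cbind(seeds$x, seeds$y), bb)
  # whisker runs at ~ -10 deg image angle (anterior up); some seed is
  # both on the backbone and within the 5 deg orientation precision
  ang_err <- abs(((seeds$angle_deg - (-10)) + 90) %% 180 - 90)
  expect_true(any(d < 2 & ang_err < 5.1))
  # sorted by decreasing eccentricity
  expect_true(!is.unsorted(rev(seeds$eccentricity)))
  # boxes always fit
  expect_true(all(seeds$site_x >= 3 & seeds$site_y >= 3))
})

test_that("seeds are intensity-shift invariant and rotate with the image", {
  spec <- clean_scene(noise_sd = 2, curl_px = 4)
  fr <- render_frame(spec, 0)$frame
  s1 <- find_seeds(fr)
  s2 <- find_seeds(wt_frame(fr$pixels + 17))
  expect_equal(s1, s2)
  # 90-degree rotation: transpose maps (x, y) -> (y, x)
  s3 <- find_seeds(wt_frame(t(fr$pixels)))
  k1 <- sort(paste(s1$site_x, s1$site_y))
  k3 <- sort(paste(s3$site_y, s3$site_x))
  expect_gt(length(intersect(k1, k3)) / max(length(k1), 1), 0.9)
})

test_that("R reference implementation agrees with the C++ scan", {
  spec <- clean_scene(noise_sd = 2)
  fr <- render_frame(spec, 0)$frame
  set.seed(1)
  cx <- sample(3:(ncol(fr$pixels) - 4), 40)
  cy <- sample(3:(nrow(fr$pixels) - 4), 40)
  fast <- whiskr:::seed_scan(fr, cx, cy)
  for (i in seq_along(cx)) {
    bm <- box_minima_partitions(fr, c(cx[i], cy[i]))
    ra <- eccentricity_and_orientation(bm$points_a)
    rb <- eccentricity_and_orientation(bm$points_b)
    # the scan adds degeneracy rules; where it reports a positive score
    # it must equal one of the two partition eccentricities
    if (fast$eccentricity[i] > 0)
      expect_true(min(abs(fast$eccentricity[i] - c(ra$eccentricity, rb$eccentricity))) < 1e-9)
  }
})
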