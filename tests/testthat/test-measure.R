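test_that("parametric fits reproduce analytic curves", {
  # straight line: zero curvature, zero residual
  t <- seq(0, 1, length.out = 40)
  pts <- cbind(10 + 90 * t, 20 + 45 * t)
  fit <- fit_parametric(pts, 5)
  expect_lt(fit$residual_rms, 1e-8)
  expect_lt(max(abs(curvature_at(fit, c(0.2, 0.5, 0.8)))), 1e-6)
  # 60-degree circle arc radius 80: curvature 1/80 within 2% at midpoint
  th <- seq(-pi / 6, pi / 6, length.out = 80)
  arc <- cbind(80 * sin(th) + 100, 100 - 80 * cos(th))
  fitc <- fit_parametric(arc, 5)
  expect_equal(abs(curvature_at(fitc, 0.5)), 1 / 80, tolerance = 0.02 / 80 * 80)
  # circle traversal sign: counterclockwise in image coords -> positive
  ccw <- cbind(100 + 80 * cos(seq(0, pi / 3, length.out = 60)),
               100 + 80 * sin(seq(0, pi / 3, length.out = 60)))
  expect_gt(curvature_at(fit_parametric(ccw, 5), 0.5), 0)
  # parabola y = x^2/2 at the vertex: unit curvature (short span so the
  # arc-length-parameterized polynomial represents it well)
  x <- seq(-0.7, 0.7, length.out = 101)
  fpar <- fit_parametric(cbind(x, x^2 / 2), 5)
  tv <- 0.5   # vertex is the arc midpoint by symmetry
  expect_equal(abs(curvature_at(fpar, tv)), 1, tolerance = 0.02)
  # vanishing speed errors
  expect_error(curvature_at(structure(list(coeffs_x = c(0, 0, 1),
                                           coeffs_y = c(0, 0, 1), degree = 2L),
                                      class = "wt_polyfit"), 0),
               "degenerate")
  # noisy backbone: the fit smooths back below the noise level
  set.seed(2)
  noisy <- pts + matrix(rnorm(80, sd = 0.2), ncol = 2)
  fitn <- fit_parametric(noisy, 5)
  smoothed <- whiskr:::polyfit_eval(fitn, t)
  expect_lt(sqrt(mean((smoothed - pts)^2)), 0.2)
})

test_that("curvature is rigid-motion invariant", {
  th <- seq(-pi / 5, pi / 5, length.out = 70)
  arc <- cbind(120 * sin(th), -120 * cos(th))
  k0 <- curvature_at(fit_parametric(arc, 5), 0.5)
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  arc2 <- t(R %*% t(arc)) + matrix(c(31, -7), nrow(arc), 2, byrow = TRUE)
  k1 <- curvature_at(fit_parametric(arc2, 5), 0.5)
  expect_equal(abs(k1), abs(k0), tolerance = 1e-6 * abs(k0))
})

test_that("measure_whisker measures angle, curvature, follicle and contact", {
  face <- wt_face_config("left", mask_offset_px = 8,
                         follicle_extrapolation_px = 10,
                         interest_point_arc_mm = 2, window_mm = 1.5)
  px_mm <- 1000 / 40
  # straight whisker at 30 deg from the lateral axis (protraction up)
  t <- seq(0, 130, 1)
  pts <- cbind(4 + t * cos(pi / 6), 150 - t * sin(pi / 6))
  cv <- wt_curve(pts, rep(1, nrow(pts)), rep(2, nrow(pts)))
  rec <- measure_whisker(cv, face, 40)
  expect_equal(rec$angle_deg, 30, tolerance = 1)
  expect_lt(abs(rec$curvature_per_mm), 0.005)
  # follicle sits ~10 px inside the mask along the tangent
  expect_equal(rec$follicle_x, 8 - 10 * cos(pi / 6) + 4 / cos(pi / 6) * 0,
               tolerance = 1.5)
  # circle-arc whisker: curvature 0.05/mm at the interest point
  r_px <- (1 / 0.05) * px_mm          # 500 px radius
  phi <- seq(0, 140 / r_px, length.out = 200)
  arc <- cbind(9 + r_px * sin(phi), 90 - (r_px - r_px * cos(phi)))
  cva <- wt_curve(arc, rep(1, 200), rep(2, 200))
  reca <- measure_whisker(cva, face, 40)
  expect_equal(abs(reca$curvature_per_mm), 0.05, tolerance = 0.005)
  # reversed point order gives the same record
  cvr <- wt_curve(arc[200:1, ], rep(1, 200), rep(2, 200))
  recr <- measure_whisker(cvr, face, 40)
  expect_equal(reca$angle_deg, recr$angle_deg, tolerance = 1e-6)
  expect_equal(reca$curvature_per_mm, recr$curvature_per_mm, tolerance = 1e-9)
  # pole contact: nearest point matches a dense-sampling oracle
  pole <- list(center = c(80, 138), radius = 3)
  recp <- measure_whisker(cv, face, 40, pole = pole)
  d_or <- min(sqrt((pts[, 1] - 80)^2 + (pts[, 2] - 138)^2))
  expect_equal(recp$contact_dist_px, d_or, tolerance = 0.05)
  # interest point beyond the curve: curvature NA, record still emitted
  short <- wt_curve(pts[1:30, ], rep(1, 30), rep(2, 30))
  face_far <- wt_face_config("left", interest_point_arc_mm = 5)
  recs <- measure_whisker(short, face_far, 40)
  expect_true(is.na(recs$curvature_per_mm))
  expect_false(is.na(recs$angle_deg))
})

test_that("windowed curvature ignores shape outside the window", {
  face <- wt_face_config("left", mask_offset_px = 8,
                         interest_point_arc_mm = 2, window_mm = 1.5)
  t <- seq(0, 150, 1)
  pts <- cbind(4 + t, 120 - 0.001 * t^2)
  cv <- wt_curve(pts, rep(1, nrow(pts)), rep(2, nrow(pts)))
  k0 <- measure_whisker(cv, face, 40)$curvature_per_mm
  # perturb only points far beyond the window (> 110 px arc)
  pts2 <- pts
  far <- t > 110
  pts2[far, 2] <- pts2[far, 2] + 5 * sin((t[far] - 110) / 6)
  k1 <- measure_whisker(wt_curve(pts2, rep(1, nrow(pts)),
                                 rep(2, nrow(pts))), face, 40)$curvature_per_mm
  expect_equal(k1, k0, tolerance = 1e-9)
})

test_that("contact episodes segment the time series against rest", {
  # constant curvature, pole far: no episodes
  rec0 <- data.frame(frame = 0:49, curvature_per_mm = 0.01,
                     contact_dist_px = 30)
  pole <- list(center = c(0, 0), radius = 3)
  expect_equal(nrow(contact_episodes(rec0, pole)), 0)
  # press-and-release: one episode with the constructed peak
  kap <- c(rep(0.01, 20), 0.01 + 0.1 * sin(seq(0, pi, length.out = 15)),
           rep(0.01, 15))
  dist <- c(rep(30, 20), rep(4, 15), rep(30, 15))
  rec1 <- data.frame(frame = 0:49, curvature_per_mm = kap,
                     contact_dist_px = dist)
  ep <- contact_episodes(rec1, pole, margin_px = 2)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_frame, 20)
  expect_equal(ep$end_frame, 34)
  expect_equal(ep$peak_delta_kappa, 0.1, tolerance = 1e-6)
  # graded contacts: peak order matches construction
  mags <- c(0.03, 0.1, 0.06)
  kap2 <- rep(0.02, 90); dist2 <- rep(30, 90)
  for (i in 1:3) {
    idx <- (i * 20):(i * 20 + 8)
    kap2[idx] <- 0.02 + mags[i] * sin(seq(0, pi, length.out = 9))
    dist2[idx] <- 4
  }
  ep2 <- contact_episodes(data.frame(frame = 0:89, curvature_per_mm = kap2,
                                     contact_dist_px = dist2), pole)
  expect_equal(order(ep2$peak_delta_kappa), order(mags))
  # all frames in contact: resting curvature undefined
  expect_error(contact_episodes(data.frame(frame = 0:9,
                                           curvature_per_mm = 0.1,
                                           contact_dist_px = 1), pole),
               "resting")
})

test_that("angle transforms equivariantly under a 90-degree rotation", {
  t <- seq(0, 120, 1)
  pts <- cbind(4 + t * cos(pi / 7), 150 - t * sin(pi / 7))
  cv <- wt_curve(pts, rep(1, nrow(pts)), rep(2, nrow(pts)))
  a_left <- measure_whisker(cv, wt_face_config("left"), 40)$angle_deg
  # rotate the scene 90 deg clockwise: (x, y) -> (H - 1 - y, x), face
  # moves to the top edge with anterior to the right
  H <- 176
  pts_rot <- cbind(H - 1 - pts[, 2], pts[, 1])
  cv_rot <- wt_curve(pts_rot, rep(1, nrow(pts)), rep(2, nrow(pts)))
  a_top <- measure_whisker(cv_rot, wt_face_config("top", anterior = "right"),
                           40)$angle_deg
  expect_equal(a_left, a_top, tolerance = 1e-6)
})
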