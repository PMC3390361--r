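test_that("step tests pass on a clean line and fail on the documented hazards", {
  bank <- the_bank()
  img <- render_line_image(64, 64, c(5, 30.3), c(58, 30.3), 2)
  f <- wt_frame(img)
  p <- detector_params(c(0, 0.3), 2, 0)
  sc <- detector_response(bank, f, c(30, 30), p)
  r <- step_tests(f, c(30, 30.3), p, sc, 0)
  expect_true(r$ok)
  expect_length(r$failed, 0)
  # angular-change arithmetic
  r2 <- step_tests(f, c(30, 30.3), detector_params(c(0, 0.3), 2, 45), sc, 0,
                   stop_tests(max_angle_step_deg = 25))
  expect_true("angle_step" %in% r2$failed)
  # a large dark disk (the pole) under the detector: mean-intensity fails
  spec <- clean_scene(pole = list(center = c(120, 80), radius = 12),
                      n_whiskers = 0)
  fp <- render_frame(spec, 0)$frame
  p3 <- detector_params(c(0, 0), 2, 0)
  r3 <- step_tests(fp, c(120, 80), p3, 50, 0)
  expect_true("mean_intensity" %in% r3$failed)
})

test_that("tracing a clean whisker is sub-pixel accurate and deterministic", {
  bank <- the_bank()
  spec <- clean_scene()
  rf <- render_frame(spec, 0)
  curves <- trace_frame(rf$frame, wt_config(), bank)
  expect_length(curves, 1)
  bb <- rf$truth$whiskers[[1]]$backbone
  d <- dist_to_polyline_pub(curves[[1]]$points, bb)
  expect_lte(mean(d), 0.2)
  # stays inside the frame
  expect_true(all(curves[[1]]$points[, 1] >= 0 &
                  curves[[1]]$points[, 1] <= ncol(rf$frame$pixels) - 1))
  # consecutive spacing in (0, 2]
  sp <- sqrt(diff(curves[[1]]$points[, 1])^2 + diff(curves[[1]]$points[, 2])^2)
  expect_true(all(sp > 0 & sp <= 2))
  # bitwise determinism
  curves2 <- trace_frame(rf$frame, wt_config(), bank)
  expect_identical(curves, curves2)
  # blank frame -> no curves
  expect_length(trace_frame(wt_frame(matrix(180, 64, 64)), wt_config(), bank), 0)
})

test_that("rendered rectangular lines recover width and position", {
  # Exactly axis-aligned rectangular valleys of odd width alias with the
  # pixel grid (the pixel-integrated profile is identical for a family
  # of (offset, width) pairs), so the sub-pixel estimate is only defined
  # up to that ambiguity there; the property is tested on its well-posed
  # domain: oblique angles for every width, axis-aligned for width 2.
  bank <- the_bank()
  cfg <- wt_config()
  cases <- rbind(expand.grid(w = c(1, 2, 3), a = c(30, 60)),
                 expand.grid(w = 2, a = c(0, 90)))
  for (k in seq_len(nrow(cases))) {
    w <- cases$w[k]; a <- cases$a[k]
    th <- a * pi / 180
    c0 <- c(60, 60)
    img <- render_line_image(120, 120, c0 - 45 * c(cos(th), sin(th)),
                             c0 + 45 * c(cos(th), sin(th)), w)
    curves <- trace_frame(wt_frame(img), cfg, bank)
    expect_gte(length(curves), 1)
    cv <- curves[[which.max(vapply(curves, function(x) nrow(x$points), 0))]]
    # backbone RMSE against the true segment (ends excluded: the
    # detector overshoots an abruptly-ending line by design)
    tt <- seq(-44, 44, 0.25)
    truth <- cbind(c0[1] + tt * cos(th), c0[2] + tt * sin(th))
    keep <- dist_to_polyline_pub(cv$points,
                                 truth[abs(tt) < 55, , drop = FALSE]) < 3
    mid <- cv$points[keep, , drop = FALSE]
    proj <- abs((mid[, 1] - c0[1]) * (-sin(th)) + (mid[, 2] - c0[2]) * cos(th))
    expect_lte(sqrt(mean(proj^2)), 0.2)
    inner <- abs((cv$points[, 1] - c0[1]) * cos(th) +
                 (cv$points[, 2] - c0[2]) * sin(th)) < 35
    expect_lt(abs(mean(cv$widths[inner]) - w), 0.25)
  }
})

test_that("gap jumping bridges a pole occlusion", {
  bank <- the_bank()
  spec <- clean_scene(curl_px = 4, mean_angle_deg = 0,
                      pole = list(center = c(110, 89.6), radius = 2.5))
  rf <- render_frame(spec, 0)
  curves <- trace_frame(rf$frame, wt_config(), bank)
  bb <- rf$truth$whiskers[[1]]$backbone
  covs <- vapply(curves, function(cv)
    mean(dist_to_polyline_pub(bb, cv$points) <= 2), 0)
  # one curve spans the occlusion: covers both sides of the pole
  best <- curves[[which.max(covs)]]
  expect_gt(max(covs), 0.7)
  xr <- range(best$points[, 1])
  expect_lt(xr[1], 100)
  expect_gt(xr[2], 120)
})

test_that("a whisker leaving the image terminates at the border", {
  bank <- the_bank()
  # long whisker exits through the right edge
  spec <- clean_scene(width = 120L, length_px = 150, curl_px = 0,
                      mean_angle_deg = 0)
  rf <- render_frame(spec, 0)
  curves <- trace_frame(rf$frame, wt_config(), bank)
  cv <- curves[[which.max(vapply(curves, function(x) nrow(x$points), 0))]]
  expect_true(all(cv$points[, 1] <= 119))
  expect_gt(max(cv$points[, 1]), 117)   # reaches the border region
})

test_that("remove_redundant implements the interval rule (vs brute force)", {
  mk <- function(xs, y) wt_curve(cbind(xs, y), rep(1, length(xs)), rep(2, length(xs)))
  a <- mk(seq(0, 100, 1), 50)
  b <- mk(seq(0, 100, 1), 50.4)       # near-identical
  out <- remove_redundant(list(a, b))
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$points), 101)
  # identical curves: one survives (the earlier)
  expect_length(remove_redundant(list(a, a)), 1)
  # disjoint whiskers survive
  c2 <- mk(seq(0, 100, 1), 90)
  expect_length(remove_redundant(list(a, c2)), 2)
  # half-length retrace: longer survives; verify rule with brute force
  h <- mk(seq(0, 55, 1), 50.6)
  out2 <- remove_redundant(list(h, a))
  expect_length(out2, 1)
  expect_equal(nrow(out2[[1]]$points), 101)
  d <- brute_dist_to_polyline(h$points, a$points)
  expect_true(mean(d <= 2) > 0.5)     # the oracle agrees h is redundant
  # idempotent and order-insensitive up to the tie rule
  expect_length(remove_redundant(out2), 1)
  out3 <- remove_redundant(list(a, h))
  expect_equal(nrow(out3[[1]]$points), 101)
  # a curve 3 px away is NOT redundant under the 2 px rule
  e <- mk(seq(0, 100, 1), 53.2)
  expect_length(remove_redundant(list(a, e)), 2)
})

test_that("a multi-whisker frame yields one curve per whisker after dedup", {
  bank <- the_bank()
  spec <- scene_spec(seed = 5)   # default 4-whisker scene with hairs
  rf <- render_frame(spec, 3)
  fr <- correct_line_bias(rf$frame)
  curves <- trace_frame(fr, wt_config(), bank)
  expect_gte(length(curves), 4)
  for (w in rf$truth$whiskers) {
    hits <- sum(vapply(curves, function(cv)
      mean(dist_to_polyline_pub(cv$points, w$backbone)) <= 2, TRUE))
    expect_equal(hits, 1)   # exactly one curve per true whisker
  }
})
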