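face_left <- wt_face_config("left")

test_that("compute_features matches analytic geometry", {
  # straight 100 px curve normal to a left face: angle ~ 0, curvature ~ 0
  pts <- cbind(seq(10, 110, 1), 80)
  cv <- wt_curve(pts, rep(1, nrow(pts)), rep(2, nrow(pts)))
  f <- compute_features(cv, face_left)
  expect_equal(unname(f["angle"]), 0, tolerance = 1)
  expect_lt(unname(f["curvature"]), 1e-6)
  expect_equal(unname(f["length"]), 100, tolerance = 0.01)
  expect_equal(unname(f["follicle"]), -80)     # AP coord of face end (-y)
  # quarter circle radius 100: mean curvature 1/100 within 5%
  th <- seq(0, pi / 2, length.out = 160)
  qc <- wt_curve(cbind(20 + 100 * sin(th), 120 - (100 - 100 * cos(th))),
                 rep(1, 160), rep(2, 160))
  fq <- compute_features(qc, face_left)
  expect_equal(unname(fq["curvature"]), 0.01, tolerance = 0.05)
  # synthetic whisker with known base angle
  spec <- clean_scene(mean_angle_deg = 42, curl_px = 0, base_y = 150,
                      length_px = 120)
  rf <- render_frame(spec, 0)
  curves <- trace_frame(rf$frame, wt_config(), the_bank())
  cv2 <- curves[[which.max(vapply(curves, function(x) nrow(x$points), 0))]]
  f2 <- compute_features(cv2, face_left)
  expect_equal(unname(f2["angle"]), 42, tolerance = 2)
})

test_that("estimate_threshold matches the exhaustive sweep definition", {
  # canonical small case: per-frame lengths {200, 210, 15}
  lens <- rep(list(c(200, 210, 15)), 3)
  thr <- estimate_threshold(lens)
  expect_equal(thr$N, 2L)
  expect_gt(thr$lambda_px, 15)
  expect_lt(thr$lambda_px, 200)
  expect_equal(thr$training_frames, 1:3)
  # single frame, single curve
  thr1 <- estimate_threshold(list(100))
  expect_equal(thr1$N, 1L)
  expect_equal(thr1$training_frames, 1L)
  # N supplied: training excludes frames lacking exactly N long curves;
  # verify against a brute-force sweep of the definition
  set.seed(9)
  lens2 <- lapply(1:30, function(i)
    c(runif(sample(2:5, 1), 90, 140), runif(sample(0:3, 1), 5, 40)))
  thr4 <- estimate_threshold(lens2, N = 4)
  count_at <- function(l, lam) sum(l > lam)
  all_l <- sort(unique(unlist(lens2)))
  cands <- c(0, (head(all_l, -1) + tail(all_l, -1)) / 2, max(all_l) + 1)
  freq <- vapply(cands, function(lam)
    sum(vapply(lens2, count_at, 0L, lam = lam) == 4L), 0L)
  expect_equal(sum(vapply(lens2, count_at, 0L, lam = thr4$lambda_px) == 4L),
               max(freq))
  expect_equal(thr4$training_frames,
               which(vapply(lens2, count_at, 0L, lam = thr4$lambda_px) == 4L))
  # unknown N on the same data agrees with the joint brute force
  thrA <- estimate_threshold(lens2)
  best_joint <- max(vapply(seq_len(8), function(n)
    max(vapply(cands, function(lam)
      sum(vapply(lens2, count_at, 0L, lam = lam) == n), 0L)), 0L))
  expect_equal(thrA$n_training, best_joint)
  expect_error(estimate_threshold(list(numeric(0), numeric(0))), "supply N")
})

test_that("shape histograms implement add-one smoothing", {
  f <- rand_features(12)
  f$length <- c(rep(100, 6), rep(10, 6))
  kind <- c(rep("W", 6), rep("FP", 6))
  m <- build_shape_model(f, kind, nbins = 8)
  h <- m$hists$length$W
  # all six W lengths in one bin: mass (6+1)/(6+8)
  expect_equal(max(h$mass), 7 / 14)
  # empty bins get exactly 1/(count+B)
  expect_equal(min(h$mass), 1 / 14)
  expect_equal(sum(h$mass), 1)
  # out-of-range queries clamp to edge bins (finite log-mass)
  expect_true(is.finite(whiskr:::hist_logmass(h, 1e6)))
})

test_that("label_frame equals brute-force enumeration (property, 200 cases)", {
  set.seed(20260910)
  for (rep in 1:200) {
    N <- sample(1:3, 1)
    n <- sample(0:5, 1)
    feats <- rand_features(n)
    trainf <- rand_features(10)
    kind <- sample(c("W", "FP"), 10, replace = TRUE)
    kind[1] <- "W"
    shape <- build_shape_model(trainf, kind, nbins = 8)
    labelings <- replicate(6, rand_labeling(sample(1:4, 1), N), simplify = FALSE)
    trans <- build_transition_model(labelings, N)
    use_change <- runif(1) < 0.5 && n > 0
    change <- NULL; neighbor <- NULL
    if (use_change) {
      change <- build_change_model(rand_features(5), rand_features(4))
      nf <- rand_features(3)
      neighbor <- list(labels = rand_labeling(3, N), features = nf)
    }
    got <- label_frame(feats, shape, trans, change, neighbor)
    want <- brute_label_frame(feats, shape, trans, change, neighbor)
    if (n == 0) {
      expect_length(got$labels, 0)
    } else {
      expect_equal(got$log_score, want$log_score, tolerance = 1e-9)
      expect_true(labeling_is_legal(got$labels))
    }
  }
})

test_that("structural rules hold: at most one W_i, ordering never violated", {
  set.seed(3)
  trainf <- rand_features(20)
  kind <- rep(c("W", "FP"), 10)
  shape <- build_shape_model(trainf, kind, nbins = 8)
  for (rep in 1:30) {
    N <- sample(1:3, 1)
    trans <- build_transition_model(
      replicate(5, rand_labeling(sample(1:5, 1), N), simplify = FALSE), N)
    lab <- label_frame(rand_features(sample(1:6, 1)), shape, trans)
    expect_true(labeling_is_legal(lab$labels))
  }
  # transitions violating ordering are never smoothed into legality
  trans <- build_transition_model(list(c("W1", "F1")), 2)
  expect_equal(trans$log_trans["F1", "W1"], -Inf)
  expect_equal(trans$log_trans["W1", "W1"], -Inf)
  expect_true(is.finite(trans$log_trans["W1", "W2"]))
})

test_that("link_video tracks identities on a short synthetic video", {
  spec <- scene_spec(seed = 21)
  frames <- list(); truths <- list()
  for (k in 1:12) {
    r <- render_frame(spec, k - 1)
    frames[[k]] <- r$frame; truths[[k]] <- r$truth
  }
  curves <- trace_video(frames, wt_config())
  lk <- link_video(curves, wt_config(n_whiskers = 4),
                   image_size = c(spec$width, spec$height))
  sc <- score_against_truth(curves, truths, lk)
  vis <- sc[sc$visible, ]
  expect_equal(mean(vis$detected), 1)
  expect_equal(mean(vis$id_correct), 1)
  # every emitted labeling is legal in AP order
  for (t in seq_along(curves)) {
    feats <- whiskr:::frame_features(curves[[t]], wt_config()$face)
    expect_true(labeling_is_legal(lk$frames[[t]]$labels[feats$curve]))
  }
  # single-frame video reduces to a shape-only labeling
  lk1 <- link_video(curves[1], wt_config(n_whiskers = 4))
  expect_length(lk1$frames, 1)
  expect_equal(sort(grep("^W", lk1$frames[[1]]$labels, value = TRUE)),
               c("W1", "W2", "W3", "W4"))
})

test_that("a whisker absent for a stretch keeps its identity on return", {
  spec <- scene_spec(seed = 33, exit = list(whisker = 4, start = 40,
                                            n_frames = 20))
  frames <- list(); truths <- list()
  for (k in 1:100) {
    r <- render_frame(spec, k - 1)
    frames[[k]] <- r$frame; truths[[k]] <- r$truth
  }
  curves <- trace_video(frames, wt_config())
  lk <- link_video(curves, wt_config(n_whiskers = 4),
                   image_size = c(spec$width, spec$height))
  sc <- score_against_truth(curves, truths, lk)
  expect_equal(sum(!sc$visible), 20)
  vis <- sc[sc$visible, ]
  expect_equal(mean(vis$id_correct), 1)
})
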