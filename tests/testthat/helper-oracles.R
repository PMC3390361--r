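# Shared fixtures and independent oracles, built in code.

# single shared detector bank (stencils memoize across tests)
the_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- detector_bank()
    bank
  }
})

# a minimal single-whisker scene with no artifacts; overrides via ...
clean_scene <- function(...) {
  args <- list(n_whiskers = 1, base_y = 88, length_px = 150,
               base_width_px = 2.5, tip_width_px = 0.05, curl_px = 8,
               mean_angle_deg = 5, noise_sd = 0, odd_line_gain = 1,
               illumination_gradient = 0, seed = 3,
               hairs = data.frame(x = numeric(0), y = numeric(0),
                                  angle_deg = numeric(0),
                                  length_px = numeric(0),
                                  width_px = numeric(0)))
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

# point-to-polyline distances by brute force over every segment
# (quadratic; independent of the package's vectorized helper)
brute_dist_to_polyline <- function(pts, poly) {
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (j in seq_len(nrow(poly) - 1L)) {
      a <- poly[j, ]; b <- poly[j + 1L, ]
      e <- b - a; L2 <- sum(e^2)
      t <- if (L2 == 0) 0 else sum((pts[i, ] - a) * e) / L2
      t <- min(1, max(0, t))
      q <- a + t * e
      best <- min(best, sqrt(sum((pts[i, ] - q)^2)))
    }
    out[i] <- best
  }
  out
}

# supersampled area integral of the continuous band detector over one
# pixel (oracle for the polygon-clipping rasterizer); n^2 samples
supersample_stencil_weight <- function(ix, iy, ox, oy, width, angle,
                                       length = 20, n = 100) {
  th <- angle * pi / 180
  ux <- cos(th); uy <- sin(th)
  g <- (seq_len(n) - 0.5) / n - 0.5
  px <- rep(ix + g, times = n); py <- rep(iy + g, each = n)
  dx <- px - ox; dy <- py - oy
  s <- dx * ux + dy * uy      # along
  p <- -dx * uy + dy * ux     # perpendicular
  hw <- width / 2
  inside <- abs(s) <= length / 2
  val <- ifelse(inside & p >= hw & p <= hw + 1, 1, 0) +
         ifelse(inside & p >= hw - 1 & p < hw, -1, 0) +
         ifelse(inside & p >= -hw - 1 & p < -hw, 1, 0) +
         ifelse(inside & p >= -hw & p < -hw + 1, -1, 0)
  mean(val)
}

# brute-force optimal frame labeling by enumerating legal sequences
brute_label_frame <- function(features, shape, trans, change = NULL,
                              neighbor = NULL, forward_delta = TRUE) {
  n <- nrow(features)
  states <- trans$states; S <- length(states)
  e <- whiskr:::emission_matrix(features, shape, trans, change,
                                neighbor, forward_delta)
  legal <- trans$legal
  best <- -Inf; bestlab <- character(0)
  rec <- function(i, prev, acc, lab) {
    if (i > n) {
      if (acc > best) { best <<- acc; bestlab <<- lab }
      return(invisible())
    }
    for (s in seq_len(S)) {
      if (i > 1L && !legal[prev, s]) next
      tr <- if (i == 1L) trans$log_start[s] else trans$log_trans[prev, s]
      rec(i + 1L, s, acc + unname(tr) + e[i, s], c(lab, states[s]))
    }
  }
  rec(1L, 0L, 0, character(0))
  list(labels = bestlab, log_score = best)
}

# random feature table with the package's six columns
rand_features <- function(n) {
  f <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, whiskr:::FEATURE_NAMES)))
  f[order(f$follicle), , drop = FALSE]
}

# random legal labeling of k curves for N whiskers
rand_labeling <- function(k, N) {
  states <- whiskr:::label_states(N)
  idx <- whiskr:::state_index(states)
  knd <- whiskr:::state_kind(states)
  lab <- character(0); cur <- -1L; usedW <- integer(0)
  for (q in seq_len(k)) {
    ok <- which(idx > cur | (idx == cur & knd == "FP"))
    if (q == 1L) ok <- seq_along(states)
    s <- if (length(ok) == 1L) ok else sample(ok, 1L)
    lab <- c(lab, states[s]); cur <- idx[s]
  }
  lab
}

# does a labeling satisfy the ordering rules?  (curves assumed sorted
# posterior -> anterior)
labeling_is_legal <- function(lab) {
  if (!length(lab)) return(TRUE)
  idx <- whiskr:::state_index(lab)
  knd <- whiskr:::state_kind(lab)
  if (any(diff(idx) < 0)) return(FALSE)
  for (i in seq_len(length(lab) - 1L))
    if (idx[i + 1L] == idx[i] && knd[i + 1L] == "W") return(FALSE)
  w <- lab[knd == "W"]
  !any(duplicated(w))
}

dist_to_polyline_pub <- whiskr:::dist_to_polyline
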