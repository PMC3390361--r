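# Growing sub-pixel curves from seeds, stopping them safely, and
# resolving duplicate traces.

#' Traced curve container
#'
#' An ordered polyline of sub-pixel points (~1 px apart) with per-point
#' detector score and width.  Bridged occlusion gaps carry score 0 and
#' interpolated widths.
#'
#' @param points n x 2 matrix of (x, y) positions.
#' @param scores,widths per-point detector response and width.
#' @param frame_index frame of origin.
#' @return object of class \code{wt_curve}.
#' @export
wt_curve <- function(points, scores, widths, frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("a curve needs at least 2 points")
  structure(list(points = points, scores = as.numeric(scores),
                 widths = as.numeric(widths),
                 frame_index = as.integer(frame_index)),
            class = "wt_curve")
}

#' @export
print.wt_curve <- function(x, ...) {
  cat(sprintf("<wt_curve  frame %d, %d points, length %.1f px>\n",
              x$frame_index, nrow(x$points), curve_arc_length(x)))
  invisible(x)
}

curve_arc_length <- function(curve) {
  p <- curve$points
  if (nrow(p) < 2L) return(0)
  sum(sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2))
}

# cumulative arc position of each point
curve_arc_pos <- function(points) {
  c(0, cumsum(sqrt(diff(points[, 1L])^2 + diff(points[, 2L])^2)))
}

# Minimum distance from each of pts (n x 2) to the polyline poly (m x 2).
dist_to_polyline <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  n <- nrow(pts); m <- nrow(poly)
  if (m == 1L)
    return(sqrt((pts[, 1L] - poly[1L, 1L])^2 + (pts[, 2L] - poly[1L, 2L])^2))
  ax <- poly[-m, 1L]; ay <- poly[-m, 2L]
  ex <- poly[-1L, 1L] - ax; ey <- poly[-1L, 2L] - ay
  L2 <- pmax(ex^2 + ey^2, 1e-300)
  best <- rep(Inf, n)
  px <- pts[, 1L]; py <- pts[, 2L]
  for (j in seq_len(m - 1L)) {
    t <- ((px - ax[j]) * ex[j] + (py - ay[j]) * ey[j]) / L2[j]
    t[t < 0] <- 0; t[t > 1] <- 1
    d2 <- (ax[j] + t * ex[j] - px)^2 + (ay[j] + t * ey[j] - py)^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Per-step reliability tests
#'
#' Four tests guard each tracing step: (1) detector response at least
#' \code{min_score}; (2) left-right asymmetry
#' \code{|IL - IR| / (IL + IR)} of the two 20 x 1 px bands flanking the
#' detector at most \code{max_asymmetry}; (3) mean intensity over the
#' detector footprint at least \code{min_mean_intensity} x frame mean
#' (fails on large dark objects such as the stimulus pole); (4) angular
#' change from the previous step (mod 180, folded to <= 90 deg) at most
#' \code{max_angle_step_deg}.
#'
#' @param frame a \code{\link{wt_frame}} or matrix.
#' @param center sub-pixel detector centre \code{c(x, y)}.
#' @param params \code{\link{detector_params}} evaluated there.
#' @param score the detector response at \code{params}.
#' @param prev_angle_deg heading of the previous step.
#' @param thresholds a \code{\link{stop_tests}} object.
#' @param length_px detector length (default 20).
#' @return list with \code{ok} and \code{failed} (names among
#'   \code{"score"}, \code{"asymmetry"}, \code{"mean_intensity"},
#'   \code{"angle_step"}).
#' @export
step_tests <- function(frame, center, params, score, prev_angle_deg,
                       thresholds = stop_tests(), length_px = 20L) {
  frame <- as_frame(frame)
  ms <- resolve_min_score(thresholds, frame)
  r <- .wt_step_tests(frame$pixels, mean(frame$pixels), as.integer(length_px),
                      center[1L], center[2L], params$width, params$angle,
                      score, prev_angle_deg, ms, thresholds$max_asymmetry,
                      thresholds$min_mean_intensity,
                      thresholds$max_angle_step_deg)
  nm <- c("score", "asymmetry", "mean_intensity", "angle_step")
  list(ok = r[1L] == 1L, failed = nm[which(r[2:5] == 1L)])
}

#' Trace one curve from a seed
#'
#' Initializes the detector at the seed (angle from the seed, width by a
#' 1-D scan over all lattice widths, sub-pixel offset by one
#' optimization step), then extends bidirectionally in 1 px steps along
#' the running tangent, re-optimizing the detector and applying the stop
#' tests at every step.  When a test fails, up to \code{max_gap_px}
#' single-pixel probes continue along the last trusted direction; if the
#' tests pass at a probe the gap is bridged with a straight segment
#' (score 0) and tracing resumes, otherwise the curve is truncated at
#' the last trusted point.
#'
#' @param frame a \code{\link{wt_frame}} or matrix.
#' @param seed one row of \code{\link{find_seeds}} output (or a list
#'   with \code{x}, \code{y}, \code{angle_deg}).
#' @param bank a \code{\link{detector_bank}}.
#' @param thresholds a \code{\link{stop_tests}} object.
#' @return a \code{\link{wt_curve}}, or \code{NULL} if initialization
#'   fails or fewer than 2 points survive.
#' @export
trace_from_seed <- function(frame, seed, bank = detector_bank(),
                            thresholds = stop_tests()) {
  frame <- as_frame(frame)
  ms <- resolve_min_score(thresholds, frame)
  m <- .wt_trace(bank$ptr, frame$pixels, mean(frame$pixels),
                 as.numeric(seed$x), as.numeric(seed$y),
                 as.numeric(seed$angle_deg), ms, thresholds$max_asymmetry,
                 thresholds$min_mean_intensity, thresholds$max_angle_step_deg,
                 thresholds$max_gap_px)
  if (nrow(m) < 2L) return(NULL)
  wt_curve(m[, 1:2, drop = FALSE], m[, 3L], m[, 4L], frame$frame_index)
}

#' Discard redundant traces
#'
#' Different seeds can retrace the same whisker.  Pairs of candidate
#' duplicates are found by shared rasterized pixels; if a contiguous
#' interval of one curve lying within \code{dist_px} of the other covers
#' more than \code{frac} of its arc length, the pair is redundant and
#' the shorter curve (by arc length; ties: the later in input order) is
#' discarded.  Repeats until no redundancy remains.
#'
#' @param curves list of \code{\link{wt_curve}}.
#' @param dist_px distance bound (default 2 px).
#' @param frac fraction of arc length (default 0.5).
#' @return the surviving curves, in input order.
#' @export
remove_redundant <- function(curves, dist_px = 2, frac = 0.5) {
  if (dist_px <= 0) stop("dist_px must be > 0")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  alive <- rep(TRUE, length(curves))
  # rasterized pixels, dilated by one 4-neighbourhood so near-parallel
  # duplicates offset by ~1 px still collide
  raster <- lapply(curves, function(cv) {
    rx <- round(cv$points[, 1L]); ry <- round(cv$points[, 2L])
    unique(paste(c(rx, rx + 1L, rx - 1L, rx, rx),
                 c(ry, ry, ry, ry + 1L, ry - 1L)))
  })
  lens <- vapply(curves, curve_arc_length, 0)

  covered_frac <- function(a, b) {
    # largest contiguous run of a's points within dist_px of b, as a
    # fraction of a's arc length
    d <- dist_to_polyline(curves[[a]]$points, curves[[b]]$points)
    ok <- d <= dist_px
    if (!any(ok)) return(0)
    arc <- curve_arc_pos(curves[[a]]$points)
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    run <- max(arc[ends[r$values]] - arc[starts[r$values]])
    if (lens[a] <= 0) 0 else run / lens[a]
  }

  repeat {
    dropped <- FALSE
    idx <- which(alive)
    for (ii in seq_along(idx)) {
      a <- idx[ii]
      if (!alive[a]) next
      for (jj in seq_along(idx)[-seq_len(ii)]) {
        b <- idx[jj]
        if (!alive[a] || !alive[b]) next
        if (!any(raster[[a]] %in% raster[[b]])) next
        red <- covered_frac(a, b) > frac || covered_frac(b, a) > frac
        if (red) {
          loser <- if (lens[a] < lens[b]) a else if (lens[b] < lens[a]) b else max(a, b)
          alive[loser] <- FALSE
          dropped <- TRUE
        }
      }
    }
    if (!dropped) break
  }
  curves[alive]
}

#' Trace all whisker-like curves in one frame
#'
#' Finds seeds, consumes them in order of decreasing eccentricity --
#' skipping seeds within 1 px of already-traced curves -- traces a curve
#' from each, and resolves duplicates.  Deterministic for a fixed frame
#' and configuration; frames are independent (no temporal state).
#'
#' @param frame a \code{\link{wt_frame}} or matrix.
#' @param config a \code{\link{wt_config}}.
#' @param bank optional pre-built \code{\link{detector_bank}} (reusing
#'   one across frames avoids re-rasterizing stencils).
#' @return list of \code{\link{wt_curve}} (possibly empty).
#' @export
trace_frame <- function(frame, config = wt_config(), bank = NULL) {
  frame <- as_frame(frame)
  if (is.null(bank)) bank <- detector_bank(config$detector_length_px)
  seeds <- find_seeds(frame, config$grid_spacing_px, config$ecc_threshold)
  H <- nrow(frame$pixels); W <- ncol(frame$pixels)
  occupied <- matrix(FALSE, H, W)
  curves <- list()
  if (nrow(seeds)) {
    frame_mean <- mean(frame$pixels)
    ms <- resolve_min_score(config$thresholds, frame)
    for (i in seq_len(nrow(seeds))) {
      sx <- seeds$x[i]; sy <- seeds$y[i]
      if (occupied[sy + 1L, sx + 1L]) next
      m <- .wt_trace(bank$ptr, frame$pixels, frame_mean, sx, sy,
                     seeds$angle_deg[i], ms,
                     config$thresholds$max_asymmetry,
                     config$thresholds$min_mean_intensity,
                     config$thresholds$max_angle_step_deg,
                     config$thresholds$max_gap_px, occupied)
      if (nrow(m) < 2L) next
      curves[[length(curves) + 1L]] <-
        wt_curve(m[, 1:2, drop = FALSE], m[, 3L], m[, 4L], frame$frame_index)
      # mark pixels within ~1 px of the new curve
      rx <- round(m[, 1L]); ry <- round(m[, 2L])
      for (dx in -1:1) for (dy in -1:1) {
        qx <- rx + dx; qy <- ry + dy
        keep <- qx >= 0 & qx < W & qy >= 0 & qy < H
        occupied[cbind(qy[keep] + 1L, qx[keep] + 1L)] <- TRUE
      }
    }
  }
  remove_redundant(curves, config$dedup_dist_px, config$dedup_frac)
}
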