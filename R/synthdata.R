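# Ground-truthed synthetic videos: dark tapered whiskers silhouetted on
# a bright background, whisking in angle, plus distractor hairs, an
# occluding pole, sensor noise and the odd-line camera artifact.

#' Synthetic scene specification
#'
#' Defaults describe the package's standard benchmark world, a
#' scaled-down analog of a head-fixed single-row rig: 256 x 176 px at
#' 40 um/px (so a 150 px whisker is 6 mm), face on the left edge with
#' anterior up, four whiskers with 2-4 px bases tapering to sub-pixel
#' tips, correlated 15 Hz sinusoidal whisking of 12 deg amplitude
#' sampled at 500 fps, six short facial hairs, a 2.5 px radius pole in
#' the sweep of whisker 2, Gaussian sensor noise (sd 2), a 10 percent
#' left-right illumination gradient and an odd-line gain of 0.9.
#' Whisker 1 is the most posterior (largest y).
#'
#' Whisker shapes are quadratic Bezier curves in a face-anchored frame
#' rotated rigidly by the per-frame whisking angle; tangents and
#' curvature are therefore closed-form for measurement oracles.
#' Optional events: a fast angular transient (about 32 deg between
#' consecutive frames, matching the fastest motion such rigs observe at
#' 500 fps, 16 deg/ms) and an exit episode during which one whisker
#' leaves the field entirely.
#'
#' @param width,height image size, px.
#' @param n_whiskers number of whiskers (1..4 supported by defaults).
#' @param base_x whisker base column (all whiskers emerge near the
#'   face edge; single scalar).
#' @param base_y whisker base rows (posterior first).
#' @param length_px chord length of each whisker.
#' @param base_width_px,tip_width_px taper of the rendered width.
#' @param curl_px perpendicular Bezier control offset (intrinsic bend).
#' @param mean_angle_deg per-whisker mean angle from the lateral axis
#'   (protraction positive).
#' @param whisk_amp_deg,whisk_freq_hz,whisk_phase shared sinusoid; amps
#'   are scaled per whisker by \code{amp_factor}.
#' @param amp_factor per-whisker amplitude factors (correlated whisking).
#' @param fps video frame rate.
#' @param transient NULL or \code{list(whisker, frame, delta_deg)}: the
#'   angle offsets added on consecutive frames starting at \code{frame}.
#' @param exit NULL or \code{list(whisker, start, n_frames)}: the
#'   whisker is absent (out of field) for those frames.
#' @param hairs data.frame(x, y, angle_deg, length_px, width_px) of
#'   distractor facial hairs; NULL for the default six.
#' @param pole NULL or \code{list(center, radius)} dark disk occluder.
#' @param face_band_px width of the dark snout silhouette along the
#'   face edge (0 disables).  The silhouetted face is always present in
#'   this imaging configuration and is what terminates traces at the
#'   whisker base; it must be wider than the detector length for the
#'   mean-intensity stop test to engage, as on a real snout.
#' @param face_band_intensity its intensity.
#' @param noise_sd Gaussian sensor noise, intensity units.
#' @param odd_line_gain multiplicative gain applied to odd rows (the
#'   camera artifact; 1 = off).
#' @param illumination_gradient peak-to-peak left-right background
#'   slope, intensity units.
#' @param background,whisker_core,pole_intensity intensity levels.
#' @param pixel_size_um micrometres per pixel.
#' @param seed RNG seed for the noise (per-frame streams are derived
#'   from it, so any frame can be rendered independently).
#' @return list of class \code{wt_scene_spec}.
#' @export
scene_spec <- function(width = 256L, height = 176L,
                       n_whiskers = 4L,
                       base_x = 3,
                       base_y = c(146, 112, 78, 44),
                       length_px = c(152, 158, 155, 149),
                       base_width_px = c(3.5, 3, 2.5, 2),
                       tip_width_px = 0.05,
                       curl_px = c(10, 8, 9, 7),
                       mean_angle_deg = c(8, 4, 0, -4),
                       whisk_amp_deg = 12, whisk_freq_hz = 15,
                       whisk_phase = 0,
                       amp_factor = c(1, 0.95, 1.05, 0.9),
                       fps = 500,
                       transient = NULL,
                       exit = NULL,
                       hairs = NULL,
                       pole = NULL,
                       face_band_px = 24, face_band_intensity = 45,
                       noise_sd = 2,
                       odd_line_gain = 0.9,
                       illumination_gradient = 10,
                       background = 200, whisker_core = 40,
                       pole_intensity = 45,
                       pixel_size_um = 40,
                       seed = 1L) {
  n <- as.integer(n_whiskers)
  if (n < 0L) stop("n_whiskers must be >= 0")
  rep_n <- function(v) if (n == 0L) numeric(0) else rep_len(v, n)
  if (is.null(hairs)) {
    hairs <- data.frame(
      x = c(25, 26, 25, 27, 26, 25),
      y = c(150, 128, 100, 60, 50, 140),
      angle_deg = c(65, -60, 70, 55, -65, -55),
      length_px = c(18, 22, 26, 30, 20, 24),
      width_px = c(1, 0.9, 1.1, 1, 0.8, 1))
    hairs <- hairs[hairs$y < height - 6, , drop = FALSE]
  }
  spec <- structure(list(
    width = as.integer(width), height = as.integer(height),
    n_whiskers = n,
    base_x = base_x,
    base_y = rep_n(base_y), length_px = rep_n(length_px),
    base_width_px = rep_n(base_width_px), tip_width_px = tip_width_px,
    curl_px = rep_n(curl_px), mean_angle_deg = rep_n(mean_angle_deg),
    whisk_amp_deg = whisk_amp_deg, whisk_freq_hz = whisk_freq_hz,
    whisk_phase = whisk_phase, amp_factor = rep_n(amp_factor),
    fps = fps, transient = transient, exit = exit, hairs = hairs,
    pole = pole, face_band_px = face_band_px,
    face_band_intensity = face_band_intensity,
    noise_sd = noise_sd, odd_line_gain = odd_line_gain,
    illumination_gradient = illumination_gradient,
    background = background, whisker_core = whisker_core,
    pole_intensity = pole_intensity, pixel_size_um = pixel_size_um,
    seed = as.integer(seed)), class = "wt_scene_spec")
  # bases may lie outside the image (a whisker entering the field from
  # beyond the crop); rendering and truth are clipped identically
  spec
}

# per-frame whisking angles (deg) for all whiskers
whisker_angles <- function(spec, frame_index) {
  t <- frame_index / spec$fps
  th <- spec$mean_angle_deg +
    spec$whisk_amp_deg * spec$amp_factor *
      sin(2 * pi * spec$whisk_freq_hz * t + spec$whisk_phase)
  tr <- spec$transient
  if (!is.null(tr)) {
    k <- frame_index - tr$frame + 1L
    if (k >= 1L && k <= length(tr$delta_deg))
      th[tr$whisker] <- th[tr$whisker] + tr$delta_deg[k]
  }
  th
}

whisker_visible <- function(spec, frame_index) {
  v <- rep(TRUE, spec$n_whiskers)
  ex <- spec$exit
  if (!is.null(ex) && frame_index >= ex$start &&
      frame_index < ex$start + ex$n_frames) v[ex$whisker] <- FALSE
  v
}

# world-frame quadratic Bezier control points of whisker i at angle theta
whisker_bezier <- function(spec, i, theta_deg) {
  L <- spec$length_px[i]; c0 <- spec$curl_px[i]
  p0l <- c(0, 0); p1l <- c(0.5 * L, c0); p2l <- c(L, 0)
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)  # +x -> lateral tilted anterior
  base <- c(spec$base_x, spec$base_y[i])
  list(p0 = base + as.vector(R %*% p0l),
       p1 = base + as.vector(R %*% p1l),
       p2 = base + as.vector(R %*% p2l))
}

bezier_points <- function(bz, tt) {
  mt <- 1 - tt
  cbind(mt^2 * bz$p0[1] + 2 * tt * mt * bz$p1[1] + tt^2 * bz$p2[1],
        mt^2 * bz$p0[2] + 2 * tt * mt * bz$p1[2] + tt^2 * bz$p2[2])
}

bezier_tangent <- function(bz, tt) {
  cbind(2 * (1 - tt) * (bz$p1[1] - bz$p0[1]) + 2 * tt * (bz$p2[1] - bz$p1[1]),
        2 * (1 - tt) * (bz$p1[2] - bz$p0[2]) + 2 * tt * (bz$p2[2] - bz$p1[2]))
}

# signed curvature of the quadratic Bezier at parameter tt
bezier_curvature <- function(bz, tt) {
  d1 <- bezier_tangent(bz, tt)
  ax <- 2 * (bz$p2[1] - 2 * bz$p1[1] + bz$p0[1])
  ay <- 2 * (bz$p2[2] - 2 * bz$p1[2] + bz$p0[2])
  (d1[, 1] * ay - d1[, 2] * ax) / (d1[, 1]^2 + d1[, 2]^2)^1.5
}

render_curve_into <- function(canvas, pts, widths, amp_scale) {
  sigma <- pmax(widths / 2.355, 0.35)
  amp <- amp_scale * pmin(1, widths)
  .wt_render_curve(canvas, pts, sigma, amp)
  canvas
}

#' Render one synthetic frame with its ground truth
#'
#' Whiskers and hairs are drawn as anti-aliased dark curves with a
#' Gaussian cross-section whose width tapers from base to tip (the
#' attainable darkness scales with width below 1 px, so sub-pixel tips
#' fade out as real whisker tips do); the pole is a dark disk drawn over
#' everything; then Gaussian noise, the odd-line gain and 8-bit
#' quantization are applied.  The per-frame noise stream is derived from
#' \code{spec$seed} and the frame index, so rendering is independent of
#' call order and bitwise reproducible.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param frame_index frame number (0-based).
#' @return list with \code{frame} (a \code{\link{wt_frame}}) and
#'   \code{truth}: per-whisker id, visibility, backbone polyline sampled
#'   at ~0.5 px (clipped to the image), base angle (deg, lateral axis
#'   convention), Bezier control points, arc length, plus the hair table
#'   and pole.
#' @export
render_frame <- function(spec, frame_index = 0L) {
  W <- spec$width; H <- spec$height
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  bg <- spec$background +
    spec$illumination_gradient * (xs / max(1, W - 1) - 0.5)
  canvas <- matrix(0, H, W)
  th <- whisker_angles(spec, frame_index)
  vis <- whisker_visible(spec, frame_index)
  amp0 <- spec$background - spec$whisker_core
  whisk_truth <- list()
  for (i in seq_len(spec$n_whiskers)) {
    bz <- whisker_bezier(spec, i, th[i])
    nt <- max(8L, ceiling(2.5 * spec$length_px[i]))
    tt <- seq(0, 1, length.out = nt)
    pts <- bezier_points(bz, tt)
    widths <- spec$base_width_px[i] +
      (spec$tip_width_px - spec$base_width_px[i]) * tt
    if (vis[i])
      canvas <- render_curve_into(canvas, pts, widths, amp0)
    tan0 <- bezier_tangent(bz, 0)[1, ]
    base_angle <- atan2(-tan0[2], tan0[1]) * 180 / pi  # anterior-positive
    inside <- pts[, 1] >= 0 & pts[, 1] <= W - 1 &
              pts[, 2] >= 0 & pts[, 2] <= H - 1
    bt <- seq(0, 1, length.out = max(8L, ceiling(2 * spec$length_px[i])))
    bpts <- bezier_points(bz, bt)
    bin <- bpts[, 1] >= 0 & bpts[, 1] <= W - 1 &
           bpts[, 2] >= 0 & bpts[, 2] <= H - 1
    bkb <- bpts[bin, , drop = FALSE]
    # backbone points hidden by the snout silhouette or the pole are
    # rendered over and count as occluded in scoring
    vmask <- bkb[, 1] > spec$face_band_px
    if (!is.null(spec$pole))
      vmask <- vmask &
        sqrt((bkb[, 1] - spec$pole$center[1])^2 +
             (bkb[, 2] - spec$pole$center[2])^2) > spec$pole$radius + 0.5
    whisk_truth[[i]] <- list(
      id = i, visible = vis[i],
      backbone = bkb,
      visible_mask = vmask,
      t = bt[bin],
      widths = (spec$base_width_px[i] +
                (spec$tip_width_px - spec$base_width_px[i]) * bt)[bin],
      angle_deg = th[i], base_angle_deg = base_angle,
      bezier = bz,
      clipped = !all(inside))
  }
  hr <- spec$hairs
  for (k in seq_len(nrow(hr))) {
    a <- hr$angle_deg[k] * pi / 180
    L <- hr$length_px[k]
    tt <- seq(0, 1, length.out = max(4L, ceiling(2.5 * L)))
    pts <- cbind(hr$x[k] + tt * L * cos(a), hr$y[k] - tt * L * sin(a))
    widths <- rep(hr$width_px[k], length(tt)) * (1 - 0.5 * tt)  # slight taper
    canvas <- render_curve_into(canvas, pts, widths, amp0)
  }
  img <- bg - canvas
  if (spec$face_band_px > 0) {
    # dark snout silhouette along the face edge, with a soft 1 px border
    cov <- pmax(0, pmin(1, spec$face_band_px + 0.5 - xs))
    img <- img * (1 - cov) + spec$face_band_intensity * cov
  }
  if (!is.null(spec$pole)) {
    pc <- spec$pole$center; pr <- spec$pole$radius
    ys <- matrix(rep(0:(H - 1), W), H, W)
    d <- sqrt((xs - pc[1])^2 + (ys - pc[2])^2)
    cov <- pmin(1, pmax(0, pr + 0.5 - d))
    img <- img * (1 - cov) + spec$pole_intensity * cov
  }
  set.seed((spec$seed + 10007L * as.integer(frame_index)) %% 2147483629L)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
  if (spec$odd_line_gain != 1) {
    odd <- seq(2L, H, by = 2L)
    img[odd, ] <- img[odd, ] * spec$odd_line_gain
  }
  img[] <- round(pmin(pmax(img, 0), 255))
  list(frame = wt_frame(img, frame_index, spec$pixel_size_um),
       truth = list(frame_index = as.integer(frame_index),
                    whiskers = whisk_truth, hairs = hr, pole = spec$pole))
}

#' Render a benchmark video with ground truth
#'
#' Renders \code{n_frames} frames under the scene's motion model and, if
#' \code{dir} is given, writes a multi-page TIFF (\code{video.tif}), the
#' ground truth (\code{truth.json}) and the full spec including the seed
#' (\code{spec.json}) there.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param n_frames number of frames.
#' @param dir optional output directory (created if missing).
#' @return invisibly, list with \code{frames} (list of
#'   \code{\link{wt_frame}}) and \code{truth} (one entry per frame), and
#'   the file paths when written.
#' @export
make_benchmark <- function(spec, n_frames = 100L, dir = NULL) {
  out <- lapply(seq_len(n_frames) - 1L, function(i) render_frame(spec, i))
  frames <- lapply(out, `[[`, "frame")
  truth <- lapply(out, `[[`, "truth")
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    video_path <- file.path(dir, "video.tif")
    write_tiff(lapply(frames, `[[`, "pixels"), video_path)
    truth_path <- file.path(dir, "truth.json")
    write_truth(truth, truth_path)
    spec_path <- file.path(dir, "spec.json")
    jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    paths <- list(video = video_path, truth = truth_path, spec = spec_path)
  }
  invisible(list(frames = frames, truth = truth, paths = paths))
}

#' Render a straight anti-aliased line with a rectangular profile
#'
#' Test utility: draws a dark straight line of exact rectangular
#' cross-section (per-pixel coverage by exact area integrals) on a
#' uniform bright background -- the intensity model the line detector
#' assumes.
#'
#' @param height,width image size.
#' @param p0,p1 segment endpoints \code{c(x, y)}.
#' @param line_width width of the dark band, px.
#' @param bg,core background and line-core intensities.
#' @return an intensity matrix.
#' @export
render_line_image <- function(height, width, p0, p1, line_width = 2,
                              bg = 200, core = 40) {
  img <- matrix(bg, height, width)
  cov <- .wt_rect_coverage(p0[1], p0[2], p1[1], p1[2], line_width)
  keep <- cov$x >= 0 & cov$x < width & cov$y >= 0 & cov$y < height
  idx <- cbind(cov$y[keep] + 1L, cov$x[keep] + 1L)
  img[idx] <- img[idx] - (bg - core) * pmin(1, cov$area[keep])
  img
}


#' The standard linking benchmark scene
#'
#' The default \code{\link{scene_spec}} world plus the three stress
#' events the tracker must survive: a fast angular transient on whisker
#' 3 (35 deg between consecutive frames, i.e. ~17.5 deg/ms at 500 fps),
#' a 30-frame episode in which whisker 4 leaves the field, and a thin
#' pole (radius 2.5 px = 0.2 mm) placed on whisker 2's sweep so that it
#' occludes the whisker over part of each whisk cycle.
#'
#' @param seed RNG seed for the sensor noise.
#' @return a \code{\link{scene_spec}}.
#' @export
benchmark_spec <- function(seed = 1L) {
  base <- scene_spec(seed = seed)
  # pole on whisker 2's backbone at 65% arc, at a mildly protracted angle
  th <- base$mean_angle_deg[2] + 0.6 * base$whisk_amp_deg * base$amp_factor[2]
  bz <- whisker_bezier(base, 2, th)
  pc <- bezier_points(bz, 0.65)[1, ]
  scene_spec(seed = seed,
             transient = list(whisker = 3, frame = 700,
                              delta_deg = c(35, 4)),
             exit = list(whisker = 4, start = 1200, n_frames = 30),
             pole = list(center = round(pc, 1), radius = 2.5))
}
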