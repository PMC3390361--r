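# Kinematic measurement: parametric polynomial fits, curvature, angle
# at base, follicle extrapolation and pole-contact geometry.

#' Fit a parametric polynomial to a polyline
#'
#' Fits x(t) and y(t) independently by least squares, with t the
#' normalized cumulative chord length in [0, 1] (arc-length
#' parameterization keeps the curvature formula well conditioned).
#' On rank deficiency the degree is reduced with a message.
#'
#' @param points n x 2 matrix, n >= degree + 1.
#' @param degree polynomial degree (2, 3 and 5 are the degrees used by
#'   the pipeline; any >= 1 accepted).
#' @return object of class \code{wt_polyfit}: coefficients (ascending
#'   powers), degree, the parameter values used and the residual RMS.
#' @export
fit_parametric <- function(points, degree = 5L) {
  points <- as.matrix(points)
  n <- nrow(points)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (n < degree + 1L) stop("need at least degree + 1 points")
  arc <- curve_arc_pos(points)
  tot <- arc[n]
  tt <- if (tot > 0) arc / tot else seq(0, 1, length.out = n)
  d <- degree
  repeat {
    V <- outer(tt, 0:d, "^")
    qr_v <- qr(V)
    if (qr_v$rank == d + 1L || d == 1L) break
    d <- d - 1L
    message(sprintf("fit_parametric: rank deficient, reducing degree to %d", d))
  }
  cx <- qr.coef(qr_v, points[, 1L])
  cy <- qr.coef(qr_v, points[, 2L])
  res <- cbind(points[, 1L] - V %*% cx, points[, 2L] - V %*% cy)
  structure(list(coeffs_x = as.numeric(cx), coeffs_y = as.numeric(cy),
                 degree = d, t = tt, arc = arc,
                 residual_rms = sqrt(mean(res^2))),
            class = "wt_polyfit")
}

# evaluate fit (or its derivatives) at parameter values
polyfit_eval <- function(fit, tt, deriv = 0L) {
  d <- fit$degree
  ex <- fit$coeffs_x; ey <- fit$coeffs_y
  for (k in seq_len(deriv)) {
    pow <- seq_along(ex) - 1L
    ex <- (ex * pow)[-1L]; ey <- (ey * pow)[-1L]
    if (!length(ex)) return(cbind(rep(0, length(tt)), rep(0, length(tt))))
  }
  V <- outer(tt, seq_along(ex) - 1L, "^")
  cbind(V %*% ex, V %*% ey)
}

#' Signed curvature of a parametric polynomial
#'
#' \code{k(t) = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)} in units of
#' 1/px; positive when the curve bends counterclockwise in image
#' coordinates (x right, y down) for increasing t.
#'
#' @param poly a \code{\link{fit_parametric}} object.
#' @param t parameter value(s) in [0, 1].
#' @return curvature value(s).  An error is raised if the
#'   parameterization is degenerate (vanishing speed) at any t.
#' @export
curvature_at <- function(poly, t) {
  if (any(t < -1e-9 | t > 1 + 1e-9)) stop("t must lie in [0, 1]")
  d1 <- polyfit_eval(poly, t, 1L)
  d2 <- polyfit_eval(poly, t, 2L)
  sp2 <- d1[, 1L]^2 + d1[, 2L]^2
  if (any(sp2 < 1e-12)) stop("degenerate parameterization: vanishing speed")
  (d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]) / sp2^1.5
}

# -- internal geometry helpers ------------------------------------------

# Signed distance of points to the mask boundary; negative = inside the
# face.  For an edge mask the boundary is a line parallel to the face
# edge at mask_offset_px (right/bottom sides need the image extent); for
# a circle mask, the circle itself.
mask_signed_distance2 <- function(pts, face, width = NULL, height = NULL) {
  if (!is.null(face$mask)) {
    d <- sqrt((pts[, 1L] - face$mask$center[1L])^2 +
              (pts[, 2L] - face$mask$center[2L])^2)
    return(d - face$mask$radius)
  }
  off <- face$mask_offset_px
  switch(face$side,
         left = pts[, 1L] - off,
         right = (if (is.null(width)) stop("image width needed for side 'right'")
                  else (width - 1 - off) - pts[, 1L]),
         top = pts[, 2L] - off,
         bottom = (if (is.null(height)) stop("image height needed for side 'bottom'")
                   else (height - 1 - off) - pts[, 2L]))
}

# angle of a tangent vector in the face frame, degrees; 0 on the
# lateral axis, protraction (anterior) positive
face_angle <- function(tangent, face) {
  ax <- face_axes(face)
  tx <- sum(tangent * ax$lateral); ty <- sum(tangent * ax$anterior)
  atan2(ty, tx) * 180 / pi
}

# ensure curve runs face -> tip using the mask distance of its endpoints
orient_face_first <- function(points, face, width = NULL, height = NULL) {
  dends <- mask_signed_distance2(points[c(1L, nrow(points)), , drop = FALSE],
                                 face, width, height)
  if (dends[2L] < dends[1L]) points[rev(seq_len(nrow(points))), , drop = FALSE]
  else points
}

#' Measure one identified whisker
#'
#' Produces the kinematic record used for downstream analysis:
#' \enumerate{
#'   \item a degree-5 parametric fit of the traced midline;
#'   \item the reference point where the curve crosses the face mask
#'     (or the linear extrapolation of its face-side end to the mask --
#'     the follicle itself is not imaged);
#'   \item the interest point \code{interest_point_arc_mm} along the
#'     curve from the reference;
#'   \item curvature at the interest point from a degree-2 re-fit over a
#'     \code{window_mm} arc window about it (so shape outside the
#'     window cannot bias the measurement), converted to 1/mm;
#'   \item angle at base: tangent angle of the degree-5 fit at the
#'     reference, 0 deg on the lateral axis, protraction positive;
#'   \item follicle: linear extrapolation a fixed distance into the
#'     face; and, when a pole is given, the contact point -- the point
#'     closest to the pole centre on the curve or on a line extrapolated
#'     from its nearest end -- and its distance.
#' }
#'
#' The reference point, arc positions and window membership are taken
#' from the raw polyline so that distal perturbations cannot leak into
#' the windowed curvature; the polynomial fit smooths the tangent and
#' tip.  Reversing the input point order yields the same record.
#'
#' @param curve a \code{\link{wt_curve}} (>= 6 points).
#' @param face a \code{\link{wt_face_config}}.
#' @param pixel_size_um micrometres per pixel.
#' @param pole optional \code{list(center = c(x, y), radius = r)}.
#' @param label whisker label stored in the record.
#' @param image_size optional \code{c(width, height)} (needed for
#'   right/bottom face sides).
#' @return a one-row data.frame (class \code{wt_whisker_record});
#'   curvature is NA when the interest point lies beyond the curve.
#' @export
measure_whisker <- function(curve, face = wt_face_config(),
                            pixel_size_um = 40, pole = NULL,
                            label = "W1", image_size = NULL) {
  pts <- curve$points
  if (nrow(pts) < 6L) stop("need at least 6 points")
  wdt <- if (is.null(image_size)) NULL else image_size[1L]
  hgt <- if (is.null(image_size)) NULL else image_size[2L]
  pts <- orient_face_first(pts, face, wdt, hgt)
  arc <- curve_arc_pos(pts)
  total <- arc[length(arc)]
  px_per_mm <- 1000 / pixel_size_um
  fit <- fit_parametric(pts, 5L)

  # reference point: curve-mask intersection, or extrapolation of the
  # face-side end along its chord direction
  md <- mask_signed_distance2(pts, face, wdt, hgt)
  s_ref <- NA_real_; ref <- NULL
  cross <- which(md[-1L] >= 0 & md[-length(md)] < 0 |
                 md[-1L] < 0 & md[-length(md)] >= 0)
  if (md[1L] >= 0) {
    # face-side end short of the mask: extrapolate backwards
    dirv <- pts[1L, ] - pts[min(6L, nrow(pts)), ]
    nd <- sqrt(sum(dirv^2)); dirv <- dirv / max(nd, 1e-12)
    # step along dirv until the mask boundary (linear solve via bisection)
    f <- function(s) mask_signed_distance2(rbind(pts[1L, ] + s * dirv),
                                           face, wdt, hgt)
    s_hi <- 0
    while (f(s_hi) > 0 && s_hi < 1e4) s_hi <- s_hi + 5
    s_star <- if (s_hi <= 0 || f(s_hi) > 0) 0
              else uniroot(f, c(0, s_hi))$root
    ref <- pts[1L, ] + s_star * dirv
    s_ref <- -s_star
  } else if (length(cross)) {
    i <- cross[1L]
    t0 <- md[i] / (md[i] - md[i + 1L])
    ref <- pts[i, ] + t0 * (pts[i + 1L, ] - pts[i, ])
    s_ref <- arc[i] + t0 * (arc[i + 1L] - arc[i])
  } else {
    # whole curve inside the face (degenerate): reference at its start
    ref <- pts[1L, ]; s_ref <- 0
  }

  t_ref <- min(1, max(0, s_ref / max(total, 1e-12)))
  tan_ref <- polyfit_eval(fit, t_ref, 1L)[1L, ]
  # tangent pointing away from the face
  if (sum(tan_ref * (pts[nrow(pts), ] - pts[1L, ])) < 0) tan_ref <- -tan_ref
  angle_base <- face_angle(tan_ref, face)

  # follicle: straight extrapolation into the face
  foll <- ref - tan_ref / sqrt(sum(tan_ref^2)) * face$follicle_extrapolation_px

  # windowed curvature at the interest point
  s_int <- s_ref + face$interest_point_arc_mm * px_per_mm
  win <- face$window_mm * px_per_mm
  curv_mm <- NA_real_
  if (s_int <= total + 1e-9 && s_int >= 0) {
    inwin <- which(arc >= s_int - win / 2 & arc <= s_int + win / 2)
    if (length(inwin) >= 3L) {
      wpts <- pts[inwin, , drop = FALSE]
      wfit <- fit_parametric(wpts, 2L)
      warc <- arc[inwin]
      t_int <- (s_int - warc[1L]) / max(warc[length(warc)] - warc[1L], 1e-12)
      t_int <- min(1, max(0, t_int))
      curv_mm <- curvature_at(wfit, t_int) * px_per_mm
    }
  }

  tipp <- polyfit_eval(fit, 1, 0L)[1L, ]

  contact <- c(NA_real_, NA_real_); contact_dist <- NA_real_
  if (!is.null(pole)) {
    tt <- seq(0, 1, length.out = 1024L)
    cpts <- polyfit_eval(fit, tt, 0L)
    d <- sqrt((cpts[, 1L] - pole$center[1L])^2 +
              (cpts[, 2L] - pole$center[2L])^2)
    i0 <- which.min(d)
    best <- cpts[i0, ]; bestd <- d[i0]
    if (i0 == 1L || i0 == length(tt)) {
      # nearest point is an end: also consider the extrapolated tangent line
      tend <- if (i0 == 1L) 0 else 1
      e0 <- cpts[i0, ]
      ev <- polyfit_eval(fit, tend, 1L)[1L, ]
      ev <- ev / max(sqrt(sum(ev^2)), 1e-12)
      if (i0 == 1L) ev <- -ev          # extrapolate outward
      s <- sum((pole$center - e0) * ev)
      if (s > 0) {
        q <- e0 + s * ev
        dq <- sqrt(sum((pole$center - q)^2))
        if (dq < bestd) { best <- q; bestd <- dq }
      }
    }
    contact <- best; contact_dist <- bestd
  }

  rec <- data.frame(frame = curve$frame_index, label = label,
                    length_px = total,
                    angle_deg = angle_base,
                    curvature_per_mm = curv_mm,
                    follicle_x = foll[1L], follicle_y = foll[2L],
                    tip_x = tipp[1L], tip_y = tipp[2L],
                    score = mean(curve$scores),
                    contact_x = contact[1L], contact_y = contact[2L],
                    contact_dist_px = contact_dist,
                    stringsAsFactors = FALSE)
  class(rec) <- c("wt_whisker_record", class(rec))
  rec
}

#' Detect pole-contact episodes in a whisker time series
#'
#' Contact frames are those whose contact distance falls below the pole
#' radius plus a margin; episodes are maximal runs of contact frames.
#' The resting curvature is the median over non-contact frames, and
#' each episode reports its peak curvature change from rest.
#'
#' @param records data.frame of \code{\link{measure_whisker}} rows for
#'   one whisker, sorted by frame.
#' @param pole \code{list(center, radius)}.
#' @param margin_px extra contact distance margin (default 2).
#' @return data.frame with \code{start_frame}, \code{end_frame},
#'   \code{peak_delta_kappa}.  Errors if no non-contact frames exist
#'   (resting curvature undefined).
#' @export
contact_episodes <- function(records, pole, margin_px = 2) {
  if (is.unsorted(records$frame)) stop("records must be sorted by frame")
  thr <- pole$radius + margin_px
  contact <- !is.na(records$contact_dist_px) & records$contact_dist_px <= thr
  if (all(contact)) stop("no non-contact frames: resting curvature undefined")
  rest <- median(records$curvature_per_mm[!contact], na.rm = TRUE)
  if (!any(contact))
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      peak_delta_kappa = numeric(0)))
  r <- rle(contact)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    data.frame(start_frame = records$frame[starts[k]],
               end_frame = records$frame[ends[k]],
               peak_delta_kappa = max(abs(records$curvature_per_mm[i] - rest),
                                      na.rm = TRUE))
  })
  do.call(rbind, out)
}
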